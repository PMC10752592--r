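#' Partition a chromosome into consecutive SNP bins
#'
#' Bins are defined on SNP counts in file order (not genomic distance):
#' ceiling(m_i / B) consecutive bins of B SNPs, the last possibly short.
#'
#' @param m_i number of SNPs on the chromosome.
#' @param B bin size in SNPs (>= 2).
#' @param chromosome optional label.
#' @return list of class `block_partition`: `chromosome`, `bin_size`,
#'   `beta` (bin count), `boundaries` (data frame `start`, `end`, 1-based
#'   inclusive SNP indices), `n_diag`, `n_offdiag`.
#' @export
partition_blocks <- function(m_i, B = 250L, chromosome = NULL) {
  if (B < 2) stop("bin size must be at least 2 SNPs")
  if (m_i < 1) stop("empty chromosome")
  beta <- ceiling(m_i / B)
  start <- seq(1L, by = as.integer(B), length.out = beta)
  end <- pmin(start + as.integer(B) - 1L, as.integer(m_i))
  structure(list(chromosome = chromosome, bin_size = as.integer(B),
                 beta = as.integer(beta),
                 boundaries = data.frame(start = start, end = end),
                 n_diag = as.integer(beta),
                 n_offdiag = beta * (beta - 1) / 2),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("block_partition%s: %d SNPs/bin, %d diagonal and %s off-diagonal grids\n",
              if (is.null(x$chromosome)) "" else paste0(" [", x$chromosome, "]"),
              x$bin_size, x$n_diag, format(x$n_offdiag, big.mark = ",")))
  invisible(x)
}

#' High-resolution grid LD for one chromosome
#'
#' Computes the mean LD of every bin (diagonal grids, self-pairs included)
#' and of every bin pair (off-diagonal grids) from per-bin GRMs: each bin's
#' GRM is built once and pairs are combined in O(n^2) each. When the GRM
#' cache budget cannot hold all bins, bin GRMs are recomputed on demand;
#' results are bit-identical across budgets.
#'
#' @param Z a `standardized_matrix` restricted to the chromosome, columns in
#'   position order.
#' @param partition a `block_partition` for `ncol(Z$values)` SNPs.
#' @param cache_budget bytes available for cached bin GRMs (default: enough
#'   for all bins). Must fit at least two bin GRMs.
#' @return list of class `grid_result`: `partition`, `diag` (beta values),
#'   `offdiag` (data frame `u`, `v`, `value`, u < v).
#' @export
grid_ld_matrix <- function(Z, partition, cache_budget = Inf) {
  m_i <- ncol(Z$values)
  bounds <- partition$boundaries
  if (bounds$end[nrow(bounds)] != m_i)
    stop("partition does not cover the chromosome's SNPs")
  n <- nrow(Z$values)
  beta <- partition$beta
  grm_bytes <- 8 * n^2
  k_cache <- if (is.finite(cache_budget)) floor(cache_budget / grm_bytes) else beta
  if (k_cache < 2 && beta > 1) stop("cache budget smaller than two bin GRMs")
  make <- function(u) build_grm(Z, bounds$start[u]:bounds$end[u], label = u)
  if (k_cache >= beta) {
    grms <- lapply(seq_len(beta), make)
    getg <- function(u) grms[[u]]
  } else {
    getg <- make   # recompute on demand; identical arithmetic, identical bits
  }
  diag_vals <- numeric(beta)
  off <- NULL
  if (beta > 1) {
    pr <- utils::combn(beta, 2)
    off <- data.frame(u = pr[1, ], v = pr[2, ], value = NA_real_)
  }
  for (u in seq_len(beta)) {
    Ku <- getg(u)
    diag_vals[u] <- intra_ld(Ku)$value
    if (beta > 1) {
      vs <- which(off$u == u)
      for (r in vs) off$value[r] <- cross_moment(Ku, getg(off$v[r]))
    }
  }
  structure(list(partition = partition, diag = diag_vals, offdiag = off),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("grid_result: %d diagonal grids (mean %.4g), %d off-diagonal (mean %s)\n",
              length(x$diag), mean(x$diag),
              if (is.null(x$offdiag)) 0L else nrow(x$offdiag),
              if (is.null(x$offdiag)) "-" else sprintf("%.4g", mean(x$offdiag$value))))
  invisible(x)
}

#' Reassemble the chromosome mean LD from grid values
#'
#' Exact weighted reconstruction sum_u (m_u/m_i)^2 l_u +
#' 2 sum_{u<v} m_u m_v / m_i^2 l_uv, valid for unequal final bins.
#'
#' @param grid a `grid_result`.
#' @return scalar; equals the chromosome's [intra_ld()] value.
#' @export
grid_reconstruct_ld <- function(grid) {
  b <- grid$partition$boundaries
  mu <- b$end - b$start + 1L
  m_i <- sum(mu)
  val <- sum((mu / m_i)^2 * grid$diag)
  if (!is.null(grid$offdiag) && nrow(grid$offdiag))
    val <- val + 2 * sum(mu[grid$offdiag$u] * mu[grid$offdiag$v] / m_i^2 *
                           grid$offdiag$value)
  val
}

.snps_in_range <- function(snps, bp_range) {
  snps$pos >= bp_range[1] & snps$pos <= bp_range[2]
}

#' Mean LD of a named base-pair region
#'
#' Intra LD over exactly the SNPs whose positions fall in the 1-based
#' inclusive interval, e.g. an HLA cluster or a centromere.
#'
#' @param Z a `standardized_matrix` restricted to one chromosome.
#' @param bp_range numeric length-2 vector, 1-based inclusive.
#' @return An `ld_estimate`.
#' @export
region_mean_ld <- function(Z, bp_range) {
  sel <- .snps_in_range(Z$snps, bp_range)
  if (sum(sel) < 2) stop("fewer than 2 SNPs in the region")
  intra_ld(build_grm(Z, sel, label = sprintf("%d-%d", bp_range[1], bp_range[2])))
}

#' Chromosome mean LD with a region knocked out
#'
#' Intra LD of the chromosome excluding the SNPs in the interval; with an
#' empty interval this equals the chromosome estimate.
#'
#' @inheritParams region_mean_ld
#' @return An `ld_estimate`.
#' @export
region_knockout <- function(Z, bp_range) {
  sel <- !.snps_in_range(Z$snps, bp_range)
  if (sum(sel) < 2) stop("fewer than 2 SNPs remain after knockout")
  intra_ld(build_grm(Z, sel,
                     label = sprintf("ko:%d-%d", bp_range[1], bp_range[2])))
}
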