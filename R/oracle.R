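#' Explicit-loop recomputation of GRM off-diagonal moments
#'
#' Independent slow route for validating [grm_moments()]: enumerates the
#' n(n-1) ordered off-diagonal entries one by one.
#'
#' @param K a `grm` or symmetric matrix.
#' @return list with `mean_off`, `mean_off_sq`, `var_off`.
#' @export
oracle_grm_moments <- function(K) {
  M <- if (inherits(K, "grm")) K$matrix else K
  n <- nrow(M)
  s1 <- 0; s2 <- 0; cnt <- 0
  for (k1 in seq_len(n)) for (k2 in seq_len(n)) {
    if (k1 != k2) {
      s1 <- s1 + M[k1, k2]
      s2 <- s2 + M[k1, k2]^2
      cnt <- cnt + 1
    }
  }
  list(mean_off = s1 / cnt, mean_off_sq = s2 / cnt,
       var_off = s2 / cnt - (s1 / cnt)^2)
}

#' Explicit-loop recomputation of the GRM cross moment
#'
#' @param Ki,Kj `grm` objects or symmetric matrices of equal size.
#' @return scalar; validates [cross_moment()].
#' @export
oracle_cross_moment <- function(Ki, Kj) {
  Mi <- if (inherits(Ki, "grm")) Ki$matrix else Ki
  Mj <- if (inherits(Kj, "grm")) Kj$matrix else Kj
  n <- nrow(Mi)
  s <- 0; cnt <- 0
  for (k1 in seq_len(n)) for (k2 in seq_len(n)) {
    if (k1 != k2) { s <- s + Mi[k1, k2] * Mj[k1, k2]; cnt <- cnt + 1 }
  }
  s / cnt
}

# Pearson r^2 of two dosage columns by the explicit textbook formula
.pair_r2 <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- (n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2)
  if (den <= 0) stop("zero-variance dosage column in oracle pair")
  num^2 / den
}

#' Exhaustive pairwise-r2 oracle over genomic grids
#'
#' Brute-force counterpart of the GRM-moment estimators: computes the
#' sample r2 of every requested SNP pair by an explicit per-pair formula
#' and aggregates grid means with the self-pair (r2 = 1) convention for
#' intra grids. Grids are the chromosomes of `G`, or the bins of a
#' [partition_blocks()] when `blocks` is supplied (single-chromosome panel).
#'
#' @param G a complete [genotype_matrix()].
#' @param blocks optional `block_partition` covering `ncol(G$dosages)`.
#' @param max_pairs guard on the total pair count (the oracle is O(n)
#'   per pair).
#' @return list of class `oracle_report`: `pair_table` (data frame `snp_a`,
#'   `snp_b`, `grid_a`, `grid_b`, `r2`; unordered distinct pairs),
#'   `intra` (per-grid mean including self-pairs), `inter` (data frame
#'   `grid_i`, `grid_j`, `value`).
#' @export
brute_force_grid <- function(G, blocks = NULL, max_pairs = 1e7) {
  X <- G$dosages
  if (anyNA(X)) stop("complete panel required")
  m <- ncol(X)
  if (is.null(blocks)) {
    grid_of <- match(G$snps$chrom, unique(G$snps$chrom))
  } else {
    if (blocks$boundaries$end[blocks$beta] != m)
      stop("block partition does not cover the panel")
    grid_of <- rep(seq_len(blocks$beta),
                   blocks$boundaries$end - blocks$boundaries$start + 1L)
  }
  if (m * (m - 1) / 2 > max_pairs)
    stop("oracle pair count exceeds the guard; shrink the instance")
  pr <- utils::combn(m, 2)
  r2 <- vapply(seq_len(ncol(pr)),
               function(k) .pair_r2(X[, pr[1, k]], X[, pr[2, k]]),
               numeric(1))
  tab <- data.frame(snp_a = pr[1, ], snp_b = pr[2, ],
                    grid_a = grid_of[pr[1, ]], grid_b = grid_of[pr[2, ]],
                    r2 = r2)
  gids <- sort(unique(grid_of))
  m_g <- vapply(gids, function(g) sum(grid_of == g), numeric(1))
  intra <- vapply(seq_along(gids), function(i) {
    g <- gids[i]
    within <- tab$r2[tab$grid_a == g & tab$grid_b == g]
    (m_g[i] + 2 * sum(within)) / m_g[i]^2   # self-pairs contribute 1 each
  }, numeric(1))
  names(intra) <- gids
  inter <- NULL
  if (length(gids) > 1) {
    gp <- utils::combn(length(gids), 2)
    inter <- data.frame(
      grid_i = gids[gp[1, ]], grid_j = gids[gp[2, ]],
      value = vapply(seq_len(ncol(gp)), function(k) {
        gi <- gids[gp[1, k]]; gj <- gids[gp[2, k]]
        mean(tab$r2[tab$grid_a == gi & tab$grid_b == gj])
      }, numeric(1)))
  }
  structure(list(pair_table = tab, intra = intra, inter = inter),
            class = "oracle_report")
}

#' @export
print.oracle_report <- function(x, ...) {
  cat(sprintf("oracle_report: %d pairs, %d grids\n",
              nrow(x$pair_table), length(x$intra)))
  invisible(x)
}

#' Pair-level recomputation of the GRM-moment LD means
#'
#' Fully independent slow route for the grid estimators: standardizes
#' dosages inline and, for every SNP pair (l1, l2), accumulates
#' (a^2 - b) / (n(n-1)) with a = sum_k z_k,l1 z_k,l2 and
#' b = sum_k z_k,l1^2 z_k,l2^2 -- the exact per-pair decomposition of the
#' mean squared (or cross) off-diagonal GRM entry. Grid means match
#' [intra_ld()] / [cross_moment()] to floating-point accuracy without ever
#' forming a GRM.
#'
#' @inheritParams brute_force_grid
#' @param F_inbreeding inbreeding coefficient for the inline
#'   standardization.
#' @return list with `intra` (per-grid means, self-pairs included) and
#'   `inter` (data frame `grid_i`, `grid_j`, `value`).
#' @export
oracle_ld_means <- function(G, blocks = NULL, F_inbreeding = 0,
                            max_pairs = 1e7) {
  X <- G$dosages
  if (anyNA(X)) stop("complete panel required")
  n <- nrow(X); m <- ncol(X)
  if ((m * (m + 1)) / 2 > max_pairs)
    stop("oracle pair count exceeds the guard; shrink the instance")
  p <- colMeans(X) / 2
  if (any(p == 0 | p == 1)) stop("monomorphic SNP in oracle panel")
  Z <- sweep(X, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * (1 + F_inbreeding) * p * (1 - p)), "/")
  if (is.null(blocks)) {
    grid_of <- match(G$snps$chrom, unique(G$snps$chrom))
    gids <- unique(grid_of)
  } else {
    grid_of <- rep(seq_len(blocks$beta),
                   blocks$boundaries$end - blocks$boundaries$start + 1L)
    gids <- seq_len(blocks$beta)
  }
  ng <- length(gids)
  acc <- matrix(0, ng, ng)       # sums of per-pair contributions, both orders
  for (l1 in seq_len(m)) for (l2 in l1:m) {
    a <- sum(Z[, l1] * Z[, l2])
    b <- sum(Z[, l1]^2 * Z[, l2]^2)
    q <- (a^2 - b) / (n * (n - 1))
    gi <- grid_of[l1]; gj <- grid_of[l2]
    if (l1 == l2) {
      acc[gi, gj] <- acc[gi, gj] + q
    } else {
      acc[gi, gj] <- acc[gi, gj] + q
      acc[gj, gi] <- acc[gj, gi] + q
    }
  }
  m_g <- vapply(gids, function(g) sum(grid_of == g), numeric(1))
  intra <- diag(acc) / m_g^2
  names(intra) <- gids
  inter <- NULL
  if (ng > 1) {
    gp <- utils::combn(ng, 2)
    inter <- data.frame(grid_i = gids[gp[1, ]], grid_j = gids[gp[2, ]],
                        value = acc[cbind(gp[1, ], gp[2, ])] /
                          (m_g[gp[1, ]] * m_g[gp[2, ]]))
  }
  list(intra = intra, inter = inter)
}
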