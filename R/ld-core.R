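#' Mean intra-set LD from a GRM
#'
#' The mean squared Pearson correlation over all m^2 SNP pairs of the set
#' (self-pairs included, each contributing 1) equals the expected squared
#' off-diagonal GRM entry, so the estimator is the empirical mean of squared
#' off-diagonal entries -- O(n^2 m) overall instead of O(n m^2). The
#' standard error is the delta-method form 2 var(k_o) / sqrt(n (n-1)), with
#' var(k_o) the empirical off-diagonal variance.
#'
#' @param K a `grm` built from the SNP set.
#' @return list of class `ld_estimate`: `value`, `se`, `n`, `snp_count_i`,
#'   `snp_count_j` (equal for an intra estimate), `label`.
#' @export
intra_ld <- function(K) {
  mom <- grm_moments(K)
  n <- mom$n
  structure(list(value = mom$mean_off_sq,
                 se = 2 * mom$var_off / sqrt(n * (n - 1)),
                 n = n, snp_count_i = K$snp_count, snp_count_j = K$snp_count,
                 label = K$label),
            class = "ld_estimate")
}

#' @export
print.ld_estimate <- function(x, ...) {
  cat(sprintf("mean LD %s= %.6g (se %.3g), n = %d, m = %d%s\n",
              if (is.null(x$label)) "" else paste0("[", x$label, "] "),
              x$value, x$se, x$n, x$snp_count_i,
              if (x$snp_count_j != x$snp_count_i)
                sprintf(" x %d", x$snp_count_j) else ""))
  invisible(x)
}

#' Mean inter-set LD from two GRMs
#'
#' The mean squared correlation over the m_i x m_j cross pairs equals the
#' expected product of the two GRMs' matching off-diagonal entries. No
#' closed-form sampling variance is available for the unscaled statistic, so
#' the standard error is a seeded bootstrap over samples (resampled pairs
#' that collapse onto the same original individual are excluded, since they
#' correspond to diagonal entries).
#'
#' @param Ki,Kj `grm` objects over the same samples.
#' @param bootstrap number of bootstrap resamples (0 skips the SE).
#' @param seed seed for the bootstrap.
#' @return An `ld_estimate`; `se` is `NA` when `bootstrap = 0`.
#' @export
inter_ld <- function(Ki, Kj, bootstrap = 200L, seed = 1L) {
  value <- cross_moment(Ki, Kj)
  n <- Ki$n
  se <- NA_real_
  if (bootstrap > 0L) {
    P <- Ki$matrix * Kj$matrix
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
    reps <- vapply(seq_len(bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      S <- P[idx, idx]
      dup <- outer(idx, idx, "==")
      diag(dup) <- TRUE
      sum(S[!dup]) / sum(!dup)
    }, numeric(1))
    se <- stats::sd(reps)
  }
  structure(list(value = value, se = se, n = n,
                 snp_count_i = Ki$snp_count, snp_count_j = Kj$snp_count,
                 label = paste(Ki$label, Kj$label, sep = ".")),
            class = "ld_estimate")
}

#' Self-pair-adjusted intra LD
#'
#' Removes the m self-pairs (each with squared correlation 1) from a mean
#' intra LD: (m l - 1) / (m - 1). Equal to 1 when all SNPs are in perfect
#' LD and 0 when only the self-pairs contribute.
#'
#' @param l_i mean intra LD (self-pairs included).
#' @param m_i SNP count of the set (>= 2).
#' @return scalar.
#' @export
self_adjusted_ld <- function(l_i, m_i) {
  if (m_i < 2) stop("self-adjustment needs at least 2 SNPs")
  (m_i * l_i - 1) / (m_i - 1)
}

#' Scaled inter-chromosomal LD and its sampling variance
#'
#' The inter LD normalized by the geometric mean of the two self-adjusted
#' intra LDs: l_ij / sqrt(lt_i lt_j), a 0-1 index of extended LD. The
#' delta-method variance is
#' 2 v^2 / (n(n-1)) * (var_i var_j / cov^2 + cov^2 / (var_i var_j) - 2),
#' where cov = l_ij - 1/(n-1)^2 and var_i, var_j are the off-diagonal
#' variances of the two GRMs (default: the moment substitution
#' l_i - 1/(n-1)^2 recovered from the self-adjusted values).
#'
#' @param l_ij inter LD.
#' @param lt_i,lt_j self-adjusted intra LDs (must be positive).
#' @param n sample count.
#' @param m_i,m_j SNP counts (used to recover l_i for the default variances).
#' @param var_i,var_j optional empirical off-diagonal GRM variances.
#' @return list with `value` and `variance`.
#' @export
scaled_inter_ld <- function(l_ij, lt_i, lt_j, n, m_i = NULL, m_j = NULL,
                            var_i = NULL, var_j = NULL) {
  if (lt_i <= 0 || lt_j <= 0)
    stop("self-adjusted intra LD must be positive for scaling")
  value <- l_ij / sqrt(lt_i * lt_j)
  covij <- l_ij - 1 / (n - 1)^2
  if (is.null(var_i)) {
    if (is.null(m_i)) stop("supply var_i or m_i")
    var_i <- (lt_i * (m_i - 1) + 1) / m_i - 1 / (n - 1)^2
  }
  if (is.null(var_j)) {
    if (is.null(m_j)) stop("supply var_j or m_j")
    var_j <- (lt_j * (m_j - 1) + 1) / m_j - 1 / (n - 1)^2
  }
  ratio <- var_i * var_j / covij^2
  variance <- 2 * value^2 / (n * (n - 1)) * (ratio + 1 / ratio - 2)
  list(value = value, variance = variance)
}

#' Genome-wide mean LD from a chromosome partition
#'
#' Exact decomposition: with m = sum m_i,
#' l_g = sum_i (m_i/m)^2 l_i + sum_{i != j} (m_i m_j / m^2) l_ij
#' (both orderings of each pair). Because the whole-genome GRM is the
#' m_i/m-weighted sum of the chromosome GRMs, this is an algebraic identity
#' with the whole-genome intra estimate. The SE uses the moment substitution
#' var(k_go) = l_g - 1/(n-1)^2.
#'
#' @param partition an `ld_partition` from [ld_partition()], or a list with
#'   elements `intra` (data frame: `m`, `value`) and `inter` (data frame:
#'   `m_i`, `m_j`, `value`, one row per unordered pair) and `n`.
#' @return An `ld_estimate`.
#' @export
genome_ld <- function(partition) {
  intra <- partition$intra; inter <- partition$inter; n <- partition$n
  if (is.null(intra) || is.null(n)) stop("partition is missing components")
  m <- sum(intra$m)
  value <- sum((intra$m / m)^2 * intra$value)
  if (nrow(intra) > 1) {
    if (is.null(inter) || nrow(inter) != nrow(intra) * (nrow(intra) - 1) / 2)
      stop("partition is missing inter-chromosomal components")
    value <- value + 2 * sum(inter$m_i * inter$m_j / m^2 * inter$value)
  }
  var_kgo <- value - 1 / (n - 1)^2
  structure(list(value = value, se = 2 * var_kgo / sqrt(n * (n - 1)),
                 n = n, snp_count_i = m, snp_count_j = m, label = "genome"),
            class = "ld_estimate")
}

#' Chromosome-partitioned LD analysis
#'
#' Builds one GRM per chromosome and assembles every LD component: the C
#' intra estimates, the C(C-1)/2 inter estimates, the scaled inter values
#' with their variances, the genome-wide mean LD, and the top-eigenvalue
#' structure surrogate of the whole-genome GRM.
#'
#' @param Z a `standardized_matrix`.
#' @param bootstrap bootstrap resamples for inter-LD SEs (0 to skip).
#' @param seed bootstrap seed.
#' @return An object of class `ld_partition`: list with `chromosomes`
#'   (data frame `chrom`, `m`), `intra`, `inter`, `scaled` data frames,
#'   `genome` (`ld_estimate`), `lambda1`, `fst_proxy`, `n`, `m`.
#' @export
ld_partition <- function(Z, bootstrap = 200L, seed = 1L) {
  chroms <- unique(Z$snps$chrom)
  n <- nrow(Z$values)
  grms <- lapply(chroms, function(cc)
    build_grm(Z, Z$snps$chrom == cc, label = as.character(cc)))
  moms <- lapply(grms, grm_moments)
  m_i <- vapply(grms, function(k) k$snp_count, numeric(1))
  m <- sum(m_i)
  intra_est <- lapply(grms, intra_ld)
  intra <- data.frame(chrom = chroms, m = m_i,
                      value = vapply(intra_est, `[[`, numeric(1), "value"),
                      se = vapply(intra_est, `[[`, numeric(1), "se"))
  C <- length(chroms)
  inter <- scaled <- NULL
  if (C > 1) {
    pairs <- utils::combn(C, 2)
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      est <- inter_ld(grms[[i]], grms[[j]], bootstrap = bootstrap,
                      seed = seed + k)
      lt_i <- self_adjusted_ld(intra$value[i], m_i[i])
      lt_j <- self_adjusted_ld(intra$value[j], m_i[j])
      sc <- if (lt_i > 0 && lt_j > 0)
        scaled_inter_ld(est$value, lt_i, lt_j, n,
                        var_i = moms[[i]]$var_off, var_j = moms[[j]]$var_off)
      else list(value = NA_real_, variance = NA_real_)
      data.frame(chrom_i = chroms[i], chrom_j = chroms[j],
                 m_i = m_i[i], m_j = m_i[j],
                 value = est$value, se = est$se,
                 scaled = sc$value, scaled_var = sc$variance)
    })
    inter <- do.call(rbind, rows)
    scaled <- inter[, c("chrom_i", "chrom_j", "scaled", "scaled_var")]
    names(scaled)[3:4] <- c("value", "variance")
    inter <- inter[, c("chrom_i", "chrom_j", "m_i", "m_j", "value", "se")]
  }
  part <- list(chromosomes = data.frame(chrom = chroms, m = m_i),
               intra = intra, inter = inter, scaled = scaled,
               n = n, m = m)
  part$genome <- genome_ld(part)
  Kg <- Reduce(`+`, lapply(seq_len(C), function(i) m_i[i] / m * grms[[i]]$matrix))
  ev <- largest_eigenvalue(Kg)
  part$lambda1 <- ev$lambda1
  part$fst_proxy <- ev$fst_proxy
  class(part) <- "ld_partition"
  part
}

#' @export
print.ld_partition <- function(x, ...) {
  cat(sprintf("ld_partition: %d chromosomes, n = %d, m = %d\n",
              nrow(x$chromosomes), x$n, x$m))
  cat(sprintf("  genome mean LD: %.6g (se %.3g)\n", x$genome$value, x$genome$se))
  cat(sprintf("  mean intra: %.6g; mean inter: %s\n", mean(x$intra$value),
              if (is.null(x$inter)) "-" else sprintf("%.6g", mean(x$inter$value))))
  cat(sprintf("  lambda1 = %.4g (Fst proxy %.4g)\n", x$lambda1, x$fst_proxy))
  invisible(x)
}

#' Intra-chromosomal fraction of total mean LD
#'
#' C a / (C a + C (C-1) b) for mean intra LD a and mean inter LD b over C
#' chromosomes: the share of the total pairwise LD mass carried within
#' chromosomes, a lower bound on the proportion of "true" (linkage-driven)
#' LD. Both orderings of every chromosome pair are counted.
#'
#' @param mean_li mean of the C intra estimates.
#' @param mean_lij mean of the C(C-1)/2 inter estimates.
#' @param C chromosome count.
#' @return scalar in (0, 1].
#' @export
intra_fraction_summary <- function(mean_li, mean_lij, C = 22L) {
  stopifnot(mean_li > 0, mean_lij >= 0, C >= 2)
  den <- C * mean_li + C * (C - 1) * mean_lij
  if (den == 0) stop("zero denominator")
  C * mean_li / den
}

#' True-LD summary from the decay-regression intercept
#'
#' mean_li / (mean_li + b0): the share of intra-chromosomal LD not
#' attributable to the long-distance (between-segment) background estimated
#' by the decay-regression intercept.
#'
#' @param mean_li mean intra LD.
#' @param b0 decay-regression intercept.
#' @return scalar in (0, 1].
#' @export
true_ld_summary <- function(mean_li, b0) {
  den <- mean_li + b0
  if (den <= 0) stop("non-positive denominator")
  mean_li / den
}

#' Brute-force mean squared Pearson correlation of dosage columns
#'
#' The conventional O(n m_i m_j) estimator over the requested pair set,
#' used as the reference for reconciling the GRM-moment estimates: at the
#' no-LD limit the sample r2 averages about 1/n per pair whereas the
#' GRM-moment route averages the population value.
#'
#' @param G a complete [genotype_matrix()].
#' @param set_i,set_j column indices of the two SNP sets (defaults: all).
#'   Equal sets give an intra mean, distinct sets a cross mean.
#' @param include_self include the diagonal (self) pairs when the two sets
#'   are identical; self-pairs contribute r2 = 1.
#' @return scalar mean r2.
#' @export
plink_mean_r2 <- function(G, set_i = NULL, set_j = NULL, include_self = TRUE) {
  X <- G$dosages
  if (anyNA(X)) stop("complete genotypes required")
  if (is.null(set_i)) set_i <- seq_len(ncol(X))
  same <- is.null(set_j)
  if (same) set_j <- set_i else same <- identical(sort(set_i), sort(set_j))
  Xi <- X[, set_i, drop = FALSE]; Xj <- X[, set_j, drop = FALSE]
  if (any(apply(Xi, 2, stats::sd) == 0) || any(apply(Xj, 2, stats::sd) == 0))
    stop("zero-variance dosage column")
  R2 <- stats::cor(Xi, Xj)^2
  if (same && !include_self) {
    mean(R2[row(R2) != col(R2)])
  } else {
    mean(R2)
  }
}
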