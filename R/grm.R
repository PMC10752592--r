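#' Build a genetic relatedness matrix for a SNP set
#'
#' K = Z Z' / m over the selected standardized columns. The GRM's
#' off-diagonal second moments carry the mean LD of the SNP set; assumes
#' unrelated samples (pairwise relatedness 0).
#'
#' @param Z a `standardized_matrix` from [standardize_genotypes()].
#' @param snp_subset integer or logical index of columns (default: all).
#' @param label optional tag (e.g. chromosome code or block index).
#' @param chunk number of SNPs accumulated per dense multiply; results are
#'   identical across chunk sizes, only peak memory changes.
#' @return An object of class `grm`: list with `matrix` (n x n), `snp_count`,
#'   `label`, `n`.
#' @export
build_grm <- function(Z, snp_subset = NULL, label = NULL, chunk = 10000L) {
  V <- Z$values
  if (!is.null(snp_subset)) V <- V[, snp_subset, drop = FALSE]
  m <- ncol(V)
  if (m < 1L) stop("empty SNP subset")
  n <- nrow(V)
  if (m <= chunk) {
    K <- tcrossprod(V) / m
  } else {
    K <- matrix(0, n, n)
    starts <- seq(1L, m, by = chunk)
    for (s in starts) {
      e <- min(s + chunk - 1L, m)
      K <- K + tcrossprod(V[, s:e, drop = FALSE])
    }
    K <- K / m
  }
  structure(list(matrix = K, snp_count = m, label = label, n = n),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: n = %d, %d SNPs%s\n", x$n, x$snp_count,
              if (is.null(x$label)) "" else paste0(" [", x$label, "]")))
  invisible(x)
}

#' Off-diagonal and diagonal moments of a GRM
#'
#' Moments are taken over all n(n-1) ordered off-diagonal entries (ordered
#' and unordered means coincide for a symmetric matrix). The variance uses
#' the population convention (divide by the count), matching the direct
#' moment substitution used by the LD sampling-variance formulas.
#'
#' @param K a `grm` (or plain symmetric matrix).
#' @return list with `mean_off`, `mean_off_sq`, `var_off`, `diag`, `n`.
#' @export
grm_moments <- function(K) {
  M <- if (inherits(K, "grm")) K$matrix else K
  n <- nrow(M)
  if (n < 2L) stop("GRM moments need at least 2 samples")
  d <- diag(M)
  no <- n * (n - 1)
  mean_off <- (sum(M) - sum(d)) / no
  mean_off_sq <- (sum(M^2) - sum(d^2)) / no
  list(mean_off = mean_off, mean_off_sq = mean_off_sq,
       var_off = mean_off_sq - mean_off^2, diag = d, n = n)
}

#' Mean cross product of two GRMs' off-diagonal entries
#'
#' mean over ordered pairs k1 != k2 of (K_i)_{k1 k2} (K_j)_{k1 k2}; with
#' K_j = K_i this is `grm_moments(K_i)$mean_off_sq`.
#'
#' @param Ki,Kj `grm` objects over the same samples in the same order.
#' @return scalar.
#' @export
cross_moment <- function(Ki, Kj) {
  Mi <- if (inherits(Ki, "grm")) Ki$matrix else Ki
  Mj <- if (inherits(Kj, "grm")) Kj$matrix else Kj
  if (!all(dim(Mi) == dim(Mj))) stop("GRM shape mismatch")
  n <- nrow(Mi)
  (sum(Mi * Mj) - sum(diag(Mi) * diag(Mj))) / (n * (n - 1))
}

#' Top eigenvalue of a GRM and the population-structure surrogate
#'
#' The largest eigenvalue lambda_1 of a GRM grows with population
#' differentiation; lambda_1 / n approximates Fst. Uses a full symmetric
#' eigendecomposition for n <= `dense_limit` and power iteration (fixed
#' deterministic start, tolerance 1e-8, at most 1000 iterations) above.
#'
#' @param K a `grm` or symmetric matrix.
#' @param dense_limit switch-over size for the solver.
#' @return list with `lambda1` and `fst_proxy` (= lambda1 / n).
#' @export
largest_eigenvalue <- function(K, dense_limit = 4000L) {
  M <- if (inherits(K, "grm")) K$matrix else K
  if (any(!is.finite(M))) stop("GRM has non-finite entries")
  n <- nrow(M)
  if (n <= dense_limit) {
    l1 <- eigen(M, symmetric = TRUE, only.values = TRUE)$values[1]
  } else {
    v <- rep(1 / sqrt(n), n)
    l1 <- 0
    for (it in seq_len(1000L)) {
      w <- M %*% v
      nw <- sqrt(sum(w^2))
      if (nw == 0) break
      v_new <- as.numeric(w / nw)
      l1_new <- sum(v_new * (M %*% v_new))
      if (abs(l1_new - l1) < 1e-8 * max(1, abs(l1_new))) { l1 <- l1_new; break }
      l1 <- l1_new; v <- v_new
    }
  }
  list(lambda1 = l1, fst_proxy = l1 / n)
}

#' Export a GRM as lower-triangle TSV
#'
#' Columns: sample_i, sample_j, value, one row per unordered pair including
#' the diagonal.
#'
#' @param K a `grm`.
#' @param path output file.
#' @param samples optional sample identifiers.
#' @export
write_grm_tsv <- function(K, path, samples = NULL) {
  M <- K$matrix
  n <- nrow(M)
  if (is.null(samples)) samples <- paste0("s", seq_len(n))
  idx <- which(lower.tri(M, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(sample_i = samples[idx[, 1]], sample_j = samples[idx[, 2]],
                   value = M[idx])
  utils::write.table(format(df, digits = 17, trim = TRUE), path,
                     quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
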