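#' LD-decay regression of chromosomal LD on inverse SNP count
#'
#' Under a block-local LD genome (strong LD within short segments, weak
#' background between segments), the chromosomal mean LD is linear in the
#' inverse SNP count: l_i = b0 + b1 / m_i + e_i. The slope b1 is the
#' genome-wide LD-decay score (approximately the mean within-segment LD
#' times the segment size) and the intercept b0 is the long-distance LD
#' score (the mean between-segment LD). Fitted by ordinary least squares
#' via population moments (b1 = cov(x, l)/var(x)), which is identical to
#' the OLS normal equations; the fit is unweighted.
#'
#' @param l numeric vector of C chromosomal mean-LD estimates.
#' @param m integer vector of C SNP counts.
#' @return list of class `decay_fit`: `b0`, `b1`, `pearson_r`, `points`
#'   (data frame `chrom`, `m`, `x` = 1/m, `l`), `residuals`, `fitted`.
#' @export
fit_decay_regression <- function(l, m) {
  C <- length(l)
  stopifnot(length(m) == C)
  if (C < 3) stop("decay regression needs at least 3 chromosomes")
  if (any(m < 2)) stop("every chromosome needs at least 2 SNPs")
  x <- 1 / m
  if (stats::var(x) == 0) stop("all chromosomes have equal SNP counts")
  b1 <- stats::cov(x, l) / stats::var(x)
  b0 <- mean(l) - b1 * mean(x)
  fitted <- b0 + b1 * x
  structure(list(b0 = b0, b1 = b1, pearson_r = stats::cor(x, l),
                 points = data.frame(chrom = seq_len(C), m = m, x = x, l = l),
                 residuals = l - fitted, fitted = fitted),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit: b0 = %.6g (long-distance LD), b1 = %.6g (LD decay), R = %.4f, C = %d\n",
              x$b0, x$b1, x$pearson_r, nrow(x$points)))
  invisible(x)
}

#' Recover segment-level LD parameters from a decay fit
#'
#' Inverts the model expectations E(b1) = (E(l_u) - E(l_uv)) * m_seg and
#' E(b0) = E(l_uv): the mean between-segment LD is the intercept and the
#' mean within-segment (diagonal-grid) LD is b1 / m_seg + b0.
#'
#' @param fit a `decay_fit`.
#' @param segment_m assumed LD-segment size in SNPs.
#' @return list with `E_lu` (within-segment mean LD) and `E_luv`
#'   (between-segment mean LD).
#' @export
recover_segment_parameters <- function(fit, segment_m) {
  stopifnot(segment_m >= 1)
  list(E_lu = fit$b1 / segment_m + fit$b0, E_luv = fit$b0)
}

#' Leave-one-chromosome-out diagnostics for the decay regression
#'
#' Refits the regression with each chromosome dropped in turn and reports
#' the refit correlation and its change against the full fit; the largest
#' gain flags the chromosome most at odds with the linear norm (e.g. one
#' carrying a high-LD centromere).
#'
#' @inheritParams fit_decay_regression
#' @return data frame of class `loco_table`: `dropped`, `b0`, `b1`,
#'   `pearson_r`, `delta_r` (refit minus full-fit correlation).
#' @export
loco_analysis <- function(l, m) {
  C <- length(l)
  if (C < 4) stop("leave-one-out needs at least 4 chromosomes")
  full <- fit_decay_regression(l, m)
  rows <- lapply(seq_len(C), function(i) {
    f <- fit_decay_regression(l[-i], m[-i])
    data.frame(dropped = i, b0 = f$b0, b1 = f$b1, pearson_r = f$pearson_r,
               delta_r = f$pearson_r - full$pearson_r)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("loco_table", "data.frame")
  out
}
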