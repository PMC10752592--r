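#' Simulation configuration for synthetic genotype panels
#'
#' @param n sample count.
#' @param chromosomes data frame (or list coercible to one) with one row per
#'   chromosome: `m` (SNP count), `s` (LD-block size in SNPs), `r`
#'   (within-block genotype correlation, |r| < 1), and optionally
#'   `r_between` (cross-block genotype correlation within the chromosome,
#'   0 <= r_between <= r; default 0).
#' @param maf_range allele-frequency interval in (0, 0.5].
#' @param ld_model `"ar1"` draws haplotypes from a latent-Gaussian copula
#'   with AR(1) correlation `r` inside each block (qualitative block
#'   structure; the genotype-scale correlation is attenuated by the
#'   threshold transform). `"shared"` uses a core-sharing haplotype model
#'   whose pairwise genotype correlation is exactly `r` within a block and
#'   exactly `r_between` across blocks, at the cost of a single allele
#'   frequency per chromosome -- the calibrated choice for quantitative
#'   targets.
#' @param structure optional `list(n1, n2, fst)`: a two-subpopulation
#'   Balding-Nichols panel with subpopulation frequencies drawn from
#'   Beta(p (1-Fst)/Fst, q (1-Fst)/Fst) around an ancestral frequency p;
#'   SNPs are independent within subpopulations (LD then arises from the
#'   mixture itself).
#' @param admixture optional `list(a, b)`: with `structure`, individual
#'   ancestry proportions are drawn from Beta(a, b) and genotype
#'   frequencies are the ancestry-weighted mixture instead of a hard split.
#' @param seed integer seed; panels are bit-reproducible given the config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n, chromosomes, maf_range = c(0.05, 0.5),
                       ld_model = c("ar1", "shared"),
                       structure = NULL, admixture = NULL, seed = 1L) {
  ld_model <- match.arg(ld_model)
  chromosomes <- as.data.frame(chromosomes)
  if (is.null(chromosomes$r_between)) chromosomes$r_between <- 0
  stopifnot(all(abs(chromosomes$r) < 1), all(chromosomes$r_between >= 0),
            all(chromosomes$m >= 1), all(chromosomes$s >= 1))
  if (any(chromosomes$r_between > pmax(chromosomes$r, 0)))
    stop("r_between must not exceed r")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("infeasible maf_range")
  if (!is.null(structure)) {
    stopifnot(structure$fst > 0, structure$fst < 1,
              structure$n1 + structure$n2 == n)
  }
  if (!is.null(admixture) && is.null(structure))
    stop("admixture requires a structure spec")
  structure(list(n = as.integer(n), chromosomes = chromosomes,
                 maf_range = maf_range, ld_model = ld_model,
                 structure = structure, admixture = admixture,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# one chromosome of haplotypes under the AR(1) latent-Gaussian copula:
# nh x m matrix of 0/1 alleles
.sim_chrom_ar1 <- function(nh, m, s, r, p) {
  Z <- matrix(stats::rnorm(nh * m), nh, m)
  if (r != 0) {
    w <- sqrt(1 - r^2)
    for (l in 2:m) {
      if ((l - 1) %% s != 0)           # block boundary resets the chain
        Z[, l] <- r * Z[, l - 1] + w * Z[, l]
    }
  }
  (Z < rep(stats::qnorm(p), each = nh)) + 0L
}

# core-sharing haplotypes: allele copies a block core with prob sqrt(r);
# block cores copy a chromosome core with prob sqrt(r_between / r).
# Pairwise genotype correlation: exactly r within a block, r_between across.
.sim_chrom_shared <- function(nh, m, s, r, r_between, p) {
  phi <- sqrt(max(r, 0))
  psi <- if (r > 0) sqrt(r_between / r) else 0
  H <- matrix(0L, nh, m)
  D <- stats::rbinom(nh, 1L, p)
  n_blocks <- ceiling(m / s)
  for (b in seq_len(n_blocks)) {
    cols <- (((b - 1) * s + 1):min(b * s, m))
    J <- stats::rbinom(nh, 1L, psi)
    Cb <- ifelse(J == 1L, D, stats::rbinom(nh, 1L, p))
    I <- matrix(stats::rbinom(nh * length(cols), 1L, phi), nh)
    X <- matrix(stats::rbinom(nh * length(cols), 1L, p), nh)
    H[, cols] <- I * Cb + (1L - I) * X
  }
  H
}

#' Simulate a genotype panel with controlled LD architecture
#'
#' Homogeneous panels are sums of two independent haplotypes per individual
#' with block-local LD (see [sim_config()] for the two LD models).
#' Structured panels follow the Balding-Nichols model with independent SNPs.
#' Fully deterministic given the config (including its seed).
#'
#' @param cfg a [sim_config()].
#' @return A [genotype_matrix()]; SNP positions are 1000 bp apart within
#'   each chromosome.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  n <- cfg$n
  ch <- cfg$chromosomes
  blocks <- vector("list", nrow(ch))
  for (i in seq_len(nrow(ch))) {
    m <- ch$m[i]; s <- ch$s[i]; r <- ch$r[i]; rb <- ch$r_between[i]
    if (!is.null(cfg$structure)) {
      st <- cfg$structure
      p_anc <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
      shp <- (1 - st$fst) / st$fst
      p1 <- stats::rbeta(m, p_anc * shp, (1 - p_anc) * shp)
      p2 <- stats::rbeta(m, p_anc * shp, (1 - p_anc) * shp)
      if (!is.null(cfg$admixture)) {
        pi_k <- stats::rbeta(n, cfg$admixture$a, cfg$admixture$b)
        P <- outer(pi_k, p1) + outer(1 - pi_k, p2)
      } else {
        P <- rbind(matrix(p1, st$n1, m, byrow = TRUE),
                   matrix(p2, st$n2, m, byrow = TRUE))
      }
      G <- matrix(stats::rbinom(n * m, 2L, P), n, m)
    } else if (cfg$ld_model == "shared") {
      p <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
      G <- .sim_chrom_shared(n, m, s, r, rb, p) +
        .sim_chrom_shared(n, m, s, r, rb, p)
    } else {
      p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
      G <- .sim_chrom_ar1(n, m, s, r, p) + .sim_chrom_ar1(n, m, s, r, p)
    }
    blocks[[i]] <- G
  }
  dos <- do.call(cbind, blocks)
  snps <- do.call(rbind, lapply(seq_len(nrow(ch)), function(i)
    data.frame(id = sprintf("c%d_s%d", i, seq_len(ch$m[i])),
               chrom = i, pos = 1000L * seq_len(ch$m[i]),
               a1 = "A", a2 = "C", stringsAsFactors = FALSE)))
  genotype_matrix(dos, snps = snps)
}
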