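# fixtures are built in code; all sizes stay small enough for loop oracles

# homogeneous block-LD panel
sim_small_panel <- function(n = 60, m = c(50, 50), s = 10, r = 0.5, seed = 1,
                            ld_model = "ar1", r_between = 0) {
  cfg <- sim_config(n, data.frame(m = m, s = s, r = r, r_between = r_between),
                    ld_model = ld_model, seed = seed)
  simulate_panel(cfg)
}

# drop monomorphic columns so the panel can be standardized directly
drop_mono <- function(G) {
  af <- allele_frequencies(G)
  genotype_matrix(G$dosages[, !af$monomorphic, drop = FALSE],
                  G$samples, G$snps[!af$monomorphic, , drop = FALSE])
}

std_panel <- function(...) standardize_genotypes(drop_mono(sim_small_panel(...)))

# single-chromosome panel with a high-LD island: island columns are noisy
# copies of one template SNP, flanks are independent
make_island_panel <- function(n = 80, m = 100, island = 41:70, seed = 7,
                              flip = 0.1) {
  set.seed(seed)
  dos <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.5)[rep(1:m, each = n)]),
                n, m)
  template <- rbinom(n, 2, 0.4)
  for (j in island) {
    x <- template
    sw <- runif(n) < flip
    x[sw] <- rbinom(sum(sw), 2, 0.4)
    dos[, j] <- x
  }
  snps <- data.frame(id = paste0("snp", seq_len(m)), chrom = 1L,
                     pos = 1000L * seq_len(m), a1 = "A", a2 = "C",
                     stringsAsFactors = FALSE)
  drop_mono(genotype_matrix(dos, snps = snps))
}

# wrap a plain numeric matrix as a standardized_matrix (for algebra tests)
as_std <- function(V, chrom = 1L) {
  m <- ncol(V)
  structure(list(values = V, inbreeding_f = 0,
                 freqs = data.frame(p = rep(NA_real_, m)),
                 samples = paste0("s", seq_len(nrow(V))),
                 snps = data.frame(id = paste0("x", seq_len(m)),
                                   chrom = chrom, pos = 1000L * seq_len(m),
                                   a1 = "A", a2 = "C")),
            class = "standardized_matrix")
}
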