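test_that("intra LD is the mean squared off-diagonal GRM entry with the
           delta-method SE", {
  K <- structure(list(matrix = matrix(c(1, 0.5, 0.5, 1), 2), snp_count = 10L,
                      label = "x", n = 2L), class = "grm")
  est <- intra_ld(K)
  expect_equal(est$value, 0.25)
  mom <- grm_moments(K)
  expect_equal(est$se, 2 * mom$var_off / sqrt(2 * 1))
  expect_gte(est$se, 0)
  # value is a mean of squares, hence never negative
  Z <- std_panel(n = 30, m = c(40), seed = 10)
  expect_gte(intra_ld(build_grm(Z))$value, 0)
})

test_that("inter LD reduces to intra for identical sets and vanishes for
           independent chromosomes", {
  Z <- std_panel(n = 60, m = c(40, 40), s = 8, r = 0.5, seed = 2)
  K1 <- build_grm(Z, Z$snps$chrom == 1, label = "1")
  expect_equal(inter_ld(K1, K1, bootstrap = 0)$value, intra_ld(K1)$value)

  Zi <- std_panel(n = 300, m = c(60, 60), s = 10, r = 0, seed = 4)
  Ka <- build_grm(Zi, Zi$snps$chrom == 1, label = "1")
  Kb <- build_grm(Zi, Zi$snps$chrom == 2, label = "2")
  est <- inter_ld(Ka, Kb, bootstrap = 100, seed = 5)
  expect_lt(abs(est$value), 3 * est$se)
  expect_error(inter_ld(Ka, build_grm(std_panel(n = 10, m = 20, seed = 1)),
                        bootstrap = 0), "mismatch")
})

test_that("self-pair adjustment has the right fixed points and arithmetic", {
  expect_equal(self_adjusted_ld(1, 5000), 1)
  expect_equal(self_adjusted_ld(0.5, 2), 0)
  expect_equal(self_adjusted_ld(1.1e-3, 136000), (136000 * 1.1e-3 - 1) / 135999)
  expect_equal(self_adjusted_ld(1.1e-3, 136000), 1.0927e-3, tolerance = 1e-4)
  expect_error(self_adjusted_ld(0.5, 1), "at least 2")
})

test_that("scaled inter LD uses the geometric-mean normalization and its
           variance vanishes at the degenerate point", {
  sc <- scaled_inter_ld(sqrt(2e-3 * 3e-3), 2e-3, 3e-3, n = 100,
                        m_i = 1000, m_j = 1000)
  expect_equal(sc$value, 1)
  # var_i var_j = cov^2 makes the delta-method bracket collapse to zero
  n <- 100
  covij <- 1.0e-4 - 1 / (n - 1)^2
  sc0 <- scaled_inter_ld(1.0e-4, 1.1e-3, 1.1e-3, n = n,
                         var_i = abs(covij), var_j = abs(covij))
  expect_equal(sc0$variance, 0)
  expect_gte(scaled_inter_ld(1e-4, 1.1e-3, 1.1e-3, n = n, m_i = 1e5,
                             m_j = 1e5)$variance, 0)
  expect_error(scaled_inter_ld(1e-4, -1e-3, 1e-3, 100), "positive")
})

test_that("genome LD reproduces trivial partitions and the whole-genome GRM
           identity", {
  one <- list(intra = data.frame(m = 100, value = 0.01), inter = NULL, n = 50)
  expect_equal(genome_ld(one)$value, 0.01)

  two <- list(intra = data.frame(m = c(100, 100), value = c(0.01, 0.01)),
              inter = data.frame(m_i = 100, m_j = 100, value = 0.001),
              n = 50)
  expect_equal(genome_ld(two)$value, 0.0055)

  Z <- std_panel(n = 50, m = c(30, 40, 25, 35), s = 10, r = 0.4, seed = 3)
  part <- ld_partition(Z, bootstrap = 0)
  whole <- intra_ld(build_grm(Z, label = "g"))
  expect_equal(part$genome$value, whole$value, tolerance = 1e-10)
  expect_error(genome_ld(list(intra = part$intra, inter = NULL, n = 50)),
               "missing inter")
})

test_that("summary ratios reproduce their closed forms", {
  expect_equal(intra_fraction_summary(1e-3, 0, 22), 1)
  expect_equal(true_ld_summary(1e-3, 0), 1)
  # spot values checked against independent arithmetic
  a <- 9.3e-4; b <- 9.5e-5
  expect_equal(intra_fraction_summary(a, b, 22),
               (22 * a) / (22 * a + 22 * 21 * b))
  expect_error(intra_fraction_summary(0, 0, 22), ">")
  expect_error(true_ld_summary(1e-3, -1e-3), "denominator")
})

test_that("brute-force mean r2 matches hand-computed Pearson correlations", {
  G <- genotype_matrix(cbind(c(0L, 1L, 2L, 1L, 0L),
                             c(0L, 1L, 2L, 1L, 0L),
                             c(2L, 1L, 0L, 1L, 2L),
                             c(0L, 2L, 1L, 1L, 1L)))
  # duplicated SNP pair
  expect_equal(plink_mean_r2(G, 1:2, include_self = FALSE), 1)
  # 3-SNP fixture: mean of the three pairwise r2, computed longhand
  r2 <- function(x, y) {
    n <- length(x)
    (n * sum(x * y) - sum(x) * sum(y))^2 /
      ((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  }
  X <- G$dosages
  manual <- mean(c(r2(X[, 1], X[, 3]), r2(X[, 1], X[, 4]), r2(X[, 3], X[, 4])))
  expect_equal(plink_mean_r2(G, c(1, 3, 4), include_self = FALSE), manual)
  # self-pairs add (m + off-pairs)/m^2
  with_self <- plink_mean_r2(G, c(1, 3, 4), include_self = TRUE)
  expect_equal(with_self, (3 + 6 * manual) / 9)
  expect_error(plink_mean_r2(genotype_matrix(cbind(rep(1L, 4), c(0L, 1L, 2L, 1L)))),
               "zero-variance")
})

test_that("chromosome partition assembles all components coherently", {
  Z <- std_panel(n = 40, m = c(30, 25, 20), s = 5, r = 0.5, seed = 8)
  part <- ld_partition(Z, bootstrap = 10, seed = 2)
  expect_equal(nrow(part$intra), 3)
  expect_equal(nrow(part$inter), 3)
  expect_equal(nrow(part$scaled), 3)
  expect_true(all(part$intra$value >= 0))
  expect_true(all(is.finite(part$inter$se)))
  # scaled values recompute from their parts
  lt <- self_adjusted_ld(part$intra$value[1], part$intra$m[1])
  lt2 <- self_adjusted_ld(part$intra$value[2], part$intra$m[2])
  expect_equal(part$scaled$value[1],
               part$inter$value[1] / sqrt(lt * lt2))
  expect_true(part$lambda1 >= 0 && part$fst_proxy == part$lambda1 / 40)
})
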