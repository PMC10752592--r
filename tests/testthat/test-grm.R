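test_that("GRM is the scaled cross product of standardized columns", {
  Z1 <- as_std(matrix(c(1, -1), 2, 1))
  expect_equal(build_grm(Z1)$matrix, matrix(c(1, -1, -1, 1), 2))

  set.seed(4)
  V <- matrix(rnorm(5 * 8), 5, 8)
  K <- build_grm(as_std(V))$matrix
  manual <- matrix(0, 5, 5)
  for (k1 in 1:5) for (k2 in 1:5)
    manual[k1, k2] <- sum(V[k1, ] * V[k2, ]) / 8
  expect_lt(max(abs(K - manual)), 1e-12)
  expect_lt(max(abs(K - t(K))), 1e-12)

  # chunked accumulation gives the same matrix
  expect_equal(build_grm(as_std(V), chunk = 3L)$matrix, K)
  expect_error(build_grm(as_std(V), integer(0)), "empty")
})

test_that("data-standardized GRM rows sum to zero and the diagonal fixes the
           off-diagonal mean exactly", {
  Z <- std_panel(n = 50, m = c(60), seed = 6)
  K <- build_grm(Z)
  n <- K$n
  expect_lt(max(abs(rowSums(K$matrix))), 1e-9 * n)
  mom <- grm_moments(K)
  # zero row sums make mean_off = -mean(diag)/(n-1), an exact identity
  expect_equal(mom$mean_off, -mean(mom$diag) / (n - 1), tolerance = 1e-12)
})

test_that("GRM moments match hand values and the explicit-loop oracle", {
  mom <- grm_moments(matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(mom$mean_off_sq, 0.25)
  expect_equal(mom$mean_off, 0.5)

  id4 <- grm_moments(diag(4))
  expect_equal(id4$mean_off, 0)
  expect_equal(id4$mean_off_sq, 0)
  expect_equal(id4$var_off, 0)

  set.seed(11)
  A <- crossprod(matrix(rnorm(36), 6))
  fast <- grm_moments(A)
  slow <- oracle_grm_moments(A)
  expect_equal(fast$mean_off, slow$mean_off, tolerance = 1e-12)
  expect_equal(fast$mean_off_sq, slow$mean_off_sq, tolerance = 1e-12)
  expect_equal(fast$var_off, slow$var_off, tolerance = 1e-12)
  expect_error(grm_moments(matrix(1, 1, 1)), "2 samples")
})

test_that("cross moments agree with self-moments, identity GRMs and the loop
           oracle", {
  set.seed(12)
  A <- crossprod(matrix(rnorm(36), 6))
  B <- crossprod(matrix(rnorm(36), 6))
  expect_equal(cross_moment(A, A), grm_moments(A)$mean_off_sq)
  expect_equal(cross_moment(A, diag(6)), 0)
  expect_equal(cross_moment(A, B), oracle_cross_moment(A, B),
               tolerance = 1e-12)
  expect_error(cross_moment(A, diag(5)), "mismatch")
})

test_that("the GRM cross-product sum equals the Frobenius route through the
           standardized columns", {
  Z <- std_panel(n = 40, m = c(30, 25), seed = 9)
  i <- Z$snps$chrom == 1; j <- Z$snps$chrom == 2
  Ki <- build_grm(Z, i); Kj <- build_grm(Z, j)
  lhs <- sum(Ki$matrix * Kj$matrix)
  rhs <- sum(crossprod(Z$values[, i], Z$values[, j])^2) /
    (Ki$snp_count * Kj$snp_count)
  expect_equal(lhs, rhs, tolerance = 1e-9 * abs(rhs))
})

test_that("top eigenvalue and Fst proxy behave on identities and match the
           dense solver under power iteration", {
  ev <- largest_eigenvalue(diag(10))
  expect_equal(ev$lambda1, 1)
  expect_equal(ev$fst_proxy, 0.1)

  set.seed(13)
  A <- crossprod(matrix(rnorm(20 * 20), 20)) / 20
  dense <- largest_eigenvalue(A)$lambda1
  power <- largest_eigenvalue(A, dense_limit = 2L)$lambda1
  expect_equal(power, dense, tolerance = 1e-6)
  expect_gte(dense, mean(diag(A)))
  A[1, 1] <- NaN
  expect_error(largest_eigenvalue(A), "non-finite")
})

test_that("adding a structured SNP set never decreases the top eigenvalue", {
  for (seed in 1:5) {
    base <- sim_small_panel(n = 80, m = c(150), s = 10, r = 0, seed = seed)
    cfg <- sim_config(80, data.frame(m = 150, s = 1, r = 0),
                      structure = list(n1 = 40, n2 = 40, fst = 0.15),
                      seed = seed + 100)
    extra <- simulate_panel(cfg)
    dos <- cbind(base$dosages, extra$dosages)
    snps <- rbind(base$snps, transform(extra$snps, chrom = 2L,
                                       id = paste0("st_", id)))
    both <- drop_mono(genotype_matrix(dos, base$samples, snps))
    l1_both <- largest_eigenvalue(build_grm(standardize_genotypes(both)))$lambda1
    l1_base <- largest_eigenvalue(
      build_grm(standardize_genotypes(drop_mono(base))))$lambda1
    expect_gte(l1_both, l1_base - 1e-8)
  }
})

test_that("GRM text export writes the full lower triangle", {
  Z <- std_panel(n = 8, m = c(10), seed = 1)
  K <- build_grm(Z)
  tmp <- tempfile(fileext = ".tsv")
  write_grm_tsv(K, tmp, samples = Z$samples)
  tab <- read.delim(tmp)
  expect_equal(nrow(tab), 8 * 9 / 2)
  expect_equal(tab$value[1], K$matrix[1, 1], tolerance = 1e-15)
})
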