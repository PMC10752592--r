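test_that("bed codes decode to dosages and missing calls", {
  # bytes pack 4 samples, sample 1 in the two lowest bits:
  # codes 00 -> 0 copies of a2, 10 -> 1, 11 -> 2, 01 -> missing
  tmp <- tempfile()
  con <- file(paste0(tmp, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  # 3 samples, 2 SNPs: snp1 codes (00, 11, 10), snp2 codes (01, 00, 11)
  writeBin(as.raw(c(0x00 + 0x0c + 0x20, 0x01 + 0x00 + 0x30)), con)
  close(con)
  writeLines(c("1\trs1\t0\t100\tA\tC", "1\trs2\t0\t200\tG\tT"),
             paste0(tmp, ".bim"))
  writeLines(paste("f", 1:3, "0 0 0 -9"), paste0(tmp, ".fam"))
  G <- read_plink(tmp)
  expect_equal(unname(G$dosages[, 1]), c(0L, 2L, 1L))
  expect_equal(unname(G$dosages[, 2]), c(NA_integer_, 0L, 2L))
  expect_equal(G$snps$pos, c(100L, 200L))
})

test_that("malformed bed files are rejected", {
  tmp <- tempfile()
  writeBin(as.raw(c(0xde, 0xad, 0x01, 0x00)), paste0(tmp, ".bed"))
  writeLines("1\trs1\t0\t1\tA\tC", paste0(tmp, ".bim"))
  writeLines("f1 f1 0 0 0 -9", paste0(tmp, ".fam"))
  expect_error(read_plink(tmp), "magic")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), paste0(tmp, ".bed"))  # truncated body
  expect_error(read_plink(tmp), "length")
})

test_that("write_plink / read_plink round-trips panels with missing calls", {
  G <- sim_small_panel(n = 13, m = c(20, 15), seed = 5)
  dos <- G$dosages
  dos[cbind(c(1, 5, 13), c(2, 7, 30))] <- NA
  G <- genotype_matrix(dos, G$samples, G$snps)
  tmp <- tempfile()
  write_plink(G, tmp)
  expect_equal(file.size(paste0(tmp, ".bed")), 3 + ceiling(13 / 4) * 35)
  G2 <- read_plink(tmp)
  expect_identical(unname(G2$dosages), unname(G$dosages))
  expect_equal(G2$snps$chrom, G$snps$chrom)
  expect_equal(G2$snps$pos, G$snps$pos)
})

test_that("quality control filters MAF, missingness and monomorphic SNPs", {
  n <- 20
  dos <- matrix(1L, n, 10)
  dos[, 1:5] <- rbind(matrix(0L, 10, 5), matrix(2L, 10, 5))  # maf 0.5, complete
  for (j in 6:8) dos[, j] <- c(1L, rep(0L, n - 1))            # maf 0.025
  for (j in 9:10) {                                           # 25% missing
    dos[, j] <- rep(c(0L, 2L), n / 2)
    dos[1:5, j] <- NA
  }
  G <- genotype_matrix(dos)
  kept <- apply_qc(G, maf_min = 0.05, miss_max = 0.2)
  expect_equal(ncol(kept$dosages), 5)
  expect_equal(kept$snps$id, paste0("snp", 1:5))
  # idempotent
  expect_identical(apply_qc(kept, 0.05, 0.2)$dosages, kept$dosages)
  # monomorphic SNPs go even when thresholds are slack
  dos2 <- cbind(dos[, 1:5], matrix(2L, n, 1))
  expect_equal(ncol(apply_qc(genotype_matrix(dos2), 0, 1)$dosages), 5)
  expect_error(apply_qc(genotype_matrix(matrix(2L, n, 2)), 0.05, 0.2),
               "every SNP")
})

test_that("HWE imputation is seeded, leaves observed calls alone, and
           respects degenerate frequencies", {
  G <- sim_small_panel(n = 40, m = c(30), seed = 2)
  expect_identical(impute_missing_hwe(G, seed = 9)$dosages, G$dosages)

  dos <- G$dosages
  miss <- matrix(runif(length(dos)) < 0.1, nrow(dos))
  dos[miss] <- NA
  Gm <- genotype_matrix(dos, G$samples, G$snps)
  a <- impute_missing_hwe(Gm, seed = 11)
  b <- impute_missing_hwe(Gm, seed = 11)
  d <- impute_missing_hwe(Gm, seed = 12)
  expect_identical(a$dosages, b$dosages)
  expect_false(anyNA(a$dosages))
  expect_identical(a$dosages[!miss], Gm$dosages[!miss])
  expect_identical(d$dosages[!miss], Gm$dosages[!miss])

  # p-hat = 1 forces dosage 2
  dos1 <- cbind(c(NA, rep(2L, 9)))
  G1 <- genotype_matrix(dos1)
  expect_equal(impute_missing_hwe(G1, seed = 1)$dosages[1, 1], 2L)
  expect_error(impute_missing_hwe(genotype_matrix(cbind(rep(NA_integer_, 4)))),
               "snp1")
})

test_that("imputed draws follow the Hardy-Weinberg genotype distribution", {
  n_miss <- 10000
  col <- c(rep(c(0L, 2L), 25), rep(NA_integer_, n_miss))  # p-hat = 0.5
  G <- genotype_matrix(cbind(col))
  imp <- impute_missing_hwe(G, seed = 42)$dosages[51:(50 + n_miss), 1]
  se <- sqrt(2 * 0.5 * 0.5 / n_miss)
  expect_lt(abs(mean(imp) - 1), 3 * se)
})

test_that("allele frequencies match a direct per-column computation", {
  expect_equal(allele_frequencies(genotype_matrix(cbind(c(0L, 1L, 2L))))$p, 0.5)
  af1 <- allele_frequencies(genotype_matrix(cbind(rep(2L, 5))))
  expect_equal(af1$p, 1)
  expect_true(af1$monomorphic)
  G <- sim_small_panel(n = 100, m = c(50), seed = 8)
  manual <- vapply(seq_len(50), function(j) sum(G$dosages[, j]) / (2 * 100),
                   numeric(1))
  expect_equal(allele_frequencies(G)$p, manual)
})

test_that("standardization matches the inbreeding-aware formula and centers
           columns", {
  G <- genotype_matrix(cbind(c(0L, 1L, 2L)))   # p-hat = 0.5
  z0 <- unname(standardize_genotypes(G, 0)$values[, 1])
  expect_equal(z0, c(-1, 0, 1) / sqrt(0.5))
  z1 <- unname(standardize_genotypes(G, 1)$values[, 1])
  expect_equal(z1[1], -1)                      # (0 - 1)/sqrt(2*2*0.25)
  Z <- std_panel(n = 70, m = c(40, 30), seed = 3)
  expect_lt(max(abs(colSums(Z$values))), 1e-9 * 70)
  Gm <- genotype_matrix(cbind(rep(2L, 6), c(0L, 1L, 1L, 2L, 0L, 1L)))
  expect_error(standardize_genotypes(Gm), "snp1")
})
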