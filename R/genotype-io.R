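#' Construct a genotype matrix object
#'
#' Bundles an n x m dosage matrix (entries 0/1/2, `NA` for missing) with its
#' sample identifiers and SNP map. Dosages count copies of the second allele
#' (`a2`) of each SNP record; squared-correlation LD statistics are invariant
#' to which allele is counted.
#'
#' @param dosages integer matrix, samples in rows, SNPs in columns.
#' @param samples character vector of sample identifiers (length n).
#' @param snps data frame with columns `id`, `chrom`, `pos`, `a1`, `a2`
#'   in file order; `pos` is a 1-based base-pair position.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, samples = NULL, snps = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(samples)) samples <- paste0("s", seq_len(n))
  if (is.null(snps)) {
    snps <- data.frame(id = paste0("snp", seq_len(m)), chrom = 1L,
                       pos = seq_len(m), a1 = "A", a2 = "C",
                       stringsAsFactors = FALSE)
  }
  stopifnot(length(samples) == n, nrow(snps) == m)
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(snps$id)) stop("SNP identifiers must be unique")
  rownames(dosages) <- samples
  colnames(dosages) <- snps$id
  structure(list(dosages = dosages, samples = samples, snps = snps),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs, %d chromosome(s), %d missing call(s)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$snps$chrom)), sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# bed byte layout: 4 samples per byte, sample 1 in the two lowest bits.
# 2-bit codes: 00 hom a1, 01 missing, 10 het, 11 hom a2.
.bed_code_to_dosage <- c(0L, NA_integer_, 1L, 2L)   # index by code + 1
.bed_dosage_to_code <- c(0L, 2L, 3L)                # index by dosage + 1

#' Read a PLINK binary genotype fileset
#'
#' Reads `prefix.bed` / `.bim` / `.fam` (PLINK 1 binary, SNP-major). Bed
#' codes are decoded as 00 -> 0, 10 -> 1, 11 -> 2 copies of the `.bim`
#' second allele, 01 -> missing.
#'
#' @param prefix path prefix of the fileset (without extension).
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing file: ", f)
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                              colClasses = c("character", "character", "numeric",
                                             "integer", "character", "character"))
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam_df); m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported: ", bed)
  bps <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bps * m)
    stop(sprintf(".bed length mismatch: expected %d body bytes, found %d",
                 bps * m, length(body)))
  v <- as.integer(body)
  # unpack the four 2-bit codes of every byte, then reshape to (4*bps) x m
  codes <- matrix(0L, nrow = 4L * bps, ncol = m)
  byte <- matrix(v, nrow = bps, ncol = m)
  codes[seq(1L, by = 4L, length.out = bps), ] <- byte %% 4L
  codes[seq(2L, by = 4L, length.out = bps), ] <- (byte %/% 4L) %% 4L
  codes[seq(3L, by = 4L, length.out = bps), ] <- (byte %/% 16L) %% 4L
  codes[seq(4L, by = 4L, length.out = bps), ] <- byte %/% 64L
  dos <- matrix(.bed_code_to_dosage[codes[seq_len(n), , drop = FALSE] + 1L],
                nrow = n, ncol = m)
  chrom <- suppressWarnings(as.integer(bim_df$chrom))
  chrom[is.na(chrom)] <- -1L
  snps <- data.frame(id = bim_df$id, chrom = chrom, pos = bim_df$pos,
                     a1 = bim_df$a1, a2 = bim_df$a2, stringsAsFactors = FALSE)
  genotype_matrix(dos, samples = as.character(fam_df[[2]]), snps = snps)
}

#' Write a genotype matrix as a PLINK binary fileset
#'
#' Inverse of [read_plink()]: dosage 0 -> code 00, 1 -> 10, 2 -> 11,
#' missing -> 01.
#'
#' @param G a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(G, prefix) {
  dos <- G$dosages
  n <- nrow(dos); m <- ncol(dos)
  code <- matrix(1L, nrow = n, ncol = m)   # 01 = missing
  ok <- !is.na(dos)
  code[ok] <- .bed_dosage_to_code[dos[ok] + 1L]
  bps <- ceiling(n / 4)
  pad <- 4L * bps - n
  if (pad > 0L) code <- rbind(code, matrix(0L, pad, m))
  i1 <- seq(1L, by = 4L, length.out = bps)
  bytes <- code[i1, , drop = FALSE] + 4L * code[i1 + 1L, , drop = FALSE] +
    16L * code[i1 + 2L, , drop = FALSE] + 64L * code[i1 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  utils::write.table(
    data.frame(G$snps$chrom, G$snps$id, 0, G$snps$pos, G$snps$a1, G$snps$a2),
    paste0(prefix, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(G$samples, G$samples, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Per-SNP missing-call rate
#' @param G a [genotype_matrix()].
#' @return numeric vector of length m.
#' @export
missing_rate <- function(G) colMeans(is.na(G$dosages))

#' Allele frequencies of a complete genotype matrix
#'
#' The counted-allele frequency is the column dosage mean over 2n (no
#' pseudo-counts), the convention under which standardized columns sum to
#' exactly zero. Missing calls are tolerated (frequency from observed calls)
#' so the same estimator can drive Hardy-Weinberg imputation.
#'
#' @param G a [genotype_matrix()].
#' @return A data frame with columns `p` (counted-allele frequency), `q`
#'   (= 1 - p), `maf`, and `monomorphic`.
#' @export
allele_frequencies <- function(G) {
  p <- colMeans(G$dosages, na.rm = TRUE) / 2
  data.frame(p = p, q = 1 - p, maf = pmin(p, 1 - p),
             monomorphic = p == 0 | p == 1, row.names = NULL)
}

#' SNP quality control
#'
#' Removes SNPs whose missing-call rate exceeds `miss_max` and keeps SNPs
#' whose minor allele frequency (from observed calls) exceeds `maf_min`.
#' Monomorphic SNPs are always removed; optionally restricts to autosomes
#' (chromosome codes 1-22). SNP order is preserved and the filter is
#' idempotent.
#'
#' @param G a [genotype_matrix()].
#' @param maf_min retain SNPs with MAF strictly greater than this.
#' @param miss_max drop SNPs with missing rate strictly greater than this.
#' @param autosomes_only restrict to chromosome codes 1-22.
#' @return A filtered [genotype_matrix()].
#' @export
apply_qc <- function(G, maf_min = 0.05, miss_max = 0.2, autosomes_only = TRUE) {
  stopifnot(maf_min >= 0, maf_min < 0.5, miss_max >= 0, miss_max <= 1)
  keep <- missing_rate(G) <= miss_max
  af <- allele_frequencies(G)
  keep <- keep & !af$monomorphic & af$maf > maf_min
  if (autosomes_only) keep <- keep & G$snps$chrom %in% 1:22
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("quality control removed every SNP")
  genotype_matrix(G$dosages[, keep, drop = FALSE], G$samples,
                  G$snps[keep, , drop = FALSE])
}

#' Impute missing genotypes under Hardy-Weinberg proportions
#'
#' Each missing call is replaced by an independent draw from {0, 1, 2} with
#' probabilities (q^2, 2pq, p^2), p estimated from the SNP's observed calls.
#' A seeded random draw, not mean imputation: the imputed panel remains a
#' valid dosage matrix.
#'
#' @param G a [genotype_matrix()].
#' @param seed integer seed; the result is reproducible given the seed.
#' @return A complete [genotype_matrix()]; non-missing entries unchanged.
#' @export
impute_missing_hwe <- function(G, seed = 1L) {
  dos <- G$dosages
  miss <- is.na(dos)
  if (!any(miss)) return(G)
  all_missing <- colSums(!miss) == 0L
  if (any(all_missing))
    stop("SNP(s) with no observed genotypes: ",
         paste(G$snps$id[all_missing], collapse = ", "))
  p <- colMeans(dos, na.rm = TRUE) / 2
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  idx <- which(miss, arr.ind = TRUE)
  dos[miss] <- stats::rbinom(nrow(idx), 2L, p[idx[, 2]])
  genotype_matrix(dos, G$samples, G$snps)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Standardize a complete genotype matrix
#'
#' Column l is transformed as (x - 2 p_l) / sqrt(2 (1 + F) p_l q_l) with p_l
#' the counted-allele frequency and F the inbreeding coefficient (0 for a
#' random-mating population, 1 for fully inbred). With data-estimated
#' frequencies every column sums to zero.
#'
#' @param G a complete [genotype_matrix()] (impute first).
#' @param F_inbreeding inbreeding coefficient in [0, 1].
#' @return An object of class `standardized_matrix` with elements `values`
#'   (n x m numeric), `freqs` (as [allele_frequencies()]), `inbreeding_f`,
#'   `samples`, and `snps`.
#' @export
standardize_genotypes <- function(G, F_inbreeding = 0) {
  stopifnot(F_inbreeding >= 0, F_inbreeding <= 1)
  if (anyNA(G$dosages)) stop("genotype matrix has missing calls; impute first")
  af <- allele_frequencies(G)
  if (any(af$monomorphic))
    stop("monomorphic SNP(s) cannot be standardized: ",
         paste(G$snps$id[af$monomorphic], collapse = ", "))
  sc <- sqrt(2 * (1 + F_inbreeding) * af$p * af$q)
  Z <- sweep(G$dosages, 2, 2 * af$p)
  Z <- sweep(Z, 2, sc, "/")
  structure(list(values = Z, freqs = af, inbreeding_f = F_inbreeding,
                 samples = G$samples, snps = G$snps),
            class = "standardized_matrix")
}

#' @export
print.standardized_matrix <- function(x, ...) {
  cat(sprintf("standardized_matrix: %d samples x %d SNPs (F = %g)\n",
              nrow(x$values), ncol(x$values), x$inbreeding_f))
  invisible(x)
}
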