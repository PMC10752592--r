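#' @keywords internal
"_PACKAGE"

.fmt_num <- function(x) {
  if (is.numeric(x)) vapply(x, function(v) sprintf("%.17g", v), character(1))
  else as.character(x)
}

# TSVs keep full double precision so downstream comparisons are exact
.write_tsv <- function(df, path) {
  out <- as.data.frame(lapply(df, .fmt_num), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

.write_log <- function(out_prefix, cmd, cfg, extra = character()) {
  path <- paste0(out_prefix, ".log")
  lines <- c(
    sprintf("ldgrid %s", as.character(utils::packageVersion("ldgrid"))),
    sprintf("command: %s", cmd),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    vapply(names(cfg), function(k)
      sprintf("%s = %s", k, paste(format(cfg[[k]]), collapse = ",")),
      character(1)),
    extra)
  writeLines(lines, path)
  invisible(path)
}

# read -> missingness filter -> HWE imputation -> MAF/monomorphic filter ->
# standardization; MAF is computed on complete data.
.load_panel <- function(bfile, maf_min = 0.05, miss_max = 0.2,
                        inbreeding_f = 0, seed = 1L, autosomes_only = TRUE,
                        chr = NULL, exclude_chr = NULL) {
  G <- read_plink(bfile)
  n_in <- ncol(G$dosages)
  if (!is.null(chr)) {
    keep <- G$snps$chrom %in% chr
    if (!any(keep)) stop("no SNPs on requested chromosome(s)")
    G <- genotype_matrix(G$dosages[, keep, drop = FALSE], G$samples,
                         G$snps[keep, , drop = FALSE])
  }
  if (!is.null(exclude_chr)) {
    keep <- !(G$snps$chrom %in% exclude_chr)
    if (!any(keep)) stop("chromosome exclusion removed every SNP")
    G <- genotype_matrix(G$dosages[, keep, drop = FALSE], G$samples,
                         G$snps[keep, , drop = FALSE])
  }
  G <- apply_qc(G, maf_min = 0, miss_max = miss_max,
                autosomes_only = autosomes_only)
  G <- impute_missing_hwe(G, seed = seed)
  G <- apply_qc(G, maf_min = maf_min, miss_max = 1,
                autosomes_only = autosomes_only)
  list(G = G, Z = standardize_genotypes(G, inbreeding_f),
       snps_in = n_in, snps_out = ncol(G$dosages))
}

#' Chromosome-scale LD analysis of a PLINK fileset
#'
#' Runs quality control, imputation and standardization, then writes
#' `<out>.ld.tsv` (C x C matrix: diagonal = intra LD, upper triangle =
#' inter LD, lower triangle = scaled inter LD), `<out>.ld_summary.tsv`
#' (genome LD with SE, component means, intra-fraction and true-LD
#' summaries, top eigenvalue and Fst proxy) and `<out>.log`.
#'
#' @param bfile PLINK fileset prefix.
#' @param out output prefix.
#' @param maf_min,miss_max QC thresholds (defaults 0.05 and 0.2).
#' @param inbreeding_f inbreeding coefficient for standardization.
#' @param chr,exclude_chr optional chromosome include/exclude vectors.
#' @param bootstrap bootstrap replicates for inter-LD SEs.
#' @param seed seed for imputation and bootstrap.
#' @return The `ld_partition`, invisibly.
#' @export
run_ld <- function(bfile, out, maf_min = 0.05, miss_max = 0.2,
                   inbreeding_f = 0, chr = NULL, exclude_chr = NULL,
                   bootstrap = 200L, seed = 1L) {
  pan <- .load_panel(bfile, maf_min, miss_max, inbreeding_f, seed,
                     chr = chr, exclude_chr = exclude_chr)
  chrom_m <- table(pan$Z$snps$chrom)
  if (any(chrom_m < 2))
    stop("QC left fewer than 2 SNPs on chromosome(s): ",
         paste(names(chrom_m)[chrom_m < 2], collapse = ", "))
  part <- ld_partition(pan$Z, bootstrap = bootstrap, seed = seed)
  C <- nrow(part$chromosomes)
  M <- matrix(NA_real_, C, C,
              dimnames = list(part$chromosomes$chrom, part$chromosomes$chrom))
  diag(M) <- part$intra$value
  if (!is.null(part$inter)) {
    ii <- match(part$inter$chrom_i, part$chromosomes$chrom)
    jj <- match(part$inter$chrom_j, part$chromosomes$chrom)
    M[cbind(ii, jj)] <- part$inter$value
    M[cbind(jj, ii)] <- part$scaled$value
  }
  ld_df <- data.frame(chrom = rownames(M), M, check.names = FALSE)
  .write_tsv(ld_df, paste0(out, ".ld.tsv"))

  mean_li <- mean(part$intra$value)
  mean_lij <- if (is.null(part$inter)) NA_real_ else mean(part$inter$value)
  b0 <- b1 <- pearson_r <- true_ld <- NA_real_
  if (C >= 3 && stats::var(part$intra$m) > 0) {
    fit <- fit_decay_regression(part$intra$value, part$intra$m)
    b0 <- fit$b0; b1 <- fit$b1; pearson_r <- fit$pearson_r
    if (mean_li + b0 > 0) true_ld <- true_ld_summary(mean_li, b0)
  }
  summary_df <- data.frame(
    n = part$n, m = part$m, C = C,
    l_genome = part$genome$value, l_genome_se = part$genome$se,
    mean_intra = mean_li, mean_inter = mean_lij,
    mean_scaled_inter = if (is.null(part$scaled)) NA_real_
      else mean(part$scaled$value),
    intra_fraction = if (C > 1 && !is.na(mean_lij) && mean_lij >= 0)
      intra_fraction_summary(mean_li, mean_lij, C) else NA_real_,
    decay_b0 = b0, decay_b1 = b1, decay_r = pearson_r, true_ld = true_ld,
    lambda1 = part$lambda1, fst_proxy = part$fst_proxy)
  .write_tsv(summary_df, paste0(out, ".ld_summary.tsv"))
  .write_log(out, "ld",
             list(bfile = bfile, maf = maf_min, geno = miss_max,
                  inbreeding_f = inbreeding_f, bootstrap = bootstrap,
                  seed = seed),
             c(sprintf("snps_in = %d", pan$snps_in),
               sprintf("snps_out = %d", pan$snps_out)))
  invisible(part)
}

#' High-resolution grid LD for one chromosome of a PLINK fileset
#'
#' Writes `<out>.grid.tsv` with one row per grid (beta diagonal plus
#' beta(beta-1)/2 off-diagonal): columns chrom, bin_u, bin_v, snp_count_u,
#' snp_count_v, start/end bp of both bins, and the mean LD.
#'
#' @inheritParams run_ld
#' @param chr the single chromosome to analyse.
#' @param bin_size SNPs per bin.
#' @param region optional "start-end" bp string: also writes region mean and
#'   knockout estimates to the log.
#' @return The `grid_result`, invisibly.
#' @export
run_grid <- function(bfile, out, chr, bin_size = 250L, maf_min = 0.05,
                     miss_max = 0.2, inbreeding_f = 0, seed = 1L,
                     region = NULL) {
  if (length(chr) != 1) stop("grid analysis takes exactly one chromosome")
  pan <- .load_panel(bfile, maf_min, miss_max, inbreeding_f, seed, chr = chr)
  Z <- pan$Z
  part <- partition_blocks(ncol(Z$values), bin_size, chromosome = chr)
  grid <- grid_ld_matrix(Z, part)
  b <- part$boundaries
  mu <- b$end - b$start + 1L
  pos <- Z$snps$pos
  rows_d <- data.frame(chrom = chr, bin_u = seq_len(part$beta),
                       bin_v = seq_len(part$beta),
                       snp_count_u = mu, snp_count_v = mu,
                       start_bp_u = pos[b$start], end_bp_u = pos[b$end],
                       start_bp_v = pos[b$start], end_bp_v = pos[b$end],
                       ld = grid$diag)
  rows <- rows_d
  if (!is.null(grid$offdiag)) {
    od <- grid$offdiag
    rows_o <- data.frame(chrom = chr, bin_u = od$u, bin_v = od$v,
                         snp_count_u = mu[od$u], snp_count_v = mu[od$v],
                         start_bp_u = pos[b$start[od$u]],
                         end_bp_u = pos[b$end[od$u]],
                         start_bp_v = pos[b$start[od$v]],
                         end_bp_v = pos[b$end[od$v]],
                         ld = od$value)
    rows <- rbind(rows_d, rows_o)
  }
  .write_tsv(rows, paste0(out, ".grid.tsv"))
  extra <- c(sprintf("snps_out = %d", pan$snps_out),
             sprintf("beta = %d", part$beta))
  if (!is.null(region)) {
    rng <- as.numeric(strsplit(region, "-", fixed = TRUE)[[1]])
    rm_ld <- region_mean_ld(Z, rng)
    ko_ld <- region_knockout(Z, rng)
    extra <- c(extra,
               sprintf("region_mean_ld = %.17g", rm_ld$value),
               sprintf("region_knockout_ld = %.17g", ko_ld$value))
  }
  .write_log(out, "grid",
             list(bfile = bfile, chr = chr, bin = bin_size, maf = maf_min,
                  geno = miss_max, seed = seed), extra)
  invisible(grid)
}

#' LD-decay regression for a PLINK fileset
#'
#' Estimates the chromosomal mean LDs, regresses them on inverse SNP count
#' and writes `<out>.decay.tsv` (fit and per-chromosome points/residuals)
#' plus `<out>.loco.tsv` (leave-one-chromosome-out refits).
#'
#' @inheritParams run_ld
#' @return The `decay_fit`, invisibly.
#' @export
run_decay <- function(bfile, out, maf_min = 0.05, miss_max = 0.2,
                      inbreeding_f = 0, seed = 1L) {
  pan <- .load_panel(bfile, maf_min, miss_max, inbreeding_f, seed)
  part <- ld_partition(pan$Z, bootstrap = 0L)
  fit <- fit_decay_regression(part$intra$value, part$intra$m)
  pts <- fit$points
  pts$chrom <- part$chromosomes$chrom
  decay_df <- data.frame(chrom = pts$chrom, m = pts$m, x = pts$x, l = pts$l,
                         fitted = fit$fitted, residual = fit$residuals,
                         b0 = fit$b0, b1 = fit$b1, pearson_r = fit$pearson_r)
  .write_tsv(decay_df, paste0(out, ".decay.tsv"))
  if (nrow(pts) >= 4) {
    loco <- loco_analysis(part$intra$value, part$intra$m)
    loco$dropped <- part$chromosomes$chrom[loco$dropped]
    .write_tsv(loco, paste0(out, ".loco.tsv"))
  }
  .write_log(out, "decay",
             list(bfile = bfile, maf = maf_min, geno = miss_max, seed = seed),
             sprintf("b0 = %.17g; b1 = %.17g; R = %.17g",
                     fit$b0, fit$b1, fit$pearson_r))
  invisible(fit)
}

#' Simulate a panel and write it as a PLINK fileset
#'
#' @param cfg a [sim_config()].
#' @param out output fileset prefix.
#' @return The output prefix, invisibly.
#' @export
run_simulate <- function(cfg, out) {
  G <- simulate_panel(cfg)
  write_plink(G, out)
  .write_log(out, "simulate",
             list(n = cfg$n, chromosomes = nrow(cfg$chromosomes),
                  m = sum(cfg$chromosomes$m), ld_model = cfg$ld_model,
                  seed = cfg$seed))
  invisible(out)
}

#' Exhaustive pairwise-r2 oracle run over a PLINK fileset
#'
#' Writes `<out>.oracle.tsv` (per-pair r2) and per-grid means in the log.
#' Intended for small validation panels only.
#'
#' @inheritParams run_ld
#' @param max_pairs pair-count guard.
#' @return The `oracle_report`, invisibly.
#' @export
run_oracle <- function(bfile, out, maf_min = 0.05, miss_max = 0.2,
                       seed = 1L, max_pairs = 1e7) {
  pan <- .load_panel(bfile, maf_min, miss_max, 0, seed)
  rep <- brute_force_grid(pan$G, max_pairs = max_pairs)
  tab <- rep$pair_table
  tab$snp_a <- pan$G$snps$id[tab$snp_a]
  tab$snp_b <- pan$G$snps$id[tab$snp_b]
  .write_tsv(tab[, c("snp_a", "snp_b", "r2")], paste0(out, ".oracle.tsv"))
  .write_log(out, "oracle",
             list(bfile = bfile, maf = maf_min, geno = miss_max),
             c(sprintf("intra_mean[%s] = %.17g", names(rep$intra), rep$intra)))
  invisible(rep)
}

#' Top GRM eigenvalue and Fst surrogate for a PLINK fileset
#'
#' @inheritParams run_ld
#' @return list with `lambda1`, `fst_proxy`, invisibly (also logged).
#' @export
run_eigen <- function(bfile, out, maf_min = 0.05, miss_max = 0.2,
                      inbreeding_f = 0, seed = 1L) {
  pan <- .load_panel(bfile, maf_min, miss_max, inbreeding_f, seed)
  K <- build_grm(pan$Z, label = "genome")
  ev <- largest_eigenvalue(K)
  .write_tsv(data.frame(n = K$n, m = K$snp_count, lambda1 = ev$lambda1,
                        fst_proxy = ev$fst_proxy),
             paste0(out, ".eigen.tsv"))
  .write_log(out, "eigen", list(bfile = bfile, maf = maf_min),
             sprintf("lambda1 = %.17g", ev$lambda1))
  invisible(ev)
}
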