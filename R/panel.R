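#' Reference SNP panel
#'
#' A `snp_panel` bundles the per-SNP table of a genotype reference panel
#' (identifier, chromosome, 1-based position, genetic-map position in cM,
#' alleles, minor allele frequency) with the samples-by-SNPs genotype matrix
#' used to estimate linkage disequilibrium. `M` is the number of SNPs retained
#' after the MAF filter; it is the denominator of the standardized effect size
#' and of annotation SNP proportions.
#'
#' @param snps Tibble with columns `snp`, `chrom`, `pos`, `cm`, `a1`, `a2`,
#'   `maf`, ordered by (`chrom`, `pos`).
#' @param genotypes Numeric matrix, samples in rows, SNPs in columns
#'   (allele-count coding 0/1/2 or dosages on the same scale). Column order
#'   matches `snps`.
#' @return An object of class `snp_panel` with elements `snps`, `genotypes`,
#'   `M` (SNP count) and `n_samples`.
#' @export
snp_panel <- function(snps, genotypes) {
  snps <- as_tibble(snps)
  required <- c("snp", "chrom", "pos", "cm", "a1", "a2", "maf")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0) {
    abort(paste0("snps table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(snps$snp)) {
    dup <- snps$snp[duplicated(snps$snp)][1]
    abort(paste0("duplicate SNP id in panel: ", dup))
  }
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != nrow(snps)) {
    abort("genotype matrix has a different SNP count than the SNP table")
  }
  ord <- order(snps$chrom, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  genotypes <- genotypes[, ord, drop = FALSE]
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0)) {
      abort(paste0("positions not strictly increasing on chromosome ", ch))
    }
  }
  colnames(genotypes) <- snps$snp
  structure(
    list(snps = snps, genotypes = genotypes,
         M = nrow(snps), n_samples = nrow(genotypes)),
    class = "snp_panel"
  )
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("<snp_panel> ", x$M, " SNPs, ", x$n_samples, " samples, ",
      length(unique(x$snps$chrom)), " chromosome(s)\n", sep = "")
  print(head(x$snps, 5))
  invisible(x)
}

#' Read a reference panel from disk
#'
#' Reads either a PLINK 1 `.bed`/`.bim`/`.fam` triplet (pass the common path
#' prefix) or a plain whitespace-delimited test matrix whose first five-plus
#' columns are `snp chrom pos cm a1 a2` followed by one genotype column per
#' sample. SNPs with minor allele frequency below `maf_min` are removed and
#' `M` reflects the retained count; ordering is deterministic by
#' (chromosome, position).
#'
#' Missing genotypes are mean-imputed per SNP before any correlation is
#' computed downstream. A `.bim` with a zero/missing cM column is accepted and
#' the cM values imputed as 0 with a warning.
#'
#' @param path Path prefix of a PLINK triplet, or path to a text matrix file.
#' @param maf_min Minimum minor allele frequency retained (default 0.005).
#' @return A [snp_panel].
#' @export
read_panel <- function(path, maf_min = 0.005) {
  stopifnot(is.numeric(maf_min), maf_min >= 0, maf_min < 0.5)
  if (file.exists(paste0(path, ".bed"))) {
    panel <- read_plink(path)
  } else if (file.exists(path)) {
    panel <- read_panel_text(path)
  } else {
    abort(paste0("no PLINK triplet or text panel found at ", path))
  }
  filter_panel_maf(panel, maf_min)
}

filter_panel_maf <- function(panel, maf_min) {
  keep <- panel$snps$maf >= maf_min
  snp_panel(panel$snps[keep, , drop = FALSE],
            panel$genotypes[, keep, drop = FALSE])
}

read_panel_text <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  meta_cols <- c("snp", "chrom", "pos", "cm", "a1", "a2")
  names(tab)[seq_along(meta_cols)] <- meta_cols
  geno <- t(as.matrix(tab[, -seq_along(meta_cols), drop = FALSE]))
  storage.mode(geno) <- "double"
  geno <- impute_missing_genotypes(geno)
  snps <- as_tibble(tab[, meta_cols])
  snps$chrom <- as.character(snps$chrom)
  snps$maf <- genotype_maf(geno)
  snp_panel(snps, geno)
}

impute_missing_genotypes <- function(geno) {
  if (anyNA(geno)) {
    mu <- colMeans(geno, na.rm = TRUE)
    idx <- which(is.na(geno), arr.ind = TRUE)
    geno[idx] <- mu[idx[, 2]]
  }
  geno
}

genotype_maf <- function(geno) {
  f <- colMeans(geno) / 2
  pmin(f, 1 - f)
}

# ---- PLINK 1 binary (.bed/.bim/.fam) ----------------------------------------

#' Read a PLINK 1 binary fileset
#'
#' Decodes the SNP-major `.bed` byte layout (magic bytes 0x6c 0x1b 0x01; two
#' bits per sample per SNP: 00 = homozygous A1, 10 = heterozygous,
#' 11 = homozygous A2, 01 = missing). Genotypes are returned as A1 allele
#' counts with missing values mean-imputed per SNP; MAF is computed from the
#' decoded matrix.
#'
#' @param prefix Path prefix shared by the `.bed`, `.bim` and `.fam` files.
#' @return A [snp_panel].
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp", "cm", "pos", "a1", "a2"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    abort("not a SNP-major PLINK .bed file (bad magic bytes)")
  }
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(con, "raw", n = bytes_per_snp * m)
  if (length(raw) < bytes_per_snp * m) abort(".bed file truncated")
  geno <- decode_bed_bytes(raw, n, m, bytes_per_snp)
  geno <- impute_missing_genotypes(geno)
  if (anyDuplicated(bim$snp)) {
    abort(paste0("duplicate SNP id in panel: ", bim$snp[duplicated(bim$snp)][1]))
  }
  if (all(bim$cm == 0) && m > 1) {
    warn("no genetic-map (cM) positions in .bim; cM imputed as 0")
  }
  snps <- tibble(
    snp = bim$snp, chrom = as.character(bim$chrom), pos = bim$pos,
    cm = bim$cm, a1 = bim$a1, a2 = bim$a2, maf = genotype_maf(geno)
  )
  snp_panel(snps, geno)
}

# two-bit code -> A1 allele count (NA for the missing code 01)
.bed_code_to_count <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)

decode_bed_bytes <- function(raw, n, m, bytes_per_snp) {
  ints <- as.integer(raw)
  # per byte, four two-bit fields, lowest bits = first sample
  codes <- rbind(ints %% 4L,
                 (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L,
                 (ints %/% 64L) %% 4L)
  codes <- matrix(codes, nrow = 4 * bytes_per_snp, ncol = m)
  counts <- matrix(.bed_code_to_count[codes + 1L], nrow = 4 * bytes_per_snp)
  counts[seq_len(n), , drop = FALSE]
}

#' Write a panel as a PLINK 1 binary fileset
#'
#' Inverse of [read_plink()]; genotypes are rounded to the nearest allele
#' count in 0..2 when writing (the bed format is hard-call only).
#'
#' @param panel A [snp_panel].
#' @param prefix Output path prefix for `.bed`, `.bim`, `.fam`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  s <- panel$snps
  utils::write.table(
    data.frame(s$chrom, s$snp, s$cm, s$pos, s$a1, s$a2),
    paste0(prefix, ".bim"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  n <- panel$n_samples
  fam <- data.frame(paste0("F", seq_len(n)), paste0("I", seq_len(n)),
                    0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  geno <- pmin(pmax(round(panel$genotypes), 0), 2)
  count_to_code <- c(3L, 2L, 0L)            # counts 0,1,2 -> bed codes
  bytes_per_snp <- ceiling(n / 4)
  codes <- matrix(0L, nrow = 4 * bytes_per_snp, ncol = panel$M)
  codes[seq_len(n), ] <- count_to_code[geno + 1L]
  byte_vals <- codes[seq(1, nrow(codes), 4), , drop = FALSE] +
    4L * codes[seq(2, nrow(codes), 4), , drop = FALSE] +
    16L * codes[seq(3, nrow(codes), 4), , drop = FALSE] +
    64L * codes[seq(4, nrow(codes), 4), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(byte_vals), con)
  invisible(prefix)
}
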