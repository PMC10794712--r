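# Tiny in-code fixtures shared across test files.

# panel from an explicit samples x SNPs genotype matrix
make_panel <- function(geno, chrom = "1", pos = NULL, cm = NULL,
                       maf = NULL) {
  m <- ncol(geno)
  pos <- pos %||% (seq_len(m) * 100L)
  cm <- cm %||% rep(0, m)
  snps <- tibble::tibble(
    snp = paste0("s", seq_len(m)),
    chrom = rep_len(chrom, m), pos = pos, cm = cm,
    a1 = "A", a2 = "G",
    maf = maf %||% pmin(colMeans(geno) / 2, 1 - colMeans(geno) / 2)
  )
  snp_panel(snps, geno)
}

# write a whitespace test-matrix panel file; rows = SNPs, genotype columns
write_text_panel <- function(path, snp, chrom, pos, cm, a1, a2, geno_by_snp) {
  tab <- data.frame(snp = snp, chrom = chrom, pos = pos, cm = cm,
                    a1 = a1, a2 = a2)
  tab <- cbind(tab, as.data.frame(geno_by_snp))
  names(tab)[-(1:6)] <- paste0("ind", seq_len(ncol(geno_by_snp)))
  write.table(tab, path, quote = FALSE, row.names = FALSE)
  path
}

write_sumstats_text <- function(path, header, rows) {
  writeLines(c(header, rows), path)
  path
}

# exact one-sided rank-sum p by enumeration of all group assignments
enumerate_ranksum_p <- function(focal, rest) {
  vals <- c(focal, rest)
  r <- rank(vals)
  obs <- sum(r[seq_along(focal)])
  combs <- combn(length(vals), length(focal))
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  mean(stats >= obs)
}

`%||%` <- rlang::`%||%`
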