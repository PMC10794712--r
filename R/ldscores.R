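#' LD window specification
#'
#' Stratified LD scores sum squared genotype correlations over the SNPs
#' within a window of the focal SNP. The window is genetic-map based by
#' default (1 centimorgan) with a physical fallback when no cM map is
#' available.
#'
#' @param mode `"cm"` or `"kb"`.
#' @param size Window half-width (default 1 cM / 1000 kb).
#' @return An `ld_window` list.
#' @export
ld_window <- function(mode = c("cm", "kb"), size = NULL) {
  mode <- match.arg(mode)
  size <- size %||% if (mode == "cm") 1 else 1000
  if (size <= 0) abort("window size must be positive")
  structure(list(mode = mode, size = size), class = "ld_window")
}

#' Squared genotype correlation between two panel SNPs
#'
#' Squared Pearson correlation of the two genotype columns (after per-SNP
#' mean imputation of missing values, which the readers already apply). With
#' `adjusted = TRUE` the finite-sample bias correction
#' r2 - (1 - r2) / (n - 2) is applied, the standard unbiased-ish estimator
#' used when panel sample sizes are modest.
#'
#' @param panel A [snp_panel].
#' @param j,k SNP indices or ids.
#' @param adjusted Apply the bias adjustment (default FALSE).
#' @return Scalar (squared correlation).
#' @export
pairwise_r2 <- function(panel, j, k, adjusted = FALSE) {
  j <- resolve_snp_index(panel, j)
  k <- resolve_snp_index(panel, k)
  gj <- panel$genotypes[, j]
  gk <- panel$genotypes[, k]
  if (sd(gj) == 0 || sd(gk) == 0) {
    abort("monomorphic SNP; filter by MAF before LD computation")
  }
  r2 <- cor(gj, gk)^2
  if (adjusted) r2 <- r2 - (1 - r2) / (panel$n_samples - 2)
  r2
}

resolve_snp_index <- function(panel, j) {
  if (is.character(j)) {
    i <- match(j, panel$snps$snp)
    if (is.na(i)) abort(paste0("SNP '", j, "' not in panel"))
    return(i)
  }
  as.integer(j)
}

#' Stratified LD scores
#'
#' For each regression SNP j and each annotation c, computes
#' l(j, c) = sum over panel SNPs k within the window of a_ck * r2_jk, where
#' r2 is the (optionally bias-adjusted) squared genotype correlation. The
#' focal SNP itself is always inside its own window; chromosomes are
#' independent (no cross-chromosome LD).
#'
#' @param panel A [snp_panel].
#' @param stack An `annot_stack` aligned to the panel.
#' @param window An [ld_window] (default 1 cM).
#' @param regression_snps Character vector of SNP ids to score (default: all
#'   panel SNPs).
#' @param adjusted Use the bias-adjusted r2 estimator (default TRUE; exact
#'   oracle comparisons use FALSE).
#' @return A tibble: `snp` then one numeric LD-score column per annotation;
#'   the window is recorded in the `"window_spec"` attribute.
#' @export
ld_scores <- function(panel, stack, window = ld_window(),
                      regression_snps = NULL, adjusted = TRUE) {
  regression_snps <- regression_snps %||% panel$snps$snp
  if (length(regression_snps) == 0) abort("empty regression SNP set")
  ridx <- match(regression_snps, panel$snps$snp)
  if (anyNA(ridx)) {
    abort(paste0("regression SNP not in panel: ",
                 regression_snps[which(is.na(ridx))[1]]))
  }
  if (!identical(stack$snp, panel$snps$snp)) {
    abort("annotation stack is not aligned to the panel")
  }
  A <- annot_matrix(stack)
  n <- panel$n_samples
  X <- scale(panel$genotypes)          # standardized per SNP
  pos_key <- if (window$mode == "cm") panel$snps$cm else panel$snps$pos / 1000
  chrom <- panel$snps$chrom
  out <- matrix(0, nrow = length(ridx), ncol = ncol(A),
                dimnames = list(NULL, colnames(A)))
  for (ch in unique(chrom[ridx])) {
    pidx <- which(chrom == ch)               # panel SNPs on this chromosome
    rsub <- which(chrom[ridx] == ch)         # regression rows on it
    Xc <- X[, pidx, drop = FALSE]
    key <- pos_key[pidx]
    for (rr in rsub) {
      j_local <- match(ridx[rr], pidx)
      win <- which(abs(key - key[j_local]) <= window$size)
      r <- crossprod(Xc[, j_local], Xc[, win, drop = FALSE])[1, ] / (n - 1)
      r2 <- r^2
      if (adjusted) r2 <- r2 - (1 - r2) / (n - 2)
      out[rr, ] <- r2 %*% A[pidx[win], , drop = FALSE]
    }
  }
  res <- dplyr::bind_cols(tibble(snp = regression_snps),
                          as_tibble(as.data.frame(out)))
  attr(res, "window_spec") <- window
  res
}

#' Brute-force all-pairs LD scores (oracle)
#'
#' O(M^2) double loop over every SNP pair on the same chromosome, ignoring
#' windows. Used as the independent oracle for [ld_scores()] with an
#' all-spanning window; quadratic, so only suitable for small panels.
#'
#' @inheritParams ld_scores
#' @return Same shape as [ld_scores()].
#' @export
ld_scores_bruteforce <- function(panel, stack, adjusted = FALSE) {
  A <- annot_matrix(stack)
  n <- panel$n_samples
  out <- matrix(0, nrow = panel$M, ncol = ncol(A),
                dimnames = list(NULL, colnames(A)))
  for (j in seq_len(panel$M)) {
    for (k in seq_len(panel$M)) {
      if (panel$snps$chrom[j] != panel$snps$chrom[k]) next
      r2 <- cor(panel$genotypes[, j], panel$genotypes[, k])^2
      if (adjusted) r2 <- r2 - (1 - r2) / (n - 2)
      out[j, ] <- out[j, ] + r2 * A[k, ]
    }
  }
  dplyr::bind_cols(tibble(snp = panel$snps$snp),
                   as_tibble(as.data.frame(out)))
}
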