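#' Read GWAS summary statistics
#'
#' Reads an LDSC-dialect sumstats table: a header containing (case-insensitive)
#' `SNP`, `A1`, `A2`, `N`, `Z`, whitespace- or tab-delimited. The chi-square
#' statistic is populated as `z^2`; row order is preserved.
#'
#' @param path Path to the sumstats file.
#' @return A tibble with columns `snp`, `a1`, `a2`, `n`, `z`, `chi2`.
#' @export
read_sumstats <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  nm <- tolower(names(tab))
  required <- c("snp", "a1", "a2", "n", "z")
  if (!all(required %in% nm)) {
    abort(paste0("sumstats header must contain SNP, A1, A2, N, Z; missing: ",
                 paste(setdiff(required, nm), collapse = ", ")))
  }
  names(tab) <- nm
  if (nrow(tab) == 0) {
    return(tibble(snp = character(), a1 = character(), a2 = character(),
                  n = numeric(), z = numeric(), chi2 = numeric()))
  }
  bad_n <- which(is.na(suppressWarnings(as.numeric(tab$n))))
  if (length(bad_n) > 0) {
    abort(paste0("non-numeric N in sumstats at data line ", bad_n[1]))
  }
  tibble(
    snp = as.character(tab$snp),
    a1 = toupper(as.character(tab$a1)),
    a2 = toupper(as.character(tab$a2)),
    n = as.numeric(tab$n),
    z = as.numeric(tab$z),
    chi2 = as.numeric(tab$z)^2
  )
}

#' Align summary statistics to a panel
#'
#' Matches sumstats rows to panel SNPs on identifier. Rows whose allele pair
#' does not match the panel's (in either order; only the chi-square enters the
#' regression, so strand/sign is irrelevant once the pair matches) are dropped
#' with a warning reporting the count.
#'
#' @param ss Sumstats tibble from [read_sumstats()].
#' @param panel A [snp_panel].
#' @return The sumstats rows present in the panel with matching alleles.
#' @export
align_sumstats <- function(ss, panel) {
  idx <- match(ss$snp, panel$snps$snp)
  ss <- ss[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  pa1 <- toupper(panel$snps$a1[idx]); pa2 <- toupper(panel$snps$a2[idx])
  ok <- (ss$a1 == pa1 & ss$a2 == pa2) | (ss$a1 == pa2 & ss$a2 == pa1)
  if (any(!ok)) {
    warn(paste0(sum(!ok), " sumstats SNP(s) dropped for allele mismatch with panel"))
  }
  ss[ok, , drop = FALSE]
}
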