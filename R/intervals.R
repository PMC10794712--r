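#' Read genomic intervals (BED dialects)
#'
#' Reads a BED file (0-based half-open `chrom start end` coordinates,
#' strand-free) in one of two dialects: `bed_peaks` for plain peak intervals,
#' or `enhancer_links` which expects a fourth `gene` column and an optional
#' fifth numeric `score` column. Intervals are returned sorted by
#' (chromosome, start); gene names are preserved verbatim and unknown
#' chromosome names pass through untouched.
#'
#' @param path Path to the BED(-like) file.
#' @param dialect `"bed_peaks"` or `"enhancer_links"`.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open)
#'   plus `gene` (and `score` if present) for the link dialect.
#' @export
read_intervals <- function(path, dialect = c("bed_peaks", "enhancer_links")) {
  dialect <- match.arg(dialect)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           sep = "", comment.char = "#")
  if (ncol(tab) < 3) abort("BED file needs at least chrom, start, end columns")
  out <- tibble(chrom = as.character(tab[[1]]),
                start = as.integer(tab[[2]]),
                end = as.integer(tab[[3]]))
  bad <- which(out$end <= out$start)
  if (length(bad) > 0) {
    abort(paste0("interval with end <= start at line ", bad[1], " of ", path))
  }
  if (dialect == "enhancer_links") {
    if (ncol(tab) < 4) abort("enhancer_links dialect needs a gene column")
    out$gene <- as.character(tab[[4]])
    if (ncol(tab) >= 5 && is.numeric(tab[[5]])) out$score <- as.numeric(tab[[5]])
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Write intervals as BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally more
#'   columns (written in order after the first three).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  utils::write.table(as.data.frame(intervals), path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRanges from a 0-based half-open interval tibble (converted to 1-based
# closed, the only place the coordinate conventions meet).
intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  )
}

snps_to_granges <- function(snps) {
  GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L)
  )
}

# logical: does each panel SNP fall in >= 1 interval
snp_in_intervals <- function(snps, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, nrow(snps)))
  hits <- GenomicRanges::findOverlaps(snps_to_granges(snps),
                                      intervals_to_granges(intervals))
  out <- rep(FALSE, nrow(snps))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}
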