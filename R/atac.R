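#' Binary cell-type annotation from open-chromatin peaks
#'
#' Marks each panel SNP 1 if its single base position falls inside at least
#' one peak of the cell type's accessible-chromatin peak set, else 0. Peaks
#' use BED semantics (0-based half-open), so a SNP whose 1-based position
#' equals a peak's `start` is the first base inside it and a SNP at `end` is
#' outside. Overlapping or duplicate peaks are merged before testing, so
#' membership does not depend on how peaks were split in the input file.
#'
#' @param peaks Interval tibble from [read_intervals()] (`chrom`, `start`,
#'   `end`), one cell type's peak set.
#' @param panel A [snp_panel].
#' @param name Annotation name (defaults to a `celltype` placeholder).
#' @return A one-annotation `annot_stack`, kind binary, role celltype.
#' @export
peaks_to_annotation <- function(peaks, panel, name = "celltype") {
  if (panel$M == 0) abort("empty panel")
  if (nrow(peaks) == 0) {
    warn(paste0("empty peak set for '", name, "'; annotation is all zero"))
    v <- rep(0, panel$M)
  } else {
    gr <- GenomicRanges::reduce(intervals_to_granges(peaks))
    hits <- GenomicRanges::findOverlaps(snps_to_granges(panel$snps), gr)
    v <- rep(0, panel$M)
    v[unique(S4Vectors::queryHits(hits))] <- 1
  }
  annot_stack(panel, setNames(list(v), name), kind = "binary", role = "celltype")
}

#' Union-of-open-chromatin background annotation
#'
#' Element-wise OR of the per-cell-type peak annotations of one dataset: 1 for
#' every SNP open in any cell type. Conditioning the heritability regression
#' on this union is what makes a focal cell type's coefficient cell-type
#' *specific* rather than merely open-chromatin specific.
#'
#' @param peak_sets Named list of peak interval tibbles (one per cell type).
#' @param panel A [snp_panel].
#' @param name Annotation name (default `"background_union"`).
#' @return A one-annotation `annot_stack`, kind binary, role background.
#' @export
union_background <- function(peak_sets, panel, name = "background_union") {
  if (length(peak_sets) == 0) abort("need at least one peak set")
  v <- rep(0, panel$M)
  for (p in peak_sets) {
    if (nrow(p) > 0) v <- pmax(v, snp_in_intervals(panel$snps, p))
  }
  annot_stack(panel, setNames(list(v), name), kind = "binary",
              role = "background")
}

#' Build the full ATAC annotation stack for one dataset
#'
#' One binary annotation per cell-type peak BED in `peaks_dir` (file stem =
#' cell-type name) plus the union background.
#'
#' @param peaks_dir Directory of `.bed` files, one per cell type.
#' @param panel A [snp_panel].
#' @return An `annot_stack` with one celltype annotation per BED plus one
#'   background annotation.
#' @export
build_atac_annotations <- function(peaks_dir, panel) {
  beds <- sort(list.files(peaks_dir, pattern = "\\.bed$", full.names = TRUE))
  if (length(beds) == 0) abort(paste0("no .bed files in ", peaks_dir))
  names(beds) <- sub("\\.bed$", "", basename(beds))
  peak_sets <- purrr::map(beds, read_intervals, dialect = "bed_peaks")
  stacks <- purrr::imap(peak_sets, ~ peaks_to_annotation(.x, panel, name = .y))
  do.call(bind_annotations,
          c(stacks, list(union_background(peak_sets, panel))))
}
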