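#' Annotation stacks
#'
#' An annotation stack is a tibble with one row per panel SNP — columns
#' `snp`, `chrom`, `pos`, `cm` — and one numeric column per annotation, every
#' value in \[0, 1\]. Per-annotation metadata (kind: binary or probabilistic;
#' role: celltype, baseline or background) travels in the `"annot_meta"`
#' attribute, a tibble with columns `name`, `kind`, `role`.
#'
#' The stack is the unit the LD-score and regression stages consume: a
#' standard cell-type fit stacks 1 focal cell-type annotation on top of the
#' baseline annotations and the background (union) annotation.
#'
#' @param panel A [snp_panel] the annotations are aligned to.
#' @param values Named list of numeric vectors (or a numeric matrix with
#'   column names), one entry per annotation, each of length `panel$M`.
#' @param kind Character vector, `"binary"` or `"probabilistic"`, recycled.
#' @param role Character vector, `"celltype"`, `"baseline"` or
#'   `"background"`, recycled.
#' @return An `annot_stack` tibble.
#' @export
annot_stack <- function(panel, values, kind = "binary", role = "celltype") {
  if (is.matrix(values)) {
    values <- setNames(lapply(seq_len(ncol(values)), function(j) values[, j]),
                       colnames(values))
  }
  if (is.null(names(values)) || any(names(values) == "")) {
    abort("every annotation needs a name")
  }
  kind <- rep_len(kind, length(values))
  role <- rep_len(role, length(values))
  for (i in seq_along(values)) {
    v <- values[[i]]
    if (length(v) != panel$M) {
      abort(paste0("annotation '", names(values)[i], "' has length ", length(v),
                   " but the panel has M = ", panel$M, " SNPs"))
    }
    if (any(v < 0 | v > 1)) {
      abort(paste0("annotation '", names(values)[i], "' has values outside [0, 1]"))
    }
    if (kind[i] == "binary" && !all(v %in% c(0, 1))) {
      abort(paste0("annotation '", names(values)[i],
                   "' declared binary but has non-0/1 values"))
    }
  }
  out <- panel$snps[, c("snp", "chrom", "pos", "cm")]
  for (nm in names(values)) out[[nm]] <- as.numeric(values[[nm]])
  meta <- tibble(name = names(values), kind = kind, role = role)
  new_annot_stack(out, meta)
}

new_annot_stack <- function(tbl, meta) {
  structure(tbl, annot_meta = meta,
            class = c("annot_stack", class(tibble())))
}

#' Per-annotation metadata of a stack
#' @param stack An `annot_stack`.
#' @return Tibble with columns `name`, `kind`, `role`.
#' @export
annot_meta <- function(stack) attr(stack, "annot_meta")

#' Annotation names of a stack
#' @param stack An `annot_stack`.
#' @param role Optional role filter (`celltype`, `baseline`, `background`).
#' @return Character vector of annotation names.
#' @export
annot_names <- function(stack, role = NULL) {
  meta <- annot_meta(stack)
  if (!is.null(role)) meta <- meta[meta$role %in% role, , drop = FALSE]
  meta$name
}

#' Annotation values as a matrix (SNPs x annotations)
#' @param stack An `annot_stack`.
#' @param names Annotation names to extract (default all).
#' @return Numeric matrix.
#' @export
annot_matrix <- function(stack, names = NULL) {
  names <- names %||% annot_names(stack)
  as.matrix(as.data.frame(stack)[, names, drop = FALSE])
}

#' Combine annotation stacks aligned to the same panel
#' @param ... `annot_stack` objects sharing identical SNP rows.
#' @return A single `annot_stack`.
#' @export
bind_annotations <- function(...) {
  stacks <- list(...)
  base <- stacks[[1]]
  for (s in stacks[-1]) {
    if (!identical(s$snp, base$snp)) {
      abort("annotation stacks are aligned to different panels")
    }
  }
  tbl <- base[, c("snp", "chrom", "pos", "cm")]
  metas <- purrr::map(stacks, annot_meta)
  for (i in seq_along(stacks)) {
    for (nm in metas[[i]]$name) tbl[[nm]] <- as.data.frame(stacks[[i]])[[nm]]
  }
  meta <- dplyr::bind_rows(metas)
  if (anyDuplicated(meta$name)) {
    abort(paste0("duplicate annotation name: ", meta$name[duplicated(meta$name)][1]))
  }
  new_annot_stack(tbl, meta)
}

#' Pearson correlation between two annotations
#'
#' Correlation across panel SNPs of two annotation value vectors. A constant
#' vector has no defined correlation; by convention 0 is returned with a
#' warning so downstream summaries stay NaN-free.
#'
#' @param a,b Numeric vectors of equal length (annotation values), or
#'   one-annotation stacks.
#' @return Pearson correlation (scalar).
#' @export
annotation_correlation <- function(a, b) {
  a <- annotation_values(a)
  b <- annotation_values(b)
  if (length(a) != length(b)) abort("annotations have different lengths")
  if (sd(a) == 0 || sd(b) == 0) {
    warn("constant annotation; correlation defined as 0")
    return(0)
  }
  cor(a, b)
}

annotation_values <- function(x) {
  if (inherits(x, "annot_stack")) {
    nms <- annot_names(x)
    if (length(nms) != 1) abort("expected a single-annotation stack")
    return(as.data.frame(x)[[nms]])
  }
  as.numeric(x)
}

#' Binarize a probabilistic annotation
#'
#' Converts every positive score to 1 (the binarized variant used to test how
#' much the graded scores matter). Idempotent; the result is flagged binary.
#'
#' @param stack An `annot_stack` (any number of annotations).
#' @return The stack with values in \{0, 1\} and `kind = "binary"`.
#' @export
binarize_annotation <- function(stack) {
  meta <- annot_meta(stack)
  tbl <- as.data.frame(stack)
  for (nm in meta$name) tbl[[nm]] <- as.numeric(tbl[[nm]] > 0)
  meta$kind <- "binary"
  new_annot_stack(as_tibble(tbl), meta)
}
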