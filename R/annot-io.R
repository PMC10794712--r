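#' Write an annotation stack in annot format
#'
#' The annot dialect is a TSV with header `CHR BP SNP CM` followed by one
#' column per annotation; one row per panel SNP. Values round-trip to 6
#' decimal places.
#'
#' @param stack An `annot_stack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annot <- function(stack, path) {
  meta <- annot_meta(stack)
  tbl <- as.data.frame(stack)
  out <- data.frame(CHR = tbl$chrom, BP = tbl$pos, SNP = tbl$snp, CM = tbl$cm,
                    check.names = FALSE)
  for (nm in meta$name) out[[nm]] <- round(tbl[[nm]], 6)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read an annotation stack from annot format
#'
#' Annotation kind is inferred from the values (binary iff all in \{0, 1\});
#' role is inferred from the column name — names starting with `base` are
#' baseline, names containing `background` or `union` are background, all
#' others cell-type.
#'
#' @param path Path to an annot TSV written by [write_annot()] (or the same
#'   dialect from elsewhere).
#' @param panel Optional [snp_panel]; when given, SNP rows must match the
#'   panel exactly.
#' @return An `annot_stack`.
#' @export
read_annot <- function(path, panel = NULL) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           sep = "\t", check.names = FALSE)
  fixed <- c("CHR", "BP", "SNP", "CM")
  if (!all(fixed %in% names(tab))) {
    abort("annot file must have CHR, BP, SNP, CM columns")
  }
  ann_cols <- setdiff(names(tab), fixed)
  if (!is.null(panel)) {
    if (!identical(as.character(tab$SNP), panel$snps$snp)) {
      abort("annot rows do not match the panel's SNPs")
    }
  }
  tbl <- tibble(snp = as.character(tab$SNP), chrom = as.character(tab$CHR),
                pos = tab$BP, cm = tab$CM)
  kinds <- character(length(ann_cols)); roles <- character(length(ann_cols))
  for (i in seq_along(ann_cols)) {
    v <- as.numeric(tab[[ann_cols[i]]])
    tbl[[ann_cols[i]]] <- v
    kinds[i] <- if (all(v %in% c(0, 1))) "binary" else "probabilistic"
    roles[i] <- infer_annot_role(ann_cols[i])
  }
  new_annot_stack(tbl, tibble(name = ann_cols, kind = kinds, role = roles))
}

infer_annot_role <- function(name) {
  lo <- tolower(name)
  if (grepl("^base", lo)) return("baseline")
  if (grepl("background|union", lo)) return("background")
  "celltype"
}

#' Write an association table as TSV
#'
#' One header line then one row per (trait, cell type) pair.
#'
#' @param table Association tibble (see [scan_associations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  utils::write.table(as.data.frame(table), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Read an association table written by [write_results()]
#' @param path Path to the results TSV.
#' @return A tibble.
#' @export
read_results <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}

#' Write a sumstats table in the LDSC dialect
#' @param ss Sumstats tibble (`snp`, `a1`, `a2`, `n`, `z`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  out <- data.frame(SNP = ss$snp, A1 = ss$a1, A2 = ss$a2, N = ss$n, Z = ss$z)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Write / read stratified LD scores as TSV
#'
#' Column `SNP` then one LD-score column per annotation.
#' @param table LD-score tibble from [ld_scores()].
#' @param path File path.
#' @return `path` (write) or a tibble (read).
#' @export
write_ldscores <- function(table, path) {
  out <- as.data.frame(table)
  names(out)[names(out) == "snp"] <- "SNP"
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_ldscores
#' @export
read_ldscores <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  names(tab)[names(tab) == "SNP"] <- "snp"
  as_tibble(tab)
}
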