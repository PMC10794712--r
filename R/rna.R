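#' Labeled cell-by-gene expression counts
#'
#' Thin container for a sparse cells x genes count matrix with one cell-type
#' label per cell. Total counts per cell are computed from the matrix.
#'
#' @param counts Cells x genes matrix of non-negative counts (dense or
#'   `Matrix` sparse). Row names = cell ids, column names = gene ids (filled
#'   in if absent).
#' @param labels Character/factor vector of cell-type labels, one per cell.
#' @return An object of class `expression_matrix` with elements `counts`,
#'   `labels`, `cells`, `genes`, `total_counts`.
#' @export
expression_matrix <- function(counts, labels) {
  counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  if (length(labels) != nrow(counts)) {
    abort("need exactly one cell-type label per cell (matrix row)")
  }
  if (any(counts@x < 0)) abort("negative counts")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("gene", seq_len(ncol(counts)))
  structure(
    list(counts = counts, labels = as.character(labels),
         cells = rownames(counts), genes = colnames(counts),
         total_counts = Matrix::rowSums(counts)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes, ", length(unique(x$labels)), " cell types\n", sep = "")
  invisible(x)
}

#' Read a MatrixMarket expression directory
#'
#' Expects `matrix.mtx` (genes x cells, the common single-cell convention),
#' `features.tsv` (gene ids, first column), `barcodes.tsv` (cell ids) and a
#' labels TSV with columns `cell` and `celltype`.
#'
#' @param dir Directory containing the four files.
#' @param labels_path Path to the label TSV (default `<dir>/labels.tsv`).
#' @return An [expression_matrix].
#' @export
read_expression <- function(dir, labels_path = file.path(dir, "labels.tsv")) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- utils::read.table(file.path(dir, "features.tsv"),
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.table(file.path(dir, "barcodes.tsv"),
                             stringsAsFactors = FALSE)[[1]]
  counts <- Matrix::t(m)   # to cells x genes
  rownames(counts) <- cells
  colnames(counts) <- genes
  lab <- utils::read.table(labels_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("cell", "celltype") %in% names(lab))) {
    abort("labels TSV needs 'cell' and 'celltype' columns")
  }
  idx <- match(cells, lab$cell)
  if (anyNA(idx)) abort("some barcodes have no cell-type label")
  expression_matrix(counts, lab$celltype[idx])
}

#' Write an expression matrix as a MatrixMarket directory
#' @param expr An [expression_matrix].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_expression <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(expr$counts), file.path(dir, "matrix.mtx"))
  writeLines(expr$genes, file.path(dir, "features.tsv"))
  writeLines(expr$cells, file.path(dir, "barcodes.tsv"))
  utils::write.table(data.frame(cell = expr$cells, celltype = expr$labels),
                     file.path(dir, "labels.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(dir)
}

#' log2(TP10K + 1) normalization
#'
#' Scales each cell's counts to transcripts-per-10,000 and log-transforms:
#' entry = log2(10000 * count / total_counts + 1). Cells with zero total
#' counts are dropped with a warning.
#'
#' @param expr An [expression_matrix].
#' @return A list with `norm` (dense cells x genes matrix) and `labels`
#'   (after any zero-count cells are dropped).
#' @export
normalize_expression <- function(expr) {
  keep <- expr$total_counts > 0
  if (any(!keep)) {
    warn(paste0(sum(!keep), " cell(s) with zero total counts dropped"))
  }
  counts <- expr$counts[keep, , drop = FALSE]
  tot <- expr$total_counts[keep]
  norm <- as.matrix(counts / tot * 1e4)
  norm <- log2(norm + 1)
  dimnames(norm) <- dimnames(counts)
  list(norm = norm, labels = expr$labels[keep])
}

#' Specific-expression gene scores per cell type
#'
#' For each cell type and each gene in the tested universe, runs a one-sided
#' Wilcoxon rank-sum test of the gene's normalized expression in the focal
#' cell type against all other cells (focal greater). Within each cell type,
#' `-2 log(p)` is min-max normalized over the gene universe to a specific-
#' expression score in \[0, 1\]: the most specifically expressed gene scores
#' 1, the least 0.
#'
#' Mid-ranks with a tie-corrected normal approximation (continuity corrected)
#' are used; when both groups have at most `exact_max` cells and the gene has
#' no ties, the exact null distribution of the rank sum is used instead. The
#' gene universe defaults to genes expressed (value > 0) in at least
#' `min_cells` cells.
#'
#' @param norm Cells x genes normalized matrix (e.g. from
#'   [normalize_expression()]), or the list that function returns.
#' @param labels Cell-type label per cell (ignored when `norm` is the list).
#' @param min_cells Minimum number of expressing cells for a gene to enter
#'   the universe (default 10).
#' @param alternative `"greater"` (default; specific *expression*) or
#'   `"two.sided"`.
#' @param exact_max Largest group size for the exact test path (default 10).
#' @return A `gene_scores` tibble: `gene` plus one score column per cell
#'   type; the per-gene one-sided p-values are in the `"pvalues"` attribute
#'   (same shape).
#' @export
specific_expression_scores <- function(norm, labels = NULL, min_cells = 10,
                                       alternative = c("greater", "two.sided"),
                                       exact_max = 10) {
  alternative <- match.arg(alternative)
  if (is.list(norm) && !is.matrix(norm)) {
    labels <- norm$labels
    norm <- norm$norm
  }
  labels <- as.character(labels)
  types <- sort(unique(labels))
  if (length(types) < 2) abort("need at least 2 cell types")
  universe <- which(Matrix::colSums(norm > 0) >= min_cells)
  if (length(universe) == 0) abort("no genes pass the expression universe filter")
  x <- norm[, universe, drop = FALSE]
  ranks <- apply(x, 2, rank)          # mid-ranks, per gene
  n_tot <- nrow(x)
  # tie term sum(t^3 - t) per gene, for the rank-sum variance
  tie_term <- apply(x, 2, function(v) {
    t <- tabulate(match(v, unique(v)))
    sum(t^3 - t)
  })
  has_ties <- tie_term > 0
  pmat <- matrix(NA_real_, nrow = ncol(x), ncol = length(types),
                 dimnames = list(colnames(x), types))
  for (ti in seq_along(types)) {
    focal <- labels == types[ti]
    m1 <- sum(focal); n2 <- n_tot - m1
    if (m1 == 0) abort(paste0("cell type '", types[ti], "' has no cells"))
    u <- colSums(ranks[focal, , drop = FALSE]) - m1 * (m1 + 1) / 2
    mu <- m1 * n2 / 2
    sig2 <- m1 * n2 / 12 * ((n_tot + 1) - tie_term / (n_tot * (n_tot - 1)))
    z <- (u - mu - 0.5) / sqrt(pmax(sig2, .Machine$double.eps))
    p <- pnorm(z, lower.tail = FALSE)
    p[sig2 == 0] <- 1
    exact_ok <- !has_ties & m1 <= exact_max & n2 <= exact_max
    if (any(exact_ok)) {
      p[exact_ok] <- pwilcox(u[exact_ok] - 1, m1, n2, lower.tail = FALSE)
    }
    if (alternative == "two.sided") p <- pmin(2 * pmin(p, 1 - p), 1)
    pmat[, ti] <- pmin(pmax(p, .Machine$double.xmin), 1)
  }
  smat <- apply(pmat, 2, minmax_neg2logp)
  out <- tibble(gene = rownames(pmat))
  for (ti in seq_along(types)) out[[types[ti]]] <- unname(smat[, ti])
  pv <- tibble(gene = rownames(pmat))
  for (ti in seq_along(types)) pv[[types[ti]]] <- unname(pmat[, ti])
  structure(out, pvalues = pv, class = c("gene_scores", class(tibble())))
}

minmax_neg2logp <- function(p) {
  x <- -2 * log(p)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warn("all -2 log(p) equal within a cell type; scores set to 0")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Link gene scores to SNPs
#'
#' Builds one probabilistic SNP annotation per cell type: each SNP's value is
#' the maximum specific-expression score among the genes linked to it, or 0
#' when no scored gene is linked. Two linking strategies: `enhancer_links`
#' uses an interval set with a `gene` column (enhancer-gene links); `window`
#' links every SNP within the gene body extended by `window_bp` on each side.
#'
#' @param scores A `gene_scores` tibble from [specific_expression_scores()].
#' @param panel A [snp_panel].
#' @param strategy `"enhancer_links"` or `"window"`.
#' @param links Interval tibble with a `gene` column (enhancer_links).
#' @param genes Gene-body tibble with `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive; window strategy).
#' @param window_bp Window half-width in bp (default 100000).
#' @return An `annot_stack` with one probabilistic celltype annotation per
#'   cell type.
#' @export
link_snps <- function(scores, panel, strategy = c("enhancer_links", "window"),
                      links = NULL, genes = NULL, window_bp = 1e5) {
  strategy <- match.arg(strategy)
  pairs <- snp_gene_pairs(panel, strategy, links, genes, window_bp)
  types <- setdiff(names(scores), "gene")
  unknown <- setdiff(unique(pairs$gene), scores$gene)
  if (length(unknown) > 0) {
    inform(paste0(length(unknown), " linked gene(s) absent from the score ",
                  "matrix; ignored"))
  }
  pairs <- pairs[pairs$gene %in% scores$gene, , drop = FALSE]
  vals <- purrr::map(types, function(ct) {
    s <- scores[[ct]][match(pairs$gene, scores$gene)]
    v <- rep(0, panel$M)
    if (nrow(pairs) > 0) {
      agg <- tapply(s, pairs$snp_idx, max)
      v[as.integer(names(agg))] <- as.numeric(agg)
    }
    v
  })
  annot_stack(panel, setNames(vals, types), kind = "probabilistic",
              role = "celltype")
}

snp_gene_pairs <- function(panel, strategy, links, genes, window_bp) {
  snp_gr <- snps_to_granges(panel$snps)
  if (strategy == "enhancer_links") {
    if (is.null(links) || is.null(links$gene)) {
      abort("enhancer_links strategy needs a link set with a gene column")
    }
    if (nrow(links) == 0) {
      return(tibble(snp_idx = integer(), gene = character()))
    }
    gr <- intervals_to_granges(links)
    gene_of <- links$gene
  } else {
    if (is.null(genes)) abort("window strategy needs gene body coordinates")
    if (nrow(genes) == 0) {
      return(tibble(snp_idx = integer(), gene = character()))
    }
    gr <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = pmax(genes$start - window_bp, 1),
                                end = genes$end + window_bp)
    )
    gene_of <- genes$gene
  }
  hits <- GenomicRanges::findOverlaps(snp_gr, gr)
  dplyr::distinct(tibble(snp_idx = S4Vectors::queryHits(hits),
                         gene = gene_of[S4Vectors::subjectHits(hits)]))
}

#' Union-of-links background annotation
#'
#' Binary annotation, 1 for every SNP linked to at least one analyzed gene
#' under the chosen strategy — the conditioning analogue of the
#' open-chromatin union for expression-derived annotations.
#'
#' @inheritParams link_snps
#' @param name Annotation name (default `"background_links"`).
#' @return A one-annotation binary `annot_stack`, role background.
#' @export
union_links_background <- function(scores, panel,
                                   strategy = c("enhancer_links", "window"),
                                   links = NULL, genes = NULL, window_bp = 1e5,
                                   name = "background_links") {
  strategy <- match.arg(strategy)
  pairs <- snp_gene_pairs(panel, strategy, links, genes, window_bp)
  pairs <- pairs[pairs$gene %in% scores$gene, , drop = FALSE]
  v <- rep(0, panel$M)
  v[unique(pairs$snp_idx)] <- 1
  annot_stack(panel, setNames(list(v), name), kind = "binary",
              role = "background")
}

#' Build the full RNA annotation stack for one dataset
#'
#' Normalizes, scores specific expression, links SNPs, and appends the
#' union-of-links background.
#'
#' @param expr An [expression_matrix].
#' @inheritParams link_snps
#' @param binarize Convert positive scores to 1 (secondary-analysis variant).
#' @param min_cells Gene-universe threshold passed to
#'   [specific_expression_scores()].
#' @return An `annot_stack`: one annotation per cell type plus the background.
#' @export
build_rna_annotations <- function(expr, panel,
                                  strategy = c("enhancer_links", "window"),
                                  links = NULL, genes = NULL, window_bp = 1e5,
                                  binarize = FALSE, min_cells = 10) {
  strategy <- match.arg(strategy)
  nz <- normalize_expression(expr)
  scores <- specific_expression_scores(nz, min_cells = min_cells)
  ct <- link_snps(scores, panel, strategy, links = links, genes = genes,
                  window_bp = window_bp)
  if (binarize) ct <- binarize_annotation(ct)
  bg <- union_links_background(scores, panel, strategy, links = links,
                               genes = genes, window_bp = window_bp)
  bind_annotations(ct, bg)
}
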