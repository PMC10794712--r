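#' Study design: traits x datasets
#'
#' Bundles the trait table (names, heritability z-scores, optional sumstats
#' paths, control-trait flags), the per-dataset cell-type rosters, and a
#' precomputed trait-by-trait genetic-correlation matrix.
#'
#' @param traits Tibble with at least `trait` and `h2_z`; optional `sumstats`
#'   (file path) and `control` (logical, default FALSE).
#' @param datasets Named list: one character vector of cell-type names per
#'   dataset.
#' @param genetic_correlation Optional symmetric matrix with unit diagonal,
#'   dimnames = trait names.
#' @return A `study_design` list.
#' @export
study_design <- function(traits, datasets, genetic_correlation = NULL) {
  traits <- as_tibble(traits)
  if (!all(c("trait", "h2_z") %in% names(traits))) {
    abort("traits table needs 'trait' and 'h2_z' columns")
  }
  if (!("control" %in% names(traits))) traits$control <- FALSE
  if (!is.null(genetic_correlation)) {
    g <- genetic_correlation
    if (!isTRUE(all.equal(g, t(g))) || !isTRUE(all.equal(unname(diag(g)),
                                                         rep(1, nrow(g))))) {
      abort("genetic correlation matrix must be symmetric with unit diagonal")
    }
  }
  structure(list(traits = traits, datasets = datasets,
                 genetic_correlation = genetic_correlation),
            class = "study_design")
}

#' Enumerate the trait x cell-type pairs of a design
#'
#' @param design A [study_design()].
#' @param control Include control traits (default FALSE: brain traits only).
#' @return Tibble with one row per (dataset, trait, celltype) and a summary
#'   in the `"pair_counts"` attribute (per-dataset pair counts and the total
#'   number of cell types).
#' @export
plan_pairs <- function(design, control = FALSE) {
  traits <- design$traits$trait[design$traits$control == control]
  rows <- purrr::imap(design$datasets, function(cts, ds) {
    tidyr::expand_grid(dataset = ds, trait = traits, celltype = cts)
  })
  out <- dplyr::bind_rows(rows)
  counts <- tibble(
    dataset = names(design$datasets),
    n_celltypes = unname(purrr::map_int(design$datasets, length)),
    n_traits = length(traits),
    n_pairs = unname(purrr::map_int(design$datasets,
                                    ~ length(.x) * length(traits)))
  )
  attr(out, "pair_counts") <- counts
  out
}

#' Prune genetically correlated traits
#'
#' While any retained pair of traits has absolute genetic correlation at or
#' above `r_max`, the member with the lower heritability z-score is dropped.
#' When several pairs violate the threshold, the pair with the largest
#' absolute correlation is resolved first; ties (equal correlation, or equal
#' z-scores within a pair) are broken lexicographically, dropping the later
#' trait id.
#'
#' @param design A [study_design()] with a genetic-correlation matrix.
#' @param r_max Correlation threshold (default 0.9).
#' @return Character vector of retained trait names.
#' @export
prune_traits <- function(design, r_max = 0.9) {
  g <- design$genetic_correlation
  if (is.null(g)) abort("design has no genetic-correlation matrix")
  traits <- design$traits$trait
  if (!all(traits %in% rownames(g))) {
    abort(paste0("missing correlation entry for trait: ",
                 setdiff(traits, rownames(g))[1]))
  }
  z <- setNames(design$traits$h2_z, traits)
  retained <- traits
  repeat {
    gm <- abs(g[retained, retained, drop = FALSE])
    diag(gm) <- 0
    if (length(retained) < 2 || max(gm) < r_max) break
    idx <- which(gm == max(gm), arr.ind = TRUE)[1, ]
    pair <- sort(c(retained[idx[1]], retained[idx[2]]))
    drop <- if (z[pair[1]] < z[pair[2]]) {
      pair[1]
    } else if (z[pair[2]] < z[pair[1]]) {
      pair[2]
    } else {
      pair[2]   # equal z: drop the lexicographically later id
    }
    retained <- setdiff(retained, drop)
  }
  retained
}

#' Scan one dataset: every trait against every cell type
#'
#' For each (trait, cell type) pair, fits the stratified regression with the
#' focal cell-type annotation conditioned on every baseline and background
#' annotation in the stack, and records tau*, its SE, and the one-sided
#' p-value for positive tau*. A failed fit flags the row and the scan
#' continues. LD scores are computed once per annotation column and reused
#' across traits and focal cell types.
#'
#' @param sumstats Named list of sumstats tibbles, one per trait.
#' @param table LD-score tibble covering every stack annotation.
#' @param stack `annot_stack` with celltype, baseline and background roles.
#' @param config A [regression_config()].
#' @param dataset Dataset label for the output rows.
#' @return An association tibble (pre-FDR): one row per (trait, celltype)
#'   with `tau_star`, `tau_star_se`, `p`, `enrichment`, `failed`.
#' @export
scan_associations <- function(sumstats, table, stack,
                              config = regression_config(),
                              dataset = "dataset") {
  celltypes <- annot_names(stack, role = "celltype")
  cond <- annot_names(stack, role = c("baseline", "background"))
  if (length(celltypes) == 0) abort("stack has no celltype annotations")
  grid <- tidyr::expand_grid(trait = names(sumstats), celltype = celltypes)
  rows <- purrr::pmap(grid, function(trait, celltype) {
    sub <- subset_stack(stack, c(celltype, cond))
    res <- tryCatch({
      f <- sldsc(sumstats[[trait]], table, sub, config)
      cf <- f$coef[f$coef$annotation == celltype, ]
      tibble(trait = trait, celltype = celltype, dataset = dataset,
             tau_star = cf$tau_star, tau_star_se = cf$tau_star_se,
             p = cf$p_pos, enrichment = cf$enrichment, failed = FALSE)
    }, error = function(e) {
      tibble(trait = trait, celltype = celltype, dataset = dataset,
             tau_star = NA_real_, tau_star_se = NA_real_, p = NA_real_,
             enrichment = NA_real_, failed = TRUE)
    })
    res
  })
  dplyr::bind_rows(rows)
}

# stack restricted to the named annotations, order preserved as given
subset_stack <- function(stack, names) {
  meta <- annot_meta(stack)
  meta <- meta[match(names, meta$name), , drop = FALSE]
  tbl <- as.data.frame(stack)[, c("snp", "chrom", "pos", "cm", names),
                              drop = FALSE]
  new_annot_stack(as_tibble(tbl), meta)
}

#' Per-dataset FDR with negative-tau* exclusion
#'
#' Rows with negative tau* are marked `excluded_negative` and removed from
#' the multiple-testing family; Benjamini-Hochberg q-values are computed over
#' the remaining rows within each (dataset, control-flag) family. A row is
#' significant iff q < `q_threshold` and tau* > 0. A Bonferroni flag is also
#' reported (denominator = family size after exclusion by default, or before
#' with `bonferroni_pre_exclusion`).
#'
#' @param table Association tibble from [scan_associations()]; an optional
#'   `control` column splits control traits into their own family.
#' @param q_threshold FDR threshold (default 0.05).
#' @param bonferroni_pre_exclusion Use the pre-exclusion family size as the
#'   Bonferroni denominator (default FALSE).
#' @return The table with `q`, `significant`, `excluded_negative`,
#'   `bonferroni` columns.
#' @export
fdr_correct <- function(table, q_threshold = 0.05,
                        bonferroni_pre_exclusion = FALSE) {
  if (!("control" %in% names(table))) table$control <- FALSE
  table$excluded_negative <- !is.na(table$tau_star) & table$tau_star < 0
  table$q <- NA_real_
  table$significant <- FALSE
  table$bonferroni <- FALSE
  for (key in unique(paste(table$dataset, table$control))) {
    fam_all <- paste(table$dataset, table$control) == key
    fam <- fam_all & !table$excluded_negative & !is.na(table$p) &
      !is.na(table$tau_star)
    m <- sum(fam)
    if (m == 0) next
    table$q[fam] <- p.adjust(table$p[fam], method = "BH")
    table$significant[fam] <- table$q[fam] < q_threshold &
      table$tau_star[fam] > 0
    m_bonf <- if (bonferroni_pre_exclusion) sum(fam_all) else m
    table$bonferroni[fam] <- table$p[fam] < q_threshold / m_bonf &
      table$tau_star[fam] > 0
  }
  table
}

#' Concordance between two association tables
#'
#' Pearson correlation of -log10 p-values over (trait, celltype) rows matched
#' across the two tables. `match_on` optionally renames table B's cell types
#' to table A's naming before matching (named character vector,
#' names = B's cell types, values = A's).
#'
#' @param table_a,table_b Association tibbles.
#' @param match_on Optional cell-type name mapping for table B.
#' @return List with `r` (correlation of -log10 p), `n` (matched rows) and
#'   the matched tibble.
#' @export
concordance <- function(table_a, table_b, match_on = NULL) {
  b <- table_b
  if (!is.null(match_on)) {
    hit <- b$celltype %in% names(match_on)
    b$celltype[hit] <- match_on[b$celltype[hit]]
  }
  m <- dplyr::inner_join(
    dplyr::select(table_a, "trait", "celltype", p_a = "p"),
    dplyr::select(b, "trait", "celltype", p_b = "p"),
    by = c("trait", "celltype")
  )
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) abort("fewer than 3 matched (trait, celltype) rows")
  r <- cor(-log10(m$p_a), -log10(m$p_b))
  list(r = r, n = nrow(m), matched = m)
}
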