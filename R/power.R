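#' Planted-effect detection power of the file-based pipeline
#'
#' For each seed, writes a complete synthetic study fixture directory with
#' [simulate_study()] (one trait carrying the planted focal cell-type
#' effect, the rest null), runs the file-based pipeline with
#' [run_pipeline()], and records whether the planted (trait, cell type)
#' pair is the top-ranked association (smallest p) and whether it is
#' FDR-significant, along with false discoveries among null pairs.
#'
#' @param cfg A [sim_config()]; per-seed configs differ only in `seed`.
#' @param seeds Integer vector of seeds.
#' @param dir Scratch directory for fixtures (default tempdir; each seed
#'   overwrites it).
#' @return Tibble with one row per seed: `seed`, `top_ranked`,
#'   `significant`, `n_null_significant`, `n_pairs`.
#' @export
power_run <- function(cfg, seeds, dir = file.path(tempdir(), "h2scan_power")) {
  purrr::map_dfr(seeds, function(s) {
    cfg$seed <- s
    unlink(dir, recursive = TRUE)
    simulate_study(cfg, dir)
    truth <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
    res <- run_pipeline(dir)
    ok <- !res$failed & !is.na(res$p)
    top <- res[ok, ][which.min(res$p[ok]), ]
    planted <- res$trait == truth$trait & res$celltype == truth$celltype
    tibble(
      seed = s,
      top_ranked = top$trait == truth$trait & top$celltype == truth$celltype,
      significant = any(res$significant[planted]),
      n_null_significant = sum(res$significant[!planted]),
      n_pairs = nrow(res)
    )
  })
}
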