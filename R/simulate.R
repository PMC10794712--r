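#' Simulation configuration
#'
#' One object holds every knob of the synthetic-data generators: the
#' LD-block-structured reference panel, the annotation stack, the GWAS
#' summary statistics following the per-SNP heritability model, the labeled
#' expression counts with planted marker genes, and the peak/link interval
#' files. All randomness flows from `seed`; each generator derives its own
#' named stream so stages can be regenerated independently, and an identical
#' config yields identical output bytes.
#'
#' @param seed Integer master seed.
#' @param n_snps,n_samples Panel dimensions (default 5000 SNPs, 300 samples).
#' @param block_size SNPs per LD block (default 20).
#' @param within_block_r Expected pairwise genotype correlation within a
#'   block (default 0.5); across blocks the expectation is 0.
#' @param maf_range MAF range, uniform (default 0.05-0.5).
#' @param genotype_mode `"dosage"` (Gaussian dosages with exact target
#'   correlation) or `"hardcall"` (0/1/2 calls via a Gaussian copula; the
#'   realized correlation is attenuated by discretization). Fixture
#'   directories use hardcall so the PLINK round trip is lossless.
#' @param gwas_n GWAS sample size (default 50000).
#' @param h2_target Total SNP heritability of simulated traits (default
#'   0.05; the synthetic panels have orders of magnitude fewer SNPs than a
#'   genome-wide panel, so total h2 is scaled down to keep the per-SNP
#'   signal N*h2/M on a realistic GWAS scale).
#' @param tau_star_target Standardized effect size planted on the focal
#'   cell-type annotation of the study generator (default 1).
#' @param n_celltypes,cells_per_type,n_genes Expression dimensions
#'   (default 3 types x 200 cells, 300 genes).
#' @param n_markers Marker genes per cell type (default 10).
#' @param marker_fold Rate multiplier of a marker gene in its own cell type
#'   (default 8).
#' @param peak_coverage Fraction of panel SNPs covered by each cell type's
#'   peaks (default 0.1).
#' @param n_traits Traits emitted by the study generator (default 3: one
#'   with the planted focal effect, the rest null).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_snps = 5000, n_samples = 300,
                       block_size = 20, within_block_r = 0.5,
                       maf_range = c(0.05, 0.5),
                       genotype_mode = c("dosage", "hardcall"),
                       gwas_n = 50000, h2_target = 0.05, tau_star_target = 1,
                       n_celltypes = 3, cells_per_type = 200, n_genes = 300,
                       n_markers = 10, marker_fold = 8,
                       peak_coverage = 0.1, n_traits = 3) {
  genotype_mode <- match.arg(genotype_mode)
  if (within_block_r < 0 || within_block_r >= 1) {
    abort("within_block_r must be in [0, 1)")
  }
  stopifnot(n_snps > 0, n_samples > 0, block_size > 0)
  structure(as.list(environment()), class = "sim_config")
}

# named sub-stream: deterministic per (seed, generator name), < 2^31
sub_seed <- function(seed, name) {
  ((as.numeric(seed) %% 1e5) * 17681 + sum(utf8ToInt(name)) * 131) %%
    2147483647
}

#' Simulate an LD-block-structured reference panel
#'
#' SNPs come in contiguous blocks; within a block genotypes share a common
#' Gaussian factor so every within-block pair has expected correlation
#' `within_block_r`, and blocks are independent. Genetic-map positions place
#' each block in its own 2-cM slot so the default 1-cM LD window spans
#' exactly one block. Dosage mode scales the Gaussian to mean 2*maf and
#' variance 2*maf*(1-maf); hardcall mode thresholds through a Gaussian
#' copula into 0/1/2 calls.
#'
#' @param cfg A [sim_config()].
#' @return A [snp_panel].
#' @export
simulate_panel <- function(cfg) {
  set.seed(sub_seed(cfg$seed, "panel"))
  m <- cfg$n_snps; n <- cfg$n_samples
  block <- ((seq_len(m) - 1) %/% cfg$block_size) + 1
  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  r <- cfg$within_block_r
  x <- matrix(0, nrow = n, ncol = m)
  for (b in unique(block)) {
    idx <- which(block == b)
    f <- rnorm(n)
    e <- matrix(rnorm(n * length(idx)), nrow = n)
    x[, idx] <- sqrt(r) * f + sqrt(1 - r) * e
  }
  if (cfg$genotype_mode == "dosage") {
    geno <- sweep(sweep(x, 2, sqrt(2 * maf * (1 - maf)), "*"),
                  2, 2 * maf, "+")
  } else {
    geno <- matrix(qbinom(pnorm(as.vector(x)), 2, rep(maf, each = n)),
                   nrow = n, ncol = m)
  }
  within_block_offset <- ((seq_len(m) - 1) %% cfg$block_size) * 0.001
  snps <- tibble(
    snp = sprintf("rs%06d", seq_len(m)),
    chrom = "1",
    pos = seq_len(m) * 5000L,
    cm = (block - 1) * 2 + within_block_offset,
    a1 = "A", a2 = "G",
    maf = if (cfg$genotype_mode == "dosage") maf else genotype_maf(geno)
  )
  snp_panel(snps, geno)
}

#' Simulate an annotation stack
#'
#' Binary annotations by independent Bernoulli SNP membership at the stated
#' coverage; probabilistic annotations by Beta(2, 2) draws on a Bernoulli
#' support. An all-ones `base` annotation (role baseline) is appended.
#'
#' @param panel A [snp_panel].
#' @param spec Tibble with columns `name`, `coverage` in (0, 1\], and
#'   optional `kind` (default binary) and `role` (default celltype).
#' @param seed Integer seed.
#' @return An `annot_stack`.
#' @export
simulate_annotations <- function(panel, spec, seed = 1) {
  spec <- as_tibble(spec)
  if (!("kind" %in% names(spec))) spec$kind <- "binary"
  if (!("role" %in% names(spec))) spec$role <- "celltype"
  if (any(spec$coverage <= 0 | spec$coverage > 1)) {
    abort("coverage must be in (0, 1]")
  }
  set.seed(sub_seed(seed, "annotations"))
  vals <- purrr::pmap(spec, function(name, coverage, kind, role, ...) {
    support <- rbinom(panel$M, 1, coverage)
    if (kind == "binary") as.numeric(support)
    else support * stats::rbeta(panel$M, 2, 2)
  })
  names(vals) <- spec$name
  vals$base <- rep(1, panel$M)
  annot_stack(panel, vals,
              kind = c(spec$kind, "binary"),
              role = c(spec$role, "baseline"))
}

#' Simulate GWAS summary statistics under the heritability model
#'
#' Per-SNP effect variance is the linear annotation model
#' Var(beta_j) = sum_c a_cj tau_c (negative totals truncated at 0 with a
#' warning), so the marginal z-score satisfies
#' E\[chi2_j\] = 1 + N * sum_c l(j,c) tau_c with the LD scores l computed
#' from the panel itself (unadjusted estimator, default window). z_j is
#' drawn as sqrt(1 + N sum_c l(j,c) tau_c) * eps_j with standard-normal eps,
#' independent across SNPs by default or LD-correlated within blocks via a
#' Cholesky factor of the block genotype correlation when
#' `correlated_noise = TRUE`.
#'
#' @param panel A [snp_panel].
#' @param stack `annot_stack` defining the architecture.
#' @param tau_true Named (or stack-ordered) per-annotation tau vector.
#' @param gwas_n GWAS sample size N.
#' @param seed Integer seed.
#' @param correlated_noise Draw eps with within-block LD correlation.
#' @param ldsc_table Optional precomputed LD-score tibble (unadjusted) to
#'   avoid recomputation across replicates.
#' @return Sumstats tibble (`snp`, `a1`, `a2`, `n`, `z`, `chi2`) with the LD
#'   scores used in the `"ldscores"` attribute.
#' @export
simulate_sumstats <- function(panel, stack, tau_true, gwas_n, seed = 1,
                              correlated_noise = FALSE, ldsc_table = NULL) {
  nms <- annot_names(stack)
  if (!is.null(names(tau_true))) tau_true <- tau_true[nms]
  if (length(tau_true) != length(nms) || anyNA(tau_true)) {
    abort("tau_true must provide one value per stack annotation")
  }
  A <- annot_matrix(stack)
  var_beta <- as.numeric(A %*% tau_true)
  if (any(var_beta < 0)) {
    warn(paste0(sum(var_beta < 0), " SNP(s) with negative model variance ",
                "truncated at 0"))
  }
  if (is.null(ldsc_table)) {
    ldsc_table <- ld_scores(panel, stack, adjusted = FALSE)
  }
  L <- as.matrix(as.data.frame(ldsc_table)[, nms, drop = FALSE])
  ev <- 1 + gwas_n * as.numeric(L %*% tau_true)
  if (any(ev < 0)) abort("negative chi-square expectation; tau too negative")
  set.seed(sub_seed(seed, "sumstats"))
  eps <- rnorm(panel$M)
  if (correlated_noise) {
    cmkey <- floor(panel$snps$cm / 2)   # one key per simulated block
    for (b in unique(cmkey)) {
      idx <- which(cmkey == b)
      if (length(idx) < 2) next
      C <- cor(panel$genotypes[, idx, drop = FALSE])
      ch <- chol(C + diag(1e-8, length(idx)))
      eps[idx] <- as.numeric(t(ch) %*% eps[idx])
    }
  }
  z <- sqrt(ev) * eps
  out <- tibble(snp = panel$snps$snp, a1 = panel$snps$a1, a2 = panel$snps$a2,
                n = gwas_n, z = z, chi2 = z^2)
  attr(out, "ldscores") <- ldsc_table
  out
}

#' Calibrate tau to a target architecture
#'
#' Returns the per-annotation tau vector giving the focal annotation a
#' chosen standardized effect size while the total heritability over the
#' panel equals `h2_target`: tau_focal = tau_star * (h2/M) / sd(a_focal),
#' with the all-ones base annotation absorbing the remainder uniformly.
#' Non-focal, non-base annotations get tau 0.
#'
#' @param stack `annot_stack` containing an all-ones `base` annotation.
#' @param focal Name of the focal annotation.
#' @param tau_star_target Planted standardized effect size.
#' @param h2_target Total heritability.
#' @return Named tau vector over the stack's annotations.
#' @export
calibrate_tau <- function(stack, focal, tau_star_target, h2_target) {
  A <- annot_matrix(stack)
  M <- nrow(A)
  base <- which(apply(A, 2, function(v) all(v == 1)))
  if (length(base) == 0) abort("stack needs an all-ones base annotation")
  tau <- setNames(rep(0, ncol(A)), colnames(A))
  sd_f <- sd(A[, focal])
  if (sd_f == 0) abort("focal annotation is constant")
  tau[focal] <- tau_star_target * (h2_target / M) / sd_f
  tau[colnames(A)[base[1]]] <- (h2_target - sum(A[, focal]) * tau[focal]) / M
  if (tau[colnames(A)[base[1]]] < 0) {
    abort("h2_target too small for the requested focal effect")
  }
  tau
}

#' Simulate labeled expression counts with planted markers
#'
#' Counts are negative binomial around gene base rates (log-normal across
#' genes) scaled by a per-cell depth factor; each cell type owns a disjoint
#' set of marker genes whose rate is multiplied by `marker_fold` in that
#' cell type only.
#'
#' @param cfg A [sim_config()].
#' @return List: `expr` (an [expression_matrix]) and `markers` (truth tibble
#'   `gene`, `celltype`).
#' @export
simulate_expression <- function(cfg) {
  if (cfg$n_celltypes < 2) abort("need at least 2 cell types")
  if (cfg$marker_fold <= 1) {
    warn("marker_fold <= 1: markers are undetectable by design")
  }
  set.seed(sub_seed(cfg$seed, "expression"))
  types <- sprintf("ct%02d", seq_len(cfg$n_celltypes))
  n_cells <- cfg$cells_per_type * cfg$n_celltypes
  labels <- rep(types, each = cfg$cells_per_type)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  if (cfg$n_markers * cfg$n_celltypes > cfg$n_genes) {
    abort("more markers requested than genes available")
  }
  marker_idx <- matrix(seq_len(cfg$n_markers * cfg$n_celltypes),
                       ncol = cfg$n_celltypes)
  base_rate <- rlnorm(cfg$n_genes, meanlog = log(0.3), sdlog = 0.6)
  depth <- rlnorm(n_cells, meanlog = 0, sdlog = 0.3)
  counts <- matrix(0L, nrow = n_cells, ncol = cfg$n_genes,
                   dimnames = list(sprintf("cell%05d", seq_len(n_cells)), genes))
  for (ti in seq_along(types)) {
    cells <- which(labels == types[ti])
    fold <- rep(1, cfg$n_genes)
    fold[marker_idx[, ti]] <- cfg$marker_fold
    mu <- outer(depth[cells], base_rate * fold)
    counts[cells, ] <- rnbinom(length(mu), mu = mu, size = 2)
  }
  markers <- tibble(gene = genes[as.vector(marker_idx)],
                    celltype = rep(types, each = cfg$n_markers))
  list(expr = expression_matrix(counts, labels), markers = markers)
}

#' Simulate peak sets, gene bodies and enhancer links over a panel
#'
#' Per-cell-type peak sets cover a Bernoulli-selected fraction of panel SNPs
#' (one short peak per selected SNP); gene bodies tile the panel; each gene
#' gets a few enhancer windows centered on random panel SNPs linking to it.
#'
#' @param panel A [snp_panel].
#' @param cfg A [sim_config()].
#' @param celltypes Cell-type names (default `ct01..`, `n_celltypes` of
#'   them).
#' @param n_genes_panel Number of gene bodies tiled over the panel
#'   (default 20).
#' @param links_per_gene Enhancer links per gene (default 3).
#' @return List: `peaks` (named list of interval tibbles), `genes` (tibble
#'   `gene`, `chrom`, `start`, `end`, 1-based), `links` (interval tibble
#'   with `gene`).
#' @export
simulate_intervals <- function(panel, cfg, celltypes = NULL,
                               n_genes_panel = 20, links_per_gene = 3) {
  celltypes <- celltypes %||% sprintf("ct%02d", seq_len(cfg$n_celltypes))
  set.seed(sub_seed(cfg$seed, "intervals"))
  pos <- panel$snps$pos
  chrom <- panel$snps$chrom
  peaks <- purrr::map(celltypes, function(ct) {
    sel <- which(rbinom(panel$M, 1, cfg$peak_coverage) == 1)
    tibble(chrom = chrom[sel], start = pos[sel] - 26L, end = pos[sel] + 25L)
  })
  names(peaks) <- celltypes
  # gene bodies tile the panel span
  span <- range(pos)
  edges <- floor(seq(span[1], span[2], length.out = n_genes_panel + 1))
  genes <- tibble(
    gene = sprintf("g%04d", seq_len(n_genes_panel)),
    chrom = chrom[1],
    start = edges[-length(edges)] + 1L,
    end = edges[-1]
  )
  links <- purrr::map_dfr(seq_len(n_genes_panel), function(i) {
    centers <- sample(pos, links_per_gene)
    tibble(chrom = chrom[1], start = pmax(centers - 2501L, 0L),
           end = centers + 2500L, gene = genes$gene[i])
  })
  list(peaks = peaks, genes = genes,
       links = dplyr::arrange(links, .data$chrom, .data$start))
}

#' Write a complete synthetic study fixture directory
#'
#' Emits everything the file-based pipeline consumes: a PLINK panel triplet
#' (`panel.*`, hardcall genotypes), one peak BED per cell type under
#' `peaks/`, one LDSC-dialect sumstats file per trait under `sumstats/`
#' (trait 1 carries the planted focal cell-type effect at
#' `tau_star_target`; the remaining traits are null for every cell type),
#' and `truth.tsv` naming the planted pair.
#'
#' @param cfg A [sim_config()]; `genotype_mode` is forced to `"hardcall"`
#'   so the on-disk panel is exactly what the generator used.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
simulate_study <- function(cfg, dir) {
  cfg$genotype_mode <- "hardcall"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_panel(cfg)
  iv <- simulate_intervals(panel, cfg)
  stack <- study_stack(panel, iv$peaks)
  focal <- names(iv$peaks)[1]
  tau <- calibrate_tau(stack, focal, cfg$tau_star_target, cfg$h2_target)
  tau_null <- calibrate_tau(stack, focal, 0, cfg$h2_target)
  ldsc_table <- ld_scores(panel, stack, adjusted = FALSE)
  write_plink(panel, file.path(dir, "panel"))
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  for (ct in names(iv$peaks)) {
    write_intervals(iv$peaks[[ct]], file.path(dir, "peaks", paste0(ct, ".bed")))
  }
  dir.create(file.path(dir, "sumstats"), showWarnings = FALSE)
  traits <- sprintf("trait%d", seq_len(cfg$n_traits))
  for (i in seq_along(traits)) {
    ss <- simulate_sumstats(panel, stack, if (i == 1) tau else tau_null,
                            cfg$gwas_n, seed = cfg$seed * 1000 + i,
                            ldsc_table = ldsc_table)
    write_sumstats(ss, file.path(dir, "sumstats", paste0(traits[i], ".sumstats")))
  }
  utils::write.table(
    data.frame(trait = traits[1], celltype = focal,
               tau_star_target = cfg$tau_star_target),
    file.path(dir, "truth.tsv"), quote = FALSE, sep = "\t", row.names = FALSE
  )
  invisible(dir)
}

# celltype peak annotations + union background + all-ones base
study_stack <- function(panel, peak_sets) {
  atac <- purrr::imap(peak_sets, ~ peaks_to_annotation(.x, panel, name = .y))
  bg <- union_background(peak_sets, panel)
  base <- annot_stack(panel, list(base = rep(1, panel$M)),
                      kind = "binary", role = "baseline")
  do.call(bind_annotations, c(atac, list(base, bg)))
}

#' Run the file-based pipeline on a fixture directory
#'
#' Reads the panel, builds the ATAC annotation stack from the peak BEDs
#' (adding the all-ones base annotation), computes stratified LD scores,
#' fits every trait x cell type pair and applies per-dataset FDR. Consumes
#' only files, so it exercises every reader.
#'
#' @param dir A directory written by [simulate_study()] (or laid out the
#'   same way).
#' @param config A [regression_config()].
#' @param adjusted LD-score estimator flag passed to [ld_scores()].
#' @return FDR-corrected association tibble.
#' @export
run_pipeline <- function(dir, config = regression_config(), adjusted = TRUE) {
  panel <- read_panel(file.path(dir, "panel"))
  atac <- build_atac_annotations(file.path(dir, "peaks"), panel)
  base <- annot_stack(panel, list(base = rep(1, panel$M)),
                      kind = "binary", role = "baseline")
  stack <- bind_annotations(atac, base)
  table <- ld_scores(panel, stack, adjusted = adjusted)
  ss_files <- sort(list.files(file.path(dir, "sumstats"),
                              pattern = "\\.sumstats$", full.names = TRUE))
  sumstats <- purrr::map(ss_files, read_sumstats)
  names(sumstats) <- sub("\\.sumstats$", "", basename(ss_files))
  sumstats <- purrr::map(sumstats, align_sumstats, panel = panel)
  res <- scan_associations(sumstats, table, stack, config,
                           dataset = basename(dir))
  fdr_correct(res)
}
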