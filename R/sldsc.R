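#' Configuration of the stratified heritability regression
#'
#' @param n_blocks Number of contiguous, equal-size jackknife SNP blocks
#'   (default 200; the remainder SNPs are spread over the leading blocks).
#' @param intercept `"free"` (estimate the regression intercept, the
#'   convention that absorbs confounding inflation) or `"fixed_one"` (pin it
#'   at 1, the literal expectation under no confounding).
#' @param chi2_max Regression SNPs with chi-square above this are excluded
#'   (default 80).
#' @param mhc Major-histocompatibility region excluded from regression SNPs:
#'   list with `chrom`, `start`, `end` (1-based, default chr6:25e6-34e6).
#' @param weighting `"two_part"` (inverse heteroskedasticity from a
#'   provisional fit times inverse LD overcounting, one iteration) or
#'   `"ols"` (unweighted; used for exact oracle tests).
#' @return A `regression_config` list.
#' @export
regression_config <- function(n_blocks = 200,
                              intercept = c("free", "fixed_one"),
                              chi2_max = 80,
                              mhc = list(chrom = "6", start = 25e6, end = 34e6),
                              weighting = c("two_part", "ols")) {
  intercept <- match.arg(intercept)
  weighting <- match.arg(weighting)
  if (n_blocks < 2) abort("need at least 2 jackknife blocks")
  structure(list(n_blocks = n_blocks, intercept = intercept,
                 chi2_max = chi2_max, mhc = mhc, weighting = weighting),
            class = "regression_config")
}

#' Filter regression SNPs
#'
#' Intersects the sumstats with the LD-score table, then removes SNPs with
#' chi-square above `chi2_max` and SNPs inside the MHC region. The removal
#' counts per rule are attached as the `"filter_counts"` attribute.
#'
#' @param ss Sumstats tibble.
#' @param table LD-score tibble from [ld_scores()].
#' @param config A [regression_config()].
#' @param snp_info Optional tibble with `snp`, `chrom`, `pos` (e.g. an
#'   `annot_stack` or `panel$snps`); without it the MHC filter cannot be
#'   applied and is skipped.
#' @return List with elements `ss` and `table`, row-aligned.
#' @export
filter_regression_snps <- function(ss, table, config = regression_config(),
                                   snp_info = NULL) {
  common <- intersect(ss$snp, table$snp)
  if (length(common) == 0) abort("sumstats and LD scores share no SNPs")
  ss <- ss[match(common, ss$snp), , drop = FALSE]
  n_chi2 <- sum(ss$chi2 > config$chi2_max)
  keep <- ss$chi2 <= config$chi2_max
  n_mhc <- 0L
  if (!is.null(snp_info)) {
    info <- as.data.frame(snp_info)[, c("snp", "chrom", "pos")]
    idx <- match(ss$snp, info$snp)
    in_mhc <- !is.na(idx) &
      info$chrom[idx] == config$mhc$chrom &
      info$pos[idx] >= config$mhc$start & info$pos[idx] <= config$mhc$end
    n_mhc <- sum(in_mhc & keep)
    keep <- keep & !in_mhc
  }
  ss <- ss[keep, , drop = FALSE]
  table <- table[match(ss$snp, table$snp), , drop = FALSE]
  out <- list(ss = ss, table = table)
  attr(out, "filter_counts") <- c(chi2 = n_chi2, mhc = n_mhc,
                                  retained = nrow(ss))
  out
}

#' Fit the stratified heritability regression
#'
#' Regresses per-SNP GWAS chi-square statistics on N times the stratified LD
#' scores: E\[chi2_j\] = N * sum_c l(j,c) tau_c + intercept. Coefficients
#' tau_c are per-SNP heritability contributions per annotation, conditional
#' on all other annotations in the stack. Their covariance comes from a
#' delete-a-block jackknife over contiguous equal-size SNP blocks, which is
#' robust to local LD and heteroskedasticity.
#'
#' Derived quantities per annotation: the standardized effect size
#' tau* = tau * sd(a) / (h2g / M) (proportionate change in per-SNP
#' heritability per one-SD increase in annotation value), its one-sided
#' p-value for tau* > 0 assuming tau*/se is standard normal, and the
#' heritability enrichment (share of h2g captured by the annotation divided
#' by its share of SNPs, where the size of a probabilistic annotation is its
#' mean value). h2g is the fit's own estimate sum_j sum_c a_cj tau_c over
#' panel SNPs.
#'
#' @param ss Sumstats tibble (regression SNPs; apply
#'   [filter_regression_snps()] first or let this function do it).
#' @param table LD-score tibble aligned to `ss` (or superset).
#' @param stack The `annot_stack` the LD scores were computed from (supplies
#'   annotation sums, SDs and M for the derived statistics).
#' @param config A [regression_config()].
#' @param filter Apply [filter_regression_snps()] internally (default TRUE).
#' @return An `sldsc_fit` object; see [tidy.sldsc_fit()] and
#'   [glance.sldsc_fit()].
#' @export
sldsc <- function(ss, table, stack, config = regression_config(),
                  filter = TRUE) {
  ann_names <- annot_names(stack)
  if (!all(ann_names %in% names(table))) {
    abort("LD-score table lacks columns for some stack annotations")
  }
  if (filter) {
    f <- filter_regression_snps(ss, table, config, snp_info = stack)
    ss <- f$ss; table <- f$table
  } else {
    table <- table[match(ss$snp, table$snp), , drop = FALSE]
  }
  L <- as.matrix(as.data.frame(table)[, ann_names, drop = FALSE])
  if (!all(is.finite(L))) abort("non-finite LD scores")
  y <- ss$chi2
  n_gwas <- ss$n
  X <- L * n_gwas
  n_snps <- nrow(X)
  if (n_snps < length(ann_names) + 1) {
    abort("fewer regression SNPs than model coefficients")
  }
  free <- config$intercept == "free"
  design <- if (free) cbind(`(intercept)` = 1, X) else X
  yfit <- if (free) y else y - 1
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  w <- sldsc_weights(yfit, design, L, stack, config,
                     offset = if (free) 0 else 1)
  n_blocks <- config$n_blocks
  if (n_blocks > n_snps) {
    warn(paste0("more jackknife blocks than SNPs; using ", max(2, n_snps %/% 2)))
    n_blocks <- max(2, n_snps %/% 2)
  }
  blocks <- jackknife_blocks(n_snps, n_blocks)
  core <- wls_jackknife(yfit, design, w, blocks)
  ann_pos <- if (free) seq_along(ann_names) + 1 else seq_along(ann_names)
  tau <- unname(core$theta[ann_pos])
  tau_cov <- core$cov[ann_pos, ann_pos, drop = FALSE]
  tau_blocks <- core$theta_blocks[, ann_pos, drop = FALSE]
  intercept <- if (free) unname(core$theta[1]) else 1
  intercept_se <- if (free) sqrt(core$cov[1, 1]) else 0
  derived <- sldsc_derived(tau, tau_cov, tau_blocks, stack)
  structure(
    c(derived,
      list(intercept = intercept, intercept_se = intercept_se,
           tau_cov = tau_cov, n_snps = n_snps, n_blocks = n_blocks,
           config = config)),
    class = "sldsc_fit"
  )
}

sldsc_weights <- function(y, design, L, stack, config, offset = 0) {
  n <- length(y)
  if (config$weighting == "ols") return(rep(1, n))
  # LD-overcounting part: total LD score, from an all-ones annotation's
  # column when the stack has one, else the summed binary columns.
  A <- annot_matrix(stack)
  all_ones <- which(apply(A, 2, function(v) all(v == 1)))
  l_tot <- if (length(all_ones) > 0) {
    L[, all_ones[1]]
  } else {
    rowSums(L)
  }
  w_ld <- 1 / pmax(l_tot, 1)
  # heteroskedasticity part from a provisional weighted fit
  theta0 <- tryCatch(
    stats::lm.wfit(design, y, w_ld)$coefficients,
    error = function(e) NULL
  )
  if (is.null(theta0) || anyNA(theta0)) return(w_ld)
  fitted <- pmax(as.numeric(design %*% theta0) + offset, 1)
  w_ld / (2 * fitted^2)
}

jackknife_blocks <- function(n, n_blocks) {
  sizes <- rep(n %/% n_blocks, n_blocks)
  extra <- n %% n_blocks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  rep(seq_len(n_blocks), sizes)
}

# weighted least squares + delete-a-block jackknife over contiguous blocks;
# the point estimate goes through QR (numerically stable even when N*l
# columns are large and nearly collinear), the jackknife through
# crossproduct downdates
wls_jackknife <- function(y, X, w, blocks) {
  sw <- sqrt(w)
  cs <- pmax(sqrt(colSums((X * sw)^2)), .Machine$double.xmin)
  Xeq <- sweep(X * sw, 2, cs, "/")           # column equilibration
  qx <- qr(Xeq, LAPACK = TRUE)
  th_eq <- qr.coef(qx, y * sw)
  # one step of iterative refinement recovers the digits lost to the
  # near-collinearity of baseline vs cell-type LD-score columns
  resid <- y * sw - Xeq %*% th_eq
  th_eq <- th_eq + qr.coef(qx, resid)
  theta <- as.numeric(th_eq) / cs
  theta[is.na(theta)] <- 0
  Xw <- X * w
  sxx <- crossprod(Xw, X)
  sxy <- crossprod(Xw, y)
  ids <- sort(unique(blocks))
  B <- length(ids)
  p <- ncol(X)
  theta_blocks <- matrix(NA_real_, nrow = B, ncol = p,
                         dimnames = list(NULL, colnames(X)))
  for (b in seq_len(B)) {
    i <- blocks == ids[b]
    sxx_b <- crossprod(Xw[i, , drop = FALSE], X[i, , drop = FALSE])
    sxy_b <- crossprod(Xw[i, , drop = FALSE], y[i])
    theta_blocks[b, ] <- solve(sxx - sxx_b, sxy - sxy_b)[, 1]
  }
  centered <- sweep(theta_blocks, 2, colMeans(theta_blocks))
  cov <- (B - 1) / B * crossprod(centered)
  list(theta = theta, cov = cov, theta_blocks = theta_blocks)
}

# tau -> tau*, enrichment, h2 partition, with jackknife SEs for the
# nonlinear derived quantities
sldsc_derived <- function(tau, tau_cov, tau_blocks, stack) {
  A <- annot_matrix(stack)
  M <- nrow(A)
  s <- unname(colSums(A))       # annotation sizes (sum of values)
  sd_a <- unname(apply(A, 2, sd))
  G <- crossprod(A)             # G %*% tau = per-annotation h2(C)
  h2g <- sum(s * tau)
  h2C <- as.numeric(G %*% tau)
  names(h2C) <- NULL
  B <- nrow(tau_blocks)
  h2g_b <- as.numeric(tau_blocks %*% s)
  h2C_b <- tau_blocks %*% t(G)           # B x C
  jack_se <- function(est_b) {
    cen <- sweep(est_b, 2, colMeans(est_b))
    sqrt((B - 1) / B * colSums(cen^2))
  }
  h2g_se <- sqrt((B - 1) / B * sum((h2g_b - mean(h2g_b))^2))
  tau_se <- unname(sqrt(diag(tau_cov)))
  prop_snp <- s / M
  # tau*/se(tau*) equals tau/se(tau) (the standardization scale cancels),
  # so the one-sided p is defined whenever the jackknife SE is
  p_pos <- ifelse(tau_se > 0, pnorm(tau / tau_se, lower.tail = FALSE),
                  NA_real_)
  if (h2g > 0) {
    scale_c <- sd_a / (h2g / M)
    tau_star <- tau * scale_c
    tau_star_se <- tau_se * scale_c
    prop_h2 <- h2C / h2g
    enrichment <- ifelse(prop_snp > 0, prop_h2 / prop_snp, NA_real_)
    enr_b <- sweep(h2C_b / h2g_b, 2, prop_snp, "/")
    enrichment_se <- unname(jack_se(enr_b))
  } else {
    warn("estimated h2g <= 0; tau* and enrichment are undefined")
    tau_star <- tau_star_se <- prop_h2 <- enrichment <- enrichment_se <-
      rep(NA_real_, length(tau))
  }
  coef <- tibble(
    annotation = colnames(A),
    role = annot_meta(stack)$role,
    tau = tau, tau_se = tau_se,
    tau_star = tau_star, tau_star_se = tau_star_se, p_pos = p_pos,
    enrichment = enrichment, enrichment_se = enrichment_se,
    prop_h2 = prop_h2, prop_snp = prop_snp, sd_annot = sd_a
  )
  list(coef = coef, h2g = h2g, h2g_se = h2g_se, M = M)
}

#' One-sided p-value for a positive standardized effect
#'
#' p = 1 - Phi(tau* / se), under the assumption that tau*/se is standard
#' normal under the null of no unique contribution.
#'
#' @param tau_star Standardized effect size(s).
#' @param se Standard error(s), strictly positive.
#' @return p-value(s) in (0, 1).
#' @export
p_positive_tau_star <- function(tau_star, se) {
  if (any(se <= 0)) abort("standard error must be positive")
  pnorm(tau_star / se, lower.tail = FALSE)
}

#' @export
print.sldsc_fit <- function(x, ...) {
  cat("<sldsc_fit> ", x$n_snps, " regression SNPs, ", nrow(x$coef),
      " annotations, ", x$n_blocks, " jackknife blocks\n",
      "h2g = ", signif(x$h2g, 4), " (SE ", signif(x$h2g_se, 3), "), intercept = ",
      signif(x$intercept, 4), "\n", sep = "")
  print(x$coef)
  invisible(x)
}

#' Tidy an S-LDSC fit
#'
#' One row per annotation: `tau`, `tau_se`, `tau_star`, `tau_star_se`,
#' `p_pos`, `enrichment`, `enrichment_se`, `prop_h2`, `prop_snp`.
#'
#' @param x An `sldsc_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sldsc_fit
#' @export
tidy.sldsc_fit <- function(x, ...) x$coef

#' One-row fit summary
#'
#' @param x An `sldsc_fit`.
#' @param ... Unused.
#' @return Tibble with `h2g`, `h2g_se`, `intercept`, `intercept_se`,
#'   `n_snps`, `n_annotations`, `n_blocks`, `M`.
#' @method glance sldsc_fit
#' @export
glance.sldsc_fit <- function(x, ...) {
  tibble(h2g = x$h2g, h2g_se = x$h2g_se, intercept = x$intercept,
         intercept_se = x$intercept_se, n_snps = x$n_snps,
         n_annotations = nrow(x$coef), n_blocks = x$n_blocks, M = x$M)
}
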