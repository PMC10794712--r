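# shared small synthetic setup for regression tests
sldsc_setup <- function(seed = 1, n_snps = 1000, n_samples = 200,
                        coverage = c(focal = 0.1, other = 0.2)) {
  cfg <- sim_config(seed = seed, n_snps = n_snps, n_samples = n_samples)
  panel <- simulate_panel(cfg)
  stack <- simulate_annotations(
    panel, tibble::tibble(name = names(coverage), coverage = coverage),
    seed = seed
  )
  L <- ld_scores(panel, stack, adjusted = FALSE)
  list(cfg = cfg, panel = panel, stack = stack, L = L)
}

noiseless_ss <- function(s, tau, n_gwas = 50000) {
  chi2 <- as.numeric(
    1 + n_gwas * as.matrix(as.data.frame(s$L)[, annot_names(s$stack)]) %*% tau
  )
  tibble::tibble(snp = s$panel$snps$snp, a1 = "A", a2 = "G", n = n_gwas,
                 z = sqrt(chi2), chi2 = chi2)
}

test_that("regression SNP filters remove chi2 > 80 and MHC SNPs", {
  s <- sldsc_setup(seed = 2, n_snps = 100)
  ss <- noiseless_ss(s, c(0, 0, 1e-6))
  # plant one extreme statistic: Z = 9.5 -> chi2 = 90.25 > 80
  ss$z[10] <- 9.5
  ss$chi2[10] <- 9.5^2
  f <- filter_regression_snps(ss, s$L, regression_config(), snp_info = s$stack)
  expect_false(ss$snp[10] %in% f$ss$snp)
  expect_equal(attr(f, "filter_counts")[["chi2"]], 1)
  expect_equal(nrow(f$ss), 99)

  # an MHC SNP: chrom 6, pos 30 Mb
  info <- s$stack
  info$chrom[5] <- "6"
  info$pos[5] <- 30e6
  f2 <- filter_regression_snps(ss, s$L, regression_config(), snp_info = info)
  expect_false(ss$snp[5] %in% f2$ss$snp)
  expect_equal(attr(f2, "filter_counts")[["mhc"]], 1)

  # clean fixture: nothing removed
  ss$z[10] <- 1; ss$chi2[10] <- 1
  f3 <- filter_regression_snps(ss, s$L, regression_config(),
                               snp_info = s$stack)
  expect_equal(nrow(f3$ss), 100)
})

test_that("all-ones chi2 gives zero taus and intercept one", {
  s <- sldsc_setup(seed = 3, n_snps = 300)
  ss <- noiseless_ss(s, c(0, 0, 0))
  expect_true(all(ss$chi2 == 1))
  fit <- suppressWarnings(
    sldsc(ss, s$L, s$stack, regression_config(weighting = "ols"))
  )
  expect_equal(fit$coef$tau, rep(0, 3), tolerance = 1e-12)
  expect_equal(fit$intercept, 1)
})

test_that("noiseless chi2 recovers tau exactly with ols + free intercept", {
  s <- sldsc_setup(seed = 4, n_snps = 1000)
  tau <- c(focal = 4e-5, other = 1e-5, base = 8e-6)
  ss <- noiseless_ss(s, tau)
  fit <- sldsc(ss, s$L, s$stack, regression_config(weighting = "ols"))
  expect_equal(fit$coef$tau, unname(tau), tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  # fixed-one intercept mode reproduces the same solution here
  fit1 <- sldsc(ss, s$L, s$stack,
                regression_config(weighting = "ols", intercept = "fixed_one"))
  expect_equal(fit1$coef$tau, unname(tau), tolerance = 1e-9)
  expect_equal(fit1$intercept, 1)
})

test_that("ols fit equals the closed-form normal-equations oracle", {
  s <- sldsc_setup(seed = 5, n_snps = 400)
  tau <- c(focal = 3e-5, other = 0, base = 1e-5)
  ss <- simulate_sumstats(s$panel, s$stack, tau, 50000, seed = 55,
                          ldsc_table = s$L)
  fit <- suppressWarnings(
    sldsc(ss, s$L, s$stack, regression_config(weighting = "ols"),
          filter = FALSE)
  )
  X <- cbind(1, as.matrix(as.data.frame(s$L)[, annot_names(s$stack)]) * 50000)
  oracle <- unname(solve(t(X) %*% X, t(X) %*% ss$chi2)[, 1])
  expect_equal(fit$intercept, oracle[1], tolerance = 1e-8)
  expect_equal(fit$coef$tau, unname(oracle[-1]), tolerance = 1e-6)
})

test_that("rank-deficient designs name the collinear column", {
  s <- sldsc_setup(seed = 6, n_snps = 200)
  A <- annot_matrix(s$stack)
  dup <- annot_stack(s$panel,
                     list(a = A[, "focal"], a_copy = A[, "focal"]),
                     kind = "binary")
  L <- ld_scores(s$panel, dup, adjusted = FALSE)
  ss <- tibble::tibble(snp = s$panel$snps$snp, a1 = "A", a2 = "G",
                       n = 1000, z = 1, chi2 = 1)
  expect_error(sldsc(ss, L, dup, regression_config(weighting = "ols")),
               "collinear.*a_copy")
})

test_that("tau_star follows the standardization identity", {
  # direct evaluation: tau 0.002, sd 0.05, h2g 0.5, M 1000 -> tau* = 0.2
  expect_equal(0.002 * 0.05 / (0.5 / 1000), 0.2)
  s <- sldsc_setup(seed = 7, n_snps = 500)
  tau <- c(focal = 4e-5, other = 1e-5, base = 8e-6)
  ss <- noiseless_ss(s, tau)
  fit <- sldsc(ss, s$L, s$stack, regression_config(weighting = "ols"))
  A <- annot_matrix(s$stack)
  for (i in seq_len(nrow(fit$coef))) {
    expect_equal(fit$coef$tau_star[i],
                 fit$coef$tau[i] * sd(A[, i]) / (fit$h2g / fit$M))
  }
  # homogeneity: doubling sd(a) doubles tau* at fixed tau and h2g
  expect_equal(2 * (0.002 * 0.05 / (0.5 / 1000)),
               0.002 * 0.10 / (0.5 / 1000))
  # tau = 0 implies tau* = 0
  expect_equal(fit$coef$tau_star[fit$coef$tau == 0], numeric(0))
})

test_that("enrichment is 1 for the all-SNPs annotation and ratios match", {
  s <- sldsc_setup(seed = 8, n_snps = 400)
  tau <- c(focal = 5e-5, other = 0, base = 1e-5)
  ss <- noiseless_ss(s, tau)
  fit <- sldsc(ss, s$L, s$stack, regression_config(weighting = "ols"))
  cf <- fit$coef
  expect_equal(cf$enrichment[cf$annotation == "base"], 1, tolerance = 1e-9)
  # enrichment = prop_h2 / prop_snp by definition
  expect_equal(cf$enrichment, cf$prop_h2 / cf$prop_snp)
  # a fixture capturing 40% of h2 on 10% of SNPs enriches 4x
  expect_equal(0.4 / 0.1, 4)
})

test_that("one-sided p for positive tau* matches the normal tail", {
  expect_equal(p_positive_tau_star(0, 1), 0.5)
  expect_equal(p_positive_tau_star(1.6449, 1), 0.05, tolerance = 1e-3)
  expect_equal(p_positive_tau_star(-50, 1), 1, tolerance = 1e-12)
  expect_error(p_positive_tau_star(1, 0), "positive")
})

test_that("disjoint partitions conserve the heritability shares", {
  cfg <- sim_config(seed = 9, n_snps = 300, n_samples = 100)
  panel <- simulate_panel(cfg)
  g <- cut(seq_len(panel$M), 3, labels = FALSE)
  stack <- annot_stack(panel,
                       setNames(lapply(1:3, function(k) as.numeric(g == k)),
                                paste0("part", 1:3)),
                       role = c("celltype", "baseline", "baseline"))
  L <- ld_scores(panel, stack, adjusted = FALSE)
  tau <- c(2e-5, 5e-6, 1e-5)
  chi2 <- as.numeric(1 + 5e4 * as.matrix(as.data.frame(L)[, -1]) %*% tau)
  ss <- tibble::tibble(snp = panel$snps$snp, a1 = "A", a2 = "G", n = 5e4,
                       z = sqrt(chi2), chi2 = chi2)
  fit <- sldsc(ss, L, stack, regression_config(weighting = "ols"))
  expect_equal(sum(fit$coef$prop_h2), 1, tolerance = 1e-9)
})

test_that("jackknife SE tracks the analytic OLS SE on homoskedastic data", {
  s <- sldsc_setup(seed = 10, n_snps = 5000, n_samples = 100)
  tau <- c(focal = 3e-5, other = 1e-5, base = 1e-5)
  ev <- noiseless_ss(s, tau)
  set.seed(123)
  ss <- ev
  ss$chi2 <- ev$chi2 + rnorm(nrow(ev), sd = 1)   # homoskedastic noise
  fit <- sldsc(ss, s$L, s$stack,
               regression_config(weighting = "ols", n_blocks = 200),
               filter = FALSE)
  X <- as.matrix(as.data.frame(s$L)[, annot_names(s$stack)]) * 50000
  lmfit <- lm(ss$chi2 ~ X)
  se_lm <- summary(lmfit)$coefficients[-1, "Std. Error"]
  ratio <- fit$coef$tau_se / se_lm
  expect_true(all(ratio > 0.8 & ratio < 1.25))
})

test_that("two-part weighting still recovers tau on average", {
  s <- sldsc_setup(seed = 11, n_snps = 2000)
  tau <- c(focal = 4e-5, other = 0, base = 1e-5)
  est <- sapply(1:20, function(k) {
    ss <- simulate_sumstats(s$panel, s$stack, tau, 5e4, seed = 100 + k,
                            ldsc_table = s$L)
    fit <- sldsc(ss, s$L, s$stack,
                 regression_config(weighting = "two_part", n_blocks = 100))
    fit$coef$tau[1]
  })
  se_mc <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - tau[["focal"]]), 4 * se_mc + 0.1 * tau[["focal"]])
})

test_that("tidy and glance expose the fit in broom shape", {
  s <- sldsc_setup(seed = 12, n_snps = 300)
  ss <- noiseless_ss(s, c(focal = 2e-5, other = 0, base = 1e-5))
  fit <- sldsc(ss, s$L, s$stack, regression_config(weighting = "ols"))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("annotation", "tau", "tau_star", "p_pos",
                    "enrichment", "prop_h2", "prop_snp") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$M, s$panel$M)
  expect_s3_class(autoplot(fit), "ggplot")
})
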