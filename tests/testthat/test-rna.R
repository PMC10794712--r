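test_that("TP10K normalization matches the closed form", {
  counts <- rbind(c(0, 5), c(2, 2), c(10, 0))
  expr <- expression_matrix(counts, c("a", "a", "b"))
  nz <- normalize_expression(expr)
  tot <- rowSums(counts)
  expected <- log2(1e4 * counts / tot + 1)
  expect_equal(unname(nz$norm), unname(expected))
  # count 0 -> 0; count = total -> log2(10001)
  expect_equal(nz$norm[1, 1], 0)
  expr2 <- expression_matrix(rbind(c(7, 0), c(1, 1)), c("a", "b"))
  expect_equal(normalize_expression(expr2)$norm[1, 1], log2(10001))
})

test_that("zero-count cells are dropped with a warning", {
  counts <- rbind(c(0, 0), c(3, 1))
  expr <- expression_matrix(counts, c("a", "b"))
  expect_warning(nz <- normalize_expression(expr), "zero total")
  expect_equal(nrow(nz$norm), 1)
  expect_equal(nz$labels, "b")
})

test_that("one-sided rank-sum p matches exact enumeration", {
  # focal (5,6,7) vs rest (1,2,3): enumeration over all C(6,3) assignments
  p_oracle <- enumerate_ranksum_p(c(5, 6, 7), c(1, 2, 3))
  expect_equal(p_oracle, 1 / 20)
  norm <- cbind(gene1 = c(5, 6, 7, 1, 2, 3),
                gene2 = c(1, 3, 2, 6, 5, 7))
  labels <- rep(c("focal", "rest"), each = 3)
  sc <- specific_expression_scores(norm, labels, min_cells = 1)
  pv <- attr(sc, "pvalues")
  expect_equal(pv$focal[pv$gene == "gene1"], p_oracle)
  expect_equal(pv$focal[pv$gene == "gene2"],
               enumerate_ranksum_p(c(1, 3, 2), c(6, 5, 7)))
  # min-max: smallest p scores 1, largest scores 0 (two genes)
  expect_equal(sc$focal[sc$gene == "gene1"], 1)
  expect_equal(sc$focal[sc$gene == "gene2"], 0)
})

test_that("normal approximation agrees with wilcox.test on larger ties-free data", {
  set.seed(11)
  norm <- cbind(g1 = rnorm(60), g2 = rnorm(60, sd = 2))
  labels <- rep(c("a", "b"), each = 30)
  sc <- specific_expression_scores(norm, labels, min_cells = 1)
  pv <- attr(sc, "pvalues")
  for (g in c("g1", "g2")) {
    ref <- wilcox.test(norm[labels == "a", g], norm[labels == "b", g],
                       alternative = "greater", exact = FALSE,
                       correct = TRUE)$p.value
    expect_equal(pv$a[pv$gene == g], ref, tolerance = 1e-10)
  }
})

test_that("scores are invariant to pooling the non-focal cell types", {
  set.seed(3)
  norm <- matrix(rnorm(40 * 5), nrow = 40,
                 dimnames = list(NULL, paste0("g", 1:5)))
  labels3 <- rep(c("focal", "x", "y"), times = c(14, 13, 13))
  labels2 <- ifelse(labels3 == "focal", "focal", "rest")
  p3 <- attr(specific_expression_scores(norm, labels3, min_cells = 1),
             "pvalues")
  p2 <- attr(specific_expression_scores(norm, labels2, min_cells = 1),
             "pvalues")
  expect_equal(p3$focal, p2$focal)
  # and to cell ordering
  ord <- sample(40)
  p3b <- attr(specific_expression_scores(norm[ord, ], labels3[ord],
                                         min_cells = 1), "pvalues")
  expect_equal(p3b$focal, p3$focal)
})

test_that("a constant gene never outranks real signal after min-max", {
  norm <- cbind(flat = rep(1, 20),
                up = c(rnorm(10, 5), rnorm(10, 0)),
                down = c(rnorm(10, 0), rnorm(10, 5)))
  labels <- rep(c("a", "b"), each = 10)
  sc <- specific_expression_scores(norm, labels, min_cells = 1)
  expect_equal(sc$a[sc$gene == "up"], 1)
  expect_equal(sc$a[sc$gene == "flat"], 0)  # p = 1 exactly, the range minimum
  expect_lt(sc$a[sc$gene == "down"], 1e-4)
})

test_that("single cell type errors", {
  norm <- matrix(rnorm(10), ncol = 2)
  expect_error(specific_expression_scores(norm, rep("a", 5), min_cells = 1),
               "2 cell types")
})

test_that("linking takes the max score over linked genes, 0 when unlinked", {
  set.seed(5)
  panel <- make_panel(matrix(rbinom(20 * 10, 2, 0.4), nrow = 10),
                      pos = seq(1000L, 20000L, by = 1000L))
  scores <- tibble::tibble(gene = c("gA", "gB"), ct1 = c(0.3, 0.9),
                           ct2 = c(0.7, 0.1))
  class(scores) <- c("gene_scores", class(scores))
  # SNP 1 (pos 1000) linked to gA only; SNP 2 (2000) to both; others none
  links <- tibble::tibble(chrom = "1",
                          start = c(900L, 1900L, 1950L),
                          end = c(2100L, 2050L, 2020L),
                          gene = c("gA", "gB", "gB"))
  ann <- link_snps(scores, panel, "enhancer_links", links = links)
  m <- annot_matrix(ann)
  expect_equal(unname(m[1, "ct1"]), 0.3)
  expect_equal(unname(m[2, "ct1"]), max(0.3, 0.9))
  expect_equal(unname(m[2, "ct2"]), 0.7)
  expect_true(all(m[3:10, ] == 0))
  # output never exceeds the max gene score of its cell type
  expect_true(all(m[, "ct1"] <= max(scores$ct1)))
  # zero exactly where the union background is zero
  bg <- annot_matrix(union_links_background(scores, panel, "enhancer_links",
                                            links = links))[, 1]
  expect_equal(rowSums(m) > 0, bg > 0)
})

test_that("window strategy links gene bodies +/- 100 kb with a hard edge", {
  panel <- make_panel(matrix(rbinom(10 * 6, 2, 0.4), nrow = 10),
                      pos = c(1000L, 99000L, 201000L, 301000L, 301001L,
                              500000L))
  genes <- tibble::tibble(gene = "gA", chrom = "1",
                          start = 150000L, end = 201000L)
  scores <- tibble::tibble(gene = "gA", ct1 = 1)
  class(scores) <- c("gene_scores", class(scores))
  ann <- link_snps(scores, panel, "window", genes = genes)
  m <- annot_matrix(ann)[, 1]
  # window = [50000, 301000]; SNP at 301001 is one bp past it
  expect_equal(m, c(0, 1, 1, 1, 0, 0))
})

test_that("genes missing from the score table are ignored with a note", {
  panel <- make_panel(matrix(rbinom(10 * 4, 2, 0.4), nrow = 10),
                      pos = c(100L, 200L, 300L, 400L) * 10L)
  scores <- tibble::tibble(gene = "known", ct1 = 0.5)
  class(scores) <- c("gene_scores", class(scores))
  links <- tibble::tibble(chrom = "1", start = c(500L, 900L),
                          end = c(3000L, 4100L),
                          gene = c("unknown", "known"))
  expect_message(ann <- link_snps(scores, panel, "enhancer_links",
                                  links = links), "absent")
  expect_equal(sum(annot_matrix(ann) > 0), 4)  # covers pos 1000..4000
})

test_that("binarization maps positives to 1 and is idempotent", {
  panel <- make_panel(matrix(rbinom(6, 2, 0.5), nrow = 2))
  st <- annot_stack(panel, list(p = c(0, 0.001, 0.999)),
                    kind = "probabilistic")
  b <- binarize_annotation(st)
  expect_equal(annot_matrix(b)[, 1], c(0, 1, 1))
  expect_equal(annot_meta(b)$kind, "binary")
  expect_equal(annot_matrix(binarize_annotation(b)), annot_matrix(b))
  z <- annot_stack(panel, list(p = rep(0, 3)), kind = "probabilistic")
  expect_equal(annot_matrix(binarize_annotation(z))[, 1], rep(0, 3))
})

test_that("expression MatrixMarket round trip preserves counts and labels", {
  set.seed(9)
  counts <- matrix(rpois(30, 2), nrow = 5)
  expr <- expression_matrix(counts, c("a", "a", "b", "b", "b"))
  dir <- withr::local_tempdir()
  write_expression(expr, dir)
  back <- read_expression(dir)
  expect_equal(as.matrix(back$counts), as.matrix(expr$counts))
  expect_equal(back$labels, expr$labels)
})
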