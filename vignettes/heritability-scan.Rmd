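---
title: "Partitioning disease heritability across single-cell-derived annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning disease heritability across single-cell-derived annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h2scan)
```

## The model

`h2scan` asks which cell types matter for a disease by testing whether SNPs
that are regulatorily active in that cell type carry more heritability than
their LD and their overlap with generic functional elements would predict.

The underlying model is the stratified LD-score regression of partitioned
heritability. Each SNP $j$ carries a vector of annotation values
$a_{cj} \in [0,1]$ — binary peak membership for chromatin-derived
annotations, graded specific-expression link scores for expression-derived
ones — and its (standardized-genotype) effect-size variance is assumed
additive across annotations:

$$\mathrm{Var}(\beta_j) = \sum_c a_{cj}\,\tau_c .$$

Because GWAS test statistics at a SNP pick up signal from everything it tags
through linkage disequilibrium, the observable consequence of this model is

$$E[\chi^2_j] = N \sum_c \ell(j,c)\,\tau_c + 1,
\qquad \ell(j,c) = \sum_k a_{ck}\, r^2_{jk},$$

with $N$ the GWAS sample size and $r_{jk}$ the genotype correlation in a
reference panel. `sldsc()` fits this as a weighted linear regression of
$\chi^2_j$ on $N\,\ell(j,c)$; the coefficients are the per-SNP heritability
contributions $\tau_c$, *conditional* on every other annotation in the
stack.

Two derived statistics summarize an annotation:

* the standardized effect size
  $\tau^*_c = \tau_c\,\mathrm{sd}(a_c) \,/\, (h^2_g / M)$ — the
  proportionate change in per-SNP heritability per one-SD increase in the
  annotation, comparable across annotations and traits; significance uses
  $\tau^*/\mathrm{se}(\tau^*) \sim N(0,1)$, one-sided for positive
  $\tau^*$ (we want annotations that *add* heritability);
* the enrichment
  $\%h^2(C) / \%\mathrm{SNP}(C)$ — the annotation's heritability share over
  its SNP share, where a probabilistic annotation's size is its mean value.
  Enrichment counts shared signal; $\tau^*$ counts only signal unique to
  the focal annotation.

Standard errors come from a delete-a-block jackknife over contiguous SNP
blocks (default 200, remainder spread over the leading blocks), which is
robust to local LD and to the heteroskedasticity of $\chi^2$ statistics.

## Annotation construction

**Chromatin (scATAC-derived).** `peaks_to_annotation()` marks a SNP 1 when
its base position falls inside any accessible-chromatin peak of the cell
type (BED semantics: 0-based half-open, so a SNP at a peak's `end` is
outside; overlapping peaks are merged first, so splitting a peak changes
nothing). `union_background()` is the OR over all cell types of a dataset.
Every focal fit conditions on the baseline annotations *and* this union, so
a significant cell type is enriched relative to open chromatin in general,
not merely relative to the genome — the conservative choice that buys
cell-type specificity.

**Expression (scRNA-derived).** Counts are normalized to
$\log_2(\mathrm{TP10K}+1)$. For each cell type and gene,
`specific_expression_scores()` runs a one-sided Wilcoxon rank-sum test
(focal cells greater than all other cells) and min-max normalizes
$-2\log p$ across the gene universe into a score in $[0,1]$. The test is
one-sided because the construct is specifically *expressed* genes; a
two-sided option exists. Mid-ranks with tie-corrected variance and
continuity correction are used, switching to the exact rank-sum null when
both groups have at most 10 cells and the gene has no ties. The gene
universe defaults to genes expressed in at least 10 cells — genes below
that cannot be meaningfully ranked and would otherwise dilute the min-max
range. If every gene ties (all $-2\log p$ equal), all scores are set to 0
with a warning: no gene is specifically expressed in that case.
`link_snps()` then assigns each SNP the *maximum* score among genes linked
to it — through enhancer–gene link intervals, or through gene bodies
±100 kb under the window variant — and 0 when nothing is linked.
`union_links_background()` plays the same conditioning role as the
open-chromatin union. `binarize_annotation()` reproduces the
all-positive-scores-to-1 variant used to probe how much the graded scores
matter.

## Tunable parameters that matter

| parameter | default | why |
|---|---|---|
| MAF filter | ≥ 0.005 | common-variant panel definition |
| LD window | 1 cM (1000 kb fallback) | the field's convention; LD beyond 1 cM is noise at panel sample sizes |
| $r^2$ estimator | bias-adjusted $r^2 - (1-r^2)/(n-2)$ | unbiased-ish at finite panel size; tests use the raw estimator for exact oracles |
| $\chi^2$ cap | 80 | guards real GWAS against outlier loci |
| MHC exclusion | chr6:25–34 Mb | extreme LD and effect sizes distort the fit |
| jackknife blocks | 200 | block length ≫ LD range, block count enough for a stable covariance |
| regression weights | two-part | inverse LD overcounting × inverse squared provisional mean; one iteration |
| intercept | free | absorbs confounding inflation; `fixed_one` reproduces the literal model |
| FDR | Benjamini–Hochberg, per dataset, 5% | negative-$\tau^*$ rows excluded from the family first |

The intercept and weighting choices deserve a word. The printed model has
"+1", but estimating a free intercept is the convention because population
stratification inflates every $\chi^2$ additively; we default to free and
expose `fixed_one`. The weights are not identified by the model either —
any positive weights give consistent estimates — so they are configuration:
`two_part` for efficiency on real-scale data, `ols` where tests need exact
closed-form behavior.

## What the synthetic generators emulate

All stochastic testing runs on synthetic data built to satisfy the model's
own assumptions:

* `simulate_panel()` draws LD in contiguous blocks: within a block every
  SNP loads on a shared Gaussian factor so each pair has expected
  correlation `within_block_r` (default 0.5, block size 20); blocks are
  independent, and each block sits in its own 2-cM slot so the default 1-cM
  window spans exactly one block. Genotypes are Gaussian dosages with the
  moments of a binomial allele count (exact target correlation); a
  `hardcall` mode converts through a Gaussian copula to 0/1/2 — used for
  on-disk fixtures so the PLINK round trip is lossless.
* `simulate_sumstats()` draws
  $z_j = \sqrt{1 + N\sum_c \ell(j,c)\tau_c}\,\varepsilon_j$ with the LD
  scores computed from the panel itself, so $E[\chi^2]$ matches the model
  identity exactly in-sample; $\varepsilon$ is independent across SNPs by
  default, with an LD-correlated option (per-block Cholesky) for SE
  calibration work. Simulating at the marginal-z level rather than through
  individual phenotypes keeps the expectation exact and the cost linear.
* `simulate_expression()` draws negative-binomial counts over log-normal
  gene rates with per-cell depth factors; each cell type owns disjoint
  marker genes whose rate is multiplied by `marker_fold` (default 8) in
  that type only, with the truth table returned for recovery tests.
* `simulate_intervals()` emits per-cell-type peak BEDs (one short peak per
  Bernoulli-selected SNP at the configured coverage), tiled gene bodies,
  and random enhancer links.
* `simulate_study()` wires these into a complete on-disk fixture — PLINK
  triplet, peak BEDs, per-trait sumstats — with one trait carrying a
  planted focal-cell-type effect at a chosen $\tau^*$ (default 1 at
  $N = 50{,}000$) and the remaining traits null.

**Scale.** The synthetic panels carry thousands of SNPs, not millions, so
total heritability defaults to 0.05: what must be on a realistic scale is
the per-SNP regression signal $N\,\bar{\ell}\,h^2/M$, and scaling $h^2$
with the miniature $M$ keeps the simulated $\chi^2$ in the range a real
GWAS produces. Problem sizes used by the test suite and the acceptance
script — 2,000-SNP panels with 100 recovery replicates and 500 null
replicates, 5,000-SNP panels with 100 end-to-end seeds — were chosen as the
smallest sizes at which the Monte-Carlo error of the checked quantities is
well below the assertion margins.

What the generators deliberately do **not** emulate: realistic human LD
maps, MAF-dependent architectures, population structure, sample overlap
between GWAS, doublets/ambient RNA in expression data. Passing tests
demonstrate the estimator and pipeline are correct under the stated model;
they do not certify behavior under real-data pathologies the model
excludes.

## Numerical choices and degenerate inputs

* The weighted least-squares point estimate goes through a
  column-equilibrated QR with one step of iterative refinement:
  $N\,\ell$ columns are large and nearly collinear (the all-ones baseline
  overlaps everything), and the normal equations lose ~8 digits there. The
  jackknife re-solves use crossproduct downdates, where speed matters and
  full precision does not.
* Rank-deficient designs abort naming the collinear columns rather than
  silently dropping them.
* $\tau^*$ and enrichment are undefined when the fitted $h^2_g \le 0$;
  they are returned as `NA` with a warning, never silently clipped. The
  one-sided p-value survives, because $\tau^*/\mathrm{se}(\tau^*)$ equals
  $\tau/\mathrm{se}(\tau)$ — the standardization scale cancels.
* Calibration tests (parameter recovery, null uniformity) disable the
  $\chi^2 > 80$ cap: on a miniature panel the simulated mean $\chi^2$ is
  high enough that the cap censors the model's own tail and visibly biases
  $\tau$ downward. The cap is an artifact guard for real data, and stays on
  in the default pipeline and in the end-to-end power runs.
* Negative $\tau^*$ rows are reported, then excluded only at the FDR
  stage; exclusion shrinks the BH family. Control traits form their own
  family. Bonferroni flags use the post-exclusion family size by default
  (the pre-exclusion denominator is a flag) — the choice is not decidable
  from first principles, so both are computable.
* Sumstats rows whose alleles mismatch the panel (in either order) are
  dropped with a count, not strand-flipped: only $\chi^2$ enters the
  regression, so the only risk is a wrong SNP identity, and guessing
  strand flips trades a visible loss for an invisible error.
* Trait pruning resolves the highest-correlation violating pair first,
  drops its lower-$h^2$-z member, ties lexicographically — deterministic
  under every input.

## Known limitations

* LD scores are computed by direct windowed crossproducts; fine for panels
  up to ~10^5 SNPs, not engineered for genome-wide panels (no chunked I/O,
  no parallelism).
* The exact Wilcoxon path requires both groups ≤ 10; real single-cell
  comparisons always use the tie-corrected normal approximation, whose
  p-values are approximate for heavily tied sparse genes.
* The per-dataset scan refits the full conditioning stack for every trait ×
  cell-type pair; at the scale of dozens of annotations this is seconds,
  but no attempt is made to share factorizations across fits.
* Genetic correlations between traits are consumed as an input matrix;
  estimating them (cross-trait regression) is out of scope.
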