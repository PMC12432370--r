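---
title: "Methods: signature discovery, response modelling and compound boosting scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature discovery, response modelling and compound boosting scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`igesbs` implements a four-stage pipeline for finding tumor-microenvironment
(TME) gene expression signatures associated with response to immune
checkpoint blockade (ICB), and for ranking compounds by their potential to
boost ICB efficacy from perturbation transcriptomes:

1. **Discovery** — per-cohort logistic association of signature activity with
   response, pooled by random-effects meta-analysis (`run_discovery()`).
2. **Expansion** — growing each signature into a cancer-type-specific gene
   list by tumor-purity-adjusted partial Spearman correlation
   (`expand_signature()`).
3. **Response model** — an elastic net over standardized signature scores,
   tuned and evaluated by nested cross-validation (`train_elastic_net()`).
4. **Compound scoring** — preranked GSEA of treated-vs-control profiles,
   cell-line-weighted aggregation into a perturb gene expression score
   (PGES), Cauchy-combination (ACAT) p-values and a coefficient-weighted
   boosting score (BS) per compound and cancer type
   (`score_conditions()`, `compute_pges()`, `compute_boosting_score()`).

A synthetic-data module (`simulation_spec()` and the `generate_*()`
functions) emulates the statistical structure of the real inputs so the whole
path is testable without external downloads.

# Signature scoring

Published TME signature collections are heterogeneous in how their sources
score them (deconvolution tools, marker means, ssGSEA variants).  This
package deliberately uses **one configurable scoring method for all sets**:

* `mean_z` (default): each gene is z-scored across samples on the
  log2(x + 1) scale and a set's score is the mean z over its member genes.
  Zero-variance genes contribute 0.  This is a marker-mean score; it is
  location/scale-free per gene and cheap at thousands of sets.
* `rank_enrichment`: a per-sample weighted Kolmogorov–Smirnov statistic of
  the member genes within the sample's expression ranking (an ssGSEA-like
  single-sample score bounded in [-1, 1]).

The unified method trades per-source fidelity for reproducibility; it
preserves the orientation of every downstream statistic (a set whose genes
rise with an unfavourable microenvironment still gets a low odds ratio).
Member genes absent from a matrix are dropped with a warning; a set needs at
least one present gene (configurable) to be scored.

Within each cohort, scores are Z-transformed (`standardize_scores()`) to
mean 0, SD 1, so the logistic slope below is a log-odds **per standard
deviation of signature activity** and is comparable across cohorts.
Constant rows are set to zero rather than NaN.

# Discovery by random-effects meta-analysis

Per cohort, `fit_cohort_logistic()` fits `response ~ score` by maximum
likelihood and reports the slope, its standard error and the Wald p-value.
Complete separation is capped at |beta| = 10 and flagged non-converged;
non-converged fits are excluded from pooling.

`pool_random_effects()` is the classic DerSimonian–Laird moment estimator
with Wald intervals: fixed-effect weights $w_i = 1/se_i^2$, Cochran's
$Q = \sum_i w_i(\beta_i - \beta_{FE})^2$,

$$\tau^2 = \max\!\left(0,\ \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right),$$

random-effect weights $w_i^* = 1/(se_i^2 + \tau^2)$, pooled log-odds
$\hat\beta = \sum w_i^* \beta_i / \sum w_i^*$ with standard error
$1/\sqrt{\sum w_i^*}$.  No Hartung–Knapp adjustment is applied: the DL/Wald
combination is the long-standing default of the classic meta-analysis
toolchain this estimator mirrors, and the labelling rule below was defined
against it.  With one cohort the pooled effect is the single effect and
$\tau^2 = 0$.

Labels: **sIGeS** (sensitivity-associated) when the pooled p < 0.05 and
OR > 1; **rIGeS** (resistance-associated) when p < 0.05 and OR < 1; an OR of
exactly 1 is never labelled.  No multiplicity correction enters the label —
the discovery filter is on the raw pooled p — but a Benjamini–Hochberg
column (`p_bh`) is reported for reference.

Only effect sizes are pooled; per-cohort residuals play no role downstream.

# Expansion with a purity confounder

Bulk tissue mixes tumor and stromal/immune cells, so a gene can correlate
with an immune signature purely through tumor purity.  For each gene,
`partial_spearman()` rank-transforms gene, score and purity and computes the
first-order partial correlation on the ranks,

$$r_{xy\cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
  {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}},$$

with a t-test on $n - 3$ degrees of freedom.  A constant purity vector
degrades to plain Spearman (logged); a purity vector perfectly collinear
with an input yields a missing value.

Genes pass when **PSCC > 0.4, BH-FDR < 0.05 and detectability DP > 0.8**,
all strict inequalities (a gene detected in exactly 8 of 10 cell lines, DP
= 0.8, fails).  DP is the fraction of cell lines with at least one read.
Survivors are ranked by PSCC descending — not |PSCC| or FDR — and capped at
200 genes; ties at the boundary break lexicographically by gene id so lists
are deterministic.  The BH universe is all genes tested for that
(signature, cancer type) pair; the adjustment universe is not prescribed by
the procedure's description, and per-signature adjustment keeps expansions
independent of which other signatures are run.  The expansion is purely
correlation-derived — original member genes are *not* force-included — but
an empty expansion falls back to the original members with DP > 0.8, loudly,
because a response-model feature must not vanish silently.

# Response model

Cohorts are first aligned by `harmonize_cohorts()`: each signature is
z-scored within a cohort and rescaled to its pooled mean/SD.  This is a
location/scale batch alignment, not empirical-Bayes ComBat: it removes
additive and multiplicative cohort offsets but does not shrink per-cohort
estimates, which is an accepted simplification here because downstream
consumption is a penalized linear model on per-signature columns.

`train_elastic_net()` runs stratified **outer 5-fold / inner 10-fold** nested
cross-validation.  The inner grid covers the mixing parameter
$\alpha \in \{0.1, 0.2, \ldots, 1.0\}$ and the glmnet lambda path
(50 values); the inner criterion is the AUC of stacked inner out-of-fold
predictions, which is stable when folds are small.  Outer test folds never
enter tuning (the returned CV report records the tuning sample sets so tests
can assert this).  Out-of-fold probabilities from the outer loop are stacked
into the overall CV AUC; the final model refits all samples at
hyperparameters chosen by the same inner search on the full data.  Fold
assignment is the only randomness and derives from the `seed` argument, so
training is exactly reproducible.  AUC is the rank-based (Mann–Whitney)
statistic with ties counted one half.

The fitted coefficients `Coe_i` (zeros included) are the weights of the
boosting score below; the model serializes to JSON.

# Compound scoring

For each perturbation condition (compound, cell line, dose, time), genes are
ranked by `treated - control` on the log scale against the plate-matched
DMSO control, ties broken lexicographically.  `gsea_prerank()` computes the
weighted KS enrichment score (exponent 1 on |metric|) of each signature; the
null distribution comes from gene-label permutations, which for a preranked
list is a uniform redraw of the member positions and therefore depends only
on the metric and the set size — the implementation shares one null per set
size within a condition.  NES divides ES by the mean |null ES| **of the
matching sign** (sign-matched normalization; the positive and negative
deviations have different scales when the metric is asymmetric), and the
permutation p is $(1 + \#\{\text{same-sign null at least as extreme}\}) /
(1 + \#\{\text{same-sign null}\})$.  FDR is BH across signatures within each
condition, *before* combination across conditions.

Per (signature, cancer type, compound) trio, `compute_pges()` aggregates:

* single condition overall: $PGES = W_{cell}\cdot NES$ exactly;
* otherwise each cell line $p$ contributes
  $W_{cell_p}(NES_{ref_p} + f_p)$, averaged over the reference conditions
  (one per cell line), where the reference is the (10 µM, 24 h) condition or
  the nearest in (log10 dose, log2 time) with ties resolved toward lower
  dose then shorter time, and the awarding term
  $f_p = \frac{1}{m}\sum_{cond}(NES_{cond} - NES_{ref_p})$ runs over the
  cell line's $m$ non-reference conditions.

The awarding term is defined on per-condition NES values: the published
formulation nests the aggregate score inside its own awarding function,
which is circular as printed, and the per-condition NES is the only
per-condition quantity the formula can refer to.  A `basket_mode = "basket"`
option instead averages within (low/high dose × short/long time) baskets
relative to the reference and sums the basket means, for users who read the
basket grouping literally.  Cell weights $W$ come from an input table
normalized to a maximum of 1 per cancer type (in the real application,
tumor–cell-line transcriptome correlations); a missing cell line falls back
to the cancer-type mean, then to 1 with a warning.

The trio's combined p-value is the **ACAT** (Cauchy combination) of the
per-condition FDR values:
$T = \sum_i w_i \tan((0.5 - p_i)\pi) / \sum_i w_i$,
$p = 0.5 - \arctan(T)/\pi$.  ACAT tolerates dependence between conditions
and is exact under the identity $p_{comb} = p$ when all inputs equal $p$.
Inputs of exactly 0 or 1 are clipped to $[10^{-15}, 1 - 10^{-15}]$ with a
warning — boundary inputs otherwise map to infinite Cauchy quantiles.

The **boosting score** of a compound for a cancer type is
$BS = \sum_{i \in N} Coe_i \cdot PGES_i$ over the subset $N$ of signatures
whose combined p is below 0.05.  A positive BS means the compound pushes
sensitivity signatures up and resistance signatures down in proportion to
their weight in the response model.  `rank_compounds()` ranks descending BS
within a cancer type (rank 1 best; percentile = rank / compounds).
`booster_enrichment_test()` compares scores of compounds with and without
prior supporting evidence (effect size = difference in means; one-sided
Wilcoxon rank-sum; "enriched" means effect > 1 and p < 0.05), and
`direction_consistency()` reports the proportion of signatures regulated in
one source (adjusted p < 0.1) whose NES sign agrees in another.

# Synthetic data: what it emulates, and what it does not

`simulation_spec()` fixes the study conditions once:

* **Cohorts** (default 5 × 100 samples, 40% responders; 1000 genes in 40
  disjoint 25-gene sets): latent set activities are standard normal,
  response follows a logistic model with the planted log-ORs per SD, member
  genes are activity + N(0, 1) noise around a log2 baseline of 6 with a
  per-cohort batch shift (SD 0.5).  Scoring a set through its noisy member
  genes attenuates the recovered slope by the score–activity correlation
  (≈ 0.96 at these settings), so a planted log-OR of 0.8 is recovered near
  0.77 — within the ±0.1 recovery band the tests assert.
* **Tissue panel** (500 genes × 200 samples): purity ~ Beta(5, 2); the
  signature score correlates with purity at 0.6, which is what makes purity
  a genuine confounder; three genes load on the score (loading 1.5, marginal
  Spearman ≈ 0.8) and three on purity only.  Cell-line counts are
  Poisson(5) with per-gene dropout for the DP filter.
* **Perturbations** (3 cell lines, 60 compounds, default single reference
  condition 10 µM/24 h): control profiles share a per-plate baseline;
  engineered boosters shift all sensitivity-set genes up and resistance-set
  genes down by 1 SD (scaled by `1 + 0.5·log10(dose/10)` and `(time/24)^0.3`
  off-reference, so a dose series brackets the reference); null compounds
  shift random non-signature genes.

The null-calibration check runs 1000 signatures across **12 cohorts of 64
samples** — the shape of a realistic multi-cohort discovery design — because
DL/Wald pooling is mildly anticonservative at very small cohort counts and
the check measures the estimator as it is used.

These generators reproduce the pipeline's statistical assumptions, not real
data: expression is Gaussian on the log scale (no count overdispersion, no
heavy tails), sets are disjoint, activities are independent, and batch
effects are additive.  Passing tests therefore demonstrate correctness of
the statistics and the engineered-signal behaviour of the pipeline — not
that real cohorts meet these assumptions, nor the published effect sizes,
which require the original patient cohorts and perturbation catalogues.

# Numerical choices and edge cases

* Logistic separation: |beta| capped at 10, flagged, excluded from pooling.
* Constant score rows: zeroed (standardization) or pinned to the pooled
  mean (harmonization), never NaN.
* GSEA with an all-tied metric degrades to the unweighted KS statistic.
* Empty permutation sign class: NES falls back to the mean |null ES| over
  both signs.
* All tie-breaks (gene ranking, PSCC boundary, compound ranking, reference
  selection) are lexicographic / toward-lower-dose so outputs are
  deterministic byte for byte; the command-line interface re-run with the
  same seed reproduces identical files.
* Problem sizes in the shipped tests (e.g. 300–1000 simulated signatures,
  20-seed replicate loops, 1000 permutations) were chosen so each property
  is measured with useful precision while a full run stays comfortably
  under typical interactive patience; they are package choices, not
  statements about the data the method targets.

# Known limitations

* The unified scoring method is a stand-in for the per-source scoring of
  published TME collections; orientation is preserved but absolute scores
  are not comparable to the original tools.
* Harmonization is location/scale only (no empirical-Bayes shrinkage).
* The meta-analysis assumes per-cohort asymptotic normality of the logistic
  slope; very small cohorts (< ~30 samples) push its limits.
* PGES's awarding interpretation (per-condition NES; pooled vs basket
  averaging) is one reading of an ambiguous construction; both readings are
  implemented and the default is the simpler pooled mean.
* Expansion assumes purity is measured without error and is the only
  confounder adjusted for.
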