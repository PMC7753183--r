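---
title: "Regularized multivariate functional connectivity: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized multivariate functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvconn)
```

## The model

Classical seed- or degree-based functional connectivity summarizes a brain
region by its *bivariate* correlations with other regions. This package
implements the multivariate alternative: for each region $i$ with time series
$Y_i$ (length $p$), model

$$Y_i = f(Y_1, \dots, Y_{i-1}, Y_{i+1}, \dots, Y_N) + \varepsilon_i$$

and score connectivity as $\mathrm{Cor}(Y_i, \hat Y_i)$ — how well the rest of
the brain jointly predicts the region. Two families of $f$ are provided:

* **RIDGEC** takes $f$ linear additive and fits it by ridge regression,
  minimizing $\mathrm{RSS} + \lambda \sum_j \beta_j^2$. With $N$ comparable to
  or larger than $p$, ordinary least squares overfits or is non-unique; the
  ridge constraint $\sum_j \beta_j^2 < c$ restores a unique, stable solution.
* **RANFORC** takes $f$ to be a random-forest regression, dropping linearity
  and additivity. Regularization comes from averaging many trees, sampling
  few candidate predictors per split, and capping each tree at a small
  number of terminal nodes.
* **GBC** (weighted global brain connectivity), the baseline: region $i$'s
  score is the mean of $|r_{ij}|$ over $j \ne i$, plus variants that average
  only the signed correlations above a threshold $t \in \{0, 0.1, 0.2, 0.3\}$.

All scores are Fisher z-transformed (`atanh`) before group statistics.

## Parameters that matter

* `lambda` (default **10**, unitless): the ridge penalty. It must stay
  constant across all regions and subjects of a study, or scores are not
  comparable. Crucially, the absolute value of `lambda` is tied to the
  solver's objective convention. Here the penalty applies to the *raw* RSS
  (no $1/(2p)$ scaling, intercept unpenalized), so `lambda = 10` on
  unit-variance series of a few hundred time points is a mild constraint;
  the same number under a scaled-RSS convention would mean something much
  stronger. Temporal autocorrelation undermines cross-validation for tuning
  `lambda`, which is why a fixed, study-wide value is used at all.
* Forest config (defaults **1000 trees, `m_try = 10`, `max_leaf_nodes = 4`**,
  bootstrap on): "variables per tree" is interpreted as `m_try` candidate
  predictors sampled *per split* — the convention of the randomForest
  software family — with a per-tree sampling mode available
  (`sample_mode = "tree"`) for sensitivity analysis. "Four nodes" is read as
  four *terminal* nodes, grown best-first by largest SSE decrease
  (`maxnodes` semantics). Both readings of the source description are
  possible; these were chosen to match the cited software family and are
  fixed here.
* Scoring uses **in-sample** predictions for both estimators: the score is
  the correlation of the observed series with the fitted values, with
  overfitting controlled by the penalty/constraints themselves, not by a
  train/test split. An out-of-bag mode (`scoring = "oob"`) exists for
  comparison; out-of-bag scores run systematically lower and are not the
  default because the workflow being reproduced correlates observed series
  with the fitted function's values.
* `alpha` (default 0.05): the Benjamini–Hochberg FDR level, applied per
  map/method across its $N$ regions (one family per analysis). Two-sided
  tests throughout; the source workflow does not print its `alpha` or
  sidedness, so the conventional choices are adopted.
* GBC thresholded variants average the *surviving* correlations only; a
  region with no correlation above $t$ scores 0 (logged), keeping all
  regions in the group analysis. A zero-fill variant (`zero_fill = TRUE`)
  averages thresholded values over all $N-1$ pairs instead.

## Numerical and design choices

* **Standardization** centers as well as scales (sample SD, denominator
  $p-1$). Unit variance is required for the penalty to weigh regions
  equally; centering is a design choice that makes the intercept exactly
  zero and is standard practice before penalized fits.
* **Fisher transform clamping**: $|r|$ is clamped at $1 - 10^{-7}$ so a
  numerically perfect fit cannot inject infinities into group models;
  clamping warns.
* **Degenerate fits**: if a model's fitted values have (numerically) zero
  variance — e.g. an enormous `lambda` shrinking all coefficients away — the
  correlation is defined as 0 rather than `NA`, with a warning, so maps stay
  complete.
* **Ridge solver**: the closed-form symmetric positive-definite solve of
  $(X^\top X + \lambda I)\beta = X^\top y$; deterministic, no iterative
  optimizer. Per subject, the Gram matrix of the standardized panel is
  computed once and per-target blocks are extracted from it.
* **Forest determinism**: all randomness derives from a splitmix64 stream
  seeded per fit by hashing (root seed, subject id, region index), so
  results are bit-identical across runs and platforms and adding or
  removing subjects never perturbs other subjects' maps. Equal-gain splits
  break ties toward the lowest predictor index, then the lowest threshold,
  which makes the single-stump configuration exactly reproducible against
  an exhaustive search. The index-based tie-break has one consequence worth
  knowing: at small deep nodes two predictors occasionally induce exactly
  the same weighted partition, and which of them the split (and its
  importance) is attributed to then depends on column order; aggregate maps
  are unaffected.
* **Pooled-variance t-tests** (not Welch): the reference cohort comparison
  reports $df = n_1 + n_2 - 2$ exactly, which identifies the pooled test.
* **Age matching** for the sex comparison is taken as given (a `matched`
  flag in the design): no matching algorithm is imposed. The synthetic
  cohort generator produces a matched-by-construction cohort by assigning
  opposite sexes within adjacent age ranks.

## What the synthetic generator emulates — and what it does not

`generate_panel()` produces Gaussian AR(1) series (default
$\varphi = 0.4$) as a stand-in for the temporal autocorrelation that
band-limited filtering (0.1–0.02 Hz) induces in real resting-state data; it
implements no actual filter, no hemodynamics, and no scanner noise model.
Cross-regional structure is either a target correlation matrix (via its
Cholesky factor on the innovations) or directed coupling rules
(linear / quadratic / interaction forms). Quadratic and interaction drivers
are standardized after construction, keeping their *linear* correlation with
the sources near zero — dependence that only a nonlinear estimator can
convert into connectivity, which is what makes the RANFORC-vs-RIDGEC
contrast testable. Default desk scale is $N = 30$ regions and $p = 256$ time
points: $p$ matches a typical resting-state volume count, $N$ is reduced
from a 246-region parcellation for runtime.

Cohorts modulate coupling weights per subject: for an effect rule on
covariate $c$ with size $e$, a rule's weight becomes $w + e \cdot c$ (age
mean-centered; sex coded 0/1). Chosen scenario magnitudes — linear base
weight 0.9 ($R^2 \approx 0.45$ for a well-connected region), an age decline
of 0.012 per year (about 1% of the base weight), a sex difference of 0.6 on
a 0.7 quadratic weight — are in the range of moderate-to-large effects
reported in aging/sex connectivity studies, stated once and not revisited.
Gray-matter covariates are Beta(8, 4) draws independent of connectivity, so
adjusting for them should (and does, in tests) leave focal estimates
essentially unchanged.

A green test on these cohorts establishes that the estimators recover the
effects they are designed for under the stated noise model; it does not
establish performance under real BOLD nonstationarity, motion artifacts,
inter-subject parcellation mismatch, or non-Gaussian noise.

## Interpreting scores, and known limitations

In-sample forest scores carry an overfitting offset: on pure white-noise
panels the RANFORC mean score sits well above the RIDGEC mean (both are
recorded as frozen fixtures in the test suite). Scores are therefore
comparable *within* a method across regions and subjects — the quantity the
group statistics use — not across methods on an absolute scale. Regions
*sourcing* a modulated coupling also shift with the covariate (connectivity
participation is symmetric), so "planted region recovery" in the tests
compares planted targets against regions untouched by any coupling.

The per-fit runtime of RANFORC is linear in trees × regions × time points;
the acceptance-level simulations run with 100-tree forests
(`options(mvconn.full_forest = TRUE)` restores 1000) and reduced replicate
counts for the age-recovery scenario, scaled to a single-CPU test budget.

Out of scope by design: fMRI preprocessing, voxel/NIfTI handling, atlas
extraction, gray-matter segmentation (GM enters only as a covariate
column), lasso/elastic-net penalties, cross-validated penalty selection,
permutation importance, and spatial cluster inference.

## A worked example

```{r example, eval = FALSE}
library(mvconn)
rules <- list(list(target = 1, sources = 2:4, weight = 0.9, form = "linear"))
cohort <- cohort_spec(20, panel_spec(N = 10, p = 128, coupling = rules),
                      effect_rules = list(list(regions = 1, covariate = "age",
                                               effect = -0.015)),
                      seed = 42)
ch <- generate_cohort(cohort)
maps <- lapply(ch$panels, ridgec_subject, lambda = 10)
group_pipeline(maps, ch$design, analysis = "age_regression")
```

The result table has one row per region with the age effect on Fisher-z
connectivity, its t statistic, raw and BH-adjusted p-values, and the FDR
decision at `alpha = 0.05`. The same workflow is scriptable end-to-end via
`run_pipeline()` or the `inst/cli/mvconn.R` command-line driver.
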