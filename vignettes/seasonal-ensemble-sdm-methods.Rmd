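---
title: "Methods: seasonally dynamic presence-only ensemble SDMs"
author: "seasonalSDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonally dynamic presence-only ensemble SDMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modeling problem

`seasonalSDM` implements a presence-only, seasonally dynamic species
distribution workflow of the kind used to map the season- and sex-specific
ranges of wide-ranging migratory bats from museum collection records. The
data situation is characteristic of historical collections: a few thousand
georeferenced records accumulated over decades, with no absences, uneven
collection effort, and per-record spatial uncertainty. The modeling unit is
the 1-km² pixel of a planar equal-area grid: a pixel is *occupied* if at
least one record falls in it, and occupied pixels are contrasted against a
uniform random *background* sample of the landscape (10,000 pixels by
default). Because several records can share a pixel, records always
outnumber *locations* (occupied pixels), and the package keeps that
distinction explicit everywhere.

The workflow is:

1. **Occurrence QC and stratification.** Records located only to state,
   province, or county are dropped, as are records whose estimated
   georeferencing error exceeds 50 km (a record at exactly 50 km is kept —
   the rule is a strict ">"). Remaining records are binned by month-day into
   four seasons — winter (Dec 1–Feb 29), spring (Mar 1–May 31), summer
   (Jun 1–Jul 31), autumn (Aug 1–Nov 30) — and stratified by sex, except in
   winter where the sexes are pooled (winter samples are too small to
   stratify). This yields seven modeling subsets. Unknown-sex records are
   included in the pooled winter subset and excluded (with an audit count)
   elsewhere; the season bins ignore the year, so winter spans the year
   boundary and February 29 is a valid winter date.
2. **Seasonal predictor stacks.** Each season's covariate set is built from
   monthly climate layers (seasonal mean temperature; the *prior* season's
   mean temperature — or the *next* season's, for autumn, on the reasoning
   that conditions in the adjacent season shape settlement and movement
   decisions; seasonal temperature range) plus static layers (precipitation
   seasonality, growing-season length, percent tree cover). Inputs in the
   WorldClim integer convention (°C×10) are rescaled on ingest and flagged
   in the stack's provenance. Candidate predictors are screened pairwise:
   if either the Pearson or the Spearman correlation of a pair exceeds 0.70
   in absolute value on a fixed-seed sample of up to 50,000 complete pixels,
   one member is dropped. The drop choice is deterministic: a priority list
   encodes the conventional choices (drop elevation in favor of temperature,
   drop diurnal range and raw precipitation totals in favor of season length
   and precipitation seasonality); for other pairs the member with the
   larger mean absolute correlation to the remaining candidates is dropped,
   with an alphabetical tie-break. This makes the retained set invariant to
   the order in which candidates are supplied.
3. **Five model forms, one contract.** Logistic GLM (linear + quadratic
   terms per covariate, no stepwise selection), MARS, boosted regression
   trees, random forest, and a Maxent-style presence-background model are
   fit to each subset's training table. Every form exposes the same
   fit/predict contract: suitability in [0, 1] for any covariate vector.
   Performance is summarized by 10-fold cross-validation, stratified on the
   label so every held-out fold contains presences; the classification
   threshold for sensitivity and specificity is the minimum training
   presence (MTP) — the lowest suitability predicted for any training
   presence, with "predicted ≥ threshold" counting as presence, which
   forces training sensitivity to be exactly 1.
4. **Importance, ensembles, exposure.** Variable importance is permutation
   ΔAUC: the drop in AUC when one covariate's column is shuffled, averaged
   over independent permutations, then averaged across the five forms and
   ranked. Per-form binary maps (thresholded at each model's MTP) are
   averaged into an ensemble map whose pixel values are the fraction of
   forms voting "suitable" — with five forms, exactly {0, 0.2, 0.4, 0.6,
   0.8, 1.0}. Ensemble suitability is extracted at point sets (wind
   turbines) and summarized by mean, range, a 10-bin histogram on [0, 1]
   and adjusted Fisher–Pearson skewness (negative skew = mass piled toward
   high suitability, i.e. strong overlap between turbines and modeled
   habitat).

## Model-form implementations and defaults

The SDM literature establishes the five forms but not their settings, so the
package fixes community-standard defaults, all overridable per run:

* **GLM** — binomial maximum likelihood with linear and quadratic terms on
  the raw covariate scale. On separation (infinite ML estimates) the fit
  falls back to a lightly ridge-penalized solution and flags it.
* **MARS** — implemented natively: a forward pass greedily adds reflected
  hinge pairs `(max(0, x−t), max(0, t−x))` by exact least-squares gain
  (candidate knots at 15 interior quantiles per covariate), up to 21 terms,
  additive only (degree 1); a backward pass prunes single terms by GCV with
  penalty 2 (effective parameters `M + 2(M−1)/2`); the selected basis is
  refit as a binomial GLM. The least-squares forward search plus
  likelihood refit mirrors the classical two-stage practice for binary
  responses.
* **BRT** — implemented natively in compiled code: stagewise boosting of
  binomial deviance with depth-3 exact-greedy regression trees grown on the
  gradient residuals, shrinkage 0.01, bag fraction 0.75, minimum node size
  10. Leaf values are refit by full per-leaf Newton maximization of the
  binomial likelihood given the current ensemble (not a single Newton
  step), so one unshrunk stump on a binary covariate reproduces per-leaf
  empirical log-odds exactly. The tree count (cap 5,000) is chosen by an
  internal stratified 20% validation split with patience 50.
* **RF** — `ranger` classification forest, 1,000 trees, `floor(sqrt(p))`
  split candidates, minimum leaf size 1. Suitability is the fraction of
  trees voting presence (per-tree votes, not probability-forest averages),
  so predictions have granularity 1/1,000.
* **Maxent** — implemented natively as the infinitely-weighted logistic
  approximation: presence rows weighted 1 and background rows 100, features
  = linear, quadratic, and reflected hinges at ten interior quantile knots
  of the internally standardized covariates, L1-penalized via `glmnet` with
  Maxent-style per-class penalty factors (linear 0.05, quadratic 0.1, hinge
  0.5). The coefficient vector is read from glmnet's regularization path at
  the target `multiplier × mean(reg) × n_presence / Σw`. Output passes
  through the logistic transform calibrated at prevalence 0.5,
  `plogis(η + α + H)`, with `α` the log-normalizer over the training
  background and `H` the entropy of the fitted background distribution.
  Standardizing covariates empirically and using symmetric quantile knots
  makes suitability *rankings* exactly invariant to affine rescaling of any
  covariate.

No class weighting is applied anywhere else: presence and background rows
enter the GLM/MARS/BRT/RF likelihoods with equal weight. Cross-validation
folds are plain stratified folds, not spatially blocked; with strongly
autocorrelated covariates, held-out metrics are therefore optimistic
relative to spatial transferability — a known property of this design, not
a defect of the implementation.

## The synthetic landscape

Because the original continental rasters and turbine database are
multi-gigabyte downloads, the package ships a generator that emulates the
statistical structure the analysis assumes, making every stage testable
offline.

* **Covariate fields.** White Gaussian noise smoothed with a separable
  Gaussian kernel (correlation length in km; 0 = white noise), rescaled
  exactly to a target mean and sd, then clipped to physical bounds. The
  default landscape is 200×200 pixels of 1 km with a 15-km correlation
  length — long enough that fields look like macroclimate, short enough
  that a 200-km window contains many independent patches. Temperature is
  generated as an annual-mean field plus an amplitude field times an annual
  cosine (coldest mid-January), realized as 12 monthly layers so the
  seasonal-mean construction operators are exercised end to end.
* **Truth and sampling.** True suitability is inverse-logit of a linear (+
  optional quadratic) model in the derived seasonal covariates. The default
  coefficients produce a growing-season-length-dominated surface with a
  unimodal optimum near 250 days, a moderate-temperature optimum, and a
  penalty for large seasonal temperature ranges — qualitatively the
  response shapes reported for wintering migratory bats. Records are drawn
  with probability proportional to suitability (optionally times an
  effort-bias field), receive coordinates uniform within the pixel, dates
  uniform over the season bin (Feb 29 only in leap years), sex from the
  subset (the pooled winter subset draws from a configurable F/M/U mix —
  collection compilations rarely report a sex ratio or unknown-sex
  fraction, so these are parameters, defaulting to 0.45/0.45/0.10), and spatial errors from an
  exponential distribution (mean 8 km) truncated at 45 km so every
  generated record passes the 50-km QC filter.
* **Counts.** The default scenario draws the seven subsets at record
  counts typical of a continental museum compilation {130, 324, 353, 342, 999, 240, 365} and, via a
  two-stage draw (distinct pixels without replacement proportional to
  suitability, then the remaining records multinomially over those pixels),
  at the printed distinct-location counts {61, 165, 89, 182, 239, 140,
  151}. This lets the full parse→filter→bin→stratify→rasterize chain be
  verified against exact expected counts. The plain i.i.d. sampling mode
  remains available (and is what the distributional tests use).
* **What the generator does not emulate:** real geography (coastlines,
  projection distortion), temporally varying collection effort, spatial
  clustering of collectors along roads and towns, and detection differences
  between sexes and seasons. Tests passing on this landscape therefore
  demonstrate the *software* recovers known structure under the stated
  sampling model; they do not validate the ecological conclusions on real
  data.

### Benchmark calibration

The model-sanity and importance-recovery benchmark uses one autocorrelated
driver and four independent noise covariates, 300 presence pixels and 2,000
background pixels on the 200×200 grid. The driver effect is realized as
**3 logits per driver standard deviation with intercept −6**. The intercept
matters as much as the slope here: with presences drawn proportionally to
inverse-logit suitability, the best achievable (Bayes) discrimination
between presence and background pixels depends on how selective the
sampling is. Under this calibration the Bayes AUC is ≈ 0.93 — comparable to
the upper range of continental presence-background analyses — so all five
forms are expected to reach held-out AUC ≥ 0.85 with headroom, while a
weaker reading of "3 logits across the covariate range" would cap even the
optimal classifier near AUC 0.80 and make the sanity bar unreachable by
construction.

## Numerical choices and degenerate inputs

* Pixels are half-open squares, lower-left inclusive; a point on a shared
  edge belongs to the pixel whose lower-left corner it touches. The same
  convention is used for occurrence rasterization and point extraction.
* AUC is the rank-statistic (Mann–Whitney) form with ties counted ½; it
  equals the trapezoidal ROC area on tie-free data to machine precision.
* The MTP rule is "≥ threshold ⇒ presence", required for exact training
  sensitivity 1; specificity counts background strictly below the
  threshold.
* Permutation importance defaults to 10 repeats (stochastic error below
  ~0.01 AUC at typical sizes); within the pipeline it is evaluated on all
  presences plus a fixed-seed subsample of at most 2,000 background rows,
  which keeps the per-form cost flat across subsets without materially
  changing the AUC estimate.
* A zero-variance covariate has undefined correlations: the screen retains
  and flags it rather than guessing. A zero-sd covariate spec yields a
  constant field (the degenerate case of the generator), while negative sd
  is rejected.
* Importance ties rank alphabetically; the correlation screen's drop
  choices are fully deterministic (priority list, then mean absolute
  correlation, then name) so screening is order-stable.
* Every stochastic stage draws its seed as a stable hash of the master seed
  and a stage label (`stageSeed`), so adding or re-running one stage never
  perturbs another's stream, and identical configurations reproduce
  byte-identical CSV outputs.
* ESRI ASCII grids are the canonical raster exchange format (plain text,
  self-describing, nodata −9999). TIFF output stores an affinely rescaled
  [0.1, 0.9] float band with the transform and grid georeferencing in a
  JSON sidecar, because no GDAL-backed reader is assumed.

## Problem sizes used by the tests and acceptance script

The package's own validation runs at desk scale, chosen so the full
factorial remains comfortably reproducible on a single CPU: the default
200×200 synthetic landscape with the seven printed subset sizes, and 4,000
background pixels for the pipeline runs (the package default outside the
test harness remains 10,000; at 4,000 the background
still outnumbers every presence set by an order of magnitude and the
training tables keep the same presence/background imbalance structure).
Cross-validation stays at the full 10 folds, and the benchmark importance
sweep uses 20 seeds with 5 permutation repeats each. A complete 7×5
factorial run takes about seven minutes at this scale.

## Known limitations

* Presence-only inference inherits all collection-effort biases of the
  record source; the generator's bias field can emulate, but not correct,
  such effort patterns.
* The Maxent implementation is the weighted-logistic approximation with a
  fixed path-point regularization, not a feature-by-feature replication of
  the reference Java implementation; agreement is exact only in the
  infinite-weight, shared-feature limit.
* No spatial cross-validation, model stacking beyond binary averaging,
  TSS/Kappa/Boyce metrics, or collision-risk modeling; these are outside
  the package's scope.
* The refit ("leave one variable out") reading of variable importance is
  not implemented; importance is permutation ΔAUC only.
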