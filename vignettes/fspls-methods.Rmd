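---
title: "Forward selection with projection deflation: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward selection with projection deflation: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fspls)
```

## The problem

Omics classifiers built by regularised regression typically keep tens to
hundreds of features — too many for a point-of-care assay, and useless
without measuring the *whole* assay anyway, because normalisation (library
size for sequencing counts) needs the full feature vector. This package
addresses both halves of that problem:

1. **Minimal signatures.** FS-PLS (forward selection with partial-least-
   squares-style deflation) selects features one at a time, each chosen for
   the outcome variation it explains *orthogonally* to everything already
   selected.
2. **Library-size-free normalisation.** A sparse gaussian FS-PLS model
   predicts each sample's log library size from one or two highly expressed
   surrogate features, so a signature plus its surrogates — a qPCR-scale
   panel — suffices to classify a single new sample.

## The selection model

Let \(X\) be an \(m \times p\) matrix (samples in rows), centred so every
column has mean zero (the means \(\mu_1, \dots, \mu_p\) are recorded for
prediction), and \(y\) an outcome with family gaussian, binomial, or
multinomial (class 0 as reference). At iteration \(k\), with selected
columns \(X^k\):

1. A thin SVD of \(X^k\) gives an orthonormal basis \(U\); the matrix is
   deflated to \(R^k = X - U U^\top X\), whose columns are exactly
   orthogonal to every selected column. Singular directions below
   \(10^{-10}\sigma_{\max}\) are dropped, guarding against collinear
   selections.
2. A univariate generalized-linear model of \(y\) on each column of
   \(R^k\) is fitted by exact maximum likelihood, carrying the accumulated
   model as a fixed linear-predictor **offset**. The column with the
   largest log-likelihood wins; ties break to the lowest index; columns
   with deflated variance below \(10^{-12}\) (all previously selected
   features, and anything they span) are not candidates.
3. The winner's coefficient is re-fitted with L2 shrinkage (below) and
   *frozen*: earlier coefficients are never revisited. The linear predictor
   accumulates \(\beta_k r_k\) plus an intercept update.
4. A chi-squared likelihood-ratio test compares the step's fit against the
   offset-only null, on 1 degree of freedom (\(C-1\) for multinomial).
   Selection stops when \(p \ge\) `pvalue_threshold` (default 0.05, a
   conventional choice — the threshold is a first-class, prominently
   exposed option), when `max_features` is reached, or when no informative
   candidate remains. `force_to_max = TRUE` continues past the threshold,
   which is how heavily imbalanced multi-class problems are best handled.

Because deflation removes from *every* feature the component correlated
with the selected set, features that merely correlate with an already
selected feature cannot re-enter on the strength of that correlation —
this is what drives the low pairwise correlation of FS-PLS signatures.

### Why the step test carries an offset

Two readings of "test the new variable against the null model (the outcome
and the offset)" are possible: (a) the new feature's univariate fit versus
the raw intercept-only null, or (b) both models carrying the accumulated
linear predictor as a fixed GLM offset. We implement (b). The deciding
observation is the normalisation task: the first surrogate typically
explains ~99% of log library size, so under reading (a) a second surrogate
can never look significant against the *raw-variance* null and every
normalisation model would stop at one feature — yet two-feature surrogate
models are exactly what this procedure is known to produce. Reading (b)
also makes the per-step log-likelihood sequence provably non-decreasing
(each step's fit contains the previous model as its offset-null), and at
step one the two readings coincide, so null calibration of the stopping
rule is unaffected.

### Fitting details

* **Gaussian** fits are closed-form weighted least squares; the
  log-likelihood uses the profile (MLE) variance so likelihood-ratio
  statistics are self-contained. The residual sum of squares is floored at
  `1e-300` so exact fits stay finite; once the accumulated model explains
  all but a \(10^{-10}\) fraction of the outcome variance, selection stops
  (`loglik_degenerate`) — any further "improvement" on a floored
  likelihood would be noise.
* **Binomial** fits use a damped Newton iteration, vectorised across all
  candidate columns at once (the screen is a sequence of \(m \times p\)
  matrix operations with per-column 2×2 Newton solves), which is what makes
  thousand-feature screens take milliseconds.
* **Multinomial** fits maximise the exact multinomial likelihood
  (L-BFGS-B with analytic gradients), not a neural-network approximation:
  the exact likelihood is better defined and testable, and the test-suite
  cross-checks it against an independent reference fitter.
* **Separation.** On (quasi-)separable data the standardized slope is
  capped at 30 on the linear-predictor scale and the fit flagged
  `converged = FALSE`, keeping selection well defined on separable toy
  data.
* **Shrinkage.** The per-step refit maximises
  \(\ell - \lambda \beta_s^2\), where \(\beta_s\) is the slope after
  standardizing the feature to unit variance (the intercept is never
  penalized), and the coefficient is rescaled back. Default
  \(\lambda = 0.01\): the method prescribes L2 shrinkage but no strength,
  so we chose a mild conventional value, user-configurable; \(\lambda = 0\)
  reproduces maximum likelihood exactly.
* **Weights.** Optional non-negative sample weights (e.g. inverse class
  proportions, `class_weights()`) multiply each sample's log-likelihood
  contribution in *both* the selection fits and the ridge refit.
* Iterative fits converge at relative log-likelihood change \(10^{-8}\),
  with a 100-iteration cap.
* The basis is recomputed by thin SVD each iteration rather than updated
  incrementally: signatures have tens of features at most, and numerical
  stability beats speed here.

### Prediction replays the training transformations

Each step records the projection coefficients of its chosen column on the
previously selected columns (in training data). For a new sample — a
single sample in isolation; no batch statistics are ever used — the
pipeline centres its features with the *training* means, reconstructs each
step's deflated value from those stored coefficients, accumulates the
frozen per-step contributions, and applies the inverse link. Only the
selected features are ever touched, which is what makes the minimal
measured panel sufficient. Model-size selection after the fact uses
`select_model_size()` on the recorded loss path (training MSE for
gaussian, mean deviance otherwise): `min`, or `one_se` — the smallest size
whose loss is within one standard error of the minimum, with the standard
error taken at the minimizing size (the usual cross-validation
convention; the package's loss-path standard errors come from per-sample
loss contributions).

## Library-size surrogates, faux and ratio normalisation

For sequencing counts, `library_sizes()` takes the log of each sample's
total count **before any filtering**, and `fit_normalization()` fits a
gaussian FS-PLS model of that log total on log-transformed, otherwise
un-normalised counts — candidates pre-filtered to the stably, highly
expressed (`filter_top_expressed()`, 5%-trimmed mean, intersected across
datasets where applicable) — capped at two surrogates and truncated by the
one-standard-error rule.

Two constructions use the fitted surrogate model:

* **Faux**: subtract the *predicted* log library size from every
  log-count. Subtraction in log space is the analogue of dividing counts
  by the total (the method names the operation but not the arithmetic;
  subtraction preserves single-sample capability, and when the prediction
  equals the truth, faux normalisation *is* ordinary normalisation).
* **Ratio**: recast the feature space as log-ratios of every feature
  against every surrogate: column \((j, g)\) is
  \(\log x_j - \log x_g\), giving \(p \cdot q\) columns. The construction
  is exactly invariant to per-sample scaling. Self-ratio columns are kept
  as constant zeros so the dimensionality statement holds exactly —
  selection ignores zero-variance columns anyway.

The baseline ("ordinary") arm subtracts the true log library size, the
simplest member of the class of library-size normalisations. Counts are
log-transformed as \(\log(\text{count} + 1)\) by default; the pseudocount
is configurable, ratios are base-invariant, and the surrogate model's fit
quality is base-invariant too. Discrimination candidates come from
`filter_top_variable()`, normalisation candidates from
`filter_top_expressed()` — deliberately different pools.

## Evaluation harness

`make_folds()` builds stratified, seed-deterministic fold plans (class
proportions within one sample per fold); the same plan is reused by the
normalisation and discrimination tasks so held-out samples are unseen by
*both* models. Within `run_benchmark()`, every training-side statistic —
expression/variance filters, the surrogate model, the signature — is
computed from training folds only; ordinary normalisation uses each
sample's own total (a per-sample quantity), and microarray-style
autoscaling is applied separately within train and test partitions.

Metrics: Mann–Whitney AUC (ties one half) for binary outcomes; one-vs-rest
AUC, sensitivity and specificity per class (argmax ties to the lowest
class index, documented in the output) with macro AUC as their unweighted
mean for multinomial; MSE and a single-predictor adjusted \(R^2\) for
continuous outcomes. Held-out predictions are concatenated across folds
for pooled per-class metrics, and the Wasserstein-1 distance between the
case and control distributions of predicted probability quantifies how
*confidently* a model separates groups — information AUC alone does not
carry. Per-fold summaries use t-based 95% confidence intervals (4 df with
five folds; the choice of CI construction is ours). Multinomial training
loss is the deviance; reporting uses macro AUC plus per-class
sensitivity/specificity. Comparator selection methods are not
re-implemented; the harness's per-fold structure only needs fit / predict
/ feature-count from a model, so external estimators can be slotted in by
mirroring `run_benchmark()`'s per-fold loop.

## What the simulator emulates — and what it does not

`simulate_counts()` draws negative-binomial counts with mean
\(s_i \, b_g \, e^{E_{ig}}\): log-normal size factors \(s_i\) (sd 0.5 by
default — strong library-size variation), log-uniform baselines, a small
set of outcome-associated features with log-fold-change effects,
housekeeping features proportional to \(s_i\) whose stated log-noise sd is
their *entire* noise (counts are rounded; ordinary genes keep NB counting
noise), and optional co-regulated blocks driven by a shared latent factor.
Block members are given low dispersion and the shared/own variance split
is calibrated against the total log-count variance, so the realized
within-block correlation of log counts lands on the requested value —
with ordinary NB noise (dispersion 0.4) the realizable correlation would
cap near 0.6 regardless of the latent structure. When a block carries
signal, the class effect rides on the shared factor: the module is
differentially expressed as a whole and its members are mutually redundant
given any one of them. (Putting the effect on a single member instead
makes the *other* members conditionally informative — they denoise the
shared factor — and any forward selection will legitimately take a
second one.)

Two scale choices matter and are stated here as the package's study
conditions. The surrogate-recovery scenario simulates \(p = 10000\)
features: with only a few hundred genes, the library total's aggregated
counting noise (relative sd \(\approx \sqrt{\sum_g b_g^2 \phi} / \sum_g
b_g\)) rivals the surrogates' planted noise and individual high-count
genes genuinely compete as predictors of the total — an artifact absent at
assay scale, where totals aggregate \(\ge 10^4\) genes. The end-to-end
parity comparison uses \(m = 150\), \(p = 2000\), five markers at
log-fold-change 1, where held-out AUC sits near 0.95 — away from the
ceiling, so agreement between normalisation modes is informative. Marker
recovery uses \(m = 300\), \(p = 1000\) gaussian features with four
markers shifted to a single-feature AUC of 0.75
(\(\delta = \sqrt{2}\,\Phi^{-1}(0.75)\)) plus a correlated signal block.

The generator does **not** emulate cross-platform or batch effects,
protocol differences (e.g. rRNA depletion changing what "library size"
means), or missing values; passing tests therefore say nothing about
transfer across platforms or cohorts, which remains the method's known
weak point, and per-feature centring by training means is exactly the
step that suffers under dataset shift.

## Other numerical and design choices

* All randomness flows through explicit integer seeds
  (`withr::with_seed`); fits themselves are deterministic given data and
  options, and identical seeds make the whole benchmark bit-reproducible.
* The LRT uses the *maximum-likelihood* log-likelihood of the selected
  step (guaranteed at or above its null); the ridge-refit coefficient is
  what enters the model. The pseudocode order (shrink, then test) leaves
  this ambiguous; testing the ML fit keeps the test statistic
  non-negative by construction.
* Serialized models are versioned JSON; readers reject unknown versions.
  Stored per-step loadings cover only features the transformations touch,
  which is the minimal-panel contract.
* Feature ids are opaque strings; no gene-symbol normalisation is
  attempted.
* Known limitations: no LARS-style acceleration (the multinomial screen
  refits every candidate each step), no ordinal outcomes, no
  cross-fold-error stopping rule; the p-value stopping rule ignores
  selection multiplicity, so on pure noise the first-step family-wise
  false-selection rate is the minimum of \(p\) correlated univariate
  tests (~0.05–0.07 at \(m = 60\), \(p = 50\)) rather than 0.05 per
  feature, and late steps can admit features whose accuracy contribution
  is negligible though statistically significant.

## Problem sizes used by the shipped checks

The test-suite and `scripts/acceptance.R` run, per invocation: 50 random
deflation problems (\(m \le 60\), \(p \le 30\)); 30 selection-oracle
problems (\(p \le 10\)); 200 pure-noise null-calibration replicates per
family at \(m = 60\), \(p = 50\); 25 marker-recovery replicates at
\(m = 300\), \(p = 1000\); 10 surrogate-recovery replicates at
\(m = 120\), \(p = 10^4\); and 10 end-to-end parity replicates at
\(m = 150\), \(p = 2000\) across three normalisation modes — sizes chosen
so the full battery completes in minutes on a laptop while keeping every
scenario in the regime its claim is about.
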