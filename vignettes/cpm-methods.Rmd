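---
title: "Connectome-based prediction of behavioural change: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based prediction of behavioural change: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmpred)
```

## The problem

Small clinical cohorts — here the motivating setting is patients with a
cerebrovascular condition undergoing revascularization surgery — are often
scanned with resting-state fMRI before an intervention, and assessed
behaviourally (e.g. processing speed) before and after it. The scientific
question is whether the *preoperative* functional connectome carries
information about the *postoperative change* in behaviour: a per-subject
change score `delta = score(follow-up) - score(baseline)`.

`cpmpred` implements connectome-based predictive modelling (CPM) for this
question. The connectome is the node-by-node matrix of Pearson correlations
between parcel-averaged BOLD time series (AAL-116 parcellation by default,
giving `E = 116*115/2 = 6670` unique edges); the estimator selects edges
associated with the behaviour in training data, sums them into network
strength scores, and predicts held-out subjects with a univariate linear
model. Everything is exercised on synthetic cohorts with known ground
truth, because cohorts of this kind are rarely shareable.

## The estimator, step by step

**Edge selection.** For each edge, the association with the behaviour
change score is the *partial Spearman correlation* controlling for age, sex
and education: all variables are rank-transformed (midranks for ties), the
ranked edge and ranked behaviour are each residualized on the ranked
covariates plus an intercept, and the correlation of the residuals is
taken. Spearman rather than Pearson because change scores in small cohorts
are routinely non-normal. The two-sided p-value uses the t distribution
with `n - C - 2` degrees of freedom. With no covariates the construction
collapses to plain Spearman exactly, which the test suite checks against a
brute-force oracle at `1e-12`.

Edges with `p < p_threshold` are split by the sign of their correlation
into a *positive network* and a *negative network* — two disjoint masks.
Selection is strict (`<`, not `<=`): thresholds come from a fine grid, so
the boundary case carries no probability for continuous data, and a fixed
convention makes runs reproducible. (At very small n the Spearman p-values
are discrete and *can* land exactly on a round threshold; strictness then
decides deterministically.)

**Network strength.** A subject's strength for a mask is the plain sum of
its raw correlation values over the mask. No Fisher z-transform is applied
anywhere: strengths are sums of raw r values, so the raw values are the
edge currency throughout.

**Prediction.** Behaviour is regressed on strength by ordinary least
squares — one model per network sign, fitted on training subjects only,
with no covariates in this stage (covariates act in selection only). In
leave-one-out cross-validation (LOOCV), each fold selects edges, computes
strengths and fits the models on the `n - 1` training subjects, then
predicts the left-out subject from its own strengths under the *training*
masks. The accuracy statistic per network is `rho_true`, the Spearman
correlation between the n cross-validated predictions and the observed
scores.

**Degenerate folds.** A fold whose mask is empty (or whose strengths are
constant) has no usable regressor; its prediction falls back to the
training-behaviour mean, the no-information optimum for squared error.
This keeps the pipeline total; such folds are counted and surfaced in the
result object. If the resulting prediction vector is constant, `rho_true`
is defined as 0 rather than `NA`, which keeps the permutation statistic
total and deterministic.

## Threshold tuning and its optimism

The selection threshold is tuned by sweeping a grid — by default 0.0001 to
0.05 in steps of 0.0001 (500 values, generated from integer multiples of
the step so the endpoints are exact) — running the full LOOCV at each
value, and taking the argmax of each network's `rho_true` curve. Exact
ties break to the *smallest* threshold (sparser selection). The sweep is
computed in one pass: per fold, the per-edge statistics are computed once,
edges are ordered by p within sign, and strengths at every mask size come
from cumulative sums; this is numerically identical to rerunning the LOOCV
per grid point (tested to `1e-10`) at a fraction of the cost.

Tuning on the observed data makes `rho_true` at the chosen threshold an
optimistically biased statistic. The permutation test therefore has two
modes (below), and the package ships a property test demonstrating the
inflation: on null cohorts, permuting at thresholds pre-tuned on the
observed data rejects *more* often than carrying the tuning into every
permutation replicate.

## Permutation significance and FDR

LOOCV folds are not independent, so `rho_true` has no usable analytic
null. Significance is assessed by permutation: the behaviour vector is
randomly reshuffled across subjects — covariates stay attached to their
subjects' connectomes, since the null being tested is "behaviour is
exchangeable given the connectome and covariates" — and the entire
cross-validated analysis is rerun `N` times (default `N = 5000`). The
p-value is the add-one exceedance fraction

```
p_permu = (#{rho_null >= rho_true} + 1) / (N + 1)
```

with denominator 5001 at the default, hence a floor of 1/5001. `>=` is
the conservative convention for ties.

With `reoptimize = FALSE` (default) replicates are evaluated at the
supplied thresholds — the usual practice when the tuned thresholds are
treated as part of the model. With `reoptimize = TRUE` each replicate
reruns the grid search and contributes its own tuned maximum, which is
the honest null when the observed statistic was itself tuned; this mode is
recommended and its calibration is verified in the test suite.

Across the declared family of models (contrast x network sign; one run of
the study pipeline corrects all four together, and the family membership
is explicit in the output), permutation p-values are adjusted by
Benjamini–Hochberg step-up FDR via `stats::p.adjust`, cross-checked in the
tests against a hand-coded step-up implementation.

## Consensus anatomy

Fold masks differ across LOOCV iterations; the reported functional
anatomy is the *consensus*: edges selected in every fold, per network
sign (elementwise AND — adding a fold can only shrink it). Consensus masks
are mapped through the fixed edge-index bijection (row-major strict upper
triangle, 0-based node indices) to labelled node pairs using the packaged
AAL-116 node table; an empty consensus renders as an em-dash row, the
conventional "no connectivity identified". The per-edge mean selection
rho across folds is reported as a convenience. The node table is a plain
CSV (canonical atlas spellings, including "Cerebelum"); any atlas can be
substituted by supplying a table with the same columns.

## Motion quality control

Framewise displacement is the Power convention: the sum of absolute
backward differences of the six rigid-body parameters, rotations converted
to arc length at a configurable head radius (50 mm default); the first
volume has FD 0. Rotations are radians on input (degrees via a flag). A
subject passes QC only if (a) fewer than 20% of volumes exceed FD 0.5 mm,
(b) maximum absolute translation is at most 3 mm *and* maximum absolute
rotation at most 3 degrees, and (c) mean FD is below 0.2 mm. Which FD
formula the motivating literature used is typically not printed; Power is
the dominant convention in the scrubbing literature and the radius is a
parameter. QC only reports — scrubbing-as-regression belongs to upstream
preprocessing, out of scope here.

## The synthetic cohort generator

The generator's job is to make every stage testable with known ground
truth, at the statistical scale of the motivating setting: around 12
subjects, AAL-116 edge spaces, correlation-valued edges, and a continuous
change score.

- **Edges** are drawn i.i.d. per subject and edge as `tanh(z)` with
  `z ~ N(0.1, 0.4^2)`: bounded in (−1, 1), centred near zero as after
  global signal regression. The bounding transform is fixed (tanh, not
  clipping) and no test depends on tail behaviour.
- **Signal.** A chosen number of edges is planted with equal coefficient
  magnitudes `effect_scale` (signs optional):
  `behaviour = effects' * edges + covariate_effects' * covariates +
  N(0, noise_sd^2)`. Equal magnitudes make the noise level for a target
  population R² a closed form (`noise_sd_for_r2()`) and the
  zero-noise least-squares recovery oracle exact.
- **Covariates** emulate the cohort demographics: age ~ N(36.6, 9.6²),
  sex ~ Bernoulli(0.75) (1 = female, a 9/3 split at n = 12), education ~
  N(13.4, 3.6²). Cosmetic only.
- **Time series** (`generate_timeseries()`) exist to test connectome
  construction end-to-end: multivariate Gaussian draws whose population
  correlation equals a target (projected to the nearest PSD correlation
  matrix if needed, and flagged), 155 volumes by default — a 160-volume
  acquisition minus five dummy scans.
- **Motion traces** are bounded low-amplitude drift plus persistent level
  shifts placed to exceed FD 0.5 mm in a requested fraction of volumes.
- **Determinism.** Every generator takes a seed and runs in an isolated
  RNG stream (the global `.Random.seed` is saved and restored); identical
  seeds reproduce cohorts bit for bit.

**What the generator does and does not emulate.** It reproduces the
dimensions, the bounded correlation-valued edges, sparse linear coupling
with noise, and nuisance covariates. It deliberately does *not* simulate
haemodynamics, realistic fMRI noise spectra, vascular pathology, or —
importantly — *correlated* edges. Real connectome edges co-fluctuate in
networks; behavioural signal in real data is typically distributed over
many mutually correlated edges, each of which then carries a usable
marginal correlation. With independent edges, k planted edges explaining a
fraction R² of the behaviour variance each carry marginal correlation only
`sqrt(R²/k)` (the squared marginals sum to R²). At n ≈ 12–20 this puts a
hard ceiling on univariate edge selection: with k = 10 and R² = 0.5 each
edge's marginal rho ≈ 0.22, below any workable selection threshold. The
recovery properties that the test suite verifies therefore use designs
where the arithmetic permits recovery (few planted edges and/or larger n,
e.g. 3 edges at n = 60 where each marginal rho = 1/√3); the suite also
*measures* the scaled-down study regime (n = 20, 10 edges) and documents
that sparse-independent-edge recovery there is weak — a true property of
CPM's univariate screening, not an implementation artifact. Passing tests
certify the machinery, not real-data effect sizes.

## Numerical choices

- Strict `p < threshold` selection; average ranks everywhere ties occur.
- Tie-break in threshold tuning: smallest threshold at equal `rho_true`.
- Degenerate folds predict the training mean; constant prediction vectors
  give `rho_true = 0`.
- The grid is generated from integer multiples of the step (no floating
  accumulation; the default grid has exactly 500 values).
- Constant edges (zero variance) get `rho = 0, p = 1` and are never
  selected; constant inputs to the scalar statistic warn.
- Asymmetry tolerance for connectivity matrices: `1e-8`; symmetrization
  `(M + M')/2` and an exactly unit diagonal after construction.
- Bundles are written atomically (write-then-rename), and the provenance
  block excludes the output path so reruns into different directories stay
  byte-identical.

## Problem sizes used by the test and acceptance runs

Chosen as the package's own verification scale: null calibration uses 200
null cohorts (n = 12, 30 nodes → 435 edges) with 200 permutations each at
fixed thresholds 0.01/0.01; the tuned-vs-retuned optimism comparison uses
100 null cohorts at a 10-point grid with 60 permutations; planted-signal
recovery uses 50 cohorts (n = 20, 30 nodes, 10 positive edges, noise from
`noise_sd_for_r2(10, 1, 0.5)`) with a 50-point grid; oracle equivalence
uses 1000 random vector pairs (n = 12) and five 5-subject × 10-edge LOOCV
instances. The analysis scripts under `analysis/` run a scaled 500-
permutation study on a simulated 12 × 6670 cohort.

## Known limitations

- The strength model is a simple univariate regression; ridge or combined
  positive+negative variants are out of scope.
- Only leave-one-out cross-validation is provided (matching the motivating
  design); k-fold variants are not.
- The generator's independent-edge design bounds recoverable sparse
  signals as described above; correlated-edge simulation would require a
  latent network model and is deliberately not included.
- The FDR family is whatever one pipeline invocation computes; combining
  p-values across separate runs is the user's responsibility.
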