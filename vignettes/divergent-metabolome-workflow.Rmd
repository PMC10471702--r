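---
title: "Detecting genetically driven metabolite differences between divergent selection lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genetically driven metabolite differences between divergent selection lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabodiverge)
```

## The problem

Two rabbit lines divergently selected for intramuscular fat content (IMF,
g fat per 100 g fresh muscle) differ genetically but share diet, housing
and rearing. Untargeted LC-MS plasma metabolomics of such lines asks: which
of ~900 metabolites differ in abundance between the high (H) and low (L)
line, and by how much? Because both line membership and the IMF phenotype
are available, a metabolite counts as a *correlated response to selection*
only when it separates the lines (a discriminant criterion) **and** tracks
the IMF value linearly (a regression criterion); requiring both guards
against genetic drift (which separates lines without tracking the trait)
and against environmental extremes of the trait (which track IMF without a
line difference).

`metabodiverge` implements that complete statistical chain and a synthetic
data generator that emulates the design, so every stage is testable without
any external dataset. The `analysis/` directory of the source repository
runs the chain as numbered stage scripts over a simulated study.

## Data model and the synthetic generator

A `metabolome_panel` holds a non-negative abundance matrix (samples x
metabolites), the acquisition block of each metabolite (positive-early,
positive-late, negative, polar — the four LC-MS methodologies), and per
sample the line, sex and IMF.

`generate_panel()` draws each metabolite's log abundance as Gaussian with a
metabolite-specific mean (uniform on 8–14, arbitrary intensity units) and
SD (uniform on 0.3–1.0). A planted line effect `delta` (SD units) shifts
the H-line mean by `+delta * sd / 2` and the L line by `-delta * sd / 2`,
so the standardized log-scale difference equals `delta` exactly and
downstream recovery is well defined. Defaults mirror the study conditions:

* 24 samples per line, 12 of each sex — the experiment's layout;
* four blocks of 242/168/399/111 metabolites (920 total) — the counts
  retained after filtering in the motivating study;
* 35% of metabolites affected, |effects| uniform on 0.23–6.04 SD with
  random sign — the range of standardized differences the study reports,
  with the affected fraction chosen so roughly a third of the panel carries
  signal;
* zeros injected per metabolite and per line at Bernoulli rates uniform on
  [0, 0.08]. The missingness mechanism of the real instrument is unknown;
  random (MCAR) zeros at rates straddling the 10% filter threshold exercise
  the filter without dominating the panel;
* IMF = 0.835 + 0.45 x (line == H) + N(0, 0.145) g/100 g, giving line
  means averaging 1.06 g/100 g, a 0.45 gap, and a gap of ~3.1 trait SD —
  the values reported for the selection experiment. IMF couples to the
  metabolites through the shared line effect; no direct metabolite-to-IMF
  loading is added.

Metabolites are independent by default; a low-rank factor option
(`corr_rank`, `corr_weight`) adds shared variation when correlated panels
are needed (the imputation benchmark uses it). What the generator does
*not* emulate: mass-spectral peaks, retention-time structure, adducts,
batch drift, or informative (intensity-dependent) missingness. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated model, not robustness to instrument artifacts.

A single seed drives everything through `derive_seed(seed, stage)`, a fixed
affine-modular split, so stages are reproducible independently and
bit-identical on reruns.

## Preprocessing

**Zero filter.** A metabolite is kept iff it has strictly less than 10%
zeros in at least one line (`min(frac_H, frac_L) < 0.10`). The inequality
is strict: with 24 samples per line, up to 2 zeros (8.3%) in the better
line passes, 3 zeros (12.5%) in both lines fails. A metabolite absent in
one line but present in the other is deliberately kept — all-H/none-L
patterns are exactly the biology of interest.

**Imputation.** Remaining zeros are treated as missing, not as true zeros,
and imputed by iterative random forest (the missForest scheme): initialize
at observed column medians, cycle columns in increasing-missingness order
regressing each on all others (ranger forests, 100 trees), and stop when
the normalized change in imputed values rises — returning the previous
iterate — or after `max_iter` sweeps (a warning, not an error). Imputed
values are floored at half the metabolite's minimum observed value so the
subsequent log-ratio step is always defined. Observed cells are never
modified.

**Why per block?** The four LC-MS methodologies are separate relative
quantifications; each block is filtered, imputed and transformed on its own
and the transformed blocks are column-joined, preserving sample identity
and per-column block provenance.

## Compositional treatment

Untargeted intensities are relative, so the information lives in ratios.
The additive log-ratio transform maps strictly positive abundances to
`ln(x_j) - ln(x_ref)` for all `j != ref`, consuming one reference column
per block (920 metabolites become 916 log-ratio traits).

The reference should (1) preserve the geometry of the full set of
log-ratios and (2) have low variance, so ratio variation reflects the
numerator. `select_alr_reference()` scores every candidate by the
Procrustes correlation between its alr configuration and the full
log-ratio geometry, screens candidates at the median log variance, and
takes the best-scoring survivor (ties: lower variance, then lexicographic
id). Two realizations deserve note:

* the full pairwise log-ratio configuration (J(J-1)/2 columns) has exactly
  the sample geometry of the centered log-ratio (clr) matrix up to rotation
  and a uniform `sqrt(J)` scale — its Gram matrix is J times the clr Gram —
  so the clr configuration stands in for it; the test suite verifies the
  equivalence against the explicit all-pairs construction;
* the published method states both criteria but no combination rule; the
  median-variance screen followed by correlation maximization is this
  package's deterministic rule, with the screen quantile configurable.

Procrustes correlation itself is computed from the singular values of the
cross-covariance of the column-centered configurations (reduced to score
space for speed): `sum(d) / sqrt(ssX * ssY)`, the square root of one minus
the minimized Procrustes statistic.

## PLS, PLS-DA, and variable importance

The model core is a from-scratch NIPALS PLS1. For a univariate response no
inner iteration is needed: each component's weight vector is the normalized
covariance direction `X'y / ||X'y||`, X is deflated by the rank-one score
reconstruction, and components collapse to a coefficient vector
`B = W (P'W)^{-1} q`. PLS-DA codes the two classes 0/1 (L = 0, H = 1) and
thresholds predictions at 0.5 (>= 0.5 predicts the class coded 1; an exact
tie has probability zero on continuous scores). At full rank the
coefficients coincide with ordinary least squares — one of the test
oracles.

VIP scores follow the standard projection-importance formula weighted by
the per-component explained response variance; mean squared VIP is exactly
1, so the conventional cutoff 0.8 flags below-average contributors out.
Coefficient uncertainty uses Martens' jackknife over the inner-CV segment
refits: `SE_j^2 = (g-1)/g * sum_m (b_mj - b_j)^2` with a t interval on
`g - 1` degrees of freedom. Prediction quality is `Q2 = 1 - PRESS/TSS`
against the training mean.

## Cross model validation

`run_cmv()` nests everything that touches the data inside the training
partition: 8 outer folds (stratified by line, so 48 samples give folds of
exactly 6 with 3 per line), 7-fold inner CV on each training set, 20
reshuffled iterations — 160 models per mode. Per model:

1. the inner CV picks the number of latent components (1–10) as the
   smallest within one standard error of the best inner error
   (misclassification for PLS-DA, MSE for PLS); the published workflow
   states no selection rule, so this conservative standard rule is the
   package's choice;
2. variables with VIP >= 0.8 **and** 95% jackknife CI excluding 0 are
   selected (the jackknife reuses the inner segments);
3. the model is refitted on the selected variables and predicts the
   held-out fold.

Standardization is global (whole matrix, once) by default, reproducing the
published workflow; a leakage-safe per-training-fold option exists but is
off by default for fidelity. A fold whose selection comes up empty is kept
as a model (it counts toward the 160) but contributes nothing to the tally
and predicts the training mean or majority class; balanced-majority ties go
to the class coded 0.

Selection tallies feed `consensus_selection()`: a metabolite must appear in
strictly more than 80% of models — more than 128 of 160 — in *both* the
PLS-DA and the PLS runs. PLS models with test `Q2 < 0.4` are dropped from
the tally but still count among the 160, so the threshold does not move
with exclusions. `permutation_cmv()` re-runs the whole machinery on a
uniformly permuted response; one permutation is the default (matching the
published test), but a single permutation of balanced 24/24 labels carries
~7 percentage points of hypergeometric overlap noise, so 20 or more
permutations are recommended — and used in the acceptance script — for a
calibrated null.

## Bayesian estimation of line differences

Each consensus metabolite's alr-transformed abundance is modelled as
`y = Xb + e`, fixed effects intercept + line + sex (coded +-1/2, so the
line coefficient *is* the H-minus-L difference), `e ~ N(0, I sigma2)`,
flat priors on `b` and `sigma2`. The Gibbs sampler alternates
`b | sigma2 ~ N(b_hat, sigma2 (X'X)^-1)` and
`sigma2 | b ~ RSS / chisq(n - 2)`; the `n - 2` degrees of freedom are what
a genuinely flat variance prior implies (a `chisq(n)` draw would correspond
to the Jeffreys prior), and the test suite checks the sampler against the
closed-form flat-prior marginal, a t distribution with `n - p - 2` degrees
of freedom. Defaults are 50,000 draws with 10,000 burn-in; the analysis
scripts use 20,000/4,000, which already give ~3-digit stability for this
3-parameter conjugate-form model, and a Geweke z beyond 4 triggers a
warning. Summaries per metabolite: posterior median `D_H-L`, the shortest
95% interval (HPD95%), `P0` (posterior probability the difference shares
the sign of its median, in [0.5, 1]), and `D_H-L` divided by the trait's
pooled across-line SD — the "SD units" in which effect sizes are reported.
Pooled SD is the package's reading of "units of their standard deviation";
a marginal SD would mix the line effect into the denominator.

One subtlety: alr traits are log-ratios to a block reference, so a planted
log-scale effect reappears in the transformed trait shifted by the
reference's own (usually small) effect and scaled by the ratio's SD.
Recovered standardized differences therefore correlate strongly with the
planted ones without matching one-to-one; the stage-5 analysis script
reports that correlation rather than pretending identity.

## Numerical choices and degenerate inputs

* NIPALS stops early when the residual covariance `X'y` is numerically
  zero; requesting more components than the data support silently yields
  the supported number.
* Zero-variance responses, rank-deficient designs, all-zero metabolite
  columns, nonpositive entries reaching the log step, and mismatched
  sample sets across blocks raise immediate errors naming the problem.
* Q2 with a test fold sitting exactly at the training mean would divide by
  zero and errors instead.
* HPD intervals use the sorted-window scan, which is exact for unimodal
  samples; with ~2,000 retained draws the interval runs ~1% short, a bias
  that vanishes with chain length.
* Stratified folds deal shuffled members round-robin with a rotating
  offset, so fold sizes differ by at most one even when strata sizes do
  not divide the fold count.

## Problem sizes used in tests and scripts

The test suite runs reduced designs chosen for statistical sharpness per
unit time: CMV invariants on 20–30-metabolite matrices with 2–5
iterations; the fold-geometry and 160-model checks at the full 20 x 8
configuration on a 20-metabolite panel; the permutation null on a ~200
metabolite panel at 5 iterations; Bayesian coverage on 300 replicates per
planted effect at 3,000 retained draws. The analysis scripts run the full
920-metabolite, 160-model design. These sizes are the package's own
verification choices; the pipeline accepts any panel of the same shape.

## Known limitations

* The generator's MCAR zeros cannot tell whether the filter/imputation
  chain is robust to intensity-dependent missingness.
* Consensus behaviour at the >80% threshold depends on the Q2 exclusion
  rate; on very narrow panels (a few dozen metabolites) IMF prediction is
  poor enough that exclusions can make the regression threshold
  unattainable — visible in the test suite, which uses realistic widths
  for end-to-end checks.
* The permutation null defaults to a single permutation for fidelity to
  the published workflow; treat single-permutation results as qualitative.
* P0 and HPD are Monte-Carlo quantities; at the analysis scripts' chain
  lengths they are stable to ~0.001 and ~1% width respectively.
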