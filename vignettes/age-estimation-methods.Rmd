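---
title: "Age-at-death estimation with deep randomized networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-at-death estimation with deep randomized networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelage)
```

This vignette is the package's own account of its science: the models
implemented, the assumptions they make, the defaults and why, and what
the synthetic-data tests do and do not establish about real skeletal
material.

## 1. The estimation problem

Adult age-at-death estimation from skeletal remains is treated here as
function approximation: a mapping from a vector of ordinal macroscopic
trait scores to an age in years, with an honest statement of the
uncertainty around each estimate. Traits are morphological variables
with two or three expression stages (scored 0-based), covering both
developmental markers (epiphyseal fusion of the clavicle, S1–S2 fusion,
symphyseal billowing) and degenerative ones (vertebral osteophytes,
joint margin lipping, entheseal changes, auricular surface texture).
The working assumption is monotonicity: the expected stage of an
informative trait does not decrease with age. No single trait is
informative over the whole adult span — developmental traits saturate by
the 30s, degenerative ones only begin to discriminate later — which is
why the model consumes the whole panel at once.

## 2. Preprocessing

**Laterality.** Bilateral traits are scored on both sides but carry
nearly redundant information. `collapse_laterality()` keeps the left
side as the primary source and substitutes the right only where the
left is missing; both missing leaves the trait missing. This is a
domain heuristic, not a model: it removes the redundancy before any
statistics are computed (a 99-column side-tagged table with 35
bilateral traits collapses to 64 unique traits).

**Imputation.** `impute_nn1_jaccard()` fills all missing values of an
individual from the single most similar donor, with similarity defined
as Jaccard overlap of one-hot indicator bits restricted to traits
observed in both individuals. Copying a whole donor profile (rather
than imputing cell-by-cell from different donors or a parametric model)
preserves the joint structure of the ordinal panel; single
nearest-neighbour donation distorts the data distribution least even
when fancier methods have lower per-cell error. Ties in similarity
break to the lowest individual index so the procedure is deterministic.
Two open conventions had to be fixed: similarity is computed on
indicator bits (for 2- and 3-stage traits this equals agreement
counting: J = a/(a + 2d)); and the donor must observe *all* traits the
recipient is missing, otherwise an error is raised rather than mixing
donors. In the evaluation harness imputation is leakage-safe by
default: test rows take donors from the training partition only; a
`global_impute` switch reproduces the impute-once-up-front order of
operations.

**Concordance.** `kendalls_w()` quantifies intra-observer scoring
reproducibility between two sessions as a per-trait tie-corrected
Kendall W (m = 2 raters), with the chi-square approximation
`m(n−1)W` on `n−1` degrees of freedom. W is undefined (reported `NA`)
for traits constant in both sessions.

## 3. The deep randomized network

### 3.1 Architecture from the sample size

Rather than searching architectures, the network is sized from the
training-set size `n` alone: with `k = log2 n`, the total number of
randomized units is `S = 2^⌊log2(8·(2^k/k))⌋` and the depth is
`L = 2^⌊log2 k⌋`, in a rectangular topology of `L` layers of `S/L`
units. For `n = 500` this gives 8 layers of 32 units, 256 units total.
`S` is read as the *total* unit count (width = S/L per layer); this is
the only reading consistent with the instantiation above.

### 3.2 Random features with skip connections

Hidden weights and biases are drawn i.i.d. standard Gaussian (a uniform
option exists) and are never trained. Layer 1 sees the standardized
traits; every deeper layer sees the previous layer's activations
concatenated with the raw standardized input (skip connections — the
difference between an RVFL network and an ELM; omitting the direct
links measurably hurts performance, so they are always on). The
activation is the ReLU. Because the ridge penalty is not scale
invariant, pre-activations and activations are standardized per unit
with training statistics that are frozen into the model and reused at
prediction time; both standardizations are applied by default and each
is toggleable.

### 3.3 Analytic output layers

For each depth `j` the design `D(j) = [H(1) … H(j) X]` feeds an
independent ridge output layer with penalty `I/C` (larger `C` = weaker
regularization). Writing the thin SVD of the centered design
`D = UΣVᵀ`, the coefficients are `β = V diag(σ/(σ² + 1/C)) Uᵀy`, the
fitted values `U diag(φ) Uᵀy` with shrinkage factors
`φ_i = σ_i²/(σ_i² + 1/C)`, and the leverages
`h_ii = Σ_k φ_k U_ik²`. The exact leave-one-out residual is then
`(y_i − ŷ_i)/(1 − h_ii)` (the PRESS identity), so the leave-one-out
error for *every* grid value of `C` costs one SVD per depth and a few
vector products. `C` is selected per depth on the grid `2^x`,
`x ∈ {−6, −4, …, 12}`, by minimizing that error; per-depth selection is
the natural reading of the implicit-ensemble construction. The
intercept is handled by centering (excluded from the penalty), and the
trait matrix and target are standardized before solving.

The model's prediction averages the per-depth estimates — an implicit
ensemble along depth that stabilizes the randomized features at no
training cost. The model's cross-validated prediction for a training
individual is likewise the average of its per-depth leave-one-out
predictions, rescaled to years; these drive both the uncertainty model
and the surrogate explanations.

### 3.4 A degeneracy of analytic LOO, and its guard

One numerical fact shapes the implementation. When a centered design
has at least `n − 1` columns, its rows sum to zero, so every left-out
row is an exact linear combination of the remaining rows; a weakly
penalized ridge then reproduces the left-out target through that
identity and the analytic leave-one-out error collapses to zero *no
matter how badly the model generalizes*. The selection rule would then
always pick the weakest penalty at the deepest layers and the ensemble
inherits wild extrapolations. `drnn_fit()` therefore caps the effective
depth (and, in the extreme, the width) so the deepest design stays at
or below `n − 2` columns. At the intended operating scale the cap is
inactive (n = 500 → 400 training rows vs. a 320-column deepest design);
it binds only for small samples, where it reduces the ensemble depth
gracefully instead of silently overfitting.

## 4. The uncertainty model

Point estimates alone are not actionable in forensic practice. The
regression uncertainty model (RUM) regresses the absolute leave-one-out
residuals on the leave-one-out predictions — capturing the
heteroskedasticity of skeletal aging (mid-adult ages predict tighter
than the extremes) — and converts the predicted absolute residual to a
conditional standard deviation by the factor 1.2533, the SD-to-MAD
ratio of a Gaussian (√(π/2) to four decimals). The prediction interval
is the central `1 − α` mass of a Gaussian centred at the point estimate
with that SD, truncated below at the minimum training age: a skeletal
reference sample carries no information below its youngest individual,
while an upper truncation is deliberately not imposed by default (both
bounds are configurable). A 1-year floor on the predicted residual
prevents zero-width intervals.

The residual regressor itself is, by default, a depth-1 randomized
network on the single predictor with PRESS-tuned ridge — the same
machinery as the age model, reused; a `linear` engine is available when
auditability of the uncertainty model matters more than flexibility.

## 5. Feature analysis

Marginal screening uses Spearman's ρ (midranks, t approximation) and
the correlation ratio η² (between-stage over total sum of squares of
age). Because the panel is deliberately redundant, marginal statistics
overstate how many traits carry *independent* signal; CAR scores
correct for this by sphering: with `R` the trait correlation matrix and
`r_xy` the marginal correlations with standardized age,
`ω = R^{−1/2} r_xy` are the correlations of the *decorrelated* traits
with age, and `Σω²` equals the multiple R² of the full least-squares
fit. Traits are ranked by squared CAR. When `R` is ill-conditioned
(always when `n ≤ p`), it is shrunk toward the identity with the
analytic intensity computed from the variance of the empirical
correlations, and the intensity is reported. Traits enter as their
integer stage codes, standardized — the one-hot expansion is used only
for imputation similarity, where it is the natural metric; stage codes
are the natural regression parameterization for monotone ordinal
traits. Significance is two-sided at 0.05 by default, unadjusted for
multiplicity (the flags are descriptive, not confirmatory).

## 6. The evaluation harness

`mccv()` runs Monte Carlo cross-validation: `B` independent random
disjoint 80/20 train/test splits (400/100 at n = 500), each fitting the
full pipeline (imputation, DRNN, RUM) on the training partition and
scoring the test partition on four axes:

* **accuracy** — mean absolute error (years);
* **bias** — the slope of residuals `y − ŷ` regressed on `y` (0 for an
  unbiased model, 1 for the mean predictor; positive slopes are the
  classic over-young/under-old pathology);
* **validity** — empirical coverage `P(α)` of the prediction intervals;
* **efficiency** — quantiles (0.5, 0.025, 0.975) of the interval
  widths, with linear interpolation between order statistics.

Aggregates are the median and the 2.5%/97.5% quantiles across
iterations. Named trait presets resolve through the schema's anatomical
blocks (each block; `standard` = clavicle + first rib + pubic symphysis
+ sacroiliac + acetabulum, 16 traits; `degenerative` = axial +
appendicular, 39 traits; `all`), and a `trait_fraction` option draws a
fresh random subset of traits each iteration — the
available-traits experiment that mimics fragmentary forensic remains.

Problem sizes used by the shipped tests and the acceptance script were
chosen as honest desk-scale instantiations of the design: the full
MCCV check runs B = 50 iterations at n = 500 (the reference-collection
scale); the trait-fraction monotonicity check uses B = 10 at n = 300.
B = 1000 remains available through the same interface.

## 7. The synthetic generator

Real identified-collection data cannot be redistributed, so the package
ships a generator (`simulate_skeletal()`) that emulates the *structure*
of such a dataset — not any particular collection's values:

* ages uniform on 19–101 years (uniformity is the standard guard
  against age mimicry, where the reference age distribution leaks into
  the estimates);
* a latent senescence score `s_i = z_i + ε_i`, with `z_i` the age
  standardized to unit variance and `ε_i ~ N(0, 0.3²)` a frailty term —
  individual variation in senescence pace at roughly a third of the
  population age spread, the reason no skeletal method can be exact;
* each trait generated by an ordered probit: latent `λ_k s_i + N(0,1)`
  cut at equal-mass quantiles of its marginal distribution (cut-points
  are part of the returned truth record). Ordered probit was chosen
  over a proportional-odds logit because it composes in closed form
  with the Gaussian frailty; tests should not over-interpret the
  family;
* block-level link strengths chosen once to mirror the qualitative
  ordering reported for real panels — sutures weak (λ = 0.6), axial
  vertebral traits strong (λ = 2.2), appendicular mixed (0.9/1.8),
  clavicle/first rib/acetabulum strong, pubic symphysis and sacroiliac
  intermediate;
* bilateral traits copy the left stage to the right, flipping to an
  adjacent stage with probability 0.05 (mild fluctuating asymmetry);
* 9.5% of the raw side-tagged cells are masked missing completely at
  random. After laterality collapse the unique-trait matrix retains
  ~5–6% missingness, since a bilateral trait goes missing only when
  both sides do.

What the generator does *not* emulate: cohort effects and secular
trends, non-MCAR (taphonomy-driven) missingness that correlates with
element survival, inter-observer error, population differences, and
the idiosyncratic stage distributions of real scoring systems. Passing
tests on this generator therefore demonstrates that the machinery is
correct and well calibrated *under its own assumptions* — it does not
validate the method on real skeletal material, which requires real
reference collections.

## 8. Explanations

The fitted network is, mechanically, a regularized linear model on
random nonlinear features plus the raw input, which invites a linear
reading. `fit_surrogate()` regresses the network's cross-validated
predictions (not the fitted values — the surrogate should explain what
the model does out of sample) on the sphered, standardized traits by
OLS. Sphering makes the coefficients additive attributions in years per
decorrelated-trait unit; because the sphered predictors are centered,
the intercept is exactly the mean network estimate. `explain_case()`
multiplies a case's sphered values by the coefficients: baseline + Σ
contributions reproduces the surrogate approximation to machine
precision, and the surrogate's residual SD (reported with every
explanation) bounds how far that approximation typically is from the
network estimate. On the synthetic panel the surrogate is nearly
exhaustive (R² ≈ 0.99), which is expected: the generator's links are
monotone and the network output is dominated by its skip connections.

## 9. Numerical choices and degenerate inputs

* Singular values below `max(σ) · 1e−12` are dropped from the SVD.
* Constant columns get unit scale in standardization (they contribute
  nothing after centering).
* `h_ii ≥ 1` raises an error (interpolation — cannot happen on a capped
  design with a finite penalty, but guards hand-built designs).
* Constant targets, constant raters, empty grids, inverted truncation
  bounds, and recipients with no observed traits raise errors rather
  than propagate NaNs; an all-zero residual vector degrades the RUM to
  the floor SD with a warning.
* A point estimate far outside the truncation bounds (possible under
  extreme extrapolation at small n) yields the widest valid interval
  with a warning rather than an inverted one.
* Quantiles everywhere use linear interpolation (`type = 7`).
* All randomness flows from explicit integer seeds; fits, the
  generator, and the MCCV harness are bit-reproducible given the seed.

## 10. Known limitations

* Calibration of the intervals rests on the Gaussian residual
  assumption; heavy-tailed residual structure would need a different
  scale factor than √(π/2).
* The bias slope of the DRNN is small but positive (~0.1 on synthetic
  data): regression-to-the-mean compression at the age extremes is
  reduced by the multifactorial panel, not eliminated.
* CAR scores are computed on ordinal stage codes; a one-hot CAR variant
  could rank non-monotone stage effects differently.
* The imputation model assumes MCAR missingness; taphonomic missingness
  in real material is element-correlated.
* The surrogate explains the network globally; strongly local behavior
  (interactions firing only in a sub-population) would lower its R² and
  widen the reported residual SD — the signal to distrust the additive
  reading.
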