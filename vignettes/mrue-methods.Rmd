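---
title: "Methods behind mrue: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind mrue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrue)
```

## The multiplicative efficiency model

For one resource *i*, annual aboveground production obeys the identity
`ANPP = R_avail,i * eps_i * RUE_i`, with `eps_i` the absorbed fraction of the
available resource and `RUE_i` the production per unit absorbed. The package
extends this to water, light and nitrogen jointly through geometric-mean
composites: `mRUE = (WUE*LUE*NUE)^(1/3)`, `eps = (eps_L*eps_W*eps_N)^(1/3)`
and a composite available resource `(PAR*Ms*Ns)^(1/3)`. The geometric mean is
the unique aggregation for which the per-resource identities multiply into
`ANPP = R_avail * eps * mRUE` exactly; `compute_efficiency_set()` followed by
`reconstruct_anpp()` is tested to reproduce the input production to a
relative error below 1e-10 on arbitrary valid records, and the geometric
means themselves are evaluated in log space for numerical stability.

Assumptions and conventions worth making explicit:

* **Units.** All resources are carried in g m⁻² yr⁻¹. Light enters as
  mass-equivalent dry matter: energy (MJ m⁻²) divided by the plant caloric
  value, default 19.38 kJ g⁻¹ (a semi-arid grassland value; configurable
  where the input declares energy units). `caloric_convert()` is the single
  conversion point.
* **Ranges.** Absorption rates are constrained to (0, 1]: absorbed amounts
  may not exceed availability, and violations are an ingestion error (or are
  dropped with a row-numbered warning in non-strict mode; nothing is ever
  clamped). Use efficiencies are *not* constrained to 1 — grassland NUE is
  typically in the tens, since uptake is a small mass flux relative to the
  dry matter it supports.
* **Soil nitrogen.** The available-nitrogen pool may be measured either as
  mineral N or as a total-N substitute; the record schema is agnostic, and
  the absorption-rate interpretation simply follows the measurement used.

## Non-recursive path analysis

The structural model is observed-variable path analysis (no latent
measurement models): endogenous variables `y = By + Gx + e` with exogenous
covariance `Phi` and error covariance `Psi`. The model-implied covariance is
assembled from `(I-B)^{-1}` in the standard way, and `fit_ml()` minimises the
maximum-likelihood discrepancy
`F = ln|Sigma| + tr(S Sigma^{-1}) - ln|S| - p`.

Numerical choices:

* **Optimizer.** BFGS on the free parameters, with error variances
  log-parameterised (positivity by construction) and a hard penalty on
  feedback loops with spectral radius >= 1 and on non-positive-definite
  implied covariances. Five starts are used by default: one from
  per-equation least squares on the sample moments (which is already near
  the optimum for the recursive part of the model) and four jittered
  replicas under a fixed internal seed, guarding against local minima that
  feedback loops can create. Non-convergence is flagged on the result, never
  silent; a model with more free parameters than sample moments is refused.
* **Standardization.** Published path coefficients are standardized, so by
  default the model is fitted to the correlation matrix and coefficients are
  read as standardized betas directly. Fitting the covariance instead is a
  flag away.
* **Fit indices.** GFI and AGFI from the trace forms, NFI against the
  independence (diagonal) baseline, RMSEA from `(chi2 - df)/(df (n-1))`
  floored at zero, and the chi-square upper-tail p-value. For a saturated
  model RMSEA, AGFI and the p-value are undefined and returned as `NA`
  rather than a numeric stand-in.
* **Stability index.** Reported as the maximum over elementary directed
  cycles of the magnitude of the product of coefficients around the cycle —
  the convention under which the reciprocal pair (0.23, -0.11) gives 0.025.
  The spectral-radius alternative is available under `method = "eigen"`; it
  yields 0.159 for that same loop (the square root of the two-edge product),
  so the two conventions must not be mixed when comparing to published
  values. Both declare the model stable below 1.

## Effect decomposition

`decompose_effects()` offers two totals. The default `"path-sum"` mode sums
coefficient products over *simple* directed paths, which is how published
effect tables are computed by hand (e.g. an indirect transpiration effect of
`0.32 x 0.66 = 0.21` through nitrogen uptake); it deliberately ignores
amplification around feedback loops. The `"series-limit"` mode takes the
closed forms `(I-B)^{-1} - I` and `(I-B)^{-1} G` — the limit of summing walks
of all lengths — and differs from path-sum only in cyclic models, by the loop
factor `1/(1 - b12 b21)`, about 0.975 for the loop above (a 2.5% deflation,
because the loop product is negative). On acyclic models the two agree to
1e-12, which the tests exploit as an equivalence oracle. The `exclude`
argument restricts path-sum intermediaries; published tables for models with
two joint composite outcomes conventionally report indirect effects through
the resource variables only, not through the other composite, and `exclude`
reproduces exactly that arithmetic. `total = direct + indirect` is an
invariant in every mode. `aggregate_effects()` sums chosen components over a
source group, and `path_effect()` exposes the product along one explicit
chain.

## LMG relative importance

`lmg()` distributes a regression R² over predictors by averaging sequential
R² increments over all orderings, computed exactly by enumerating the `2^p`
subset models with the combinatorial weights `s!(p-s-1)!/p!`. Enumeration is
capped at p = 12 with a clear error beyond — efficiency analyses use two or
three predictors, so exactness is cheap and sampling orderings would only add
noise. Subset R² values come from the correlation structure
(`r' Rxx^{-1} r`), and a brute-force average over explicit orderings (with
`lm()` refits) serves as the independent oracle in the tests, agreeing to
1e-10. Responses and predictors are used as supplied: the pipeline
log-transforms upstream, because the composites are exact *linear* functions
of their components only on the log scale (where the decomposition of
log mRUE on the three log efficiencies has R² = 1 by construction). Shares
are scale-sensitive, so raw-scale and log-scale percentages differ and the
choice must be reported alongside any percentage.

## Spurious correlation of ratio composites

Composites share measured variables with the quantities they are correlated
against, so some correlation appears even under full independence.
`spurious_r2()` quantifies it: per replicate, draw the seven variables as
independent normals at their specified means and SDs, form the composite
(`eps` as the geometric mean of the three absorption ratios; `mrue` as
production over the geometric mean of the three absorbed amounts), and take
the squared Pearson correlation between the log common variable and the log
composite; the reported central value is the *mean of the per-replicate
sample R²*, which includes the finite-sample bias of order `1/n` — that is
the quantity a practitioner comparing against an observed R² at the same n
needs.

Design decisions, each of which was validated against the delta-method
oracle below:

* The specified means and SDs are treated as measurement-scale parameters of
  the drawn variables and the composites are computed directly from the
  draws. (The variables of the motivating study are log-scale accumulations,
  so their coefficients of variation are small.)
* Correlation is computed on log scale by default, matching a pipeline that
  log-transforms before analysis; the raw-scale option is retained, and at
  these CVs the two differ by well under 0.01 — a robustness check encoded
  in the oracle tolerance of the tests.
* Non-positive draws (possible at large SD multiples in the sensitivity
  scans) are rejection-resampled; the count is recorded, and a rejection
  rate above 10% is an error, because the normal model is then a poor
  description of a positive quantity.
* A degenerate replicate (constant composite or common variable) reports
  R² = 0 with a warning instead of NaN.

`analytic_spurious_r2()` is the independent oracle: at small CV,
`sd(log X) ≈ sd(X)/mean(X)`, the log composite is a signed linear
combination of component logs, so the population
`rho² = (c_common cv_common)² / sum((c_i cv_i)²)`, plus the `(1-rho²)²/n`
finite-sample term. The Monte Carlo mean is required (and tested) to sit
within two Monte Carlo standard errors of this approximation for every
shared-variable pair, and a variable absent from the composite must
reproduce the independence baseline `1/(n-1)`.

The sensitivity scans use a generic two-variable setup (common variable A,
independent variable B, mean 20, initial SD(A) = 1, n = 200, 1000 replicates
per scenario): scaling both SDs together leaves the spurious correlation
unchanged (scale invariance); growing SD(B) relative to SD(A) shrinks it as
`1/(1 + k²)`; growing the sample size leaves the mean unchanged while
narrowing the replicate distribution. `compare_groups()` summarises scenario
differences with all-pairs Welch t-tests under Holm correction and a
compact-letter display; the source analyses never name their test, so Welch
+ Holm is this package's documented, swappable choice.

## The synthetic experiment generator

`generate_experiment()` emulates a randomized-block rainfall-manipulation
experiment: 7 precipitation levels (-60% to +60% of a 380 mm ambient), 6
blocks, 3 years, 126 records. Variables are generated on the log scale —
additive Gaussian noise there is multiplicative on the measurement scale,
appropriate for strictly positive accumulations and matching an analysis
pipeline that log-transforms for variance homogeneity. Each variable is
`exp(log_mean + log_sd * z)` with unit-variance scores `z` linked by
standardized structural coefficients: the precipitation driver
(`log(1 + delta)`, scaled by its design SD but deliberately *not* centred,
so control plots sit exactly at the baseline log means) raises soil water
and transpiration; transpiration carries nitrogen uptake (mass flow);
soil water and nitrogen uptake raise absorbed light; and production loads
log-linearly on transpiration, absorbed light, nitrogen uptake and — with a
negative sign — soil water, which induces the declining-marginal-returns
signature: water availability raises the composite absorption rate while
suppressing the composite use efficiency. Block and year effects are shared
additive intercepts on the water-driven scores.

Default choices and their reasoning:

* Baseline log means and SDs are the observed log-scale magnitudes of the
  motivating study's variables (e.g. production `exp(5.3) ≈ 200` g m⁻²
  yr⁻¹, soil water `exp(15) ≈ 3.3e6` g m⁻² yr⁻¹).
* Structural coefficients among resources default to the fitted path values
  (0.32 transpiration → uptake; 0.58 and 0.35 into absorbed light), and the
  tests require a path-model fit on ten pooled generations (n = 1260) to
  recover each within ±0.05.
* The precipitation sensitivities (0.85 for soil water, 0.75 for
  transpiration, on the standardized score scale) reflect that an imposed
  rainfall treatment dominates accumulated soil water and strongly but less
  completely controls transpiration. The mapping from precipitation to
  accumulated soil water is a linear-in-log placeholder: the real
  field relationship was not available, and this is the main respect in
  which the generator is *not* a claim about the physical system.
* Physical invariants hold for every returned row: the mean structure must
  imply absorption rates below 1 (else generation refuses with the
  offending variable named), and the rare far-tail row violating
  absorbed <= available (about half a percent of tables per row at
  defaults, only for light) is resampled.

`calibrate_to_control()` retargets the baselines so a noiseless control
record reproduces given control-plot WUE/LUE/NUE/ANPP exactly, preserving
the log-offsets that define the baseline absorption rates.

One property deserves honesty: the generator's *expected* composite
absorption rate rises strictly across the seven levels, but at the default
n = 126 the level means carry standard errors comparable to the treatment
gap between the two wettest levels (the log driver compresses there), so a
single realization reorders adjacent wet levels in a substantial fraction of
seeds. The monotonicity test therefore evaluates the systematic gradient at
high replication (600 blocks, n = 12 600), where the standard error is far
below the smallest gap; scatter at n = 126 is a faithful feature of the
emulated design, not a defect. More generally, passing tests on generated
data show that the *algorithms* behave as specified under the stated
structural assumptions — multiplicative noise, log-linear links, shared
block/year intercepts — and not that real grassland data satisfy those
assumptions; the generator has no spatial autocorrelation, no rainfall time
series, no sub-annual accumulation dynamics, and independent incident light
and soil nitrogen pools.

## Problem sizes and tolerances

The test suite and the reproduction script size their simulations to be
decisive yet quick: 1000 Monte Carlo replicates of n = 126 per
spurious-correlation pair (Monte Carlo standard errors near 0.002, an order
of magnitude below the comparison tolerances), 1000 random records for the
reconstruction identity (tolerance 1e-10 relative), path-model recovery at
n = 5000–10 000 simulated observations (sampling error well inside the
±0.05/±0.06 bands), decomposition equivalences at 1e-12, and the LMG oracle
at 1e-10. Exact published arithmetic (effect sums, the stability index, the
chi-square p-value) is checked at the printed rounding. The deliberately
non-reproduced quantities are those that depend on the unavailable field
data: observed efficiency tables, fitted R² values and the empirical
relative-importance percentages; for these the package tests internal
consistency instead.
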