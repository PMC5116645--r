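# mrue

Multiple resource use efficiency (mRUE) modelling for ecosystem production,
with the statistical machinery needed to analyse it honestly: non-recursive
path analysis, effect decomposition, LMG relative importance, and Monte Carlo
quantification of the spurious correlation that ratio-derived indices carry by
construction.

## The problem and the model

Ecosystem production is often summarised through single-resource use
efficiencies — water (WUE = ANPP/Tr), light (LUE = ANPP/aPAR) and nitrogen
(NUE = ANPP/N_uptake) — yet resources change together, and the efficiency of
one resource is constrained by the others. For each resource *i* the annual
aboveground net primary production satisfies the identity

    ANPP = R_avail,i · ε_i · RUE_i

where `ε_i = absorbed/available` is the absorption rate (aPAR/PAR, Tr/Ms,
N_uptake/Ns) and `RUE_i = ANPP/absorbed`. Combining resources by geometric
means gives the multiplicative composite form

    ANPP = R̄_avail · ε · mRUE,
    mRUE = (WUE·LUE·NUE)^(1/3),  ε = (ε_L·ε_W·ε_N)^(1/3),
    R̄_avail = (PAR·Ms·Ns)^(1/3)

which holds *exactly* for every record. Light is carried in mass-equivalent
units (g m⁻²) after division by the plant caloric value (default
19.38 kJ g⁻¹) so all resources share units.

Because ε and mRUE are built from the same measured variables they correlate
with those variables even when everything is statistically independent. The
package quantifies this spurious determination coefficient by Monte Carlo
(with a delta-method analytic oracle), fits the non-recursive path model
linking water, light, nitrogen, ε and mRUE (including the ε ⇄ mRUE feedback
loop, its stability index, and fit indices GFI/AGFI/NFI/RMSEA), decomposes
direct/indirect/total standardized effects, and attributes composite variance
to components via the LMG decomposition. A synthetic randomized-block
precipitation-gradient experiment generator (7 levels × 6 blocks × 3 years,
n = 126) makes the full pipeline testable without field data.

## Worked example

```r
library(mrue)

# a synthetic precipitation-gradient experiment: 7 levels x 6 blocks x 3 years
tab <- generate_experiment(experiment_design(seed = 42), generator_params())
eff <- compute_efficiency_set(tab)
head(eff[, c("anpp", "wue", "lue", "nue", "mrue", "eps")], 3)
#>    anpp     wue      lue   nue    mrue    eps
#> 1 159.1 0.00062 0.007779 47.12 0.06103 0.1467
#> 2 160.9 0.00055 0.006406 48.65 0.05554 0.1424
#> 3 112.6 0.00029 0.005648 37.26 0.03935 0.1465

# the reconstruction identity: available x absorption x efficiency = production
all.equal(reconstruct_anpp(eff), tab$anpp)   # TRUE, to machine precision

# how much of mRUE's variation does each component efficiency carry?
lmg(log(as.matrix(eff[, c("wue", "lue", "nue")])), log(eff$mrue))
#> LMG decomposition (total R2 = 1.0000)
#>  predictor lmg_share   pct
#>        wue    0.3369 33.69
#>        lue    0.3324 33.24
#>        nue    0.3307 33.07

# spurious correlation between nitrogen uptake and the composite absorption
# rate when all seven variables are drawn independently (n = 126, 1000 reps)
spurious_r2(mc_config(n = 126, reps = 1000, seed = 42), "N_uptake", "eps")
#> Spurious R2: N_uptake vs eps (n = 126, reps = 1000)
#>   mean = 0.3206 (MC SE 0.00223)
#>   quantiles: 10% 0.2270 25% 0.2724 50% 0.3199 75% 0.3690 90% 0.4126

# stability of the eps <-> mRUE feedback loop (reciprocal coefficients
# 0.23 and -0.11): far below the divergence threshold of 1
B <- matrix(c(0, 0.23, -0.11, 0), 2, 2,
            dimnames = list(c("eps", "mRUE"), c("eps", "mRUE")))
signif(stability_index(B), 2)
#> [1] 0.025
```

An `lmg` total R² of 1 is expected here: log mRUE is an exact linear function
of the three log component efficiencies, so the decomposition splits all of
its variance. The spurious R² of ≈ 0.32 means that roughly a third of an
observed N_uptake–ε correlation at this sample size and these dispersions
would appear even for independent data — bivariate correlations with
composite indices must be read net of this baseline.

The same functionality is scriptable through a thin CLI
(`inst/cli/mrue.R`): subcommands `generate`, `compute`, `fit`, `decompose`,
`relimp`, `spurious`, `scan`, `pipeline`.

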