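# richtitr

Richards-function modelling of serum antibody titration.

## What problem this solves

Serum antibody titers are usually reported as end-point or mid-point
dilutions — numbers defined relative to an arbitrary signal threshold, hard
to compare across assays, antigens and platforms. Under mass-independent
(microspot) assay conditions, the *shape* of the titration curve carries
thermodynamic information, and a dual titration — serially diluting both the
immobilized antigen and the serum — separates the enthalpic and entropic
contributions to binding. `richtitr` is for assay developers and
immunoassay statisticians who want to fit these curves and surfaces and
report a threshold-free, thermodynamically meaningful titer.

## The model

The titration curve is the Richards (generalized logistic) function in the
ν-parametrization,

    R(x) = A (1 + ν e^{−k(x − x_i)})^{−1/ν},    A, ν, k > 0,

with ν = 1 the logistic curve and ν → 0 the Gompertz limit. A dual
titration surface is the separable product of one Richards factor in
x = ln[Ag] and one in the log serum dilution y, fitted on the ln FI scale
in the inflection-normalized convention:

    ln Rn(x, y) = ln Cn
                + (1/ν₁) ln[(1+ν₁)/(1 + ν₁ e^{−k(x − x_i)})]
                + (1/ν₂) ln[(1+ν₂)/(1 + ν₂ e^{−k₂(y − y_i)})],

so that the fitted log amplitude ln Cn is the surface value at the pair of
inflection points. Estimation is by Levenberg–Marquardt nonlinear least
squares with data-driven starting values (`fit_nls()`), or by Bayesian MCMC
with weakly informative priors (`fit_bayes()`); both carry honest
convergence flags.

The fitted asymmetries are then read thermodynamically:

    ln ν_Ag = ln(K_D′/K_D) = ΔΔH/RT        (antigen axis)
    ln ν_Ab = ln([Ab]_s/K_D) = ΔΔS/R       (serum axis)

ν_Ab is the **thermodynamic titer** [Ab]_s/K_D: at value 1 the antigen is
half saturated, and the saturation at titer t is t/(1+t). See the methods
vignette (`vignettes/richards-titration.Rmd`) for assumptions, priors,
sampler details and limitations.

## Worked example

Simulate a dual titration from the built-in reference parameter row
(ln Cn = 9.75, ν₁ = 0.08, x_i = −12.92, ν₂ = 0.99, y_i = −2.97, rate k = 1,
noise SD 0.05 on ln FI), refit it, and interpret the fit:

```r
library(richtitr)
d <- reference_fixture("nls", simulation_design(noise_sd_ln = 0.05, seed = 7))
fit <- fit_nls(d)
print(fit)
#> double_richards fit (nls)
#>     estimate std_error
#> lnC   9.7620    0.0187
#> nu1   0.0863    0.0097
#> x_i -12.9173    0.0159
#> nu2   0.9946    0.0242
#> y_i  -2.9726    0.0264
#> k     1.0065    0.0203
#>   residual RMSE (ln FI scale): 0.04575

assay_report(fit)
#> Thermodynamic summary
#>   nu_Ag = 0.0862907  ->  ddH/RT = -2.45003, K_D'/K_D = 0.0862907
#>   nu_Ab = 0.994556  ->  ddS/R = -0.0054587
#>   thermodynamic titer [Ab]_s/K_D = 0.994556; antigen occupancy = 0.4986
#>   axis mapping: nu_ag <- nu1 (antigen axis, x); nu_ab <- nu2 (serum axis, y)
```

All five generating parameters are recovered within about one standard
error; the residual RMSE (0.046) matches the injected noise scale (0.05).
The report says: apparent affinity is ~12× stronger than true affinity
(K_D′/K_D ≈ 0.086, an enthalpic excess of −2.45 RT), and the serum contains
almost exactly enough antibody to half-saturate the antigen (titer ≈ 0.99,
occupancy ≈ 0.499).

The same pipeline runs from the shell via the bundled CLI
(`inst/cli/richtitr`): `simulate`, `fit2d`, `fit1d`, `titer`, `report`.

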