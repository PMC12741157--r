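---
title: "Modelling serum antibody titration with Richards curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling serum antibody titration with Richards curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(richtitr)
```

## The problem

Serum antibody titers are conventionally reported as end-point or mid-point
dilutions — quantities defined relative to an arbitrary signal threshold, and
therefore hard to compare across assays, antigens and platforms. When a
binding assay is run under mass-independent (microspot) conditions, where the
measured signal tracks solution-phase concentration rather than total
analyte mass, the shape of the titration curve itself carries thermodynamic
information. `richtitr` implements that reading: it models titration curves
and dual antigen–antibody titration surfaces with the Richards (generalized
logistic) function, and interprets the fitted *asymmetry* parameters as
dimensionless thermodynamic quantities, including a thermodynamic titer
$[Ab]_s/K_D$ that does not depend on a reporting threshold.

## The model family

The working sigmoid is the Richards function in the $\nu$-parametrization

$$R(x) = A\,\bigl(1 + \nu e^{-k(x - x_i)}\bigr)^{-1/\nu},
\qquad A, \nu, k > 0,$$

where $x$ is a log concentration (natural logs throughout), $A$ the upper
limit, $k$ the rate, and $x_i$ the inflection abscissa. The asymmetry $\nu$
interpolates the family: $\nu = 1$ is the symmetric logistic curve, and
$\nu \to 0$ the Gompertz limit $A\exp(-e^{-k(x - x_i)})$. An equivalent
d-form with $d = \nu + 1$ is provided (`richards_value_d()`); the ratio of
the curve's value at its inflection to its upper limit is $d^{1/(1-d)}$,
which ranges over $(1/e, 1)$ for $d > 1$. The branch $0 < d < 1$ (curves
defined from a zero point on a half-line) is deliberately not modelled: every
fitted form in the package uses $\nu > 0$. An optional additive baseline
`c0` yields the 4PL/5PL immunoassay forms.

Fitting happens on the log scale,
$\ln R(x) = \ln A - \tfrac{1}{\nu}\ln(1 + \nu e^{-k(x-x_i)})$, a concave
function with upper asymptote $\ln A$ and left-asymptote slope $k/\nu$.

A dual titration varies both the immobilized antigen concentration ($x =
\ln[Ag]$) and the serum dilution ($y$, treated as log dilution; see the
units note below). The surface model is the separable product of one
Richards factor per axis. The package's default convention is the
inflection-normalized form, whose log surface is

$$\ln R_n(x,y) = \ln C_n
 + \frac{1}{\nu_1}\ln\frac{1+\nu_1}{1 + \nu_1 e^{-k(x - x_i)}}
 + \frac{1}{\nu_2}\ln\frac{1+\nu_2}{1 + \nu_2 e^{-k_2(y - y_i)}},$$

so that $\ln R_n(x_i, y_i) = \ln C_n$ exactly: the reported log amplitude is
the surface value at the pair of inflection points. The raw product
convention interconverts exactly via
$C_n = C (1+\nu_1)^{-1/\nu_1}(1+\nu_2)^{-1/\nu_2}$
(`normalize_amplitude()`). A single shared rate $k$ is the default — the
model's symmetry assumption for the two axes — with `free_k2 = TRUE`
available where the serum axis should carry its own rate.

## Fitting

**Least squares.** `fit_nls()` minimizes the sum of squared residuals of
observed $\ln FI$ against $\ln R_n$ with the Levenberg–Marquardt algorithm
(via `minpack.lm`). Positivity of $\nu_1$, $\nu_2$, $k$ is enforced by
fitting their logarithms. Records with $FI \le 0$ are dropped with a logged
count rather than floored: flooring would bias the left asymptote, which is
exactly where the asymmetry information lives.

Starting values matter for this model — flat and multimodal likelihood
regions are common — so initialization is data-driven and deterministic:
both shape parameters start at 1 (the logistic), the rate at 1, the log
amplitude at the 0.95 quantile of observed $\ln FI$, and each inflection at
the median of the distinct axis values when the axis design is
near-symmetric (absolute sample skewness at most 1), otherwise at the design
point nearest the half-rise of the axis-marginal mean $\ln FI$. The
skewness cut-off and quantile are package choices, fixed in code; a
derivative-based alternative (largest marginal first difference) is
available behind `rule = "derivative"` but is not the default.

Non-convergence is data, not an exception: results always carry an explicit
`converged` flag. The flag is false when the iteration budget is exhausted,
when the response is constant (no inflection identifiable), or when the
final Jacobian is numerically rank-deficient (condition number of $J^\top J$
above $10^{14}$) — the signature of designs that never leave one asymptote.
Standard errors come from a central-difference Jacobian computed at the
solution; the solver's own Gauss–Newton matrix is not trusted because it
degenerates at zero-residual optima. On the natural scale, standard errors
for the positivity-constrained parameters use the delta method.

**Bayesian estimation.** `fit_bayes()` samples the posterior under a
Gaussian observation model on $\ln FI$ with an estimated noise scale — the
likelihood that matches the least-squares objective — and weakly informative
priors: normal(start, 5) on $\ln C_n$, $x_i$, $y_i$ (centered on the
data-driven initialization), normal(0, 1.5) on $\log\nu_1$, $\log\nu_2$,
$\log k$, and half-normal(1) on the noise SD. The sampler is a mixture
Metropolis kernel built around a Laplace approximation at the posterior
mode: each iteration composes an independence Metropolis–Hastings update
(two-component multivariate-t proposal — a core matched to the estimated
posterior covariance plus a three-times-wider tail guard, so the proposal
dominates the posterior tails) with an adaptive random-walk update.
Warm-up runs in two stages, refining the proposal covariance from pooled
warm-up draws; the proposal is then frozen, so the kept chains are valid
Markov chain Monte Carlo. Defaults are 4 chains with 1000 warm-up and 2000
kept draws each. Convergence is declared only when the split-chain
$\widehat{R}$ is below 1.01 for every parameter; effective sample sizes
(via `coda`) and acceptance rates are reported alongside. A run that fails
the $\widehat{R}$ bar returns `converged = FALSE` with all diagnostics
retained — with this model that happens occasionally even on clean data,
when a chain makes an excursion into the heavy left tail of $\log\nu_1$.

A practical note: a *noiseless* dataset makes this posterior improper in the
noise scale (the likelihood grows without bound as $\sigma \to 0$ when the
model interpolates the data), so Bayesian runs are only meaningful on data
with noise; the generator's default noise level is used in all NLS–Bayes
comparison checks.

## Thermodynamic interpretation

For a converged dual fit, the two asymmetries map to dimensionless
thermodynamic quantities (`excess_energies()`, `assay_report()`):

$$\ln \nu_{Ag} = \ln(K_D'/K_D) = \Delta\Delta H/RT, \qquad
  \ln \nu_{Ab} = \ln([Ab]_s/K_D) = \Delta\Delta S/R,$$

with the antigen-axis asymmetry $\nu_1 \mapsto \nu_{Ag}$ and the serum-axis
asymmetry $\nu_2 \mapsto \nu_{Ab}$. Everything is reported relative to $RT$
and $R$; no temperature or unit system is imposed. Under mass-independent
conditions apparent affinity exceeds true affinity, so $\ln\nu_{Ag}$ is
expected to be negative; a fit with $\nu_{Ag} > 1$ triggers a warning, not
an error, while $\ln\nu_{Ab}$ may legitimately take either sign.

$\nu_{Ab}$ itself is the **thermodynamic titer** $[Ab]_s/K_D$: at value 1
the antigen is half saturated. The package reports the saturation at a
titer $t$ as $t/(1+t)$ — the single-site equilibrium isotherm under excess
antibody. This functional form is an interpretive choice: the anchor facts
(half saturation at 1, monotone above/below) do not pin down a curve, and
the hyperbolic isotherm is the natural one consistent with the
$[Ab]_s/K_D$ reading. A serum-only (one-axis) fit still yields the titer and
entropy-side quantities, but not the affinity-side ones — those require
antigen titration. With a calibrated `signal_model()` the amplitude converts
to a standard binding-site occupancy in concentration units.

## Synthetic data

No public dual-titration dataset accompanies the package, so
`simulate_dataset()` generates them: $FI = \exp(\ln R_n(x,y) +
\varepsilon)$ with $\varepsilon \sim N(0, \sigma_{\ln FI}^2)$ —
multiplicative log-normal noise, matching the log-scale fitting objective.
The default design is 9 antigen points equally spaced on $[-15, -11]$ (ln
molar, the concentration range typical of the assays this model targets), 8
serum-dilution points on $[-8, -1]$ bracketing a serum-axis inflection near
$-3$, 2 replicate spots per grid point, and $\sigma_{\ln FI} = 0.05$. The
built-in `reference_fixture()` rows are point estimates typical of an
anti-RBD IgG dual titration ($\ln C_n \approx 9.75$, $\nu_1 \approx 0.08$,
$x_i \approx -12.9$, $\nu_2 \approx 1$, $y_i \approx -3$), completed with
$k = 1$ — a package choice recorded in the fixture metadata, since the rate
is not part of the rows.

What the generator does *not* emulate: spot-level microarray artifacts
(spatial gradients, saturation clipping, scanner gain), heteroscedastic or
outlier-prone noise, and background offsets (an option adds a baseline for
4PL/5PL testing, but the default is zero). Passing the recovery tests
therefore demonstrates correctness of the estimation machinery under the
stated error model, not robustness to real microarray pathology.

## Numerical choices

* All Richards factors are evaluated in log space:
  $\nu e^{-k(x - x_i)}$ enters as $\mathrm{log1pexp}(\log\nu - k(x -
  x_i))$, so points far left of the inflection cannot overflow.
* For $\nu < 10^{-6}$ evaluation switches to the Gompertz limit form,
  avoiding catastrophic cancellation in $(\cdot)^{-1/\nu}$.
* The relative growth rate uses the algebraic simplification
  $k/(e^{k(x-x_i)} + \nu)$, stable on both tails.
* Ties in the half-rise initializer resolve to the first matching design
  point (`which.min`); degenerate designs (fewer than two distinct values on
  an axis) raise an error naming the axis.
* Every stochastic path (simulation, MCMC) takes an integer seed and is
  bit-reproducible given it; seeding is scoped so library RNG state is
  restored afterwards.

## Simulation sizes used by the test suite

The recovery properties are checked on 50 simulated datasets from the
reference parameters on the default 9×8×2 design at $\sigma_{\ln FI} =
0.05$; the Bayesian interval-coverage component of that study uses 2 chains
of 400 warm-up + 800 kept draws per dataset (the frozen independence
proposal makes short chains adequate for quantiles), while single-fixture
comparisons use the full defaults. These sizes are the package's own study
design choices.

## Known limitations

* Precision for a small antigen-axis asymmetry is intrinsically limited: at
  $\nu_1 \approx 0.08$ the surface is close to its Gompertz limit, where
  sensitivity to $\nu_1$ is weakest. Under the default design and noise the
  posterior SD of $\log\nu_1$ is about 0.11, so typical relative errors in
  $\hat\nu_1$ are 7–10% — an information limit of the design, not of the
  optimizer; enlarging the grid or replication is the remedy.
* The serum axis is treated as log *dilution*; where the fitted $y$ is
  truly $\ln[Ab]$ the titer interpretation is unchanged, but the metadata
  units note should be updated by the user.
* A single homoscedastic noise scale on $\ln FI$ is assumed; there is no
  outlier-robust loss and no model selection across sigmoid families.
* The Bayesian convergence bar ($\widehat{R} < 1.01$ on every parameter) is
  deliberately strict; expect occasional honest `converged = FALSE` flags
  on re-runs with other seeds.
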