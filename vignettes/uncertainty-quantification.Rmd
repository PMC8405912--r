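---
title: "Uncertainty quantification for field-grown plant-based manufacturing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty quantification for field-grown plant-based manufacturing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molfarmUQ)
```

## The problem

Techno-economic analysis (TEA) of ultra-large-scale plant molecular farming
— producing a recombinant protein in field-grown tobacco — is usually run
deterministically: one number per input, one forecast per output. In
reality the dominant inputs (field biomass yield, expression level,
recoveries and fluxes of the downstream train) are uncertain, and a fixed
facility cannot absorb arbitrary excursions: equipment has rated per-batch
capacities. This package propagates input uncertainty through a transparent
surrogate facility model by Monte Carlo simulation and provides the
downstream analyses a process engineer needs: scenario comparison,
normality assessment, univariate sensitivity, contribution to variance,
extremal-trial extraction, and optimization of a retrofit decision variable
under uncertainty.

## The temperature-driven growth model

Tobacco dry weight per plant is stepped forward by the explicit Euler rule

$$W_{i} = W_0 + W_0\,r(T)\,\Delta t, \qquad
  r(T) = \frac{A\,T\,e^{-k/T}}{1 + e^{S - H/T}},$$

with $T$ in kelvin. Below the optimum the rate follows the Arrhenius term
$A\,T\,e^{-k/T}$; the logistic denominator represents the loss of active
enzyme above the optimum (a Johnson/Eyring-type form). Both $k$ and $H$
divide the temperature and carry units of kelvin; $S$ is dimensionless.

Two conventions deserve emphasis:

* **$r(T)$ is treated as a relative growth rate (day$^{-1}$).** The update
  multiplies the rate by the current weight, so the trajectory compounds:
  at constant temperature, $n$ daily steps give $W_0 (1+r)^n$. Some
  presentations of this form label $r$ in g/(plant day); with the
  weight-multiplying update only the relative-rate reading is dimensionally
  coherent, and we document that choice prominently rather than hide it.
* **Constants reported in the literature for this form do not produce a
  usable relative rate.** The widely quoted set
  $(A, S, k, H) = (924.67,\ 5.434,\ 1992\ \mathrm{K},\ 22{,}780\ \mathrm{K})$
  gives $r(300\,\mathrm{K}) \approx 362\ \mathrm{day}^{-1}$ — about 2,500
  times too large to reproduce observed 27-day yields from a 0.5 g seedling
  — and is strictly increasing over 273–320 K, so it has no optimum in the
  physiological range. `growth_rate()` evaluates the formula exactly as
  written for any parameter set; the package's working default,
  `default_growth_params()` ($A = 0.55914$, $k = 1992$, $S = 27$,
  $H = 8250$), was calibrated once so that the optimum falls at 295.1 K
  (22 °C, inside the 18.5–28.5 °C optimal range reported for tobacco) and a
  0.5 g seedling reaches ≈21 g/plant in 27 days at a subtropical mean
  temperature.

### Fitting and what is identifiable

`fit_growth()` minimises the pooled RMSE across all chamber regimes
(every observation weighted equally, the convention when no weighting is
stated) with a deterministic Nelder–Mead + BFGS local search on
$(\log A, \log k, S, \log H)$, restarted until the RMSE improves by less
than $10^{-8}$ g/plant. The returned fit never has a higher RMSE than the
initial guess.

On noise-free synthetic data the fitter recovers the generating parameters
to solver tolerance (pooled RMSE $< 10^{-13}$ in the test suite). Under
observation noise, however, the **individual constants are structurally
non-identifiable**: $(A, k)$ trade off along the classical Arrhenius
compensation valley ($\log A - k/\bar T \approx$ const) and $(S, H)$ along
the inactivation-midpoint valley ($H/S \approx T_{opt}$), so the global
RMSE minimum of a noisy realisation can sit arbitrarily far from the truth
in parameter space while the fitted *rate curve* $r(T)$ matches the truth
to a few percent over the sampled range. Our diagnosis runs (five seeds per
noise level) found parameter errors of 86% and worse at a 0.5 g observation
noise, and still above 10% at 0.02 g, while the rate-curve error stayed
below 2.4% and 0.1% respectively. The test suite therefore asserts the
scientifically meaningful property — rate-curve recovery — and the exact
noise-free recovery; a parameter-wise 10% recovery claim under noise is not
attainable for this model family at realistic designs, and we say so rather
than weaken the check.

## From weather to the yield-input distribution

`monthly_dry_weight()` simulates exactly 27 days (648 hourly steps,
$\Delta t = 1/24$ day) from a constant 0.5 g/plant seedling, starting at
the first hour of each month. The 27 days count from seedling emergence;
with a 15-day germination period this is day 42 post seeding, but the
offset is bookkeeping only. Gaps up to 3 h in the hourly record are filled
by linear interpolation; longer gaps invalidate the month (skipped with a
warning by `build_yield_table()`). Three years give a 36-row monthly yield
table; `normalize_by_max()` rescales it to $(0, 1]$, and
`fit_scaled_beta()` fits a four-parameter beta distribution: the maximum is
anchored at 1 (the sample maximum is a poor estimator of a soft upper
bound, and the normalization makes 1 the natural anchor), the minimum set
just below the sample minimum, and the shapes estimated by maximum
likelihood. The base-case published parameter set
$(\alpha, \beta, \min, \max) = (2.57, 4.80, 0.63, 1)$ has closed-form mean

$$\mu = \min + (\max - \min)\frac{\alpha}{\alpha + \beta} = 0.759 \approx 0.76,$$

which is the base-case field-growth yield used throughout.

## Assumption registry and sampling

The nine uncertain inputs and their families (`default_registry()`):

| parameter | family | parameters | units |
|---|---|---|---|
| field_growth_yield | scaled beta | 2.57, 4.80 on [0.63, 1] | fraction |
| field_growth_time | triangular | 35 / 42 / 56 | day |
| expression_level | logistic | mean 1.50, scale 0.248 | g/kg FW |
| harvest_time | scaled beta | α = β = 2 on [8, 80] | h |
| pf_recovery | triangular | 0.88 / 0.95 / 0.99 | fraction |
| pf_flux | triangular | base 150 ± 25% | L/m²/h |
| tff_recovery | triangular | 0.90 / 0.95 / 0.99 | fraction |
| tff_flux | triangular | base 30 ± 25% | L/m²/h |
| cex_recovery | uniform | 0.90 ± 10% | fraction |

Printed anchors: the yield beta, the 1.50 g/kg expression mean, the ±25%
triangular UF/DF flux, the ±10% uniform CEX recovery, and harvest-time
bounds derived from a 1–10 km/h harvester speed (here over an 80 km total
swath distance, hence 8–80 h). The logistic scale is not published; the
default gives a 30% CV and is an explicit stand-in, as are the triangular
field-growth-time and plate-&-frame parameters and the harvest-time
shapes (α = β = 2) — all config-overridable. The expression level is
truncated at zero (the logistic has unbounded support); the truncation
removes ≈0.2% of the lower tail and shifts the mean by well under one
standard error at n = 20,000.

`normalize_to_mean()` re-centres a spec on a target mean; the logistic
family shifts its location (its mean), bounded families rescale
multiplicatively, and both policies are available explicitly.

`sample_trials()` uses inverse-transform sampling per column (so
truncation is exact and sampling is bit-reproducible given the seed and
registry order). Rank correlation, when requested, is induced by
Iman–Conover reordering: correlated normal scores with the Spearman-adjusted
Pearson matrix $2\sin(\pi\rho/6)$, each marginal reordered to the score
ranks. The marginals are untouched by construction, and at n = 20,000 the
achieved Spearman correlations sit well within ±0.05 of target. A
non-positive-definite target matrix is rejected with the offending
parameter names. No published correlation values exist for the base case,
so the default is independence.

## The surrogate facility model

The published analyses drove a commercial process simulator; this package
replaces it with a transparent surrogate whose structure is our own design
and whose every constant is a config field (`econ_config()`,
`equipment_spec()`):

* **Mass balance** (`run_batch()`): harvested biomass =
  100,000 kg FW/batch nominal × field-growth yield, extract volume at
  2 L/kg, product = biomass × expression level, multiplied through
  plate-&-frame, TFF and CEX recoveries.
* **Effective-value clamping** (`effective_clamp()`): the field stream
  volume and the CEX product mass are capped at rated capacities; excess
  yield/recovery is reduced to the effective value at the cap and flagged.
  The CEX capacity is 80 kg per m² of column cross-section, so the column
  diameter (base 1.6 m) is a genuine capacity lever; `oversize_factor`
  scales all capacities (and capex) for the facility-oversizing scenarios.
* **Purity**: odds-multiplicative enrichment per purification stage
  (3× clarification, 2× TFF, 10× CEX at base recovery) from a 5% crude
  purity, with a recovery–purity trade-off at the CEX step (higher
  recovery, broader peak cut, lower enrichment, exponent 0.5). No purity
  equation is published; this model is ours and is stated as such.
* **Duration** (`batch_duration()`): harvest time + fixed handling +
  filtration times volume/(flux × area) + fixed CEX and turnaround times.
* **Economics** (`economics()`): batches/yr = ⌊operating hours /
  duration⌋ over a 330-day year; COGS = itemized annual operating cost
  (including straight-line depreciation, so COGS is fully loaded) divided
  by annual product mass; IRR after tax is the root of the NPV of
  [−capex, 20 equal operating years] found by bracketed root-finding on
  (−0.99, 10) to a 10⁻¹² rate tolerance (every returned IRR satisfies
  |NPV| < 10⁻⁶·capex). Trials whose cash flows never change sign carry an
  undefined IRR: retained with `NA`, flagged, counted, excluded from IRR
  statistics.

Default prices (10, 20, 40 \$/g) and cost constants were chosen once to
make the base case plausible for an ultra-large facility (base IRR ≈ 12%
at 20 \$/g, COGS ≈ 17 \$/g, ≈7 t/yr, purity ≈ 0.76, CEX clamping on a few
percent of trials); they are placeholders, not estimates of any published
facility, and the headline checks do not depend on them.

## Trial loop and analyses

`run_simulation()` draws the trial-input matrix once per scenario from a
single seeded stream and reuses it across selling prices, so
process-related forecasts (throughput, purity) are price-invariant and can
be pooled: 20,000 trials × 3 prices = 60,000 pooled process rows, with
profitability forecasts (IRR, COGS) analysed per price
(`split_forecasts()`). Whether the published runs re-sampled per price is
not stated; pooling of process forecasts implies reuse, which is what we
implement and document.

Downstream, `compare_scenarios()` applies a Welch t-test (the unequal-
variance default is the safer reading of "two-sample t-test") and a
two-sample Kolmogorov–Smirnov test; no multiple-testing correction is
applied, matching the raw reported tests. `qq_points()` uses plotting
positions $(i-0.5)/n$. `tornado()` sweeps each input to its 10th/90th
percentile (unstated in the source; config-overridable) holding others at
base; `spider()` sweeps a 5–95% grid. `contribution_to_variance()` uses
the signed squared-Spearman convention
$\mathrm{share}_i = \mathrm{sign}(\rho_i)\,\rho_i^2 / \sum_j \rho_j^2$,
whose absolute shares sum to 100%. `extremal_trials()` returns the input
vectors of the minimum, nearest-to-mean and maximum trials with
lowest-index tie-breaking.

## Optimization under uncertainty

`optimize_decision()` replaces a proprietary metaheuristic with grid search
under common random numbers: every candidate CEX column diameter is
evaluated on literally the same sampled inputs, so a decision-independent
objective is constant across candidates to machine precision and the
argbest is an honest ranking. The diameter couples to the surrogate through
capacity (∝ d²) and capex (∝ d²), which creates an interior optimum: small
columns clamp away product, large ones carry dead capital. The direction
flag defaults to maximizing mean IRR after tax; the source text says
"minimize", which is economically perverse for a rate of return and is
treated as a typo, with the direction exposed as a flag.

## Synthetic data: what it emulates and what it does not

`synth_weather()` generates hourly temperature as seasonal sinusoid +
diurnal sinusoid + AR(1) noise (defaults: mean 297.15 K, amplitudes 5 K
and 4 K, hourly AR coefficient 0.95, innovation sd 0.6 K, July/mid-
afternoon peaks; 365-day years, no leap days). This reproduces the features
the yield model is sensitive to — level, seasonal contrast, diurnal swing,
short-range persistence — and nothing else: no fronts, no humidity or
radiation, no inter-annual trends. Passing tests therefore demonstrate the
pipeline's correctness on a station-like series, not climatological
fidelity. With the default profile the monthly yields show the expected
mid-summer dip (the optimum sits below the July mean) and a relative SD of
5–7% across 36 months, versus ≈11% reported for the real station data —
our synthetic seasonality is smoother than south-Florida weather.

`synth_chamber_data()` mirrors the chamber protocol: 10 day/night regimes
(18/14 to 38/32 °C, held 9 h/15 h), observations every 4 days to day 28,
Gaussian observation noise (default sd 0.5 g/plant), forward-simulated at
the weighted day temperature $\frac{9\,T_{high} + 15\,T_{low}}{24}$.

## Numerical choices and limitations

* Temperatures are kelvin internally; file readers convert from °C.
* Hourly integration uses $\Delta t = 1/24$ day; daily steps with the
  weighted day temperature for chamber regimes. The discretisations agree
  to <1% per day at realistic rates (asserted in tests).
* RMSE convergence tolerance $10^{-8}$ g/plant; IRR rate tolerance
  $10^{-12}$; beta-fit lower-bound margin 0.5% of the sample range.
* Degenerate inputs: zero-variance samples, empty tables, non-PSD
  correlation targets, hour splits not summing to 24, and non-positive
  weights/temperatures/capacities all raise typed errors naming the
  offence; ties in extremal trials break to the lowest index.
* Problem sizes in the shipped tests: 20,000-trial sampling checks,
  one 60,000-row simulation, 10,000-draw fit recoveries — each runs in
  seconds because the mass balance is fully vectorised and only the IRR
  root-find loops per trial.
* The surrogate's absolute economics are placeholders; conclusions
  supported by this package are about propagation, ranking and comparison
  under uncertainty, not about the absolute profitability of any real
  facility. Germination efficiency, photon flux, CO₂, nutrients, wind and
  humidity are outside the growth model by design.
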