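---
title: "Modelling forest-fire occurrence probability from multi-scale drought characteristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling forest-fire occurrence probability from multi-scale drought characteristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtfire)
library(dplyr)
```

## The modelling problem

Drought reshapes fire regimes, but not uniformly: in humid, fuel-rich
landscapes drought dries fuels and promotes ignition, while in arid,
fuel-limited landscapes drought suppresses the vegetation that fires need.
A single global regression therefore misrepresents the drought–fire
relationship wherever its sign flips in space. `droughtfire` implements a
pipeline that confronts this spatial non-stationarity head on:

1. **SPEI** — the Standardized Precipitation Evapotranspiration Index is
   computed from monthly temperature and precipitation at 1-, 3-, 6- and
   12-month accumulation scales.
2. **Run theory** — drought events are maximal runs of months with SPEI at
   or below a threshold, lasting at least three months; each event carries a
   duration (DD), severity (DS, the sum of SPEI over the run) and intensity
   (DI = DS/DD), aggregated per period into MDN (events per year), MDD, MDS
   and MDI.
3. **Covariates** — the four drought characteristics are near-collinear by
   construction (longer droughts are more severe), so they enter the model
   as principal-component scores; all predictors are min-max normalized.
4. **GWLR** — fire-occurrence probability per grid cell (fraction of years
   with at least one fire) is modelled by a geographically weighted
   logistic regression: at every cell a binomial logistic model is fitted
   with adaptive bi-square kernel weights, giving a local coefficient
   vector per cell. The kernel bandwidth (a neighbour count) is chosen by
   minimizing the small-sample-corrected AIC.
5. **Evaluation and projection** — models are scored on a held-out window
   (ROC/AUC, Brier score, AICc) and applied to future-scenario drought
   characteristics to map probability changes by region.

Everything runs on synthetic data with known ground truth, so every stage
is testable without external downloads.

## The probability model

Let $s_i$ be the number of fire-years and $n_i$ the number of years
observed in cell $i$ at location $(u_i, v_i)$. The response is binomial,

$$s_i \sim \mathrm{Binomial}\!\left(n_i,\; p_i\right), \qquad
\operatorname{logit}(p_i) = \beta_0(u_i, v_i) + \sum_k \beta_k(u_i, v_i)\, x_{ik},$$

so the logit link acts on the occurrence probability itself. Setting all
coefficient surfaces constant recovers the global logistic model. We chose
the binomial formulation over a binary fire-ever/never encoding because the
per-cell fraction of fire-years is the quantity being modelled; the binary
mode remains available (`response = "binary"` in the pipeline config) for
comparison.

Local coefficients at cell $i$ maximize the kernel-weighted binomial
log-likelihood with weights
$w_{ij} = \left(1 - (d_{ij}/b_i)^2\right)^2$ for $d_{ij} < b_i$ (zero
beyond), where $d_{ij}$ is the great-circle distance and $b_i$ the distance
to the $N$-th nearest neighbour of $i$ (self included, so $w_{ii} = 1$).
The adaptive (nearest-neighbour) bandwidth keeps the local sample size
stable when cells are irregularly spread. Each local problem is solved by
iteratively reweighted least squares, converged when the largest
coefficient change falls below `1e-8` (at most 100 iterations), with a
`1e-8` ridge jitter on near-singular local designs (flagged per location)
and automatic bandwidth enlargement if a local design stays singular.

Model complexity is the trace of the local hat contributions: at
convergence, location $i$ contributes
$a_{ii}\, x_i^\top (X^\top A_i X)^{-1} x_i$ with $A_i$ the final working
-weight matrix of its own local fit. This effective parameter count $k$
enters $\mathrm{AIC} = -2\ln L + 2k$ and
$\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(m-k-1)$, where $m$ is the number
of cells and $\ln L$ evaluates every observation at its own local fit. The
bandwidth is selected by golden-section search over integer neighbour
counts (ties to the smaller bandwidth; a grid search is available for
non-unimodal profiles, and bandwidths whose effective parameters exhaust
the sample score as infeasible).

## SPEI choices

Potential evapotranspiration uses the classic Thornthwaite formulation —
monthly mean temperature only, annual heat index
$I = \sum (T_m/5)^{1.514}$ over above-freezing months, the standard cubic
exponent $a(I)$, and a day-length/month-length correction from solar
declination. Months at or below 0 °C contribute zero PET; a fully frozen
year is valid input. The high-temperature (> 26.5 °C) variant of the
formula is deliberately not applied; the basic formula is used for all
above-freezing months, which is the common dialect in drought-index work.

The climatic water balance $D = P - \mathrm{PET}$ is accumulated over
$k \in \{1, 3, 6, 12\}$ months and standardized per calendar month by a
three-parameter log-logistic distribution fitted with unbiased
probability-weighted moments; the fitted CDF value is mapped to a standard
normal deviate with the classic Abramowitz–Stegun rational approximation.
Numerical guards: a fitted origin above the sample minimum is clamped just
below it; fits with non-positive scale, shape at most 1, or a degenerate
moment system are flagged and yield missing SPEI for that calendar month
(never silently zero — zero is a meaningful SPEI value). The leading
$k - 1$ months of each accumulated series are likewise missing, never zero.

The calibration window is configurable. By default each series is
self-calibrated on its own full span, which is how standard SPEI software
behaves when given one series at a time; a fixed historical baseline window
can be supplied instead (`calibration = c(first, last)`), which is the mode
to use when future drought should be measured against historical
climatology. Both modes are exercised in the tests; neither is asserted to
be the uniquely correct choice, and projections default to per-scenario
self-calibration.

## Run-theory conventions

A month is in drought when $\mathrm{SPEI} \le$ threshold: the
classification bands are half-open on the dry side (light drought is
$(-1.0, -0.5]$), so the threshold value itself counts as drought. The
event end time is recorded exclusively (first month after the run), which
makes the printed identity DD = DTT − DIT equal the month count exactly.
Events are assigned whole to the period containing their start month —
cutting an event at a period boundary would corrupt its duration and
severity. Cells with no events in a period receive 0 for MDN/MDD/MDS/MDI
(the no-drought end of both sign conventions) so the downstream regression
has complete covariates; the event count `n = 0` flags the fill. Missing
SPEI months split candidate runs because continuity cannot be certified
across a gap. At a threshold of −0.5, runs are not terminated when SPEI
dips below −1: exceedance semantics, not class-band membership.

## Covariate transforms

The four drought characteristics are standardized (mean 0, SD 1) and
eigen-decomposed — a correlation-matrix PCA, appropriate because the
characteristics have different units. Components are retained in
decreasing-variance order until the cumulative proportion reaches 90 %.
Eigenvector signs are arbitrary, so each loading column's
largest-magnitude entry is made positive; loadings, means and SDs are
stored (and serializable to JSON) so future-period characteristics are
projected with the identical transform. The PC scores are then min-max
normalized like every other predictor. For future data both transforms use
the historical parameters, and values outside the historical range are
clipped to [0, 1] rather than extrapolated — clipping keeps the logistic
linear predictor inside the domain the model was trained on, at the cost
of flattening extreme scenarios; this is the documented default rather
than a hidden behaviour.

Collinearity is diagnosed with variance inflation factors
($\mathrm{VIF}_j = 1/(1 - R_j^2)$, severe at 10 or more); exact linear
dependence reports an infinite VIF rather than an error.

## What the synthetic generator emulates

The generator produces a rectangular lon/lat grid of 0.5° cells with up to
seven contiguous rectangular regions and a smooth forest fraction.
Temperature is a latitude gradient (warm south, continental north whose
winters cross 0 °C, so the frozen-PET branch is exercised) plus a
sinusoidal seasonal cycle, optional linear trend, and Gaussian noise.
Precipitation is seasonal gamma draws whose scale is modulated by a
per-cell AR(1) wetness anomaly (lag-1 autocorrelation 0.8) — the
persistence is what makes multi-month droughts occur — together with a
smooth spatial aridity surface and an optional drying trend per decade.
Fire occurrence is Bernoulli per cell-year with probability given by a
planted logistic model whose drought-component coefficient varies smoothly
with latitude and flips sign mid-domain (promoting in the south,
inhibiting in the north), mirroring the asymmetry such models report for
real fire regimes; static-covariate coefficient surfaces are drawn on the
±3 scale typical of reported regional mean local coefficients on
normalized predictors. One master seed spawns independent per-stream seeds
(grid, covariates, climate, truth, fires), so stages can be regenerated in
isolation and every run is bit-reproducible.

The generator does **not** emulate: real geography or elevation fields,
individual climate-model biases (ensemble members differ only by seed),
spatially correlated ignition processes beyond the planted surfaces,
record duplication or geocoding error in fire archives, or
observation-driven covariate drift. Passing tests therefore demonstrate
that the estimators recover the structure this generator plants —
calibrated SPEI, run statistics, coefficient surfaces, skill metrics — not
that any particular real-world fire regime satisfies the model.

## Problem sizes and numerical tolerances

The test suite and the acceptance script use problem sizes chosen to make
the statistical checks sharp while keeping a full run interactive: a
100-year single-cell series for SPEI calibration (per-calendar-month mean
within ±0.1 and SD within [0.85, 1.15] at all four scales), 500 random
264-month series for exact run-scanner equivalence, a 15 × 15 grid with 20
trial-years per cell for coefficient-surface recovery (Pearson r ≥ 0.7,
sign agreement ≥ 90 % at the AICc-selected bandwidth), a 200-cell dataset
for the global-limit identity (coefficients within 1e-6 of the global
fit), and a 10 × 10, 22-year study for the end-to-end holdout AUC. The
holdout window is two years, so test labels are binary (any fire in the
window); with the planted effect sizes the fitted model's AUC tracks the
true-probability ceiling within a few hundredths.

## Known limitations

Thornthwaite PET is temperature-only and biased in arid and
energy-limited climates; the pipeline's structure accepts any PET series
but only Thornthwaite is implemented. SPEI parity with archived global
products is not claimed — fitting constants and calibration windows
differ across implementations. The bandwidth search assumes an
approximately unimodal AICc profile (use `method = "grid"` otherwise).
Coefficient non-stationarity is estimated, not tested — no Monte-Carlo
significance machinery is included. Drought spatial extent across cells is
not tracked; events are per-cell.

## A worked example

```{r example, eval = FALSE}
library(droughtfire)

cfg <- fire_config(list(seed = 1, scales = 3L, thresholds = -0.5,
                        grid = list(n_lon = 10L, n_lat = 10L,
                                    lon0 = 100, lat0 = 20, cell_size = 0.5)))
run <- run_fire_pipeline(cfg, project = TRUE)

run$evaluation      # holdout AUC, Mann-Whitney p, Brier, training AICc
run$bandwidth       # AICc-selected neighbour count
glance(run$model)   # logL, effective k, AIC, AICc
autoplot(run$model) # local coefficient surfaces
run$projection      # regional mean delta-FP by scenario and period
```
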