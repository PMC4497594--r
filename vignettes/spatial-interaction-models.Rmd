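---
title: "Modelling regional mobility flows: gravity, radiation, and how to tell them apart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling regional mobility flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobflow)
```

## The problem

Infectious-disease models need a matrix of travel volumes between regions,
and such matrices are rarely measured directly. Two spatial interaction
models are the standard substitutes. The **gravity model** posits

$$N_{ij} = k \,\frac{\mathrm{pop}_i^{\alpha}\,\mathrm{pop}_j^{\beta}}{d(i,j)^{\gamma}},$$

with four free parameters fitted to data. The **radiation model** is
parameter-free up to a traveler fraction $T_c/T$:

$$\langle N_{ij}\rangle = N_i\,
  \frac{\mathrm{pop}_i\,\mathrm{pop}_j}
       {(\mathrm{pop}_i + s_{ij})(\mathrm{pop}_i + \mathrm{pop}_j + s_{ij})},
  \qquad N_i = \mathrm{pop}_i \cdot \frac{T_c}{T},$$

where $s_{ij}$ is the population inside the circle of radius $d(i,j)$
centred on the origin, excluding both endpoints. mobflow implements both
models, the machinery to derive observed flow tables from daily-location
diaries (the granularity of mobile-phone call detail records), three
distance measures, and a diagnostic suite for deciding where each model
can be trusted.

This vignette records the modelling assumptions, the tunable parameters,
and the design decisions taken where more than one defensible choice
existed.

## From call records to trips

A diary row is (subscriber, day, routing tower). Daily locations are
assigned by majority tower; ties are broken uniformly at random with a
stream keyed on (seed, subscriber, day), so re-running one subscriber
never reshuffles another. Call-free days inherit the most recent assigned
location, and days before a subscriber's first call are dropped — there is
nothing to carry forward. A **trip** opens whenever the day's district
differs from the previous day's, and its duration is the run length of
consecutive days spent in the visited district. Days are 0-based and the
window is half-open, $[0, n_{\text{days}})$.

Two conventions needed a decision:

* **Truncation.** A stay cut off by the end of the window has a censored
  duration. Truncated trips are flagged, kept in the `All` stratum, and
  excluded from duration bins by default (`include_truncated = FALSE`),
  since binning censored durations biases the short bins.
* **Duration bins.** `Week` (< 14 days), `Biweek` (14–29), `Month`
  (30–59), `Month2` (60–89), `Month3` (90–119), `Month4plus` (≥ 120),
  with the edges exposed as an argument because the boundary between
  "up to a week" and "one–two weeks" is read differently by different
  authors; the default puts every sub-two-week trip in the first bin.

Within-district movement is deliberately ignored throughout: the package
targets regional (inter-district) flows.

## Distance measures

Three measures are supported between district reference points, either
polygon centroids or population-weighted centroids (the population-weighted
mean of grid-cell centres, with an optional snap to the nearest road node):

1. **Euclidean** straight-line km (planar coordinates are assumed; an
   equirectangular lon/lat helper is provided and documented as
   approximate).
2. **Road distance**: shortest path over an undirected weighted edge list,
   after snapping each centroid to its nearest node (ties to the lowest
   node id). Road distance can never be shorter than Euclidean because
   every edge is at least as long as the straight line between its nodes.
3. **Travel time**: least-cost path over a friction surface — a raster of
   traversal speeds derived as `base_speed[land_class] * exp(-slope_coef
   * slope)`, with road cells raised to the road speed and non-positive
   speeds marking impassable cells. Costs live on the 8-connected cell
   graph; a move costs the mean of the two adjacent cell-crossing times,
   times $\sqrt 2$ diagonally. This is the standard symmetric least-cost
   convention, so the matrix is symmetric; a route with no passable path
   is reported as `Inf` with a warning and excluded downstream. Note the
   implied geometry: a straight line of $n$ cells costs $(n-1)$
   cell-crossings centre to centre, and on a uniform grid the octile
   metric elongates Euclidean distance by at most a factor 1.0824.

The speed table and slope coefficient are configuration with documented
defaults (walking-range speeds, roads at 50 km/h), not estimates: real
friction surfaces are built from land-cover and topography products that
this package does not ship.

## Fitting the models

**Gravity.** Poisson regression with log link on $\log \mathrm{pop}_i$,
$\log \mathrm{pop}_j$, $\log d$; the intercept is $\log k$ (a constant of
around $-20$ is only interpretable on the log scale). Zero-flow routes are
retained — they carry likelihood information. Wald 95% intervals are
reported per parameter together with the percentage reduction in deviance
against the intercept-only model. The fit is returned as a classed object
with `coef`, `confint`, `predict`, `simulate`, `residuals` and `plot`
methods.

**Constrained variants.** `production` (origin totals), `attraction`
(destination totals) and `doubly` constrained models estimate the kernel
exponents by Poisson regression with origin and/or destination fixed
effects, then compute balancing factors by iterative proportional fitting
to a maximum relative margin error of $10^{-8}$ (cap $10^4$ iterations;
non-convergence is an error carrying the last margin error). For the
doubly constrained model the kernel is the pure distance term — population
effects are absorbed by the factors. On three districts $\log d$ is
exactly collinear with the two fixed-effect margins, the GLM drops it, and
every $\gamma$ yields the same balanced table; the dropped term is
recorded and zero is used.

**Radiation.** $s_{ij}$ uses the classical convention: both endpoint
populations excluded, and districts exactly at the radius excluded
(strict inequality), which makes the construction deterministic under
ties. On tie-free instances the row sums then telescope exactly:
$\sum_j \langle N_{ij}\rangle = N_i\,(1 - \mathrm{pop}_i/M)$ with $M$ the
total population — the test suite holds this to $10^{-10}$ relative. The
traveler fraction is fitted by grid search (step 0.001 on $(0, 1]$)
minimising squared differences of $\log(1+x)$-transformed flows — robust
to the heavy right tail — with the closed-form linear-scale least-squares
solution reported alongside; the two can disagree when the model
over-predicts many small routes while under-predicting the total.

## Diagnostics and model choice

Per-route errors are $\log(\text{obs}) - \log(\text{pred})$, defined where
both are positive; zero routes are counted and reported separately. Under
the working assumption that errors are standard normal, a route is flagged
when $|e| > 2$; a route flagged for **every** model under comparison is
*unmodelable*. An empirical variant (mean ± 2 SD of each model's own
errors) is switchable because the fixed band conflates miscalibration of
scale with genuine outliers. A one-sample Kolmogorov–Smirnov statistic
against N(0, 1) (fixed moments, matching the assumption — not estimated
ones) quantifies how far the error distribution actually is from that
assumption.

Goodness of fit is summarised by: reduction in Poisson deviance (defined
for parameter-free models too, against the grand-mean null); an adjusted
$R^2$ defined — since several definitions circulate — as the OLS
$R^2$ of log observed on log predicted over positive–positive routes,
adjusted by the interaction model's parameter count (4 for gravity, 1 for
fitted-fraction radiation); per-route Sørensen–Dice agreement
$2\min(o,p)/(o+p)$; and the mean and 2.5/97.5% quantiles of both ratio
directions (pred/obs and obs/pred), which are *not* reciprocals of each
other and are both reported.

For model choice, the route winner is the model with the smaller absolute
error (exact ties go to gravity, deterministically), and a logistic
regression predicts the winner from the **gravity factor**
$g_m = \mathrm{pop}_i \mathrm{pop}_j / d(i,j)$ — a parameter-free proxy
for route volume. $g_m$ spans many orders of magnitude, so the covariate
is $\log_{10} g_m$ by default with a raw-scale switch. Complete separation
is detected and raised as an error rather than reported as a fit.
Urban/rural sub-analyses classify districts by population-density
terciles and refit the gravity model per subset and distance measure.

## The synthetic world

Every stage is testable without data because the generators produce
districts, flows, diaries and rasters with known ground truth. Design
choices, fixed once:

* **Populations** are log-normal (meanlog 12.61, sdlog 1.0: mean ≈ 490k,
  69 districts total ≈ 34 million, the largest draws reaching
  primate-city scale). Any heavy-tailed law would serve; log-normal gives
  two-parameter control.
* **Coordinates** are uniform on an 800 km square with three planted city
  clusters so urban/rural contrasts exist, and a 20 km minimum centroid
  spacing — districts are areal units; allowing near-coincident centroids
  lets the $d^{-\gamma}$ kernel manufacture mega-routes that dominate the
  Poisson score and destabilise every fit.
* **Flows** are independent Poisson draws around the truth-model means;
  optional median-one log-normal route heterogeneity makes log errors
  N(0, sdlog) around the truth, the structure the error diagnostics
  assume. The heterogeneity SD is damped on busy routes
  ($\sigma/\sqrt{1 + \mu/\mu_{1/2}}$), emulating the consistent empirical
  finding that interaction models describe the largest flows best.
* **The national stand-in table** (`synthetic_national_od()`) fixes the
  study conditions for the acceptance checks: gravity truth
  $\alpha=\beta=1.22$, $\gamma=2.05$; the intercept solved so yearly
  inter-district trips total 6 per resident (a realistic rate; any rate
  above ~1.2 drives the fitted traveler fraction to its upper boundary,
  as observed on real national tables); heterogeneity
  $\sigma = 2/\Phi^{-1}(0.95) \approx 1.216$ so that roughly a tenth of
  routes fall outside the fixed ±2 error band; damping scale
  $\mu_{1/2} = 10^4$ trips/year. It is a synthetic object: it reproduces
  the statistical conditions of a national CDR-derived table, not any
  real geography, tower layout or operator market share.
* **Diaries** place each subscriber at a home district; departures are
  Bernoulli per at-home day, durations log-uniform, and destination
  choice follows a gravity kernel whose destination exponent rises — and
  distance exponent falls — with the planned duration, planting the
  qualitative trend that duration-stratified fits must recover. Calls per
  day are Bernoulli × (1 + Poisson) across multiple towers per district,
  which exercises the majority/tie logic; a missing-period option blanks
  out a block of days to test robustness to observation gaps. The
  Bernoulli call process is a stand-in, not calibrated to any observed
  per-subscriber call-frequency distribution.
* **Rasters** are Gaussian-kernel population spreads, smoothed-noise land
  classes and slopes, and a k-nearest-neighbour road graph bridged to a
  single component, with per-edge windiness factors so road distance can
  be made to diverge from Euclidean selectively (e.g. windy rural roads).
* One RNG stream per generator, derived from the master seed, so adding a
  generator never shifts another's draws.

## What the tests do and do not show

The acceptance suite runs the full pipeline on the national stand-in at
problem sizes chosen to finish in seconds on one CPU (69 districts, 4,692
routes, 50-replicate Monte-Carlo loops; diaries with 1,035 subscribers
over 240 days) and checks: recovery of the planted gravity parameters
within the estimator's measured sampling spread; the boundary traveler
fraction; the gravity-over-radiation adjusted-$R^2$ contrast; radiation's
systematic under-prediction of volumes; a realistic flagged-route share;
95% CI coverage ≥ 90% for both the gravity and the choice-model
coefficients; the exact IPF, telescoping, circle-population, Dijkstra and
round-trip identities; and the planted duration trend.

Passing these shows the pipeline is correct and well-calibrated **under
the generator's assumptions**. Real CDR-derived tables violate several of
them — ownership bias, tower density correlated with population, temporal
gaps, non-log-normal heterogeneity — so numeric agreement with any real
table's published diagnostics is not implied, and the deviance reduction
on the stand-in runs higher than is typical of real tables because the
top-route heterogeneity is smoothly damped.

## Known limitations

* Poisson maximum likelihood weights routes by their expected volume;
  under heavy-tailed overdispersion the exponent estimates carry a small
  systematic attenuation (about 0.05 under the stand-in's conditions)
  that vanishes as the heterogeneity does.
* The friction surface is toy-scale: no hydrology, no one-way roads, no
  seasonal speeds; the travel-time matrix is symmetric by construction.
* `read_od_table()` ingests CSV (with a column-synonym map); spreadsheet
  ingestion is out of scope.
* The trip definition cannot see multiple moves within one day, matching
  the daily-location granularity of the source data.
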