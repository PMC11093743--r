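---
title: "Wave climate and barnacle quality: methods notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wave climate and barnacle quality: methods notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(percebe)
```

This vignette records how the package's methods work, the assumptions they
make, and the design choices taken where the problem left them open. It
states no empirical result beyond what the test suite and the acceptance
script themselves compute.

## The scientific problem

Wave-exposed intertidal organisms trade growth for mechanical safety. For
the stalked barnacle, the length-to-width ratio S = TL/DBC summarises that
trade-off: elongated animals (high S) are more breakage-prone under the
orbital currents of breaking waves, and — because market quality tracks the
stubby morphotype — less valuable. The package quantifies the chain

offshore sea state → inshore orbital current → population morphometry →
market quality,

per extraction site, and asks which topographic settings transmit or
buffer the wave signal.

## Wave transformation

Offshore significant heights are shoaled to the 1 m intertidal depth with
the linear-theory energy-flux coefficient, using the explicit wavelength
approximation (deep-to-shallow interpolant) rather than the implicit exact
dispersion relation. Assumptions worth keeping in mind:

* No refraction, breaking, directional spreading or tide-dependent depth:
  the transformation is a pure shoaling gain, so inshore heights of several
  metres are a stress *scale*, not a literal surf-zone height.
* The explicit wavelength formula is exact in the deep- and shallow-water
  limits but overestimates by up to ~5 % in intermediate water
  (dimensionless depth near 1). The test suite pins this envelope against
  an iterative exact-dispersion oracle. With hindcast points at 50–300 m
  and an inshore depth of 1 m, both ends of the transformation sit near the
  limits, and the end-to-end shoaling coefficient agrees with the exact
  oracle to better than 1 %.
* The printed form of the shoaling bracket circulating in the applied
  literature carries a `2 k_i d_o` term where the energy-flux derivation
  requires `2 k_i d_i`; the symmetric form is the default (it alone gives
  the equal-depth identity a shoaling coefficient of 1 when `d_o` differs
  from `d_i`), and `literal_printed = TRUE` reproduces the variant for
  comparison.
* Daily maxima are taken *after* transforming each hour (the period enters
  the shoaling gain hour by hour), on UTC calendar days.

The orbital current u = sqrt(g H) turns the daily maximum height into the
velocity scale that the coupling analysis consumes; 5 m waves correspond to
7 m/s currents.

## Trend decomposition

The daily u series is decomposed as intercept + smooth long-term trend +
cyclic seasonal component by penalized least squares: a cubic B-spline
basis (15 functions) for the trend and a cyclic cubic B-spline basis
(12 functions, period one year, 365.25-day folding with Feb 29 mapped onto
day 59) for the season, each under a second-difference roughness penalty.
Because the cyclic basis partitions unity, the seasonal block carries a
sum-to-zero reparameterization (orthogonal complement of the ones vector),
and the basis is centred over a uniform day-of-year grid so the seasonal
component integrates to zero over a year. The two penalties are chosen by
generalized cross-validation on a log-spaced 10-point grid from 1e-4 to
1e4 (100 combinations), ties resolved toward the heavier penalty. The
long-term rate of change is the OLS slope of the fitted trend against time
in years, with its t-test p-value; no autocorrelation correction is applied
(a known limitation — daily wave series are strongly persistent, so the
p-values are optimistic). Seasonal-subset trends (January–March,
June–August) are plain OLS on annual means. This deterministic additive
decomposition is the package's stand-in for mixed-model smoothing: the
quantities consumed downstream are only the smooth trend and its slope.

## Morphometry, quality and filters

The Parada limit is a four-parameter sigmoid in the TL–DBC plane (upper
asymptote 67.8055 mm, lower 10.9002 mm, half-saturation 12.216 mm, Hill
exponent 2.8008, all for thawed specimens). A point exactly on the curve is
classified good — the choice makes HQF upper-semicontinuous and is asserted
in tests. All computation is in millimetres; centimetres appear only in
reports. The study filters drop individuals at or below the 2 mm DBC
measurement floor and sites with fewer than 6 sampling years; "6
consecutive years" is relaxed to 6 distinct years by default (observed
monitoring series contain gaps), with a strict-consecutive flag. Site-level
summaries are offered both pooled across intertidal levels (the grouping
used against winter currents) and per level.

## Topography

Metric geometry runs in a local equidistant projection about each site
(metres east/north); at the 500–1000 m scales involved the distortion is
negligible. The coastline orientation proxy is the chord between the two
crossings of a 500 m-radius circle with the coastline polyline; when a
convoluted coast yields more than two crossings, the two whose along-coast
positions bracket the point nearest the site are kept. The shore-normal is
the chord perpendicular oriented toward deeper water (mean bilinear depth
over the first 250 m of each candidate). The relative incidence angle α is
the absolute circular difference between the resultant-vector mean wave
direction (nautical "coming from") and that normal, folded to [0, 180]:
values above 90° mean a shore facing away from the swell (published site
tables reach 86°, consistent with either folding). The nearshore slope is
the OLS slope of negative depth against distance at 50 m steps along the
1000 m seaward transect, so seaward deepening is negative; the transect may
leave the grid with a warning if at least 5 samples remain.

## Coupling and model ranking

Per site, yearly level-pooled mean S and HQF are regressed on the mean
January–March orbital current preceding each sampling (at least 3 paired
years); R² equals the squared Pearson correlation and is the site's
coupling strength. Gamma GLMs with log link serve skewed positive
responses: coefficients come from IRLS (which is shape-free under the log
link), the shape is then estimated by maximum likelihood given the fitted
means, and the reported log-likelihood is the exact Gamma likelihood at
that shape — so the shape counts as one parameter in AICc, and each model
gets its own ML shape rather than a shared dispersion. HQF values of
exactly 0 or 1 should be compressed by (HQF·(n−1)+0.5)/n before Gamma
fitting. Model selection is exhaustive: every term subset respecting
marginality is fitted, ranked by the small-sample AICc
(−2logLik + 2p + 2p(p+1)/(n−p−1) — the small-sample reading of
"conditional AICc", since no random-effect structure exists here), with
AICc differences and Akaike weights; ties go to the smaller model, and
failed fits are flagged and excluded from the weights. Random effects are
deliberately not implemented: sites and levels enter as fixed factors,
which matches the fixed-term structures the ranked tables report.

## Quality–morphometry geometry

The population-level law HQF(S) = A/(1+exp((S−x0)/b)) is fitted by
nonlinear least squares with multi-start (x0 at five S quantiles, b at 0.1,
0.3, 1.0, A at max HQF; best SSE kept), since the transition is sharp and
single-start fits stall on flat plateaus. The printed double-negative
exponent of the published equation is normalised to the b > 0 decreasing
form — algebraically identical. Constant-S rays TL = S·DBC are intersected
with the Parada limit by sign-change bracketing on a dense grid plus
bisection to 1e-8 mm over DBC in [2, 50] mm (lower bound = measurement
floor, upper bound above any observed width); on that domain and for S in
[1, 4] the ray and the sigmoid cross at most once (asserted against a
0.001 mm grid-scan oracle). An empty root set is a valid outcome: below
S ≈ 1.5 the whole measurable width range is good quality.

## Synthetic worlds

The generators define the study conditions for every test:

* **Waves** — 15 years of hourly states by default (matching the hindcast
  span); height = base 1.45 m + 0.65 m seasonal cosine peaking at day 45 +
  linear trend (default 0.02 m/yr) + AR(1) noise (phi = 0.9, marginal sd
  0.35 m — sea-state persistence) + winter storm bursts (Poisson, 8 per
  season, exponential surcharge mean 1.5 m decaying over ~18 h), floored at
  0.1 m. Periods are height-coupled and clipped to 4–20 s; directions are
  von Mises about the prevailing bearing (290°, concentration 4). With an
  80 m offshore depth these defaults place winter mean orbital currents in
  the observed 5–8 m/s envelope and summer means near 4–5 m/s.
* **Barnacles** — 30–50 individuals per site × level × year (the sampling
  design of the monitoring programmes); S is the generative variable
  (lognormal, baseline mean 2.3 near the observed grand mean, shape 0.22),
  with small level and site offsets, and TL derived as S·DBC from a
  truncated lognormal DBC on [2, 35] mm. Coupled sites shift mean S by
  −0.3 per m/s of winter-current anomaly; refractory sites do not.
* **Coast/bathymetry** — a straight coastline of prescribed bearing through
  the site and a planar depth field deepening seaward at a prescribed rate,
  giving exact ground truth for the shore-normal, α and the transect slope.

What the generators do *not* emulate: spectral wave physics, tides,
refraction, recruitment dynamics, spatial correlation between sites, and
measurement error in TL/DBC. Green tests therefore demonstrate that the
estimators recover known structure under the stated statistical model, not
that the model captures every feature of field data.

## Numerical choices and problem sizes

Root-finding tolerances are 1e-8 mm (ray crossings) and 1e-12 on the
dispersion oracle. The GCV grid is fixed (no continuous optimisation) to
keep the decomposition deterministic. Stochastic recovery properties run at
sizes chosen to make the checks sharp yet quick: 15-year daily series and
20 seeds for trend recovery; n = 200 and 20 seeds for model-selection
recovery; 10 sites × 8 years × 20 seeds for the end-to-end
coupled-vs-refractory contrast; Gamma-likelihood oracle checks at n ≤ 20
where a (coefficients × shape) grid refinement is exact enough at 1e-4.

## Known limitations

* Trend p-values ignore serial correlation.
* The Gamma GLM replaces the mixed-effects formulation; with site and level
  as fixed factors, variance partitioning differs from a random-effects
  treatment.
* The explicit wavelength's ~5 % intermediate-water error propagates into
  shoaling only weakly at the depths used here, but would matter for
  shallow offshore points (tens of metres) with long periods.
* Quality classification assumes the thawed-specimen limit applies
  unchanged to fresh measurements.
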