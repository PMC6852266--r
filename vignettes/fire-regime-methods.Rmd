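---
title: "Methods: delineating fires and modelling their drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delineating fires and modelling their drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and procedures the package implements, the
assumptions behind them, and the choices made where the methodology was
genuinely open. It is written for a reader who wants to understand *why* the
code does what it does; the function reference documents *what* each function
does.

## The problem

Savannah fire regimes are described by the long-term pattern of four
characteristics of individual fires — size, ignition date (season), time
since last fire (frequency) and radiative power (intensity) — plus two
aggregates, the total number of fires and the total area burnt. Remote
sensing supplies two complementary inputs: a *burned-area* product that dates
each 500 m pixel's burn, and an *active-fire* product that detects thermal
anomalies at overpass with a fire radiative power (FRP). Neither product
identifies individual fires; the first analytical step is therefore to
cluster dated burned pixels into discrete fire events, and everything
downstream — descriptive surfaces, temporal trend models, spatial driver
models — works on those events.

Because the satellite, livestock and telemetry inputs of a real study of
this kind are large external downloads, the package is built around a
synthetic-landscape generator with known ground truth. Every stage can
therefore be tested for *parameter recovery*: the generator plants a known
fire partition, rainfall trend, boma-density slope or motion variance, and
the tests assert the estimator finds it.

## Fire-event delineation

Two burned-pixel records belong to the same fire when they are spatially
adjacent (8-connected by default; 4-connectivity is available) and their
burn dates differ by at most 5 days. The event partition is the transitive
closure of this relation, computed by union-find — the raster equivalent of
a flood fill. Three consequences are deliberate:

* the 5-day rule applies *pairwise along chains*, so a slow-spreading fire
  whose total date span exceeds 5 days is still one event; a global
  span cap would contradict flood-fill semantics;
* repeat burns of one pixel in different years are distinct records and
  join different events (same-pixel records count as spatially adjacent,
  so a reburn *within* the gap tolerance would merge);
* event ids are assigned deterministically (by ignition date, then row,
  then column of the first-burning pixel), so reruns are bit-identical.

Per event we derive: size in pixels and km² (one 500 m pixel = 0.25 km²);
ignition date = the earliest pixel date; its calendar year, rainfall year
and day of year; mean time since last fire; and maximum FRP. Day of year is
encoded zero-based (January 1st = 0, December 31st = 364 or 365): an
encoding in which 366 always denotes December 31st is satisfiable only in
leap years, so we use the ordinal convention and note the difference.

*Time since last fire* is the mean, over the event's pixels that burned at
least once before its ignition date, of the years (365.25-day) since each
pixel's most recent prior burn. Pixels never seen burning contribute
nothing, and the value is missing when no pixel has a prior burn — so early
study years are biased toward missing values and the statistic is capped by
record length; both artefacts are properties of the definition, not bugs.

FRP attaches by footprint-and-date matching: a detection must fall on an
event pixel and be dated within the event's span ± 1 day (overpass timing
and burn-date compositing are offset by up to a day). Detection is
incomplete by nature — the generator's default 21% per-fire detection
probability reproduces the kind of sparse FRP coverage real products give —
so FRP is missing for most events, without spatial bias.

## The rainfall calendar and covariates

A *rainfall year* runs October–September, containing one full bimodal cycle
(short rains October–December, long rains March–May); we label it by its
ending year, so October 2005–September 2006 is "2006". Two rainfall
covariates deliberately partition a fire's history: *monthly rainfall* is
the fire month's value at the centroid, and *cumulative rainfall* sums the
months from a window start through the month **before** ignition, excluding
the ignition month so the two never double-count. Two window conventions are
implemented because the underlying methodology is stated both ways in the
literature this design follows: from the start of the previous rainfall
year (the default), or from one rainfall year earlier still; they differ by
exactly one rainfall year's total, which the tests assert.

Raster cells are half-open, `[x, x+Δ) × [y, y+Δ)`, so every point belongs
to exactly one cell and boundary fires are never double-assigned. Covariate
sampling is at the fire *centroid* (point extraction), not averaged over the
footprint; footprint averaging would be a defensible alternative but point
extraction matches how categorical layers such as soil are naturally
queried.

## Boma density (livestock pressure)

Active livestock enclosures (bomas) are counted in areas where satellite
images from different years overlap. Each footprint with counts in ≥ 2
years gets its own Poisson GLM (log link) of count against year with
`log(area)` as offset — counts, so a Poisson family; one GLM per footprint
because the footprint is the unit of observation. The rate of change is
reported on the density scale by the delta method at the footprint's mean
year. The fitted log-linear curve's derivative at the central year tracks a
linear density trend closely (curvature enters the central derivative only
at third order), which is why the recovery tests against the generator's
*linear* truth pass with small bias. Footprints observed once contribute a
baseline only; all-zero footprints get rate 0 with a degeneracy flag.

Footprint rates interpolate to a 6 km surface by a stratified scheme:
inside protected areas, regression kriging with management unit as the
auxiliary (unit-mean trend, residuals kriged with an exponential variogram
fitted by Cressie-weighted least squares to a 12-bin empirical
semivariogram); in the buffer, universal kriging with a linear drift. The
two strata are interpolated separately because management is expected to
set the level. Baselines are kriged with the same scheme, and
`density(year) = max(0, baseline + rate·(year − 2001))`, clamped at zero.
Kriging weights always include the constant drift function, so they sum to
one at every cell — an unbiasedness property the tests check numerically —
and prediction with a zero nugget is exact at the data points.

Verification holds out a fraction (default 25%) of cells with no
observations, compares predicted with independently counted density
(Pearson), and reports the predicted-to-actual ratio. Cells split across
the protected/buffer boundary are excluded by rule (their prediction is a
mixture of two different models) and the exclusion count is reported.
Kriging smooths across strata, so the ratio can sit well above 1 where
sparsely observed low-density areas border dense ones; the package reports
the ratio rather than correcting it.

## Wildebeest utilization

Trajectories are modelled as Brownian bridges between consecutive GPS
fixes. The motion variance σ²ₘ is estimated by the leave-one-out
construction: odd fixes are treated as observations of the bridge spanning
their neighbours, whose mean is the time-linear interpolation and whose
variance is `T·a(1−a)·σ²ₘ + ((1−a)² + a²)·δ²` with δ the GPS error SD
(default 20 m). The likelihood is maximized on the log scale; a stationary
trajectory pins the estimate at the lower search bound with a warning.

The utilization distribution integrates the bridge density over time by
50-point midpoint quadrature per segment (segments weighted by duration).
At each quadrature time the position is an isotropic Gaussian, so the mass
in each 500 m cell is an exact product of normal-CDF differences —
truncated at 5 SD — rather than a density-at-centre approximation; against
a dense Monte-Carlo simulation of the bridge the total-variation error is
below 0.02. "500 m" is read as the cell edge, consistent with the burn
grid. Shorter gaps and faster movement give narrower corridors, which the
tests check as monotonicity of corridor width in σ²ₘ.

Unbalanced sampling across months is corrected by weighting each month by
`min(n)/n_m` over pooled fix counts (the sparsest month keeps weight 1);
fix counts are pooled across individuals by default, with a per-individual
option. The Voronoi fracture machinery — assigning each cell to its nearest
fix — partitions a UD exactly (fracture masses sum to the UD mass), so
fracture-level weighting and whole-month weighting agree when the weight is
constant within a month.

Monthly population UDs sum the weighted individual UDs, rescale to 1, drop
the low-use tail and renormalize. The exclusion phrase "the lower 5% of
utilization values" is ambiguous; the default drops the lowest-valued cells
whose *cumulative* mass totals 5% (so 95% of mass is retained before
renormalization), and a value-quantile alternative is a flag.
Renormalization after exclusion is applied because downstream covariates
treat the surface as a distribution. The fire-level covariate is the sum of
the population-UD values at the centroid cell for the fire month and the
two months before.

## Temporal trends

Ecosystem-wide trends use Pearson correlations with the `n − 2` df
convention (14 years → df = 12). Spatially explicit trends fit, in every
6 km cell, a GLM of the yearly value against `year − 2001`: Gaussian with
the closed-form least-squares solution for areas and medians (the
implementation is vectorized but *exactly* equals the per-cell formula,
which the tests assert to 1e-12), Poisson log-linear for counts. The
intercept is the 2001 baseline. Cells with fewer than 3 yearly values are
flagged missing.

The change in burnt area is modelled by a Gaussian GLM on the per-cell
area slope with main effects (boma rate, management unit, mean annual
rainfall, rainfall trend, 2001 baseline) plus three interactions of
interest (boma rate × rainfall mean, boma rate × baseline, rainfall trend
× rainfall mean). Model reduction is by single-term deletions under
likelihood-ratio tests at α = 0.05, respecting marginality (a main effect
under a surviving interaction is never a candidate), dropping the
least-supported term each round until all survivors are significant. For
Gaussian models the statistic is the profile LRT `n·log(RSS₀/RSS₁)`, which
is mildly anticonservative in small samples; the calibration simulations
therefore use cells-per-fit large enough (n = 400) for the χ² reference to
hold, and find the type-I rate statistically indistinguishable from 0.05.
Tukey HSD contrasts on the management factor use the studentized-range
adjustment via estimated marginal means; Poisson fits are checked for
overdispersion with Pearson χ²/df and a one-sided test.

## Spatial drivers

The spatial regression is `y = Xβ + Au + ε`: centred-and-scaled fixed
effects (cumulative rainfall also enters squared, built *after* scaling),
dummy-coded factors, and a latent intrinsic-CAR Gaussian Markov random
field `u` on a regular 12 km mesh, with a small diagonal ridge (10⁻⁶) for
propriety. Hyperparameters (noise variance, field precision τ) are chosen
by a deterministic grid search over the profile marginal likelihood,
computed with the Woodbury identity and sparse Cholesky factors; β and its
plug-in Gaussian 95% intervals come from the conditional precision at the
selected hyperparameters. `τ = ∞` (field off) is always in the grid, and
with the field off the estimator reduces *exactly* to ordinary least
squares — the tests assert agreement to 10⁻⁶. Support for a covariate
means its 95% interval excludes zero.

This is a deliberate approximation to a fully Bayesian SPDE/INLA fit: the
same model family (latent GMRF plus Gaussian fixed effects), but with
grid-searched hyperparameters instead of hyperparameter posteriors, hence
slightly narrow intervals in principle. In calibration simulations — a
spatial confounder drawn from the CAR prior at mesh scale, a covariate
correlated with it, 200 replicates — the 95% intervals cover the planted
coefficient at the nominal rate within binomial error. The intercept is
weakly identified against the field's near-constant mode (a standard
property of intrinsic CAR models) and its interval is accordingly wide;
driver inference concerns the other coefficients. Ignition day is treated
as a linear response (not circular), and size, time since last fire and
FRP are log-transformed (strictly positive, right-skewed); both choices
are configurable defaults, not claims that they are the only reasonable
ones.

## The synthetic landscape

The generator mirrors the structure of a multi-unit protected-area
complex: a 2 × 4 tiling of eight protected units inside a buffer strip,
with varying fire policy and livestock permission. Its defaults are the
study conditions the tests run under:

* **Grid and years** — 500 m pixels, 2001–2014; dates are integer days
  since 2000-01-01 so the 5-day rule is exact across leap years.
* **Fires** — grown by stochastic dilation from seed pixels; pixel date =
  ignition + hop count capped at 5 days, so every fire satisfies the
  clustering contract *by construction*; fires of one year are separated
  by a one-pixel moat and ignition days stay inside day-of-year 15–340, so
  the truth partition is exactly recoverable (and the tests demand
  exactness, not approximate agreement). Sizes are truncated log-normal
  (the real size distribution is right-skewed but its form is unknown;
  log-normal is a modelling choice). Ignition days favour the two dry
  seasons (65% long dry, 35% short).
* **Detections** — per-fire Bernoulli(0.21) coverage, 1–3 detections per
  detected fire, log-normal FRP with recorded parameters.
* **Rainfall** — a fixed bimodal monthly profile (peaks April and
  November) scaled by a mean annual surface with a west–east gradient
  (−8 mm/yr per km by default) and an optional linear trend, times
  mean-one log-normal noise, so expected annual totals are exactly linear
  in year and trend recovery is well-posed. The rain grid is 10× coarser
  than the burn grid, as climate products are.
* **Bomas** — rectangular image footprints (clipped at the landscape edge
  so the buffer strip is sampled), Poisson counts around
  `max(0, base + slope·(year−2001))·area` with management-dependent bases
  (buffer 2, livestock-permitted 1, excluded 0.15 bomas/km²) and default
  slope 0.05 bomas km⁻² yr⁻¹.
* **Trajectories** — Brownian walkers (default σ²ₘ = 30–50 m²/s depending
  on the driver script) with 20 m location error at 3 h fixes; per-month
  fix counts can be forced unbalanced to exercise the reweighting rule.

What the generator does **not** emulate: cloud and overpass gaps beyond a
uniform detection probability, fire-spread physics, sub-pixel burned
fraction, serially correlated movement (the walkers are pure Brownian
motion, which is exactly the BBMM assumption), or boma mis-detection.
Passing tests therefore demonstrate that the estimators recover what they
are defined to estimate under their own assumptions — not that those
assumptions hold for any particular real landscape.

## Problem sizes and numerical choices

The bundled analyses run on a 96 × 96-pixel (48 km) landscape with 40
fires/year — about 4,500 burned pixels and 560 fires — chosen so that the
6 km temporal grid has 64 fully informative cells and every script
completes in seconds; the pipeline fixture in `run_all()` is smaller still
(40 × 40 pixels). Simulation-based checks use 200 replicates for coverage
claims and 1,000 for type-I rates. Other numerical defaults: 50-point
bridge quadrature (30 in the pipeline for speed); 5-SD Gaussian
truncation; 12 lag bins and an exponential model for variograms, with a
pure-nugget fallback on degenerate fits; ties in Voronoi assignment go to
the lowest fix index; medians of even counts use the midpoint. All
randomness flows from a single configured seed, and `run_all()` reruns are
digest-identical.

## Known limitations

* The CAR approximation reports plug-in intervals; full posteriors would
  be wider, most visibly for the intercept.
* Kriging assumes second-order stationarity within each stratum; strong
  within-unit gradients in boma rate would be attributed partly to the
  residual field.
* The per-footprint delta-method rate is biased away from the central year
  when density trends are strongly non-linear.
* FRP units are carried through as given by the input product
  (MW/km²-scale values in the generator); no unit conversion is attempted
  because detection-level and pixel-level conventions differ between
  products.
* The ignition-day response is linear, so models of seasonality near the
  calendar wrap (December–January) are distorted; the synthetic fire
  seasons avoid the wrap.
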