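---
title: "Land use regression exposure surfaces: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land use regression exposure surfaces: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanlur)
```

## The model

Land use regression (LUR) estimates long-term pollutant concentration at
an unmonitored location from the GIS characteristics of its
surroundings. The package implements the standard intra-urban form: a
multivariable spatial regression

$$ Z(x_i, y_i) = \beta_0 + \sum_j \beta_j Z_j(x_i, y_i) + \varepsilon, \qquad
   \varepsilon \sim N(0, v^2), $$

where $Z$ is the annual-mean concentration of PM2.5 or NO2 at a
monitoring site and the $Z_j$ are buffer predictors: summaries of land
use, roads, traffic, population, altitude and meteorology inside closed
discs of radius 100, 200 and 500 m centred on the site. Concentrations
may be modelled on the natural-log scale (`transform = "log"`);
predictions are then back-transformed with `exp()` and no smearing
correction is applied, so log-model predictions estimate medians rather
than means. Whether a model is fitted on the log scale is an input
choice, not inferred from the data.

Annual means come from two two-week campaigns, one in the dry and one in
the rainy season: each campaign mean averages its valid weekly values,
the annual mean averages the two campaign means with equal weights, and
sites contributing only one successful campaign are excluded from the
annual analysis.

## Buffer predictors and their units

`build_predictor_table()` computes the variable catalogue
(`predictor_catalogue()`, 69 columns with traffic and meteorology
present). All geometry is exact rather than rasterised:

* land-use fractions use the closed-form area of a disc intersected
  with the category's polygons (Green's-theorem sector decomposition),
  stored as fractions in [0, 1] — published coefficients such as 44.4
  on an industrial fraction are only plausible on that scale, not on a
  percent scale;
* road lengths clip each centreline segment to the disc (chord
  geometry) and are stored in metres;
* population buffers weight each raster cell by the exact area of its
  intersection with the disc, which removes the resolution bias a
  centre-in-disc rule would introduce at 100 m radii; density is
  count / $\pi r^2$;
* distances to the nearest road of each class are unbuffered minima.
  When a class is absent citywide the value is an NA sentinel (later
  removed by screening): zero would fabricate proximity and infinity
  would distort fits. The table also carries radius-suffixed aliases
  (DPRIM500, DSEC200, ...) because published equations name distance
  variables that way; the duplicates are pruned deterministically by
  screening.

Traffic speed (VEL) and volume (VOL) are length-weighted means of the
segment attributes inside the disc. Meteorology (TPROM, PPROM) is read
from terrain-regression surfaces and HR/WD/WPROM pass through as
nearest-station values.

## Traffic: speed-density-flow fundamental diagrams

Monitoring sites observe speeds, not counts, so volumes are estimated
through a fitted speed-density relation and $q = k \, v \cdot$ lanes.
The six canonical forms are pinned in the package documentation
(`?traffic`): Greenshields (linear), Greenberg (logarithmic), Underwood
(exponential), Pipes and Drew (fixed-exponent power forms) and
May-Keller (free exponent). Each is estimated by least squares on its
linearising transform (the May-Keller exponent is profiled over a
grid), on bootstrap resamples of the observations whose parameter
estimates are averaged (200 resamples by default; the replicate studies
use 25 as their problem size). Candidate forms are compared by their
mean RMSE on the out-of-bag observations of each resample, always on
the speed scale. Out-of-bag scoring matters because the forms nest:
May-Keller contains Greenshields at exponent 1, so in-sample RMSE would
select the richer form on overfit alone. All six $v(k)$ curves are
strictly decreasing, so speed-to-density inversion is single-valued;
the stored traffic regime (interrupted / semi-interrupted /
uninterrupted) records which operating branch of the flow-speed
relation the observations represent. Speeds are treated as space-mean
speeds.

## Meteorological surfaces

Station temperature and precipitation are regressed on terrain
covariates from the DTM — altitude, slope, and exposure (the azimuth
of steepest descent) — and predicted cellwise. Exposure is circular,
so it enters as a (sin, cos) pair rather than raw degrees, which would
be discontinuous at north. Cities with fewer than four stations are
refused outright (no valid spatial estimation) and their LUR models
simply omit the meteorological columns. An optional inverse-distance
residual correction exists but the default is regression-only.

## Screening and supervised selection

Screening applies the zero-fraction rule first (columns with zeros at
more than 90% of sites are dropped), then prunes pairwise correlations
above 0.7 in descending order of |r|; within a pair the member with the
weaker absolute correlation to the outcome is dropped, and exact ties
(the definitionally proportional POB/DEN pair) are resolved by dropping
the earlier column so the decision is deterministic.

Selection then enforces three constraints on every retained term:
two-sided $t$-test $p < 0.05$, coefficient sign consistent with its
expected theoretical direction (`expected_signs()`; "either" for
predictors whose direction is genuinely ambiguous, e.g. residential
fraction, speed, meteorology — published models do contain sign
surprises), and a maximum VIF of 5 (published models report all VIF
below about 2, but state no threshold; 5 is a conventional cap,
configurable). Two modes are provided because the usual description —
"all the predictors are included in the model" and then assessed — is
ambiguous:

* `prune` (default): fit everything, iteratively drop the worst
  violator (wrong sign first, then weakest significance, then VIF
  above the cap, judged on the candidate model as VIFs are reported for
  final models), refit. Because an all-in fit with $p$ approaching $n$
  produces meaningless signs and p-values, the starting set is capped
  at $n/2$ columns ranked by correlation with the outcome.
* `forward`: supervised forward search in the style of the large
  European multi-city campaigns — add the predictor with the largest
  adjusted-$R^2$ gain among sign-consistent additions, stop when the
  gain falls below 0.01, then prune.

With 20-80 sites and a 60+ column catalogue the forward mode is the
statistically stable configuration (the working model never grows
beyond a handful of terms), and it is what the package's own
parameter-recovery study uses; the prune mode follows the all-in
wording literally and is retained for comparability. Selection is
deterministic: ties break by p-value and then column order.

## GWR and concentration surfaces

The selected equation is recalibrated locally by geographically
weighted regression: at each calibration site, weighted least squares
with distance-kernel weights (gaussian by default; bisquare available).
No bandwidth rule is prescribed by the usual descriptions, so the
default selects it by leave-one-out prediction error over a geometric
candidate grid; candidates within 0.5% of the minimum are ties resolved
toward the smoother bandwidth, so homogeneous data select the flattest
kernel offered. A bandwidth so small that some site has fewer effective
neighbours than parameters is an error naming the site.

Prediction builds the predictor table on a regular 200-m point mesh
anchored at the extent's lower-left corner, evaluates the model there
(globally for an OLS model; by kernel-weighted local calibration at
each mesh point for a GWR model — never nearest-site coefficient
copying; the choice is recorded in the output), and interpolates with
an exact thin-plate spline ($U(r) = r^2 \log r$ plus affine part, no
smoothing penalty, coordinates rescaled for conditioning), so the
raster reproduces the mesh values to interpolation accuracy. Buffers
that cross the city boundary use the clipped disc with area
renormalisation for fractions; lengths and populations are
used-as-observed.

## The synthetic-city generator

No campaign measurement data or municipal GIS layers are
redistributable, so verification rests on seeded synthetic cities with
known ground truth (`generate_city()`, `generate_sites()`,
`simulate_measurements()`):

* a 6 x 6 ... 7 x 7 km projected-metric extent (default 7 km), matching
  the sampling density of real campaigns — roughly 1-4 sites per km²,
  so that 500-m buffers of different sites rarely overlap;
* land use as a Voronoi partition of ~220 seeded parcels (~450 m
  across) with categories drawn from a fixed urban mix; categories
  partition the extent exactly, so fractions sum to 1 at any point;
* a jittered road grid: trunk and primary corridors on the coarse
  lattice tiers (every 8th and 4th line), minor lines split into ~500-m
  segments with secondary/tertiary/local class drawn per segment, as
  street class changes along real corridors — per-line classes would
  correlate buffer compositions citywide;
* population density by land-use category modulated by an independent
  block-scale log-normal field (wavelengths ~0.5-1.5 km, factor ~2
  variation), emulating the within-category heterogeneity of census
  data; altitude as a smooth long-wavelength surface with configurable
  relief;
* six meteorological stations observing temperature with a lapse rate
  on altitude, precipitation, humidity, wind direction and mean wind
  speed.

Measurements follow the study design: two campaigns (dry, rainy) of two
weekly values per site, weekly value = true-model prediction + campaign
offset + $N(0, v)$. The within-site weekly variance of real campaigns
is not published anywhere usable, so the weekly noise SD is an explicit
config value; the recovery study sets it to 10% of the signal SD.
Campaign offsets default to (+1, -1) µg/m³ so dry means sit above rainy
means, as observed in the field, while symmetric offsets cancel exactly
in the annual mean. All randomness flows from one integer seed through
`withr::with_seed`, leaving global RNG state untouched.

What the generator does **not** emulate: regional transport and
wildfire contributions, street-canyon dispersion, NO2 chemistry,
instrument error structure beyond i.i.d. Gaussian noise, and real
city geography. Passing recovery tests therefore demonstrate the
correctness of the pipeline's computations under the stated error
model, not the field performance of LUR in any particular city.

## The replicate studies

`recovery_experiment()` is the package's core evidence: 100 seeded
cities, 40 sites each, a fixed 3-term ground truth (population density
in the 500-m buffer, local-road length in the 500-m buffer, altitude —
one term from each of three predictor groups, with coefficient
magnitudes of the order seen in published models and comparable
per-term contributions), weekly noise at 10% of the signal SD, ten pure
noise predictors appended, and the full screening + forward-selection
pipeline run per replicate. A coefficient is *recovered* when its
predictor is selected and the generating value lies inside the fitted
95% confidence interval; recovery is reported per coefficient. (A joint
"all three inside their intervals simultaneously" statistic is bounded
near 0.86 for three independent 95% intervals and is therefore not a
meaningful target for any implementation; the per-coefficient rates are
the interpretable quantity.) Expected behaviour: each coefficient
recovered in well over 90% of replicates, and noise predictors entering
at no more than the nominal type-I rate.

`form_selection_experiment()` does the analogous study for the traffic
module: 100 seeded sets of 200 (density, speed) observations from a
known form with 2 km/h speed noise; the generating form should win the
out-of-bag RMSE comparison in at least 90% of replicates.

Problem sizes throughout (100 replicates, 40 sites, 200 observations,
25 bootstrap resamples in the studies, mesh spacing 200 m) are the
package's chosen study design, balancing the stability of the estimated
rates against the cost of exact geometry on replicated cities.

## Numerical choices and degenerate inputs

* Disc-polygon and disc-rectangle areas are closed-form; no disc
  rasterisation anywhere.
* The thin-plate spline system is solved in centred, rescaled
  coordinates via a LAPACK QR; at metre scale the raw system is
  numerically singular.
* Extents smaller than 1 km² (or thinner than twice the largest buffer
  radius) are rejected; a blob count of 0 produces a single residential
  polygon; spacing larger than the extent degenerates the mesh to the
  corners with a warning.
* Equation parsing accepts the printed dialect of published tables:
  optional "Ln (...)" prefix, ASCII or Unicode minus signs and
  multiplication signs, arbitrary spacing; serialisation emits
  canonical ASCII with round-trip-exact coefficient formatting.
* LOOCV holds the selected term set fixed (validating "the model", as
  stability reports do) and refits coefficients only; a `reselect`
  mode re-runs selection per fold for honesty analyses. CV $R^2$ is
  the squared Pearson correlation between observed values and left-out
  predictions on the concentration scale; the $1 - SSE/SST$ variant and
  both mean and sum squared error are also reported, labelled. The
  stability gap is reported as rounded integer percentage points,
  matching the published convention.

## Known limitations

* The prune selection mode undercovers slightly in small samples
  (post-selection inference); the forward mode is preferred at $n
  \le 40$.
* Log-scale RMSE values of log-transform models are reported on the
  modelled (log) scale and labelled as such; they are not comparable
  with identity-scale RMSEs.
* GWR standard errors are not computed; the module provides local
  coefficients and fit summaries, not inference on them.
* The generator's Voronoi land use cannot represent nested or
  non-convex parcels; fractions remain exact for what it does
  represent.
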