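---
title: "Methods: fire-attributable health burden and exposure equity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fire-attributable health burden and exposure equity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fireburden)
```

## Scope and data model

fireburden analyses *paired* gridded concentration fields: an
"all-sources" run and a "fires-off" run of the same atmospheric-chemistry
model on one regular latitude–longitude grid. Everything attributed to
fires is a difference between these two runs — the package never
apportions sources within a single field. The central containers are S4
classes with validity rules: `ConcentrationField` (nonnegative values on
a strictly increasing, constant-spacing grid), `ScenarioPair` (same
products in both scenarios, with all ≥ nofire enforced for particulate
species but deliberately *not* for ozone, since fire aerosol can suppress
photochemical ozone production), `PopulationGrid`, `IMRGrid` (0–200
deaths per 1,000 live births), `RegionMask` and `StationSeries`.

## Exposure metrics

Regridding is bilinear at target cell centres (`regridLinear`), with no
extrapolation; block means (`aggregateMeanToGrid`) are used where a finer
surface (such as the IMR raster) must be brought onto the analysis grid.
Regional exposure is summarised population-weighted
(`populationWeightedMean`, Σ C·P / Σ P), because the health calculation
weights people, not area; a cos-latitude area-weighted alternative exists
behind a flag (`regionalMean(areaWeight = TRUE)`) and is off by default.

Long-term ozone exposure is the ADM8h: per calendar day, the maximum of
the 17 running 8-hour means fully contained in the day (hours 0–23),
averaged over the year. Windows are confined within calendar days by
default — the simplest convention consistent with a "daily" maximum — and
a `crossDay` flag enables midnight-spanning windows for sensitivity
checks. A window containing a missing hour is skipped; a day without a
complete window is excluded; a cell with no valid day is missing. Every
metric over a mask ignores missing cells.

Threshold exceedance (`populationAboveThreshold`) uses a strict `>`,
reading "above" literally. Percentage change between scenarios is
100·(with − without)/with: the reduction realised when fires are removed,
missing where the with-fire value is zero.

## Health burden

The PM2.5 exposure–response is the GEMM curve

$$RR(z) = \exp\!\left\{\theta \,\log(1 + z/\alpha)\,
\frac{1}{1 + e^{-(z-\mu)/\nu}}\right\}, \qquad z = \max(0, c - c_f).$$

Coefficients are configuration inputs read from CSV, not package
constants. Two curve shapes are shipped because assessments in this
literature use either: the NCD+LRI aggregate (default in the demo) and
the 5-cause specification (IHD, stroke, COPD, lung cancer, LRI). The
counterfactual defaults to 2.4 µg m⁻³, the low-concentration cutoff of
the GEMM cohort pool, and is exposed in the parameter files. The ozone
response is log-linear, $RR = rr^{\max(0, x - \mathrm{tmrel})/10}$ per
10 ppbv of ADM8h; the example file carries 1.12 (1.08–1.16) with a TMREL
of 26.7 ppbv, and the TMREL deliberately lives in the file rather than in
code.

Burden per stratum is AF·rate·fraction·population summed over cells,
with AF = (RR − 1)/RR. Baseline rates may be supplied per region (the
usual case; broadcast to cells through the region masks) and must exist
for every region×cause×age-group combination — a missing combination is
a hard error naming the region. Fire attribution is the subtraction
method, M_FIRE = M_ALL − M_FIRE_OFF, per stratum. Negative differences
are retained rather than clipped: the subtraction is a plain difference,
and ozone burdens can legitimately fall when fires are added. DALYs
follow the same attributable-fraction scaling applied to baseline DALY
rates; no life-table modelling is attempted.

### Uncertainty

95% uncertainty intervals are propagated by Monte Carlo (default 1,000
draws, seeded) rather than endpoint arithmetic: θ (and log rr for ozone)
is drawn normal with its standard error, baseline rates lognormal matched
to their 95UIs, age fractions logit-normal matched to theirs. Three
design points matter:

1. **Draws are shared where the quantity is shared.** A curve coefficient
   is one global object, so its draws are common to all regions and to
   both scenarios; rate and fraction draws are independent per stratum.
   This makes the per-draw subtraction coherent and regional totals
   honestly correlated.
2. **Central estimates use central inputs**, not draw means, so they are
   invariant to the draw count.
3. **Aggregation sums draws, not endpoints.** Summing interval endpoints
   assumes perfect dependence and overstates group uncertainty; the
   per-draw sum respects the dependence actually induced by shared
   coefficients. The test suite checks the draw-aggregated interval is
   never wider than the endpoint sum.

Zero input uncertainty collapses the interval to the central estimate
exactly; identical seeds reproduce intervals bit-for-bit.

## Model evaluation

Fire-influenced stations are those whose grid cell has
(all − nofire)/all ≥ 0.20 in the simulated annual mean. The fire-derived
signal in a monthly series is the enhancement over that calendar year's
minimum non-missing month, each year treated independently; years with
fewer than two valid months are flagged missing, ties at the minimum need
no tie-break (the value, not the month, is subtracted), and the operation
is idempotent. The NMBF follows the symmetric definition: ΣM/ΣO − 1 when
the model mean is not below the observed mean, 1 − ΣO/ΣM otherwise, so
+x means overestimation by the factor x+1 and −x underestimation by the
factor 1−(−x). Station-to-cell sampling takes the containing cell;
multi-station composites are unweighted means across stations at each
timestamp. Metrics of a composite series generally differ from averaged
per-station metrics, so both modes are provided and neither is asserted
equal to the other.

## Poverty–exposure analysis

The poverty proxy is the gridded IMR, classed by the widely used
cutpoints 15/32/65/100 (not poor / moderately poor / poor / very poor).
All interval conventions are left-closed right-open, final bin closed —
applied uniformly to IMR classes, PM classes and histogram bins, which
also resolves the boundary value 32 appearing in two classes in some
published versions of the scheme.

Fig-8-style summaries bin *cell-level* PM by IMR (the quantity described
by such figures is the gridded value, not a person-weighted one); a
population-weighted variant of the bin means sits behind the `pop`
argument. The anomaly is the bin mean minus the unweighted mean of bin
means, so anomalies average to zero across occupied bins by construction.
Box statistics use quartiles with whiskers at 1.5×IQR.

The extreme-group comparison (defaults IMR ≤ 20 versus ≥ 60 at 99%
confidence) needs a two-sample test, and no canonical choice exists for
this comparison; the default is the unequal-variance Welch t-test, with a
seeded permutation test as an alternative. Groups with fewer than two
cells report means but no test, with a warning. The bivariate map crosses
IMR classes (0–20/20–60/60–100) with fire-PM classes (0–5/5–15/15–30
µg m⁻³); cells beyond a top edge are flagged and counted, not silently
assigned.

## Reporting

Regional groups sum member central estimates exactly and aggregate
uncertainty per draw (see above). Group exposure-reduction percentages
are recomputed from group-level population-weighted means, never averaged
over members. Rounding — nearest 100 for PM2.5 mortality and DALYs,
nearest 10 for ozone mortality, halves away from zero — is applied only
in presentation columns (`*_rounded`); machine-readable outputs keep the
unrounded values, and totals are rounded after summation, not before.
Region rules in the packaged demo are lat/lon boxes (quadrants);
polygon rules are supported via `polygonMask`. Where a published box rule
contains an evident sign typo ("east of 98°W" for a Southeast-Asian
subdomain), the packaged example uses the 98°E reading; the rule is
user-supplied either way.

Gridded products are written as long-format CSV with a JSON metadata
sidecar (species, temporal resolution, scenario, units, shape), station
series as CSV (station_id, lat, lon, date, observed, model_all,
model_nofire) and configurations as YAML; all round-trip losslessly.
This keeps every artifact plain text and diffable.

## The synthetic generator

`syntheticConfig()` declares a complete study; its defaults are the demo
conditions used throughout the documentation and tests: a 40×40 cell
0.25° domain (10–20°N, 95–105°E), a 12-month year with a January–May
fire season peaking in March, two Gaussian fire plumes (peak-month
centre amplitudes 75 and 40 µg m⁻³ PM2.5, decay lengths 250 and 300 km)
over a smooth background of mean 18 µg m⁻³, a PM10/PM2.5 ratio of 1.7
for the background and 1.15 for the fire contribution, daily-max-8h
ozone of ~38 ppbv background with an 8 ppbv in-season fire enhancement,
80 million people in five Gaussian clusters, and monitoring stations
whose observations are the sampled model times a 1.1 multiplicative bias
plus additive noise. These magnitudes are chosen so the fire-derived
annual PM2.5 spans the 0–30 µg m⁻³ classification range, monthly
fire-derived PM10 at fire-influenced stations peaks in the tens of
µg m⁻³, and the IMR surface (base 30, coupling 3 IMR-units per µg m⁻³ of
annual fire PM2.5, Gaussian noise SD 12, clipped to [0, 100]) spans the
full poverty scheme with poorer cells preferentially under the plumes —
the disparity structure the equity analysis exists to detect. Setting
the coupling to 0 severs that association, which is how the type-I-error
calibration of the extreme-group test is run (500 replicate IMR surfaces
with noise SD 20 so both extreme classes are well populated).

Construction guarantees, all tested: the all-sources field equals the
fires-off field plus a nonnegative fire contribution that is zero
outside the fire season (triangular in time, weight 1 at the peak
month); annual means equal the mean of the 12 monthly fields; noise is
multiplicative lognormal for concentrations (preserving positivity and
the scenario ordering, since the background and the fire term are
perturbed and then added) and additive Gaussian with clipping for IMR;
each product draws from its own stream derived from the master seed by a
fixed offset, so adding a product never perturbs the others, and a fixed
seed is bit-reproducible. An auxiliary hourly ozone generator emits an
hourly field together with daily maxima computed by exhaustive window
scan, as an independent check on the ADM8h operation.

What the generator does **not** emulate: meteorology, chemistry and
emission inventories (plumes are stationary Gaussians, not transported
smoke); spatially correlated noise; interannual variability (one year
only); population–pollution co-location beyond what clustering produces
by chance; and any toxicity difference between fire and nonfire PM2.5.
Consequently, passing tests demonstrate the *correctness of the
analysis machinery* under known ground truth — conservation,
identities, calibration, parameter recovery — not the realism of any
particular burden number; the demo's absolute mortality figures are
properties of the synthetic configuration, not predictions.

## Numerical choices and degenerate inputs

- Grid alignment checks use `all.equal` tolerances; coordinate spacing
  must be constant to 1e-6 relative.
- The annual-mean identity of the generator holds to 1e-9 relative; the
  hourly/daily ADM8h consistency likewise.
- Welch's statistic and quantiles come from `stats`; quantiles are type
  7 (R default).
- Zero population under a mask, zero-variance observed series,
  zero-sum NMBF inputs, empty poverty classes and empty IMR overlap all
  raise explicit errors or warnings rather than returning NaN.
- RR below 1 (possible under sampled θ < 0) yields a negative AF with a
  warning in the user-facing function and is retained in Monte-Carlo
  draws.
- Problem sizes in the shipped tests and demo — 40×40 cells, 12 months,
  365-day ozone, 12 stations, 1,000 draws, 500 calibration replicates —
  were chosen as the smallest sizes at which every statistical property
  under test is comfortably resolved.

## Limitations

The package deliberately stops at the analysis layer: it does not run or
emulate the atmospheric model, build emission inventories, or handle map
projections beyond regular lat-lon grids (no conservative regridding).
Baseline-rate and exposure-response files ship as *examples* with
literature-typical magnitudes; any real assessment must substitute its
own vetted inputs. The equity analysis is descriptive — exposure
disparity across a poverty proxy — and supports no causal claims.
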