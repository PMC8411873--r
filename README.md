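# fireburden

Landscape fires degrade air quality across whole regions, and the
question policy-makers ask — *how many premature deaths would be averted
if fire emissions stopped, and who bears the exposure?* — cannot be read
off a concentration map. **fireburden** is an R package for the
post-simulation half of that assessment. It takes paired gridded
concentration fields from an atmospheric-chemistry model — one run with
all emission sources, one with fire emissions switched off — and
computes:

- **exposure metrics**: bilinear regridding, population-weighted annual
  means, annual average daily-maximum-8-h (ADM8h) ozone, percentage
  changes between scenarios, and populations above WHO thresholds
  (10 and 25 µg m⁻³ annual PM2.5);
- **health burdens**: cause-specific attributable mortality and DALYs
  from PM2.5 via the Global Exposure Mortality Model (GEMM) and from
  ozone via a log-linear exposure-response, attributed to fires by the
  scenario-subtraction method, with Monte-Carlo 95% uncertainty
  intervals;
- **model evaluation**: fire-influenced station selection, per-year
  fire-derived PM isolation, the normalized mean bias factor (NMBF),
  Pearson correlation and normalized standard deviation;
- **exposure equity**: gridded infant mortality rate (IMR) as a poverty
  proxy — exposure distributions binned by IMR, extreme-group
  comparisons at a stated confidence level, fire/nonfire source shares
  per poverty class, and a 3×3 bivariate poverty × exposure map.

A seeded synthetic-data generator emulates the whole input stack
(scenario pairs with a January–May fire season peaking in March,
clustered population, baseline health rates, an IMR surface with
configurable coupling to fire PM, noisy monitoring stations), so every
stage is testable with known ground truth and the package runs with no
external data.

## The model at the core

For a cell with annual-mean PM2.5 concentration *c*, the GEMM relative
risk is

```
RR(z) = exp{ θ · log(1 + z/α) / (1 + exp(−(z − μ)/ν)) },   z = max(0, c − c_f)
```

with cause-specific coefficients (θ, α, μ, ν) and counterfactual
concentration *c_f* (2.4 µg m⁻³ in the packaged files). The population
attributable fraction is AF = (RR − 1)/RR, and the burden in a stratum
(region × cause × age group) is

```
M = Σ_cells AF(RR(c_cell)) · P_cell · baseline_rate · age_fraction
```

Fire-attributable burden uses the subtraction method,
`M_FIRE = M_ALL − M_FIRE_OFF`, evaluated per stratum and per
Monte-Carlo draw. Ozone burdens use `RR = rr^(max(0, ADM8h − TMREL)/10)`
with the packaged example response of 1.12 (95% CI 1.08–1.16) per
10 ppbv. The 95UIs propagate coefficient uncertainty (normal), baseline
rate uncertainty (lognormal matched to the 95UI) and age-fraction
uncertainty (logit-normal) through the full calculation; regional totals
aggregate per-draw samples, never interval endpoints.

## Worked example

```r
library(fireburden)

cfg <- syntheticConfig()                 # 40 x 40 demo study, seed 42
res <- runPipeline(cfg, "demo_out")      # generate -> ... -> report
res$summary[, c("region", "pm25_exposure_reduction_pct",
                "pm25_burden_reduction_pct", "pm25_mortality",
                "mortality_per_100k")]
```

```
  region pm25_exposure_reduction_pct pm25_burden_reduction_pct pm25_mortality mortality_per_100k
1     NW                        46.8                      32.3         3579.3               29.1
2     NE                        39.5                      26.6         2519.1               20.3
3     SW                        12.8                       8.0         1405.6                5.5
4     SE                        23.0                      14.9         3093.9               10.4
5  TOTAL                        27.2                      18.0        10597.9               13.2
```

Removing fires cuts the population-weighted PM2.5 exposure of the
north-western quadrant (where the synthetic plumes sit) by 46.8% and its
attributable mortality by 32.3% — the burden responds less than
proportionally because the exposure-response is concave at these
concentrations. The domain total of ~10,600 averted deaths per year
(95UI 8,500–12,700 in `pm25_mortality_low/high`) carries a per-capita
rate of 13.2 per 100,000. The station composite evaluates at
NMBF = −0.15 (the model underestimates observed fire-derived PM10 by a
factor 1.15, by construction of the demo's station bias) with
r² = 0.999. On the equity side, cells with IMR ≥ 60 see a mean
fire-derived PM2.5 of 12.5 µg m⁻³ against 1.8 µg m⁻³ for IMR ≤ 20
(Welch p ≈ 4×10⁻⁵⁹), and fire smoke supplies 43% of the total PM2.5
exposure of the "very poor" class versus 10% for "not poor" — the
generator's default coupling encodes exactly this disparity structure.

Single pieces are usable on their own, e.g.

```r
rr <- gemmRelativeRisk(35, theta = 0.143, alpha = 1.6, mu = 15.5,
                       nu = 36.8, cf = 2.4)   # 1.3086
attributableFraction(rr)                      # 0.2358
nmbf(model = c(20, 40), observed = c(40, 80)) # -1: factor-2 underestimate
```

## Layout

- `R/` — S4 classes (`ConcentrationField`, `ScenarioPair`,
  `PopulationGrid`, `IMRGrid`, `RegionMask`, `StationSeries`, parameter
  and result containers) and the five analysis stages.
- `inst/extdata/` — GEMM coefficient files (NCD+LRI aggregate and
  5-cause), an example ozone response YAML, and a small published-table
  example used by the aggregation worked example.
- `vignettes/methods.Rmd` — the model, its assumptions, what the
  synthetic generator does and does not emulate, and the numerical
  choices.
- `tests/testthat/` — unit, property and end-to-end suites; all
  fixtures are generated in code.
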