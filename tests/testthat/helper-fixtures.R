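# Shared fixtures: everything is generated in code, nothing on disk.

# small 10 x 10 domain for fast tests
smallConfig <- function(..., seed = 7L) {
  syntheticConfig(latRange = c(10, 15), lonRange = c(100, 105),
                  resolution = 0.5, seed = seed, ...)
}

# noise-free variant for exact construction checks
quietNoise <- function(bias = 1.0)
  list(concSDLog = 0, stationBias = bias, stationNoiseSD = 0)

# simple annual field on an n x n grid
constantField <- function(value, n = 4L, species = "PM2.5",
                          scenario = "all") {
  ConcentrationField(matrix(value, n, n), lat = seq_len(n),
                     lon = seq_len(n), species = species,
                     temporal = "annual", scenario = scenario)
}

uniformPop <- function(perCell, n = 4L)
  PopulationGrid(matrix(perCell, n, n), lat = seq_len(n), lon = seq_len(n))

wholeMask <- function(n = 4L, name = "ALL")
  RegionMask(name, matrix(TRUE, n, n), lat = seq_len(n), lon = seq_len(n))

# GEMM parameter row whose log-RR basis is exactly 1 at conc = exp(1) - 1:
# logistic weight ~ 1 (mu very negative), alpha = 1, cf = 0, so
# RR(exp(1) - 1) = exp(theta) exactly
unitBasisGEMM <- function(theta, theta_se = 0) {
  GEMMParameters(data.frame(
    cause = "ncd_lri", age_group = "25plus", theta = theta,
    theta_se = theta_se, alpha = 1, mu = -1e3, nu = 1, cf = 0))
}

# one-region baseline with explicit rate / fraction and optional UIs
flatBaseline <- function(region = "ALL", cause = "ncd_lri",
                         mort = 0.01, daly = 0.1, frac = 1,
                         relUI = 0) {
  BaselineHealthData(data.frame(
    region = region, cause = cause, age_group = "25plus",
    mort_rate = mort, mort_low = mort * (1 - relUI),
    mort_high = mort * (1 + relUI),
    daly_rate = daly, daly_low = daly * (1 - relUI),
    daly_high = daly * (1 + relUI),
    age_fraction = frac,
    frac_low = max(0, frac - relUI * frac),
    frac_high = min(1, frac + relUI * frac)))
}

# direct single-expression evaluation of the GEMM curve, kept independent
# of the package implementation
gemmOracle <- function(conc, theta, alpha, mu, nu, cf) {
  z <- pmax(0, conc - cf)
  exp(theta * log(1 + z / alpha) * (1 / (1 + exp(-(z - mu) / nu))))
}

# direct evaluation of the normalized mean bias factor definition
nmbfOracle <- function(m, o) {
  if (mean(m) >= mean(o)) sum(m) / sum(o) - 1 else 1 - sum(o) / sum(m)
}
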