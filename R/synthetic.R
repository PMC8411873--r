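## Synthetic study generator: paired scenario fields, population, IMR
## surface and station series with known ground truth.

## fixed offsets deriving one RNG stream per product from the master seed
.STREAM <- c(scenario = 101L, population = 202L, imr = 303L,
             stations = 404L, hourly = 505L)

.monthDays <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

.gridCenters <- function(config) {
  d <- config@domain; res <- config@resolution
  list(lat = seq(d[1] + res / 2, d[2] - res / 2, by = res),
       lon = seq(d[3] + res / 2, d[4] - res / 2, by = res))
}

## triangular temporal weight over the fire season, 1 at the peak month,
## decaying linearly to a positive value at the season edges, 0 outside
.fireSeasonWeight <- function(config) {
  w <- numeric(config@nMonths)
  L <- max(abs(config@fireSeason - config@peakMonth))
  w[config@fireSeason] <- 1 - abs(config@fireSeason - config@peakMonth) /
    (L + 1)
  w
}

## Gaussian plume superposition at peak-month amplitude, matrix [lat, lon]
.plumeField <- function(config, lat, lon) {
  f <- matrix(0, length(lat), length(lon))
  if (!nrow(config@plumes)) return(f)
  pts <- cbind(rep(lon, each = length(lat)), rep(lat, length(lon)))
  for (i in seq_len(nrow(config@plumes))) {
    p <- config@plumes[i, ]
    dKm <- geosphere::distHaversine(pts, c(p$lon, p$lat)) / 1000
    f <- f + p$amplitude * exp(-0.5 * (dKm / p$decayKm)^2)
  }
  f
}

.backgroundField <- function(config, lat, lon) {
  b <- config@background
  latFrac <- (lat - mean(range(lat))) / diff(range(config@domain[1:2]))
  lonFrac <- (lon - mean(range(lon))) / diff(range(config@domain[3:4]))
  pmax(config@background$mean + outer(b$latGradient * latFrac,
                                      b$lonGradient * lonFrac, `+`), 0.1)
}

#' Default synthetic study configuration
#'
#' The defaults emulate a mainland Southeast-Asia-like study year on a
#' 40 x 40 cell 0.25-degree grid: a January-May fire season peaking in
#' March, two Gaussian fire plumes over a smooth polluted background,
#' clustered population, GBD-style baseline rates for four quadrant
#' regions, and an IMR surface positively coupled to local fire-derived
#' PM2.5 (poorer areas sit closer to the burning).
#'
#' @param latRange,lonRange domain bounds, degrees.
#' @param resolution grid spacing, degrees (default 0.25).
#' @param fireSeason,peakMonth fire-season months and the peak month.
#' @param plumes data.frame(lat, lon, amplitude, decayKm).
#' @param background list(mean, latGradient, lonGradient), ug m-3.
#' @param pm10Ratio list(background, fire) PM10/PM2.5 ratios.
#' @param ozone list(background, seasonalAmplitude, fireEnhancement), ppbv.
#' @param population list(total, nClusters, clusterDecayKm, uniformFloor).
#' @param baseline baseline rate table; default \code{\link{defaultBaseline}}.
#' @param imr list(base, coupling, noiseSD).
#' @param noise list(concSDLog, stationBias, stationNoiseSD).
#' @param seed master seed.
#' @return A validated \code{\link{SyntheticConfig}}.
#' @export
syntheticConfig <- function(latRange = c(10, 20), lonRange = c(95, 105),
                            resolution = 0.25,
                            fireSeason = 1:5, peakMonth = 3L,
                            plumes = data.frame(
                              lat = c(17.5, 14.0), lon = c(99.0, 103.5),
                              amplitude = c(75, 40), decayKm = c(250, 300)),
                            background = list(mean = 18, latGradient = -6,
                                              lonGradient = 4),
                            pm10Ratio = list(background = 1.7, fire = 1.15),
                            ozone = list(background = 38,
                                         seasonalAmplitude = 6,
                                         fireEnhancement = 8),
                            population = list(total = 8e7, nClusters = 5L,
                                              clusterDecayKm = 150,
                                              uniformFloor = 0.2),
                            baseline = defaultBaseline(),
                            imr = list(base = 30, coupling = 3,
                                       noiseSD = 12),
                            noise = list(concSDLog = 0.08,
                                         stationBias = 1.1,
                                         stationNoiseSD = 2),
                            seed = 42L) {
  new("SyntheticConfig",
      domain = c(latRange, lonRange), resolution = resolution,
      nMonths = 12L, fireSeason = as.integer(fireSeason),
      peakMonth = as.integer(peakMonth), plumes = plumes,
      background = background, pm10Ratio = pm10Ratio, ozone = ozone,
      population = population, baseline = baseline, imr = imr,
      noise = noise, seed = as.integer(seed))
}

#' Generate a matched all-sources / fires-off scenario pair
#'
#' Constructs monthly PM2.5 and PM10 fields, annual-mean PM2.5, and a
#' year of daily-maximum-8-h ozone for both scenarios. The all-sources
#' field equals the fires-off field plus a nonnegative fire contribution
#' that is zero outside the fire-season months; the annual mean equals the
#' arithmetic mean of the 12 monthly fields. Multiplicative lognormal noise
#' (SD \code{noise$concSDLog} on the log scale) perturbs the background and
#' the fire contribution independently while preserving positivity and the
#' all >= nofire ordering.
#'
#' @param config a \code{\link{SyntheticConfig}}.
#' @return A \code{\link{ScenarioPair}} with products \code{pm25_monthly},
#'   \code{pm25_annual}, \code{pm10_monthly}, \code{o3_dm8h}.
#' @export
generateScenarioPair <- function(config) {
  g <- .gridCenters(config)
  nlat <- length(g$lat); nlon <- length(g$lon); nm <- config@nMonths
  set.seed(config@seed + .STREAM[["scenario"]])

  bg <- .backgroundField(config, g$lat, g$lon)
  plume <- .plumeField(config, g$lat, g$lon)
  wMonth <- .fireSeasonWeight(config)
  sdl <- config@noise$concSDLog

  noiseM <- function() {
    if (sdl == 0) array(1, c(nlat, nlon, nm))
    else array(exp(stats::rnorm(nlat * nlon * nm, 0, sdl)),
               c(nlat, nlon, nm))
  }
  nzBg <- noiseM(); nzFire <- noiseM()
  pm25NoFire <- array(bg, c(nlat, nlon, nm)) * nzBg
  fire25 <- outer(plume, wMonth) * nzFire
  pm25All <- pm25NoFire + fire25

  mkF <- function(v, sp, tres, scen)
    ConcentrationField(v, g$lat, g$lon, sp, tres, scen)
  annual <- function(a) apply(a, c(1, 2), mean)

  rB <- config@pm10Ratio$background; rF <- config@pm10Ratio$fire
  pm10NoFire <- pm25NoFire * rB
  pm10All <- pm10NoFire + fire25 * rF

  ## ozone: smooth seasonal background plus an in-season enhancement that
  ## follows the normalised plume shape; generated directly as daily max-8h
  nd <- sum(.monthDays)
  dayMonth <- rep(seq_len(12L), .monthDays)
  o3cfg <- config@ozone
  dayBg <- o3cfg$background +
    o3cfg$seasonalAmplitude * sin(2 * pi * (seq_len(nd) - 80) / nd)
  shape <- if (max(plume) > 0) plume / max(plume) else plume
  o3NoFire <- array(rep(1, nlat * nlon), c(nlat, nlon, nd)) *
    rep(dayBg, each = nlat * nlon)
  o3Fire <- outer(shape * o3cfg$fireEnhancement, wMonth[dayMonth])
  o3All <- pmax(o3NoFire + o3Fire, 0)
  o3NoFire <- pmax(o3NoFire, 0)

  ScenarioPair(
    all = list(
      pm25_monthly = mkF(pm25All, "PM2.5", "monthly", "all"),
      pm25_annual  = mkF(annual(pm25All), "PM2.5", "annual", "all"),
      pm10_monthly = mkF(pm10All, "PM10", "monthly", "all"),
      o3_dm8h      = mkF(o3All, "O3", "daily", "all")),
    nofire = list(
      pm25_monthly = mkF(pm25NoFire, "PM2.5", "monthly", "nofire"),
      pm25_annual  = mkF(annual(pm25NoFire), "PM2.5", "annual", "nofire"),
      pm10_monthly = mkF(pm10NoFire, "PM10", "monthly", "nofire"),
      o3_dm8h      = mkF(o3NoFire, "O3", "daily", "nofire")),
    lat = g$lat, lon = g$lon)
}

#' Generate a clustered synthetic population grid
#'
#' Population density is a uniform floor plus Gaussian kernels around
#' randomly placed cluster centres, rescaled so the grid sums exactly to
#' the configured total (zero total gives an all-zero grid).
#'
#' @param config a \code{\link{SyntheticConfig}}.
#' @return A \code{\link{PopulationGrid}}.
#' @export
generatePopulation <- function(config) {
  g <- .gridCenters(config)
  nlat <- length(g$lat); nlon <- length(g$lon)
  set.seed(config@seed + .STREAM[["population"]])
  p <- config@population
  dens <- matrix(p$uniformFloor, nlat, nlon)
  if (p$nClusters > 0) {
    cLat <- stats::runif(p$nClusters, config@domain[1], config@domain[2])
    cLon <- stats::runif(p$nClusters, config@domain[3], config@domain[4])
    pts <- cbind(rep(g$lon, each = nlat), rep(g$lat, nlon))
    for (i in seq_len(p$nClusters)) {
      dKm <- geosphere::distHaversine(pts, c(cLon[i], cLat[i])) / 1000
      dens <- dens + exp(-0.5 * (dKm / p$clusterDecayKm)^2)
    }
  }
  counts <- if (p$total > 0) p$total * dens / sum(dens)
            else matrix(0, nlat, nlon)
  PopulationGrid(counts, g$lat, g$lon)
}

#' Generate an IMR poverty-proxy surface coupled to fire PM
#'
#' IMR = base + coupling x fire PM2.5 + Gaussian noise, clipped to
#' \code{[0, 100]}. A positive coupling makes poorer cells (higher IMR)
#' coincide with fire-exposed cells, the exposure-disparity structure the
#' equity analysis is designed to detect; coupling 0 decouples them.
#'
#' @param config a \code{\link{SyntheticConfig}}.
#' @param firePM annual fire-derived PM2.5 as a
#'   \code{\link{ConcentrationField}} on the same grid (see
#'   \code{\link{fireContribution}}).
#' @return An \code{\link{IMRGrid}}.
#' @export
generateIMRGrid <- function(config, firePM) {
  g <- .gridCenters(config)
  if (!isTRUE(all.equal(firePM@lat, g$lat)) ||
      !isTRUE(all.equal(firePM@lon, g$lon)))
    stop("alignment error: fire PM field is not on the configured grid")
  fv <- fieldValues(firePM)
  if (length(dim(fv)) == 3L) fv <- apply(fv, c(1, 2), mean)
  set.seed(config@seed + .STREAM[["imr"]])
  im <- config@imr
  noise <- if (im$noiseSD > 0)
    matrix(stats::rnorm(length(fv), 0, im$noiseSD), nrow(fv)) else 0
  vals <- pmin(pmax(im$base + im$coupling * fv + noise, 0), 100)
  IMRGrid(matrix(vals, nrow(fv)), g$lat, g$lon,
          provenance = "synthetic: base + coupling * fire PM2.5 + noise")
}

#' Generate synthetic monitoring-station series
#'
#' Stations are placed at random cell centres inside the domain. Observed
#' monthly PM10 is the sampled all-sources model series times a
#' multiplicative bias plus additive Gaussian noise (clipped at zero);
#' model series for both scenarios are sampled at the station cell and the
#' true fire fraction of the annual mean is recorded as metadata.
#'
#' @param config a \code{\link{SyntheticConfig}}.
#' @param pair a \code{\link{ScenarioPair}} with a \code{pm10_monthly}
#'   product.
#' @param nStations number of stations (>= 1).
#' @return A list of \code{\link{StationSeries}}.
#' @export
generateStationSeries <- function(config, pair, nStations = 12L) {
  if (nStations < 1L) stop("nStations must be >= 1")
  g <- .gridCenters(config)
  set.seed(config@seed + .STREAM[["stations"]])
  iLat <- sample.int(length(g$lat), nStations, replace = TRUE)
  iLon <- sample.int(length(g$lon), nStations, replace = TRUE)
  allV <- fieldValues(scenarioField(pair, "pm10_monthly", "all"))
  nofV <- fieldValues(scenarioField(pair, "pm10_monthly", "nofire"))
  bias <- config@noise$stationBias
  nsd <- config@noise$stationNoiseSD
  dates <- as.Date(sprintf("2014-%02d-01", seq_len(config@nMonths)))
  lapply(seq_len(nStations), function(k) {
    mAll <- allV[iLat[k], iLon[k], ]
    mNof <- nofV[iLat[k], iLon[k], ]
    obs <- bias * mAll +
      if (nsd > 0) stats::rnorm(length(mAll), 0, nsd) else 0
    ff <- (mean(mAll) - mean(mNof)) / mean(mAll)
    StationSeries(
      id = sprintf("ST%02d", k), lat = g$lat[iLat[k]], lon = g$lon[iLon[k]],
      species = "PM10",
      data = data.frame(time = dates, observed = pmax(obs, 0),
                        model_all = mAll, model_nofire = mNof),
      fireFraction = ff)
  })
}

#' Generate a short hourly ozone record plus its daily max-8h product
#'
#' A testing aid for the ADM8h operation: emits an hourly ozone field with
#' a smooth diurnal cycle and, alongside it, the daily maximum 8-h means
#' computed by a direct exhaustive scan over the 17 in-day windows.
#'
#' @param config a \code{\link{SyntheticConfig}}.
#' @param nDays number of days to emit.
#' @return list(hourly = ConcentrationField, dm8h = ConcentrationField).
#' @export
generateHourlyO3 <- function(config, nDays = 5L) {
  g <- .gridCenters(config)
  nlat <- length(g$lat); nlon <- length(g$lon)
  set.seed(config@seed + .STREAM[["hourly"]])
  base <- config@ozone$background
  amp <- matrix(stats::runif(nlat * nlon, 0.3, 0.7) * base, nlat, nlon)
  hours <- seq_len(24L * nDays) - 1L
  diurnal <- pmax(sin(pi * ((hours %% 24) - 6) / 14), 0) # daytime bump
  hourly <- array(0, c(nlat, nlon, length(hours)))
  for (h in seq_along(hours))
    hourly[, , h] <- base * 0.6 + amp * diurnal[h]
  dm8h <- array(NA_real_, c(nlat, nlon, nDays))
  for (d in seq_len(nDays)) {
    day <- hourly[, , (d - 1L) * 24L + seq_len(24L), drop = FALSE]
    best <- array(-Inf, c(nlat, nlon))
    for (s in seq_len(17L)) { # windows starting hours 0..16
      wm <- apply(day[, , s:(s + 7L), drop = FALSE], c(1, 2), mean)
      best <- pmax(best, wm)
    }
    dm8h[, , d] <- best
  }
  list(hourly = ConcentrationField(hourly, g$lat, g$lon, "O3", "hourly",
                                   "all"),
       dm8h = ConcentrationField(dm8h, g$lat, g$lon, "O3", "daily", "all"))
}
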