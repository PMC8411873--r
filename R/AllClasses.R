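## Core S4 containers for the fire air-quality / health-burden pipeline.

.SPECIES <- c("PM2.5", "PM10", "O3")
.TEMPORAL <- c("hourly", "daily", "monthly", "annual")
.SCENARIOS <- c("all", "nofire", "fire", "unspecified")

.checkGrid <- function(lat, lon) {
  msg <- character()
  for (nm in c("lat", "lon")) {
    v <- if (nm == "lat") lat else lon
    if (length(v) < 1L || anyNA(v))
      msg <- c(msg, sprintf("'%s' must be non-empty and finite", nm))
    else if (length(v) > 1L) {
      d <- diff(v)
      if (any(d <= 0))
        msg <- c(msg, sprintf("'%s' coordinates must be strictly increasing", nm))
      else if (diff(range(d)) > 1e-6 * mean(d))
        msg <- c(msg, sprintf("'%s' spacing must be constant", nm))
    }
  }
  msg
}

#' Gridded concentration field
#'
#' A regular latitude-longitude field of a pollutant concentration, either a
#' single 2-D slice (e.g. an annual mean) or a lat x lon x time array
#' (hourly, daily or monthly slices). Units are ug m-3 for particulate
#' species and ppbv for ozone.
#'
#' @slot values numeric matrix \code{[lat, lon]} or array
#'   \code{[lat, lon, time]}; nonnegative or \code{NA} (missing).
#' @slot lat,lon cell-centre coordinates in degrees, strictly increasing with
#'   constant spacing.
#' @slot species one of \code{"PM2.5"}, \code{"PM10"}, \code{"O3"}.
#' @slot temporal one of \code{"hourly"}, \code{"daily"}, \code{"monthly"},
#'   \code{"annual"}.
#' @slot scenario one of \code{"all"}, \code{"nofire"}, \code{"fire"},
#'   \code{"unspecified"}.
#' @exportClass ConcentrationField
setClass("ConcentrationField",
  slots = c(values = "array", lat = "numeric", lon = "numeric",
            species = "character", temporal = "character",
            scenario = "character"))

setValidity("ConcentrationField", function(object) {
  msg <- .checkGrid(object@lat, object@lon)
  d <- dim(object@values)
  if (!length(d) %in% c(2L, 3L))
    msg <- c(msg, "'values' must be a 2-D matrix or 3-D array")
  else if (d[1L] != length(object@lat) || d[2L] != length(object@lon))
    msg <- c(msg, "dim(values)[1:2] must match length(lat), length(lon)")
  if (!object@species %in% .SPECIES)
    msg <- c(msg, sprintf("'species' must be one of: %s",
                          paste(.SPECIES, collapse = ", ")))
  if (!object@temporal %in% .TEMPORAL)
    msg <- c(msg, sprintf("'temporal' must be one of: %s",
                          paste(.TEMPORAL, collapse = ", ")))
  if (!object@scenario %in% .SCENARIOS)
    msg <- c(msg, sprintf("'scenario' must be one of: %s",
                          paste(.SCENARIOS, collapse = ", ")))
  v <- object@values
  if (any(v < 0, na.rm = TRUE))
    msg <- c(msg, "'values' must be nonnegative or NA")
  if (length(msg)) msg else TRUE
})

#' @param values,lat,lon,species,temporal,scenario see slot descriptions.
#' @return A \code{ConcentrationField} object.
#' @rdname ConcentrationField-class
#' @export
ConcentrationField <- function(values, lat, lon, species,
                               temporal, scenario = "unspecified") {
  if (is.matrix(values)) values <- array(values, dim = dim(values))
  new("ConcentrationField", values = values, lat = as.numeric(lat),
      lon = as.numeric(lon), species = species, temporal = temporal,
      scenario = scenario)
}

#' Matched all-sources / fires-off scenario fields
#'
#' The pipeline's central input: gridded concentration products from two
#' model runs that differ only in whether fire emissions are included.
#' Products share one analysis grid; for particulate products the
#' all-sources field is everywhere >= the fires-off field (the fire
#' contribution is nonnegative). Ozone is exempt from that constraint
#' because fire aerosol can suppress photochemical ozone production.
#'
#' @slot all,nofire named lists of \code{\link{ConcentrationField}} objects,
#'   same names in both (e.g. \code{pm25_monthly}, \code{pm25_annual},
#'   \code{pm10_monthly}, \code{o3_dm8h}).
#' @slot lat,lon the shared analysis grid.
#' @exportClass ScenarioPair
setClass("ScenarioPair",
  slots = c(all = "list", nofire = "list", lat = "numeric", lon = "numeric"))

setValidity("ScenarioPair", function(object) {
  msg <- .checkGrid(object@lat, object@lon)
  if (!identical(sort(names(object@all)), sort(names(object@nofire))))
    msg <- c(msg, "'all' and 'nofire' must hold the same product names")
  for (nm in names(object@all)) {
    fa <- object@all[[nm]]; fn <- object@nofire[[nm]]
    if (!is(fa, "ConcentrationField") || !is(fn, "ConcentrationField")) {
      msg <- c(msg, sprintf("product '%s' is not a ConcentrationField", nm))
      next
    }
    if (!isTRUE(all.equal(fa@lat, object@lat)) ||
        !isTRUE(all.equal(fa@lon, object@lon)))
      msg <- c(msg, sprintf("product '%s' is not on the pair grid", nm))
    if (!identical(dim(fa@values), dim(fn@values)))
      msg <- c(msg, sprintf("product '%s': scenario dims differ", nm))
    else if (fa@species %in% c("PM2.5", "PM10")) {
      diffs <- fa@values - fn@values
      if (any(diffs < -1e-9, na.rm = TRUE))
        msg <- c(msg, sprintf(
          "product '%s': all-sources field below fires-off field", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param all,nofire,lat,lon see slot descriptions.
#' @return A \code{ScenarioPair}.
#' @rdname ScenarioPair-class
#' @export
ScenarioPair <- function(all, nofire, lat, lon) {
  new("ScenarioPair", all = all, nofire = nofire,
      lat = as.numeric(lat), lon = as.numeric(lon))
}

#' Gridded population counts
#'
#' @slot counts persons per grid cell (nonnegative, finite).
#' @slot lat,lon the analysis grid.
#' @exportClass PopulationGrid
setClass("PopulationGrid",
  slots = c(counts = "matrix", lat = "numeric", lon = "numeric"))

setValidity("PopulationGrid", function(object) {
  msg <- .checkGrid(object@lat, object@lon)
  if (nrow(object@counts) != length(object@lat) ||
      ncol(object@counts) != length(object@lon))
    msg <- c(msg, "dim(counts) must match grid")
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    msg <- c(msg, "'counts' must be finite and nonnegative")
  if (length(msg)) msg else TRUE
})

#' @param counts,lat,lon see slot descriptions.
#' @rdname PopulationGrid-class
#' @export
PopulationGrid <- function(counts, lat, lon)
  new("PopulationGrid", counts = counts, lat = as.numeric(lat),
      lon = as.numeric(lon))

#' Gridded infant mortality rate (poverty proxy)
#'
#' Infant deaths before age one per 1,000 live births, used as a subnational
#' poverty proxy.
#'
#' @slot values IMR per cell, in \code{[0, 200]} or \code{NA}.
#' @slot lat,lon the analysis grid.
#' @slot provenance free-text note on where the surface came from.
#' @exportClass IMRGrid
setClass("IMRGrid",
  slots = c(values = "matrix", lat = "numeric", lon = "numeric",
            provenance = "character"))

setValidity("IMRGrid", function(object) {
  msg <- .checkGrid(object@lat, object@lon)
  if (nrow(object@values) != length(object@lat) ||
      ncol(object@values) != length(object@lon))
    msg <- c(msg, "dim(values) must match grid")
  if (any(object@values < 0 | object@values > 200, na.rm = TRUE))
    msg <- c(msg, "IMR values must lie in [0, 200] or be NA")
  if (length(msg)) msg else TRUE
})

#' @param values,lat,lon,provenance see slot descriptions.
#' @rdname IMRGrid-class
#' @export
IMRGrid <- function(values, lat, lon, provenance = "synthetic")
  new("IMRGrid", values = values, lat = as.numeric(lat),
      lon = as.numeric(lon), provenance = provenance)

#' Named region membership mask on the analysis grid
#'
#' @slot name region name.
#' @slot mask logical membership matrix \code{[lat, lon]}; at least one cell.
#' @slot lat,lon the analysis grid.
#' @exportClass RegionMask
setClass("RegionMask",
  slots = c(name = "character", mask = "matrix",
            lat = "numeric", lon = "numeric"))

setValidity("RegionMask", function(object) {
  msg <- .checkGrid(object@lat, object@lon)
  if (!is.logical(object@mask))
    msg <- c(msg, "'mask' must be logical")
  if (nrow(object@mask) != length(object@lat) ||
      ncol(object@mask) != length(object@lon))
    msg <- c(msg, "dim(mask) must match grid")
  else if (!any(object@mask))
    msg <- c(msg, "mask must contain at least one member cell")
  if (length(msg)) msg else TRUE
})

#' @param name,mask,lat,lon see slot descriptions.
#' @rdname RegionMask-class
#' @export
RegionMask <- function(name, mask, lat, lon)
  new("RegionMask", name = name, mask = mask, lat = as.numeric(lat),
      lon = as.numeric(lon))

#' Build a RegionMask from a lat/lon box rule
#'
#' Cells with centre inside \code{[latRange[1], latRange[2])} x
#' \code{[lonRange[1], lonRange[2])} are members (half-open so that box
#' partitions tile the domain without overlap; the top edges of the domain
#' are included when a range end coincides with the domain end).
#'
#' @param name region name.
#' @param latRange,lonRange numeric length-2 bounds in degrees.
#' @param lat,lon grid cell-centre coordinates.
#' @return A \code{\link{RegionMask}}.
#' @export
latLonBoxMask <- function(name, latRange, lonRange, lat, lon) {
  inLat <- lat >= latRange[1] & lat < latRange[2]
  inLon <- lon >= lonRange[1] & lon < lonRange[2]
  ## cell centres never sit on domain edges, so half-open is safe
  RegionMask(name, outer(inLat, inLon, `&`), lat, lon)
}

#' Build a RegionMask from a polygon rule
#'
#' Cells whose centres fall inside (or on the boundary of) the polygon are
#' members. Vertices are given in order; the polygon is closed
#' automatically.
#'
#' @param name region name.
#' @param polyLat,polyLon polygon vertex coordinates, degrees.
#' @param lat,lon grid cell-centre coordinates.
#' @return A \code{\link{RegionMask}}.
#' @export
polygonMask <- function(name, polyLat, polyLon, lat, lon) {
  pts <- expand.grid(lat = lat, lon = lon)
  inside <- pracma::inpolygon(pts$lon, pts$lat, polyLon, polyLat,
                              boundary = TRUE)
  RegionMask(name, matrix(inside, length(lat), length(lon)), lat, lon)
}

#' Monitoring-station time series with co-sampled model values
#'
#' @slot id station identifier.
#' @slot lat,lon station location (degrees).
#' @slot species measured species.
#' @slot data data.frame with columns \code{time} (Date), \code{observed},
#'   \code{model_all}, \code{model_nofire}; times strictly increasing,
#'   values nonnegative or \code{NA}.
#' @slot fireFraction the true simulated fire fraction of the annual mean at
#'   the station cell (metadata).
#' @exportClass StationSeries
setClass("StationSeries",
  slots = c(id = "character", lat = "numeric", lon = "numeric",
            species = "character", data = "data.frame",
            fireFraction = "numeric"))

setValidity("StationSeries", function(object) {
  msg <- character()
  need <- c("time", "observed", "model_all", "model_nofire")
  if (!all(need %in% names(object@data)))
    msg <- c(msg, sprintf("data must have columns: %s",
                          paste(need, collapse = ", ")))
  else {
    tt <- object@data$time
    if (is.unsorted(tt, strictly = TRUE))
      msg <- c(msg, "timestamps must be strictly increasing")
    for (cn in c("observed", "model_all", "model_nofire"))
      if (any(object@data[[cn]] < 0, na.rm = TRUE))
        msg <- c(msg, sprintf("'%s' must be nonnegative or NA", cn))
  }
  if (length(msg)) msg else TRUE
})

#' @param id,lat,lon,species,data,fireFraction see slot descriptions.
#' @rdname StationSeries-class
#' @export
StationSeries <- function(id, lat, lon, species, data,
                          fireFraction = NA_real_)
  new("StationSeries", id = id, lat = lat, lon = lon, species = species,
      data = data, fireFraction = fireFraction)

#' GEMM exposure-response parameters
#'
#' Coefficients of the Global Exposure Mortality Model relative-risk curve
#' per cause and age group:
#' \deqn{RR(z) = \exp\{\theta \log(1 + z/\alpha) / (1 + e^{-(z-\mu)/\nu})\}}
#' with \eqn{z = \max(0, c - c_f)}, concentration c in ug m-3 and
#' counterfactual \eqn{c_f} (default 2.4 ug m-3).
#'
#' @slot table data.frame with columns \code{cause}, \code{age_group},
#'   \code{theta}, \code{theta_se}, \code{alpha}, \code{mu}, \code{nu},
#'   \code{cf}.
#' @exportClass GEMMParameters
setClass("GEMMParameters", slots = c(table = "data.frame"))

setValidity("GEMMParameters", function(object) {
  tb <- object@table
  need <- c("cause", "age_group", "theta", "theta_se", "alpha", "mu",
            "nu", "cf")
  msg <- character()
  if (!all(need %in% names(tb)))
    msg <- c(msg, sprintf("table must have columns: %s",
                          paste(need, collapse = ", ")))
  else {
    if (any(!is.finite(tb$theta))) msg <- c(msg, "theta must be finite")
    if (any(tb$alpha <= 0)) msg <- c(msg, "alpha must be > 0")
    if (any(tb$nu <= 0)) msg <- c(msg, "nu must be > 0")
    if (any(tb$cf < 0)) msg <- c(msg, "cf must be >= 0")
    if (any(tb$theta_se < 0)) msg <- c(msg, "theta_se must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' @param table see slot description.
#' @rdname GEMMParameters-class
#' @export
GEMMParameters <- function(table) new("GEMMParameters", table = table)

#' Log-linear ozone exposure-response parameters
#'
#' Relative risk per 10 ppbv of warm-season ADM8h ozone above a
#' theoretical-minimum-risk exposure level (TMREL), applied to respiratory
#' mortality: \eqn{RR = rr^{\max(0, x - tmrel)/10}}.
#'
#' @slot rr central relative risk per 10 ppbv (> 0).
#' @slot rrLow,rrHigh 95\% CI on \code{rr}.
#' @slot tmrel counterfactual threshold, ppbv (>= 0).
#' @slot cause affected cause label (default \code{"resp"}).
#' @exportClass OzoneERFParameters
setClass("OzoneERFParameters",
  slots = c(rr = "numeric", rrLow = "numeric", rrHigh = "numeric",
            tmrel = "numeric", cause = "character"))

setValidity("OzoneERFParameters", function(object) {
  msg <- character()
  if (object@rr <= 0) msg <- c(msg, "rr must be > 0")
  if (object@tmrel < 0) msg <- c(msg, "tmrel must be >= 0")
  if (object@rrLow > object@rr || object@rrHigh < object@rr)
    msg <- c(msg, "must have rrLow <= rr <= rrHigh")
  if (length(msg)) msg else TRUE
})

#' @param rr,rrLow,rrHigh,tmrel,cause see slot descriptions.
#' @rdname OzoneERFParameters-class
#' @export
OzoneERFParameters <- function(rr, rrLow = rr, rrHigh = rr, tmrel,
                               cause = "resp")
  new("OzoneERFParameters", rr = rr, rrLow = rrLow, rrHigh = rrHigh,
      tmrel = tmrel, cause = cause)

#' Baseline mortality/DALY rates and population age fractions
#'
#' @slot table data.frame with columns \code{region}, \code{cause},
#'   \code{age_group}, \code{mort_rate}, \code{mort_low}, \code{mort_high}
#'   (deaths per person per year with 95UI), \code{daly_rate},
#'   \code{daly_low}, \code{daly_high} (DALYs per person per year with
#'   95UI), \code{age_fraction}, \code{frac_low}, \code{frac_high}.
#' @exportClass BaselineHealthData
setClass("BaselineHealthData", slots = c(table = "data.frame"))

setValidity("BaselineHealthData", function(object) {
  tb <- object@table
  need <- c("region", "cause", "age_group", "mort_rate", "mort_low",
            "mort_high", "daly_rate", "daly_low", "daly_high",
            "age_fraction", "frac_low", "frac_high")
  msg <- character()
  if (!all(need %in% names(tb)))
    msg <- c(msg, sprintf("table must have columns: %s",
                          paste(need, collapse = ", ")))
  else {
    if (any(tb$mort_rate < 0) || any(tb$daly_rate < 0))
      msg <- c(msg, "baseline rates must be >= 0")
    if (any(tb$age_fraction < 0 | tb$age_fraction > 1))
      msg <- c(msg, "age fractions must lie in [0, 1]")
    if (any(tb$mort_low > tb$mort_rate | tb$mort_high < tb$mort_rate) ||
        any(tb$daly_low > tb$daly_rate | tb$daly_high < tb$daly_rate) ||
        any(tb$frac_low > tb$age_fraction | tb$frac_high < tb$age_fraction))
      msg <- c(msg, "95UI bounds must bracket central values")
    fracSums <- tapply(tb$age_fraction,
                       interaction(tb$region, tb$cause, drop = TRUE), sum)
    if (any(fracSums > 1 + 1e-9))
      msg <- c(msg, "age fractions must sum to <= 1 over modelled groups")
  }
  if (length(msg)) msg else TRUE
})

#' @param table see slot description.
#' @rdname BaselineHealthData-class
#' @export
BaselineHealthData <- function(table) new("BaselineHealthData", table = table)

#' Attributable-burden result
#'
#' Mortality and DALY burden per (region, cause, age group) stratum for a
#' single scenario, or the fire-attributable difference. Uncertainty, when
#' propagated, is carried both as 95UI columns and as per-draw Monte-Carlo
#' samples so that regional aggregation can sum draws rather than interval
#' endpoints.
#'
#' @slot strata data.frame with columns \code{region}, \code{cause},
#'   \code{age_group}, \code{mortality}, \code{dalys} and optionally
#'   \code{mortality_low}, \code{mortality_high}, \code{dalys_low},
#'   \code{dalys_high}.
#' @slot scenario \code{"all"}, \code{"nofire"} or \code{"fire"}.
#' @slot draws list, empty or with matrices \code{mortality} and
#'   \code{dalys} of dim (strata x draws).
#' @exportClass BurdenResult
setClass("BurdenResult",
  slots = c(strata = "data.frame", scenario = "character", draws = "list"))

setValidity("BurdenResult", function(object) {
  msg <- character()
  need <- c("region", "cause", "age_group", "mortality", "dalys")
  if (!all(need %in% names(object@strata)))
    msg <- c(msg, sprintf("strata must have columns: %s",
                          paste(need, collapse = ", ")))
  if (!object@scenario %in% c("all", "nofire", "fire"))
    msg <- c(msg, "scenario must be 'all', 'nofire' or 'fire'")
  else if (object@scenario %in% c("all", "nofire") &&
           all(need %in% names(object@strata)) &&
           any(object@strata$mortality < -1e-9, na.rm = TRUE))
    msg <- c(msg, "per-scenario burden must be nonnegative")
  if (length(object@draws)) {
    for (nm in c("mortality", "dalys"))
      if (!is.null(object@draws[[nm]]) &&
          nrow(object@draws[[nm]]) != nrow(object@strata))
        msg <- c(msg, sprintf("draws$%s rows must match strata", nm))
  }
  if (length(msg)) msg else TRUE
})

#' @param strata,scenario,draws see slot descriptions.
#' @rdname BurdenResult-class
#' @export
BurdenResult <- function(strata, scenario, draws = list())
  new("BurdenResult", strata = strata, scenario = scenario, draws = draws)

#' Model-evaluation metrics for one model/observation series pair
#'
#' @slot nmbf normalized mean bias factor (dimensionless).
#' @slot r Pearson correlation coefficient.
#' @slot rSquared squared correlation.
#' @slot nsd normalized standard deviation, sd(model)/sd(observed).
#' @slot nPairs number of complete pairs used.
#' @exportClass EvaluationMetrics
setClass("EvaluationMetrics",
  slots = c(nmbf = "numeric", r = "numeric", rSquared = "numeric",
            nsd = "numeric", nPairs = "integer"))

setValidity("EvaluationMetrics", function(object) {
  msg <- character()
  if (is.finite(object@r) && abs(object@r) > 1 + 1e-12)
    msg <- c(msg, "|r| must be <= 1")
  if (is.finite(object@nsd) && object@nsd < 0)
    msg <- c(msg, "nsd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ordered poverty classification of IMR values
#'
#' Default follows the widely used classification of gridded IMR surfaces:
#' not poor (IMR < 15), moderately poor (15-32), poor (32-65), very poor
#' (65-100). Intervals are left-closed, right-open, final class
#' right-closed.
#'
#' @slot cutpoints strictly increasing class edges (length = classes + 1).
#' @slot labels class labels.
#' @exportClass PovertyClassScheme
setClass("PovertyClassScheme",
  slots = c(cutpoints = "numeric", labels = "character"))

setValidity("PovertyClassScheme", function(object) {
  msg <- character()
  if (any(diff(object@cutpoints) <= 0))
    msg <- c(msg, "cutpoints must be strictly increasing")
  if (length(object@labels) != length(object@cutpoints) - 1L)
    msg <- c(msg, "need one label per interval")
  if (length(msg)) msg else TRUE
})

#' @param cutpoints,labels see slot descriptions.
#' @rdname PovertyClassScheme-class
#' @export
PovertyClassScheme <- function(cutpoints = c(0, 15, 32, 65, 100),
                               labels = c("not poor", "moderately poor",
                                          "poor", "very poor"))
  new("PovertyClassScheme", cutpoints = cutpoints, labels = labels)

#' Synthetic study configuration
#'
#' Declares the domain, grid, fire-season structure, plume geometry,
#' background fields, population clustering, baseline health rates, IMR
#' surface and noise levels from which all synthetic pipeline inputs are
#' generated. Same seed + same config gives bit-identical outputs; each
#' generated product draws from its own stream derived from the master seed
#' by a fixed offset, so adding a product never perturbs the others.
#'
#' @slot domain numeric(4): latMin, latMax, lonMin, lonMax (degrees).
#' @slot resolution grid spacing in degrees; must divide both extents.
#' @slot nMonths months in the simulated year (12).
#' @slot fireSeason months with nonzero fire contribution.
#' @slot peakMonth month at which the fire temporal weight is 1.
#' @slot plumes data.frame(lat, lon, amplitude, decayKm): Gaussian fire
#'   plumes; amplitude is the peak-month PM2.5 enhancement at the centre.
#' @slot background list(mean, latGradient, lonGradient): smooth nonfire
#'   PM2.5 surface (ug m-3; gradients span the whole domain).
#' @slot pm10Ratio list(background, fire): PM10/PM2.5 scaling of the
#'   nonfire background and of the fire contribution.
#' @slot ozone list(background, seasonalAmplitude, fireEnhancement) in ppbv
#'   for the daily-max-8h ozone product.
#' @slot population list(total, nClusters, clusterDecayKm, uniformFloor).
#' @slot baseline baseline rate table (BaselineHealthData schema).
#' @slot imr list(base, coupling, noiseSD): IMR = base + coupling x annual
#'   fire PM2.5 + noise, clipped to [0, 100].
#' @slot noise list(concSDLog, stationBias, stationNoiseSD).
#' @slot seed master random seed (integer).
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  slots = c(domain = "numeric", resolution = "numeric", nMonths = "integer",
            fireSeason = "integer", peakMonth = "integer",
            plumes = "data.frame", background = "list", pm10Ratio = "list",
            ozone = "list", population = "list", baseline = "data.frame",
            imr = "list", noise = "list", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  d <- object@domain
  if (length(d) != 4L || d[1] >= d[2] || d[3] >= d[4])
    msg <- c(msg, "domain must be c(latMin < latMax, lonMin < lonMax)")
  res <- object@resolution
  if (res <= 0) msg <- c(msg, "resolution must be > 0")
  else if (length(d) == 4L) {
    for (ext in c(d[2] - d[1], d[4] - d[3])) {
      k <- ext / res
      if (abs(k - round(k)) > 1e-8)
        msg <- c(msg, "resolution must divide the domain extent exactly")
    }
  }
  if (object@nMonths != 12L) msg <- c(msg, "nMonths must be 12")
  if (!all(object@fireSeason %in% seq_len(object@nMonths)))
    msg <- c(msg, "fireSeason months must lie in 1..nMonths")
  if (!object@peakMonth %in% object@fireSeason)
    msg <- c(msg, "peakMonth must be a fire-season month")
  if (nrow(object@plumes) &&
      (any(object@plumes$amplitude < 0) || any(object@plumes$decayKm <= 0)))
    msg <- c(msg, "plume amplitudes must be >= 0 and decay lengths > 0")
  nonneg <- c(object@background$mean, object@ozone$background,
              object@ozone$fireEnhancement, object@population$total,
              object@imr$base, object@imr$noiseSD, object@noise$concSDLog,
              object@noise$stationNoiseSD)
  if (any(nonneg < 0))
    msg <- c(msg, "means, totals, amplitudes and noise SDs must be >= 0")
  if (is.na(object@seed) || abs(object@seed) > 2^31 - 1e4)
    msg <- c(msg, "seed must be an integer well below 2^31")
  if (length(msg)) msg else TRUE
})
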