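## Station-based model evaluation: fire-influenced station selection,
## per-year fire-derived PM isolation, NMBF, Pearson r and NSD.

#' Normalized mean bias factor
#'
#' The symmetric bias metric of Yu et al.: with paired model values M and
#' observations O,
#' \deqn{NMBF = \Sigma M / \Sigma O - 1 \quad (\bar M \ge \bar O), \qquad
#'       NMBF = 1 - \Sigma O / \Sigma M \quad (\bar M < \bar O).}
#' A positive NMBF means the model overestimates by a factor NMBF + 1; a
#' negative NMBF means it underestimates by a factor 1 - NMBF. The metric
#' is antisymmetric under exchanging the series and invariant to rescaling
#' both by a common factor. Missing values are excluded pairwise.
#'
#' @param model,observed paired series (same length).
#' @return Scalar NMBF.
#' @export
nmbf <- function(model, observed) {
  ok <- is.finite(model) & is.finite(observed)
  m <- model[ok]; o <- observed[ok]
  if (!length(m)) stop("no complete pairs")
  sm <- sum(m); so <- sum(o)
  if (sm <= 0 || so <= 0)
    stop("undefined: NMBF needs positive series sums")
  if (mean(m) >= mean(o)) sm / so - 1 else 1 - so / sm
}

#' Pearson correlation and normalized standard deviation of a series pair
#'
#' Computes the standard Pearson r (and r squared) on complete pairs, the
#' normalized standard deviation NSD = sd(model)/sd(observed), and the
#' NMBF, bundled as an \code{\link{EvaluationMetrics}} object.
#'
#' @param model,observed paired series.
#' @return An \code{\link{EvaluationMetrics}}.
#' @export
evaluateSeries <- function(model, observed) {
  ok <- is.finite(model) & is.finite(observed)
  m <- model[ok]; o <- observed[ok]
  if (length(m) < 2L) stop("need at least 2 complete pairs")
  if (stats::sd(o) == 0) stop("undefined: observed series has zero variance")
  r <- if (stats::sd(m) == 0) NA_real_ else stats::cor(m, o)
  bias <- tryCatch(nmbf(m, o), error = function(e) NA_real_)
  new("EvaluationMetrics", nmbf = bias, r = r, rSquared = r^2,
      nsd = stats::sd(m) / stats::sd(o), nPairs = length(m))
}

#' Isolate the fire-derived enhancement of a monthly series
#'
#' Within each calendar year independently, subtracts that year's minimum
#' non-missing monthly mean from every month, so the cleanest month maps
#' to zero and the remainder is the enhancement above the annual floor --
#' the standard trick for isolating the fire signal in both observations
#' and model without source apportionment. Years with fewer than 2 valid
#' months are returned as missing. The operation is idempotent.
#'
#' @param x monthly values.
#' @param year calendar year of each value (defaults to a single year).
#' @return Fire-derived series, same length as \code{x}.
#' @export
fireDerivedSeries <- function(x, year = rep(1L, length(x))) {
  stopifnot(length(x) == length(year))
  out <- rep(NA_real_, length(x))
  for (y in unique(year)) {
    i <- which(year == y)
    ok <- i[is.finite(x[i])]
    if (length(ok) < 2L) next # year flagged missing
    out[i] <- x[i] - min(x[ok])
  }
  out
}

#' Apply fire-derived isolation to a station's observed and model series
#'
#' @param station a \code{\link{StationSeries}} with monthly records.
#' @return A \code{\link{StationSeries}} whose observed and model columns
#'   hold fire-derived enhancements.
#' @export
fireDerivedStation <- function(station) {
  d <- stationData(station)
  yr <- as.integer(format(d$time, "%Y"))
  for (cn in c("observed", "model_all", "model_nofire"))
    d[[cn]] <- fireDerivedSeries(d[[cn]], yr)
  StationSeries(stationId(station), station@lat, station@lon,
                station@species, d, fireFraction(station))
}

#' Select fire-influenced stations from a scenario pair
#'
#' Keeps stations whose grid cell has a simulated fire contribution of at
#' least \code{threshold} (default 20\%) of the annual mean: cell value of
#' \code{(all - nofire)/all} >= threshold. Station-to-cell sampling uses
#' the containing cell (nearest centre).
#'
#' @param allField,nofireField annual \code{\link{ConcentrationField}}s.
#' @param stations list of \code{\link{StationSeries}}.
#' @param threshold fire fraction cutoff in \code{[0, 1]}.
#' @return The selected subset (possibly empty list).
#' @export
selectFireInfluenced <- function(allField, nofireField, stations,
                                 threshold = 0.20) {
  stopifnot(threshold >= 0, threshold <= 1)
  .checkAligned(allField, nofireField, "scenario fields")
  va <- .annualValues(allField); vn <- .annualValues(nofireField)
  frac <- ifelse(va > 0, (va - vn) / va, 0)
  lat <- gridLat(allField); lon <- gridLon(allField)
  res <- if (length(lat) > 1) diff(lat[1:2]) else 1
  outside <- character()
  keep <- vapply(stations, function(s) {
    iLat <- which.min(abs(lat - s@lat)); iLon <- which.min(abs(lon - s@lon))
    if (abs(lat[iLat] - s@lat) > res || abs(lon[iLon] - s@lon) > res) {
      outside <<- c(outside, stationId(s)); return(FALSE)
    }
    frac[iLat, iLon] >= threshold
  }, logical(1))
  if (length(outside))
    stop("stations outside the model grid: ",
         paste(outside, collapse = ", "))
  stations[keep]
}

#' Composite (multi-station average) series
#'
#' Unweighted mean across stations at each timestamp, the convention for
#' regional-average evaluation plots. Note that metrics of the composite
#' series generally differ from the average of per-station metrics; both
#' modes are available (\code{\link{evaluateStations}}).
#'
#' @param stations list of \code{\link{StationSeries}} sharing timestamps.
#' @param column one of \code{"observed"}, \code{"model_all"},
#'   \code{"model_nofire"}.
#' @return data.frame(time, value).
#' @export
compositeSeries <- function(stations, column = "observed") {
  tt <- stationData(stations[[1L]])$time
  vals <- vapply(stations, function(s) {
    d <- stationData(s)
    if (!identical(d$time, tt)) stop("stations must share timestamps")
    d[[column]]
  }, numeric(length(tt)))
  data.frame(time = tt,
             value = rowMeans(as.matrix(vals), na.rm = TRUE))
}

#' Evaluate model against stations, per station or as a composite
#'
#' @param stations list of \code{\link{StationSeries}}.
#' @param scenario model column to evaluate (default \code{"model_all"}).
#' @param mode \code{"per_station"} (one metrics row per station) or
#'   \code{"composite"} (stations averaged at each timestamp first).
#' @return data.frame of metrics (station id \code{"composite"} for the
#'   composite mode).
#' @export
evaluateStations <- function(stations, scenario = "model_all",
                             mode = c("per_station", "composite")) {
  mode <- match.arg(mode)
  asRow <- function(id, em)
    data.frame(station = id, nmbf = em@nmbf, r = em@r,
               r_squared = em@rSquared, nsd = em@nsd, n_pairs = em@nPairs)
  if (mode == "composite") {
    obs <- compositeSeries(stations, "observed")$value
    mod <- compositeSeries(stations, scenario)$value
    return(asRow("composite", evaluateSeries(mod, obs)))
  }
  do.call(rbind, lapply(stations, function(s) {
    d <- stationData(s)
    asRow(stationId(s), evaluateSeries(d[[scenario]], d$observed))
  }))
}
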