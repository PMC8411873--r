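## Exposure metrics: regridding, aggregation, population weighting, ADM8h
## ozone, scenario percentage change, threshold exceedance populations.

.asSlices <- function(x) {
  v <- if (is(x, "ConcentrationField")) fieldValues(x) else x
  if (length(dim(v)) == 2L) array(v, c(dim(v), 1L)) else v
}

.annualValues <- function(field) {
  v <- fieldValues(field)
  if (length(dim(v)) == 3L) apply(v, c(1, 2), mean, na.rm = TRUE) else v
}

.checkAligned <- function(a, b, what = "inputs") {
  if (!isTRUE(all.equal(gridLat(a), gridLat(b))) ||
      !isTRUE(all.equal(gridLon(a), gridLon(b))))
    stop(sprintf("alignment error: %s are not on the same grid", what))
  invisible(TRUE)
}

#' Bilinear regridding of a concentration field
#'
#' Interpolates the field to the cell centres of a target grid with
#' bilinear interpolation (per time slice for 3-D fields). The source grid
#' must cover the target cell centres; no extrapolation is performed.
#'
#' @param field a \code{\link{ConcentrationField}}.
#' @param targetLat,targetLon target cell-centre coordinates.
#' @return A \code{\link{ConcentrationField}} on the target grid.
#' @export
regridLinear <- function(field, targetLat, targetLon) {
  lat <- gridLat(field); lon <- gridLon(field)
  if (min(targetLat) < min(lat) || max(targetLat) > max(lat) ||
      min(targetLon) < min(lon) || max(targetLon) > max(lon))
    stop("extrapolation error: target grid extends outside the source grid")
  v <- .asSlices(field)
  nt <- dim(v)[3]
  tp <- expand.grid(lat = targetLat, lon = targetLon)
  out <- array(NA_real_, c(length(targetLat), length(targetLon), nt))
  for (t in seq_len(nt)) {
    ## interp2 wants Z with length(y) rows x length(x) cols; our slices are
    ## [lat, lon] so lat plays y and lon plays x
    out[, , t] <- matrix(
      pracma::interp2(x = lon, y = lat, Z = v[, , t],
                      xp = tp$lon, yp = tp$lat, method = "linear"),
      nrow = length(targetLat))
  }
  if (length(dim(fieldValues(field))) == 2L) out <- out[, , 1L]
  ConcentrationField(out, targetLat, targetLon, speciesTag(field),
                     temporalTag(field), scenarioTag(field))
}

#' Block-average a fine field onto a coarser grid
#'
#' Each target cell receives the arithmetic mean of the non-missing fine
#' cells whose centres fall inside it (the fine grid must nest within the
#' target cells); a target cell whose fine cells are all missing is
#' missing.
#'
#' @param values fine-grid matrix \code{[lat, lon]} (or a 2-D
#'   \code{\link{ConcentrationField}} / \code{\link{IMRGrid}}).
#' @param fineLat,fineLon fine-grid cell centres (ignored when
#'   \code{values} carries its own grid).
#' @param targetLat,targetLon coarse-grid cell centres with constant
#'   spacing.
#' @return Matrix on the target grid.
#' @export
aggregateMeanToGrid <- function(values, fineLat = NULL, fineLon = NULL,
                                targetLat, targetLon) {
  if (is(values, "ConcentrationField") || is(values, "IMRGrid")) {
    fineLat <- gridLat(values); fineLon <- gridLon(values)
    values <- fieldValues(values)
  }
  resLat <- if (length(targetLat) > 1) diff(targetLat[1:2]) else
    2 * (targetLat - min(fineLat))
  resLon <- if (length(targetLon) > 1) diff(targetLon[1:2]) else
    2 * (targetLon - min(fineLon))
  iLat <- findInterval(fineLat, c(targetLat - resLat / 2,
                                  max(targetLat) + resLat / 2),
                       rightmost.closed = TRUE)
  iLon <- findInterval(fineLon, c(targetLon - resLon / 2,
                                  max(targetLon) + resLon / 2),
                       rightmost.closed = TRUE)
  if (any(iLat < 1 | iLat > length(targetLat)) ||
      any(iLon < 1 | iLon > length(targetLon)))
    stop("fine grid does not nest within the target grid")
  out <- matrix(NA_real_, length(targetLat), length(targetLon))
  cellIdx <- outer(iLat, iLon, function(a, b) (b - 1L) * length(targetLat) + a)
  sums <- tapply(values, cellIdx, function(x)
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  out[as.integer(names(sums))] <- as.numeric(sums)
  out
}

#' Population-weighted mean concentration over a region
#'
#' \eqn{\sum C_i P_i / \sum P_i} over the (optionally masked) cells with
#' non-missing concentration.
#'
#' @param field annual \code{\link{ConcentrationField}} (3-D fields are
#'   first averaged over time).
#' @param pop a \code{\link{PopulationGrid}} on the same grid.
#' @param mask optional \code{\link{RegionMask}}.
#' @return Scalar population-weighted mean.
#' @export
populationWeightedMean <- function(field, pop, mask = NULL) {
  .checkAligned(field, pop, "field and population")
  v <- .annualValues(field)
  p <- fieldValues(pop)
  keep <- is.finite(v)
  if (!is.null(mask)) {
    .checkAligned(field, mask, "field and mask")
    keep <- keep & maskValues(mask)
  }
  if (sum(p[keep]) <= 0)
    stop("undefined value: zero population in the evaluated region")
  sum(v[keep] * p[keep]) / sum(p[keep])
}

#' Area-weighted (cos latitude) regional mean concentration
#'
#' Unweighted-by-population alternative regional mean, with optional
#' cos(latitude) cell-area weighting (off by default since the headline
#' quantities of this pipeline are population-weighted).
#'
#' @param field annual \code{\link{ConcentrationField}}.
#' @param mask optional \code{\link{RegionMask}}.
#' @param areaWeight logical; weight cells by cos(latitude).
#' @return Scalar regional mean.
#' @export
regionalMean <- function(field, mask = NULL, areaWeight = FALSE) {
  v <- .annualValues(field)
  w <- if (areaWeight)
    matrix(cos(gridLat(field) * pi / 180), nrow(v), ncol(v)) else
    matrix(1, nrow(v), ncol(v))
  keep <- is.finite(v)
  if (!is.null(mask)) keep <- keep & maskValues(mask)
  sum(v[keep] * w[keep]) / sum(w[keep])
}

#' Annual average daily maximum 8-h ozone (ADM8h)
#'
#' For hourly input, each day's maximum over the 17 running 8-hour-mean
#' windows fully contained in the calendar day is taken (windows starting
#' hours 0..16; a window containing a missing hour is skipped, and a day
#' with fewer than 8 valid consecutive hours contributes nothing); for
#' daily-max-8h input the values are used directly. The annual value is
#' the mean of the daily maxima; a cell with no valid day is missing.
#' Cross-midnight windows can be enabled for sensitivity analysis.
#'
#' @param field an hourly or daily \code{\link{ConcentrationField}} of O3.
#' @param crossDay logical; also consider windows spanning midnight.
#' @return An annual \code{\link{ConcentrationField}}.
#' @export
adm8h <- function(field, crossDay = FALSE) {
  v <- .asSlices(field)
  if (temporalTag(field) == "daily") {
    ann <- apply(v, c(1, 2), function(x)
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  } else if (temporalTag(field) == "hourly") {
    nh <- dim(v)[3]
    if (nh %% 24L != 0L) stop("hourly field must hold complete days")
    nd <- nh %/% 24L
    dims <- dim(v)[1:2]
    dailyMax <- array(NA_real_, c(dims, nd))
    for (d in seq_len(nd)) {
      idx <- if (crossDay && d < nd) (d - 1L) * 24L + seq_len(48L)
             else (d - 1L) * 24L + seq_len(24L)
      day <- v[, , idx, drop = FALSE]
      nWin <- dim(day)[3] - 7L
      if (crossDay && d < nd) nWin <- 24L # windows starting within day d
      best <- array(NA_real_, dims)
      for (s in seq_len(nWin)) {
        wm <- apply(day[, , s:(s + 7L), drop = FALSE], c(1, 2),
                    function(x) if (anyNA(x)) NA_real_ else mean(x))
        best <- ifelse(is.na(best), wm, pmax(best, wm, na.rm = TRUE))
      }
      dailyMax[, , d] <- best
    }
    ann <- apply(dailyMax, c(1, 2), function(x)
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  } else stop("adm8h needs an hourly or daily field")
  ConcentrationField(ann, gridLat(field), gridLon(field), "O3", "annual",
                     scenarioTag(field))
}

#' Percentage change between scenarios
#'
#' \eqn{100 (C_{with} - C_{without}) / C_{with}}: the percentage reduction
#' realised when the source is excluded. Cells where the with-source value
#' is zero are missing.
#'
#' @param withFire,withoutFire \code{\link{ConcentrationField}}s or
#'   numerics (with-source and source-removed).
#' @return Same shape as the inputs (matrix for fields, numeric for
#'   numerics).
#' @export
percentChange <- function(withFire, withoutFire) {
  wf <- if (is(withFire, "ConcentrationField"))
    .annualValues(withFire) else withFire
  wo <- if (is(withoutFire, "ConcentrationField"))
    .annualValues(withoutFire) else withoutFire
  out <- 100 * (wf - wo) / wf
  out[wf == 0] <- NA_real_
  out
}

#' Population living above a concentration threshold
#'
#' Sums population over cells whose concentration strictly exceeds the
#' threshold (e.g. the WHO annual PM2.5 guideline of 10 ug m-3 or Interim
#' Target 2 of 25 ug m-3).
#'
#' @param field annual \code{\link{ConcentrationField}}.
#' @param pop a \code{\link{PopulationGrid}}.
#' @param threshold concentration threshold (strict \code{>}).
#' @param mask optional \code{\link{RegionMask}}.
#' @return Person count.
#' @export
populationAboveThreshold <- function(field, pop, threshold, mask = NULL) {
  .checkAligned(field, pop, "field and population")
  v <- .annualValues(field)
  keep <- is.finite(v) & v > threshold
  if (!is.null(mask)) keep <- keep & maskValues(mask)
  sum(fieldValues(pop)[keep])
}
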