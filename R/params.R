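## Packaged parameter sets and demo-study helpers. Exposure-outcome
## coefficients are configuration inputs read from files, not constants of
## the pipeline.

#' Read GEMM coefficients from a CSV parameter file
#'
#' Expected columns: cause, age_group, theta, theta_se, alpha, mu, nu, cf.
#'
#' @param path CSV file path.
#' @return A \code{\link{GEMMParameters}}.
#' @export
readGEMMParameters <- function(path)
  GEMMParameters(utils::read.csv(path, stringsAsFactors = FALSE))

#' Packaged GEMM coefficient sets
#'
#' Two curve shapes are shipped: the NCD+LRI aggregate (one
#' noncommunicable-disease plus lower-respiratory-infection curve for the
#' adult population) and the 5-cause specification (IHD, stroke, COPD,
#' lung cancer, LRI). Which one a given assessment should use is a
#' configuration choice.
#'
#' @param variant \code{"ncd_lri"} or \code{"5cause"}.
#' @return A \code{\link{GEMMParameters}}.
#' @export
defaultGEMMParameters <- function(variant = c("ncd_lri", "5cause")) {
  variant <- match.arg(variant)
  readGEMMParameters(system.file("extdata",
                                 sprintf("gemm_%s.csv", variant),
                                 package = "fireburden", mustWork = TRUE))
}

#' Read ozone exposure-response parameters from a YAML file
#'
#' Expected keys: rr_per_10ppb, rr_low, rr_high, tmrel_ppbv, cause.
#'
#' @param path YAML file path.
#' @return An \code{\link{OzoneERFParameters}}.
#' @export
readOzoneERF <- function(path) {
  y <- yaml::read_yaml(path)
  OzoneERFParameters(rr = y$rr_per_10ppb, rrLow = y$rr_low,
                     rrHigh = y$rr_high, tmrel = y$tmrel_ppbv,
                     cause = y$cause)
}

#' Packaged example ozone exposure-response parameters
#'
#' Log-linear respiratory-mortality response of 1.12 (95\% CI 1.08-1.16)
#' per 10 ppbv of ADM8h ozone with a TMREL of 26.7 ppbv, read from the
#' example parameter file; the TMREL is a file-level setting, not a
#' package constant.
#'
#' @return An \code{\link{OzoneERFParameters}}.
#' @export
defaultOzoneERF <- function()
  readOzoneERF(system.file("extdata", "ozone_erf.yaml",
                           package = "fireburden", mustWork = TRUE))

#' Default synthetic baseline health-rate table
#'
#' GBD-style adult (25+) rates per region for the NCD+LRI aggregate cause
#' and for respiratory mortality (the ozone-affected cause), with 95UIs.
#' Regional multipliers give mild between-region contrast.
#'
#' @param regions region names (default the four demo quadrants).
#' @param multipliers per-region rate multipliers.
#' @return data.frame in the \code{\link{BaselineHealthData}} schema.
#' @export
defaultBaseline <- function(regions = c("NW", "NE", "SW", "SE"),
                            multipliers = c(1.10, 0.95, 1.00, 0.90)) {
  multipliers <- rep_len(multipliers, length(regions))
  one <- function(region, m) {
    data.frame(
      region = region,
      cause = c("ncd_lri", "resp"),
      age_group = "25plus",
      mort_rate = m * c(0.0060, 0.0007),
      mort_low = m * c(0.0054, 0.0006),
      mort_high = m * c(0.0066, 0.0008),
      daly_rate = m * c(0.230, 0.016),
      daly_low = m * c(0.190, 0.013),
      daly_high = m * c(0.270, 0.019),
      age_fraction = 0.65, frac_low = 0.62, frac_high = 0.68)
  }
  do.call(rbind, Map(one, regions, multipliers))
}

#' Quadrant region masks for a rectangular domain
#'
#' Splits the grid into NW/NE/SW/SE quadrants at the domain midpoints --
#' the demo stand-in for country masks. The quadrants partition the
#' domain (disjoint, exhaustive).
#'
#' @param lat,lon grid cell-centre coordinates.
#' @return Named list of four \code{\link{RegionMask}} objects.
#' @export
quadrantMasks <- function(lat, lon) {
  midLat <- mean(range(lat)); midLon <- mean(range(lon))
  top <- max(lat) + 1; right <- max(lon) + 1
  list(NW = latLonBoxMask("NW", c(midLat, top), c(min(lon) - 1, midLon),
                          lat, lon),
       NE = latLonBoxMask("NE", c(midLat, top), c(midLon, right), lat, lon),
       SW = latLonBoxMask("SW", c(min(lat) - 1, midLat),
                          c(min(lon) - 1, midLon), lat, lon),
       SE = latLonBoxMask("SE", c(min(lat) - 1, midLat), c(midLon, right),
                          lat, lon))
}
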