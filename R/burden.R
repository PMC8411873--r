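## Health-burden attribution: GEMM and log-linear ozone relative risk,
## population attributable fractions, per-scenario burden, the
## scenario-subtraction method, Monte-Carlo 95% uncertainty intervals and
## per-capita rates.

#' GEMM relative risk of mortality at an ambient PM2.5 exposure
#'
#' The Global Exposure Mortality Model curve
#' \deqn{RR(z) = \exp\{\theta \, \log(1 + z/\alpha) \,/\,
#'   (1 + e^{-(z - \mu)/\nu})\}, \quad z = \max(0, c - c_f),}
#' a supra-linear log term damped at low concentrations by a logistic
#' weight. RR is 1 at or below the counterfactual and nondecreasing in
#' concentration for \eqn{\theta \ge 0}.
#'
#' @param conc ambient PM2.5, ug m-3 (vectorised; must be >= 0).
#' @param theta log-RR slope coefficient.
#' @param alpha concentration scaling, ug m-3 (> 0).
#' @param mu,nu logistic weight centre and width, ug m-3 (nu > 0).
#' @param cf counterfactual concentration, ug m-3 (default 2.4, the
#'   low-concentration cutoff of the GEMM cohort data).
#' @return Relative risk, same shape as \code{conc}.
#' @export
gemmRelativeRisk <- function(conc, theta, alpha, mu, nu, cf = 2.4) {
  if (any(conc < 0, na.rm = TRUE))
    stop("input error: concentrations must be nonnegative")
  z <- pmax(0, conc - cf)
  exp(theta * log(1 + z / alpha) / (1 + exp(-(z - mu) / nu)))
}

## log-RR basis: log RR = theta * G(c). Shared by the central and the
## Monte-Carlo paths so a theta draw only rescales a precomputed vector.
.gemmBasis <- function(conc, alpha, mu, nu, cf) {
  z <- pmax(0, conc - cf)
  log(1 + z / alpha) / (1 + exp(-(z - mu) / nu))
}

#' Log-linear ozone relative risk at an ADM8h exposure
#'
#' \eqn{RR = rr^{\max(0, x - tmrel)/10}}: multiplicative in 10-ppbv
#' increments of annual daily-maximum-8-h ozone above the TMREL.
#'
#' @param x ADM8h ozone, ppbv (vectorised).
#' @param erf an \code{\link{OzoneERFParameters}} object.
#' @return Relative risk, same shape as \code{x}.
#' @export
ozoneRelativeRisk <- function(x, erf) {
  stopifnot(is(erf, "OzoneERFParameters"))
  erf@rr ^ (pmax(0, x - erf@tmrel) / 10)
}

#' Population attributable fraction of relative risk
#'
#' \eqn{AF = (RR - 1)/RR}, the fraction of the baseline burden
#' attributable to the exposure; lies in \code{[0, 1)} for RR >= 1. RR
#' values below 1 are permitted (negative AF, protective exposure) with a
#' warning.
#'
#' @param rr relative risk (> 0, vectorised).
#' @return Attributable fraction, same shape as \code{rr}.
#' @export
attributableFraction <- function(rr) {
  if (any(rr <= 0, na.rm = TRUE))
    stop("input error: relative risk must be positive")
  if (any(rr < 1, na.rm = TRUE))
    warning("relative risk below 1: returning negative attributable fraction")
  (rr - 1) / rr
}

## ---- internal stratum machinery -------------------------------------

## Builds one record per (region, cause, age_group): the log-RR basis G and
## population over the region's valid cells, plus central theta and
## baseline rates. Used by both the central and Monte-Carlo paths.
.buildStrata <- function(field, pop, baseline, params, masks) {
  .checkAligned(field, pop, "field and population")
  conc <- .annualValues(field)
  popv <- fieldValues(pop)
  if (is(params, "GEMMParameters")) {
    curves <- paramTable(params)
  } else if (is(params, "OzoneERFParameters")) {
    base <- paramTable(baseline)
    ages <- unique(base$age_group[base$cause == params@cause])
    if (!length(ages))
      stop(sprintf("missing baseline for ozone cause '%s'", params@cause))
    ## log-linear curve recast in the theta * G(c) form
    seLog <- (log(params@rrHigh) - log(params@rrLow)) /
      (2 * stats::qnorm(0.975))
    curves <- data.frame(cause = params@cause, age_group = ages,
                         theta = log(params@rr), theta_se = seLog,
                         alpha = NA_real_, mu = NA_real_, nu = NA_real_,
                         cf = params@tmrel)
  } else stop("params must be GEMMParameters or OzoneERFParameters")
  isO3 <- is(params, "OzoneERFParameters")
  base <- paramTable(baseline)
  curveKey <- interaction(curves$cause, curves$age_group, drop = TRUE)

  strata <- list()
  for (m in masks) {
    rname <- regionName(m)
    .checkAligned(field, m, "field and mask")
    keep <- maskValues(m) & is.finite(conc)
    cc <- conc[keep]; pp <- popv[keep]
    for (i in seq_len(nrow(curves))) {
      cu <- curves[i, ]
      b <- base[base$region == rname & base$cause == cu$cause &
                base$age_group == cu$age_group, ]
      if (nrow(b) == 0L)
        stop(sprintf(
          "missing baseline rates for region '%s' (cause %s, age %s)",
          rname, cu$cause, cu$age_group))
      G <- if (isO3) pmax(0, cc - cu$cf) / 10
           else .gemmBasis(cc, cu$alpha, cu$mu, cu$nu, cu$cf)
      strata[[length(strata) + 1L]] <- list(
        region = rname, cause = cu$cause, age_group = cu$age_group,
        theta = cu$theta, theta_se = cu$theta_se,
        curve = as.integer(curveKey[i]), G = G, pop = pp, baseline = b)
    }
  }
  list(strata = strata, nCurves = nlevels(curveKey))
}

## population-weighted attributable-fraction sum for one stratum and a
## vector of theta values: sum_i (1 - exp(-theta G_i)) pop_i
.afPopSum <- function(G, pop, thetas) {
  if (!length(G)) return(rep(0, length(thetas)))
  sum(pop) - as.numeric(crossprod(exp(-outer(G, thetas)), pop))
}

#' Attributable burden of one scenario field
#'
#' Per (region, cause, age group): burden =
#' \eqn{\sum_{cells} AF(RR(C_{cell})) \, P_{cell} \times} baseline rate
#' \eqn{\times} age fraction, evaluated with central inputs. Mortality and
#' DALYs use their respective baseline rates. Pass the annual PM2.5 field
#' with \code{\link{GEMMParameters}}, or the ADM8h ozone field with
#' \code{\link{OzoneERFParameters}}.
#'
#' @param field annual \code{\link{ConcentrationField}} of the scenario.
#' @param pop a \code{\link{PopulationGrid}}.
#' @param baseline a \code{\link{BaselineHealthData}}.
#' @param params \code{\link{GEMMParameters}} or
#'   \code{\link{OzoneERFParameters}}.
#' @param masks list of \code{\link{RegionMask}} defining the regions.
#' @return A \code{\link{BurdenResult}} for the field's scenario tag.
#' @export
scenarioBurden <- function(field, pop, baseline, params, masks) {
  built <- .buildStrata(field, pop, baseline, params, masks)
  rows <- lapply(built$strata, function(s) {
    afSum <- .afPopSum(s$G, s$pop, s$theta)
    data.frame(region = s$region, cause = s$cause,
               age_group = s$age_group,
               mortality = afSum * s$baseline$mort_rate *
                 s$baseline$age_fraction,
               dalys = afSum * s$baseline$daly_rate *
                 s$baseline$age_fraction)
  })
  scen <- scenarioTag(field)
  if (!scen %in% c("all", "nofire")) scen <- "all"
  BurdenResult(do.call(rbind, rows), scenario = scen)
}

#' Fire-attributable burden by scenario subtraction
#'
#' The subtraction method: the burden attributable to fires is the
#' difference between the burden from all sources and the burden with fire
#' emissions removed, per stratum
#' (\eqn{M_{FIRE} = M_{ALL} - M_{FIRE\_OFF}}). Negative differences
#' (possible for ozone where fire aerosol suppresses photochemistry) are
#' retained, not clipped. The result also carries the percentage burden
#' reduction \eqn{100 \, M_{FIRE} / M_{ALL}} per stratum.
#'
#' @param all,nofire \code{\link{BurdenResult}}s with identical
#'   stratification.
#' @return A \code{\link{BurdenResult}} with scenario \code{"fire"}.
#' @export
fireAttributableBurden <- function(all, nofire) {
  sa <- burdenStrata(all); sn <- burdenStrata(nofire)
  key <- c("region", "cause", "age_group")
  if (nrow(sa) != nrow(sn) ||
      !identical(sa[key], sn[key]))
    stop("alignment error: scenario burdens have different stratification")
  out <- sa[key]
  out$mortality <- sa$mortality - sn$mortality
  out$dalys <- sa$dalys - sn$dalys
  out$mortality_reduction_pct <- ifelse(sa$mortality > 0,
                                        100 * out$mortality / sa$mortality,
                                        NA_real_)
  out$dalys_reduction_pct <- ifelse(sa$dalys > 0,
                                    100 * out$dalys / sa$dalys, NA_real_)
  da <- burdenDraws(all); dn <- burdenDraws(nofire)
  draws <- list()
  if (length(da) && length(dn))
    draws <- list(mortality = da$mortality - dn$mortality,
                  dalys = da$dalys - dn$dalys)
  res <- BurdenResult(out, scenario = "fire", draws = draws)
  if (length(draws)) .attachUI(res) else res
}

## sampling helpers: distributions matched to 95UIs
.lognormalDraws <- function(central, low, high, n) {
  if (central <= 0 || high <= low) return(rep(central, n))
  sdlog <- (log(high) - log(low)) / (2 * stats::qnorm(0.975))
  stats::rlnorm(n, log(central), sdlog)
}

.logitNormalDraws <- function(central, low, high, n) {
  if (central <= 0 || central >= 1 || high <= low)
    return(rep(central, n))
  sd <- (stats::qlogis(high) - stats::qlogis(low)) /
    (2 * stats::qnorm(0.975))
  stats::plogis(stats::rnorm(n, stats::qlogis(central), sd))
}

.attachUI <- function(res) {
  st <- burdenStrata(res); dr <- burdenDraws(res)
  qs <- function(m) t(apply(m, 1L, stats::quantile, c(0.025, 0.975),
                            names = FALSE))
  qm <- qs(dr$mortality); qd <- qs(dr$dalys)
  st$mortality_low <- qm[, 1]; st$mortality_high <- qm[, 2]
  st$dalys_low <- qd[, 1]; st$dalys_high <- qd[, 2]
  BurdenResult(st, scenario = res@scenario, draws = dr)
}

#' Monte-Carlo 95% uncertainty intervals on attributable burdens
#'
#' Propagates the uncertainty of the exposure-outcome coefficients
#' (normal on theta / log RR), baseline mortality and DALY rates
#' (lognormal matched to their 95UIs) and population age fractions
#' (logit-normal matched to their 95UIs) through the full burden
#' calculation. Coefficient draws are shared across regions and between
#' the two scenarios of a pair (the curve is one global object), so the
#' per-draw fire-attributable difference is coherent; rate and fraction
#' draws are independent per stratum. Central estimates use central
#' inputs; interval bounds are the 2.5th/97.5th percentiles over draws.
#' Per-draw samples are retained on the result so that regional
#' aggregation can sum draws rather than interval endpoints.
#'
#' @param allField,nofireField annual \code{\link{ConcentrationField}}s of
#'   the two scenarios (PM2.5 for GEMM, ADM8h for ozone).
#' @param pop a \code{\link{PopulationGrid}}.
#' @param baseline a \code{\link{BaselineHealthData}}.
#' @param params \code{\link{GEMMParameters}} or
#'   \code{\link{OzoneERFParameters}}.
#' @param masks list of \code{\link{RegionMask}}.
#' @param nDraws Monte-Carlo draws (>= 100; default 1000).
#' @param seed RNG seed for reproducibility.
#' @return list(all, nofire, fire) of \code{\link{BurdenResult}}s carrying
#'   95UI columns and per-draw samples.
#' @export
uncertaintyInterval <- function(allField, nofireField, pop, baseline,
                                params, masks, nDraws = 1000L, seed = 1L) {
  if (nDraws < 100L) stop("nDraws must be >= 100")
  builtA <- .buildStrata(allField, pop, baseline, params, masks)
  builtN <- .buildStrata(nofireField, pop, baseline, params, masks)
  ns <- length(builtA$strata)
  ## draw every uncertain input once, up front, so both scenarios (and
  ## hence the per-draw subtraction) see identical parameter realisations
  set.seed(seed)
  curveTheta <- matrix(NA_real_, builtA$nCurves, nDraws)
  for (s in builtA$strata)
    if (anyNA(curveTheta[s$curve, ]))
      curveTheta[s$curve, ] <- stats::rnorm(nDraws, s$theta, s$theta_se)
  rateDraws <- lapply(builtA$strata, function(s) {
    b <- s$baseline
    list(mRate = .lognormalDraws(b$mort_rate, b$mort_low, b$mort_high,
                                 nDraws),
         dRate = .lognormalDraws(b$daly_rate, b$daly_low, b$daly_high,
                                 nDraws),
         frac = .logitNormalDraws(b$age_fraction, b$frac_low, b$frac_high,
                                  nDraws))
  })
  mkRes <- function(built, scen) {
    mort <- matrix(0, ns, nDraws); daly <- matrix(0, ns, nDraws)
    rows <- vector("list", ns)
    for (i in seq_len(ns)) {
      s <- built$strata[[i]]; b <- s$baseline; rd <- rateDraws[[i]]
      afSum <- .afPopSum(s$G, s$pop, curveTheta[s$curve, ])
      mort[i, ] <- afSum * rd$mRate * rd$frac
      daly[i, ] <- afSum * rd$dRate * rd$frac
      afC <- .afPopSum(s$G, s$pop, s$theta)
      rows[[i]] <- data.frame(
        region = s$region, cause = s$cause, age_group = s$age_group,
        mortality = afC * b$mort_rate * b$age_fraction,
        dalys = afC * b$daly_rate * b$age_fraction)
    }
    .attachUI(BurdenResult(do.call(rbind, rows), scenario = scen,
                           draws = list(mortality = mort, dalys = daly)))
  }
  resAll <- mkRes(builtA, "all")
  resNof <- mkRes(builtN, "nofire")
  list(all = resAll, nofire = resNof,
       fire = fireAttributableBurden(resAll, resNof))
}

#' Burden per 100,000 persons per year
#'
#' @param burden attributable burden (deaths per year): a scalar or a
#'   \code{\link{BurdenResult}} (mortality summed over strata).
#' @param pop a \code{\link{PopulationGrid}} or a scalar person count.
#' @param mask optional \code{\link{RegionMask}} restricting the population.
#' @return Deaths per 100,000 persons per year.
#' @export
perCapitaRate <- function(burden, pop, mask = NULL) {
  b <- if (is(burden, "BurdenResult")) sum(burdenStrata(burden)$mortality)
       else burden
  p <- if (is(pop, "PopulationGrid")) {
    cnt <- fieldValues(pop)
    if (!is.null(mask)) sum(cnt[maskValues(mask)]) else sum(cnt)
  } else pop
  if (p <= 0) stop("zero population: per-capita rate undefined")
  1e5 * b / p
}
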