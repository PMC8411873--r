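## Poverty-exposure disparity analysis: IMR-binned exposure distributions
## and anomalies, extreme-group comparison at a stated confidence level,
## exposure-source fractions per poverty class, and the 3x3 bivariate
## poverty x exposure classification.

## interval convention used throughout: [a, b) with the final bin closed
.binIndex <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[x < edges[1L] | x > edges[length(edges)]] <- NA_integer_
  i
}

.alignedCells <- function(pmField, imr) {
  .checkAligned(pmField, imr, "PM field and IMR grid")
  pm <- .annualValues(pmField)
  iv <- fieldValues(imr)
  ok <- is.finite(pm) & is.finite(iv)
  list(pm = pm[ok], imr = iv[ok], ok = ok)
}

#' Bin cell-level exposure by IMR and summarise per bin
#'
#' Distributes grid cells into IMR bins (default width 10) and reports,
#' per occupied bin, box statistics of the PM values (quartiles, whiskers
#' at 1.5 x IQR beyond the quartiles, outlier count) plus the anomaly:
#' bin mean minus the grand mean of bin means, so anomalies average to
#' zero across occupied bins. Cell-level (unweighted) statistics by
#' default; population weighting of the means is available.
#'
#' @param pmField annual \code{\link{ConcentrationField}}.
#' @param imr an \code{\link{IMRGrid}} on the same grid.
#' @param binEdges IMR bin edges (default 0 to 100 by 10).
#' @param pop optional \code{\link{PopulationGrid}} for population-weighted
#'   bin means.
#' @return data.frame, one row per occupied bin: bin bounds, n, mean,
#'   median, q25, q75, whiskers, n_outliers, anomaly.
#' @export
binExposureByIMR <- function(pmField, imr, binEdges = seq(0, 100, 10),
                             pop = NULL) {
  if (any(diff(binEdges) <= 0)) stop("bin edges must be ascending")
  cells <- .alignedCells(pmField, imr)
  idx <- .binIndex(cells$imr, binEdges)
  if (all(is.na(idx)))
    stop("no finite overlap between the PM field and the IMR bins")
  w <- if (!is.null(pop)) fieldValues(pop)[cells$ok] else NULL
  rows <- lapply(sort(unique(idx[!is.na(idx)])), function(b) {
    v <- cells$pm[which(idx == b)]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
    mu <- if (is.null(w)) mean(v) else {
      wb <- w[which(idx == b)]
      if (sum(wb) > 0) sum(v * wb) / sum(wb) else mean(v)
    }
    data.frame(imr_low = binEdges[b], imr_high = binEdges[b + 1L],
               n = length(v), mean = mu, median = q[2],
               q25 = q[1], q75 = q[3],
               whisker_low = max(lo, min(v)),
               whisker_high = min(hi, max(v)),
               n_outliers = sum(v < lo | v > hi))
  })
  out <- do.call(rbind, rows)
  out$anomaly <- out$mean - mean(out$mean)
  out
}

#' Compare mean exposure between the extreme poverty groups
#'
#' Means of cell-level PM in the high-IMR group (IMR >= \code{highCut})
#' and the low-IMR group (IMR <= \code{lowCut}), their difference, and a
#' two-sample unequal-variance (Welch) test of the mean difference at the
#' stated confidence level; a seeded permutation test is available as an
#' alternative since no canonical test exists for this comparison.
#'
#' @param pmField annual \code{\link{ConcentrationField}}.
#' @param imr an \code{\link{IMRGrid}}.
#' @param lowCut,highCut IMR cutoffs (defaults 20 and 60).
#' @param confidence confidence level for the significance decision
#'   (default 0.99).
#' @param test \code{"welch"} or \code{"permutation"}.
#' @param nPerm permutations for the permutation test.
#' @param seed seed for the permutation test.
#' @return list(mean_low, mean_high, difference, statistic, p_value,
#'   significant, n_low, n_high).
#' @export
compareExtremeGroups <- function(pmField, imr, lowCut = 20, highCut = 60,
                                 confidence = 0.99,
                                 test = c("welch", "permutation"),
                                 nPerm = 2000L, seed = 1L) {
  test <- match.arg(test)
  cells <- .alignedCells(pmField, imr)
  lo <- cells$pm[cells$imr <= lowCut]
  hi <- cells$pm[cells$imr >= highCut]
  if (!length(lo) || !length(hi))
    stop("both extreme IMR groups must be nonempty")
  out <- list(mean_low = mean(lo), mean_high = mean(hi),
              difference = mean(hi) - mean(lo),
              n_low = length(lo), n_high = length(hi))
  if (length(lo) < 2L || length(hi) < 2L) {
    warning("a group has < 2 cells: test undefined, means still reported")
    out$statistic <- NA_real_; out$p_value <- NA_real_
    out$significant <- NA
    return(out)
  }
  if (test == "welch") {
    tt <- stats::t.test(hi, lo, var.equal = FALSE)
    out$statistic <- unname(tt$statistic)
    out$p_value <- tt$p.value
  } else {
    set.seed(seed)
    pooled <- c(hi, lo); nh <- length(hi)
    obs <- abs(out$difference)
    exceed <- sum(vapply(seq_len(nPerm), function(i) {
      sh <- sample.int(length(pooled), nh)
      abs(mean(pooled[sh]) - mean(pooled[-sh])) >= obs
    }, logical(1)))
    out$statistic <- obs
    out$p_value <- (exceed + 1) / (nPerm + 1)
  }
  out$significant <- out$p_value < (1 - confidence)
  out
}

#' Fire vs nonfire share of exposure per poverty class
#'
#' Per poverty class of the IMR scheme: mean fire-derived PM divided by
#' the sum of mean fire and mean nonfire PM over the class's cells (and
#' the complement), so the two shares sum to exactly 1. Empty classes are
#' omitted with a warning.
#'
#' @param firePM,nonfirePM annual \code{\link{ConcentrationField}}s of the
#'   fire-derived and nonfire PM2.5.
#' @param imr an \code{\link{IMRGrid}}.
#' @param scheme a \code{\link{PovertyClassScheme}}.
#' @return data.frame(class, imr_low, imr_high, n, mean_fire, mean_nonfire,
#'   fire_fraction, nonfire_fraction).
#' @export
exposureSourceFractionByClass <- function(firePM, nonfirePM, imr,
                                          scheme = PovertyClassScheme()) {
  .checkAligned(firePM, nonfirePM, "fire and nonfire fields")
  cells <- .alignedCells(firePM, imr)
  nf <- .annualValues(nonfirePM)[cells$ok]
  idx <- .binIndex(cells$imr, scheme@cutpoints)
  rows <- lapply(seq_along(scheme@labels), function(k) {
    sel <- which(idx == k)
    if (!length(sel)) {
      warning(sprintf("poverty class '%s' is empty: omitted",
                      scheme@labels[k]))
      return(NULL)
    }
    mf <- mean(cells$pm[sel]); mn <- mean(nf[sel])
    if (mf + mn <= 0)
      stop("fire + nonfire exposure must be positive in evaluated cells")
    data.frame(class = scheme@labels[k],
               imr_low = scheme@cutpoints[k],
               imr_high = scheme@cutpoints[k + 1L],
               n = length(sel), mean_fire = mf, mean_nonfire = mn,
               fire_fraction = mf / (mf + mn),
               nonfire_fraction = mn / (mf + mn))
  })
  do.call(rbind, rows)
}

#' Bivariate poverty x exposure classification map
#'
#' Assigns each cell one of nine categories by crossing IMR classes
#' (default low 0-20, medium 20-60, high 60-100 deaths per 1,000 births)
#' with PM classes (default low 0-5, medium 5-15, high 15-30 ug m-3),
#' intervals left-closed right-open with the final bin closed. Cells
#' beyond the top edge of either axis are flagged \code{NA} and counted
#' separately.
#'
#' @param pmField annual \code{\link{ConcentrationField}}.
#' @param imr an \code{\link{IMRGrid}}.
#' @param pmEdges,imrEdges ascending class edges.
#' @param pop optional \code{\link{PopulationGrid}} for per-category
#'   population totals.
#' @return list(map = integer matrix of category codes 1..9 (NA =
#'   flagged/missing), legend = data.frame(code, imr_class, pm_class),
#'   counts = per-category cell counts, population = per-category person
#'   totals (if \code{pop} given), n_flagged = cells outside the top
#'   edges).
#' @export
bivariateClassification <- function(pmField, imr,
                                    pmEdges = c(0, 5, 15, 30),
                                    imrEdges = c(0, 20, 60, 100),
                                    pop = NULL) {
  if (any(diff(pmEdges) <= 0) || any(diff(imrEdges) <= 0))
    stop("configuration error: class edges must be ascending")
  .checkAligned(pmField, imr, "PM field and IMR grid")
  pm <- .annualValues(pmField)
  iv <- fieldValues(imr)
  nI <- length(imrEdges) - 1L; nP <- length(pmEdges) - 1L
  iPM <- matrix(.binIndex(pm, pmEdges), nrow(pm))
  iIM <- matrix(.binIndex(iv, imrEdges), nrow(iv))
  code <- (iIM - 1L) * nP + iPM
  labs <- c("low", "medium", "high")
  legend <- data.frame(
    code = seq_len(nI * nP),
    imr_class = rep(labs[seq_len(nI)], each = nP),
    pm_class = rep(labs[seq_len(nP)], nI))
  counts <- tabulate(code, nbins = nI * nP)
  out <- list(map = code, legend = legend,
              counts = stats::setNames(counts, legend$code),
              n_flagged = sum(is.finite(pm) & is.finite(iv) & is.na(code)))
  if (!is.null(pop)) {
    pv <- fieldValues(pop)
    out$population <- vapply(seq_len(nI * nP), function(k)
      sum(pv[which(code == k)]), numeric(1))
  }
  out
}
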