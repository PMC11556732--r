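#' Extract a metabolic rate from an oxygen trace
#'
#' Implements a ranked local linear regression: every contiguous window
#' covering at least `ceiling(alpha * n)` of the `n` observations is fit
#' by ordinary least squares, and windows are scored by the equally
#' weighted percentile ranks of three diagnostics: absolute skewness of
#' the standardized residuals (lower is better), relative width of the
#' 95% confidence interval of the slope (lower is better), and window
#' length (longer is better). The slope of the best-ranked window is
#' returned. This favors long, clean, linear stretches and discards
#' curved equilibration artifacts at the start of a run.
#'
#' @param trace an [OxygenTrace-class] with at least 10 points.
#' @param alpha minimum window fraction (default 0.4).
#' @param stride step between candidate window start/end indices
#'   (default 1; larger values thin the enumeration for long traces).
#' @param weights named numeric weights for the `skew`, `ci` and `length`
#'   criteria (default all 1).
#' @param ... unused.
#' @return list of class `RateEstimate`: `slope` (umol L^-1 min^-1),
#'   `window` (start and end index), `diagnostics` (residual skewness,
#'   relative CI width, window fraction), `degenerate` flag.
#' @name extractRate
NULL

#' @describeIn extractRate ranked-window rate extraction.
setMethod("extractRate", "OxygenTrace",
  function(trace, alpha = 0.4, stride = 1L,
           weights = c(skew = 1, ci = 1, length = 1), ...) {
    validObject(trace)
    tm <- trace@times; y <- trace@o2
    n <- length(tm)
    if (n < 10L) stop("rate extraction requires at least 10 points")
    if (diff(range(y)) < 1e-12)
      return(structure(list(slope = 0, window = c(1L, n),
                            diagnostics = c(skewness = 0, ciWidth = 0,
                                            windowFraction = 1),
                            degenerate = TRUE), class = "RateEstimate"))
    minLen <- ceiling(alpha * n)
    starts <- seq(1L, n - minLen + 1L, by = stride)
    wins <- do.call(rbind, lapply(starts, function(s) {
      ends <- seq(s + minLen - 1L, n, by = stride)
      cbind(s, ends)
    }))
    dimnames(wins) <- NULL
    fitOne <- function(s, e) {
      xs <- tm[s:e]; ys <- y[s:e]; L <- e - s + 1L
      xm <- mean(xs); ym <- mean(ys)
      sxx <- sum((xs - xm)^2)
      slope <- sum((xs - xm) * (ys - ym)) / sxx
      res <- ys - ym - slope * (xs - xm)
      rss <- sum(res^2)
      se <- sqrt(rss / (L - 2L) / sxx)
      ciw <- if (abs(slope) > 0) 2 * stats::qt(0.975, L - 2L) * se / abs(slope)
             else Inf
      c(slope = unname(slope), skew = abs(residSkewness(res)),
        ciw = unname(ciw), len = unname(L))
    }
    stats_ <- t(apply(wins, 1L, function(w) fitOne(w[1L], w[2L])))
    score <- (weights["skew"] * percentileRank(-stats_[, "skew"]) +
              weights["ci"] * percentileRank(-stats_[, "ciw"]) +
              weights["length"] * percentileRank(stats_[, "len"])) /
             sum(weights)
    best <- which(score == max(score))
    if (length(best) > 1L) best <- best[which.max(stats_[best, "len"])]
    structure(list(
      slope = unname(stats_[best, "slope"]),
      window = c(start = unname(wins[best, 1L]),
                 end = unname(wins[best, 2L])),
      diagnostics = c(skewness = unname(stats_[best, "skew"]),
                      ciWidth = unname(stats_[best, "ciw"]),
                      windowFraction = unname(stats_[best, "len"]) / n),
      degenerate = FALSE), class = "RateEstimate")
  })

#' @export
print.RateEstimate <- function(x, ...) {
  cat("RateEstimate: slope =", format(x$slope, digits = 5),
      "umol L^-1 min^-1; window", x$window[1L], "-", x$window[2L], "\n")
  invisible(x)
}

#' Blank-corrected, per-individual, size-normalized metabolic rate
#'
#' `(rawSlope - blankSlope) * wellVolume / nIndividuals`, converted from
#' umol to nmol, gives the per-individual rate (nmol O2 individual^-1
#' min^-1); dividing by the mean individual volume gives the
#' size-normalized rate (nmol O2 mm^-3 min^-1).
#'
#' @param rawSlope,blankSlope trace slopes in umol L^-1 min^-1 (the blank
#'   is typically the mean of the plate's blank wells).
#' @param wellVolume well volume in liters.
#' @param nIndividuals number of individuals in the well (>= 1).
#' @param meanSizeMm3 optional mean individual volume in mm^3.
#' @return list with `perIndividual` and (when a size is given)
#'   `sizeNormalized`.
#' @examples
#' normalizeRate(-0.5, -0.1, 80e-6, 6)$perIndividual  # -5.333e-3
#' @export
normalizeRate <- function(rawSlope, blankSlope, wellVolume, nIndividuals,
                          meanSizeMm3 = NULL) {
  if (nIndividuals < 1) stop("'nIndividuals' must be >= 1")
  if (wellVolume <= 0) stop("'wellVolume' must be positive")
  perInd <- (rawSlope - blankSlope) * wellVolume / nIndividuals * 1e3
  out <- list(perIndividual = perInd)
  if (!is.null(meanSizeMm3)) {
    if (meanSizeMm3 <= 0) stop("'meanSizeMm3' must be positive")
    out$sizeNormalized <- perInd / meanSizeMm3
  }
  out
}

#' Gross photosynthesis and P:R ratio
#'
#' Gross photosynthesis is net photosynthesis plus respiration (oxygen
#' produced plus oxygen consumed); the P:R ratio divides gross
#' photosynthesis by respiration. Respiration enters as a positive
#' consumption magnitude.
#'
#' @param netP net photosynthesis rate (oxygen production).
#' @param respiration respiration rate as a positive magnitude.
#' @return list with `grossP` and `pToR` (NA with a warning when
#'   respiration is zero).
#' @examples
#' photosynthesisMetrics(1, 1)  # gross 2, P:R 2
#' @export
photosynthesisMetrics <- function(netP, respiration) {
  if (any(respiration < 0))
    stop("'respiration' must be a positive consumption magnitude")
  grossP <- netP + respiration
  pToR <- ifelse(respiration > 0, grossP / respiration, NA_real_)
  if (any(respiration == 0))
    warning("respiration of 0: P:R ratio undefined")
  list(grossP = grossP, pToR = pToR)
}

#' Chlorophyll a and c2 from acetone-extract absorbances
#'
#' Dinoflagellate equations `chl_a = 11.43 E663 - 0.64 E630` and
#' `chl_c2 = 27.09 E630 - 3.63 E663` (ug per extract volume), divided by
#' the plate path-length correction (default 0.584).
#'
#' @param e663,e630 absorbances at 663 and 630 nm, non-negative.
#' @param pathCorrection path-length divisor (default 0.584).
#' @return list with `chlA`, `chlC2`, `total`.
#' @examples
#' chlorophyll(0.1, 0.05)
#' @export
chlorophyll <- function(e663, e630, pathCorrection = 0.584) {
  if (any(e663 < 0) || any(e630 < 0))
    stop("absorbances must be non-negative")
  chlA <- (11.43 * e663 - 0.64 * e630) / pathCorrection
  chlC2 <- (27.09 * e630 - 3.63 * e663) / pathCorrection
  list(chlA = chlA, chlC2 = chlC2, total = chlA + chlC2)
}

#' Larval volume as an elliptical sphere
#'
#' `V = (4/3) * pi * a * b^2` with `a = width / 2` and `b = length / 2`,
#' in mm^3.
#'
#' @param lengthMm,widthMm larval length and width in mm, positive.
#' @return Volume in mm^3.
#' @examples
#' larvalVolume(0.2, 0.1)  # 2.0944e-3
#' @export
larvalVolume <- function(lengthMm, widthMm) {
  if (any(lengthMm <= 0) || any(widthMm <= 0))
    stop("dimensions must be positive")
  (4 / 3) * pi * (widthMm / 2) * (lengthMm / 2)^2
}

#' Settlement proportion
#'
#' @param nSettled number of settled primary polyps.
#' @param nStart number of starting larvae (> 0).
#' @return `nSettled / nStart`.
#' @export
settlementProportion <- function(nSettled, nStart) {
  if (any(nStart <= 0)) stop("'nStart' must be positive")
  if (any(nSettled < 0) || any(nSettled > nStart))
    stop("'nSettled' must lie in [0, nStart]")
  nSettled / nStart
}

#' Larval density from replicate aliquot counts
#'
#' @param counts larvae counted in each replicate aliquot.
#' @param aliquotVolumeMl aliquot volume in ml (> 0).
#' @return Mean larvae per ml.
#' @export
survivalDensity <- function(counts, aliquotVolumeMl) {
  if (aliquotVolumeMl <= 0) stop("'aliquotVolumeMl' must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  mean(counts) / aliquotVolumeMl
}
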