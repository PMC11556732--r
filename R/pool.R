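#' Assemble a PoolMatrix from a long-format spectra table
#'
#' The pool size of a metabolite in a sample is its total ion count: the
#' sum of all isotopologue peak intensities.
#'
#' @param spectra long-format data.frame with columns `metabolite`,
#'   `n_carbons`, `isotopologue`, `sample`, `intensity`.
#' @return A [PoolMatrix-class] in `raw` state.
#' @export
poolFromSpectra <- function(spectra) {
  spectra <- validateSpectraTable(spectra)
  agg <- stats::aggregate(intensity ~ sample + metabolite, data = spectra,
                          FUN = sum)
  samples <- sort(unique(agg$sample))
  mets <- sort(unique(agg$metabolite))
  m <- matrix(0, length(samples), length(mets),
              dimnames = list(samples, mets))
  m[cbind(match(agg$sample, samples), match(agg$metabolite, mets))] <-
    agg$intensity
  PoolMatrix(m, state = "raw")
}

#' Median-normalize metabolite pool sizes
#'
#' Divides every intensity by the median peak intensity of all metabolites
#' within its sample, removing sample-to-sample differences in total
#' biomass. After normalization the within-sample median is exactly 1.
#'
#' @param pool a [PoolMatrix-class] in `raw` state.
#' @param ... unused.
#' @return A [PoolMatrix-class] in `median_normalized` state.
#' @examples
#' m <- matrix(c(2, 4, 6), 1, dimnames = list("s1", c("a", "b", "c")))
#' poolValues(medianNormalize(PoolMatrix(m)))  # 0.5 1.0 1.5
#' @name medianNormalize
NULL

#' @describeIn medianNormalize per-sample median scaling.
setMethod("medianNormalize", "PoolMatrix", function(pool, ...) {
  if (pool@state != "raw")
    stop("medianNormalize() expects a PoolMatrix in 'raw' state, got '",
         pool@state, "'")
  med <- apply(pool@values, 1L, stats::median)
  bad <- med <= 0
  if (any(bad))
    stop("degenerate input: zero median peak intensity in sample(s) ",
         paste(rownames(pool@values)[bad], collapse = ", "))
  PoolMatrix(sweep(pool@values, 1L, med, "/"), state = "median_normalized")
})

#' Log(x + 1) transform of normalized pool sizes
#'
#' Applies the natural-log `log(value + 1)` transform used before
#' distance-based and discriminant analyses. Requires median-normalized
#' input so the state machine `raw -> median_normalized -> log1p` is
#' explicit.
#'
#' @param pool a [PoolMatrix-class] in `median_normalized` state.
#' @param ... unused.
#' @return A [PoolMatrix-class] in `log1p` state.
#' @name log1pTransform
NULL

#' @describeIn log1pTransform natural-log transform.
setMethod("log1pTransform", "PoolMatrix", function(pool, ...) {
  if (pool@state != "median_normalized")
    stop("log1pTransform() expects a 'median_normalized' PoolMatrix, got '",
         pool@state, "'")
  if (any(pool@values < 0))
    stop("negative values cannot be log(x + 1) transformed")
  PoolMatrix(log1p(pool@values), state = "log1p")
})

#' Between-treatment fold change as relative difference
#'
#' `fc = (meanHigh - meanAmbient) / meanAmbient`, so a fold change of
#' 0.10 is a 10 percent increase at high temperature and negative values
#' mark metabolites larger at ambient.
#'
#' @param meanAmbient non-negative mean at the reference (ambient) level;
#'   must be positive.
#' @param meanHigh non-negative mean at the comparison (high) level.
#' @return Numeric fold change, `>= -1` for non-negative means.
#' @examples
#' foldChange(10, 11)  # 0.10
#' @export
foldChange <- function(meanAmbient, meanHigh) {
  stopifnot(length(meanAmbient) == length(meanHigh))
  if (any(!is.finite(meanAmbient)) || any(!is.finite(meanHigh)) ||
      any(meanHigh < 0))
    stop("means must be finite and non-negative")
  if (any(meanAmbient <= 0))
    stop("degenerate input: reference (ambient) mean must be positive")
  (meanHigh - meanAmbient) / meanAmbient
}

#' Per-metabolite group means with standard errors
#'
#' @param values a [PoolMatrix-class] or a numeric samples-by-metabolites
#'   matrix with sample row names, or a long data.frame with columns
#'   `metabolite`, `sample` and a value column named by `valueCol`.
#' @param metadata data.frame with a `sample` column and the grouping
#'   factor.
#' @param factor name of the grouping column in `metadata`.
#' @param valueCol value column name for long-format input (default
#'   `"value"`; `"enrichment"` tables work by passing that name).
#' @return data.frame with columns `metabolite`, `level`, `n`, `mean`,
#'   `se` (NA when a level has a single observation).
#' @export
groupMeans <- function(values, metadata, factor, valueCol = "value") {
  if (is(values, "PoolMatrix")) values <- poolValues(values)
  if (is.matrix(values)) {
    long <- data.frame(
      metabolite = rep(colnames(values), each = nrow(values)),
      sample = rep(rownames(values), ncol(values)),
      value = as.vector(values))
    valueCol <- "value"
  } else {
    long <- as.data.frame(values)
    stopifnot(all(c("metabolite", "sample", valueCol) %in% names(long)))
  }
  checkSamplesCovered(long$sample, metadata)
  lev <- metadata[[factor]][match(long$sample, metadata$sample)]
  if (any(is.na(lev)))
    stop("missing '", factor, "' metadata for some samples")
  key <- paste(long$metabolite, lev, sep = "\r")
  sp <- split(long[[valueCol]], key)
  keys <- strsplit(names(sp), "\r", fixed = TRUE)
  data.frame(
    metabolite = vapply(keys, `[`, "", 1L),
    level = vapply(keys, `[`, "", 2L),
    n = vapply(sp, length, 0L),
    mean = vapply(sp, mean, 0),
    se = vapply(sp, function(v)
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_, 0),
    row.names = NULL)
}
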