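#' @import methods
NULL

#' Raw isotopologue spectrum for one metabolite in one sample
#'
#' Holds the observed M+0 ... M+n ion intensities of a metabolite with
#' `nCarbons` carbon atoms, as exported by MAVEN-style peak picking. Index
#' `i + 1` of `intensities` is the ion count at observed mass shift M+i.
#'
#' @slot metaboliteId character(1) metabolite identifier.
#' @slot sampleId character(1) sample identifier.
#' @slot nCarbons integer(1) number of carbon atoms (>= 1).
#' @slot intensities numeric vector of length `nCarbons + 1`, non-negative,
#'   with at least one positive entry.
#'
#' @seealso [IsotopologueSpectrum()], [correctNaturalAbundance()]
#' @export
setClass("IsotopologueSpectrum",
  representation(
    metaboliteId = "character",
    sampleId     = "character",
    nCarbons     = "integer",
    intensities  = "numeric"
  )
)

setValidity("IsotopologueSpectrum", function(object) {
  msg <- character()
  if (length(object@nCarbons) != 1L || is.na(object@nCarbons) ||
      object@nCarbons < 1L)
    msg <- c(msg, "'nCarbons' must be a single positive integer")
  if (length(object@intensities) != object@nCarbons + 1L)
    msg <- c(msg, sprintf("'intensities' must have length nCarbons + 1 = %d",
                          object@nCarbons + 1L))
  if (any(!is.finite(object@intensities)) || any(object@intensities < 0))
    msg <- c(msg, "'intensities' must be finite and non-negative")
  if (all(object@intensities == 0))
    msg <- c(msg, "all intensities are zero: not a valid spectrum")
  if (length(msg)) msg else TRUE
})

#' Construct an IsotopologueSpectrum
#'
#' @param metaboliteId,sampleId identifiers.
#' @param nCarbons number of carbon atoms in the metabolite.
#' @param intensities numeric vector of `nCarbons + 1` non-negative ion
#'   counts, ordered M+0 ... M+n.
#' @return An [IsotopologueSpectrum-class] object.
#' @examples
#' IsotopologueSpectrum("glucose", "s1", 6, c(900, 60, 5, 0, 0, 0, 35))
#' @export
IsotopologueSpectrum <- function(metaboliteId, sampleId, nCarbons,
                                 intensities) {
  new("IsotopologueSpectrum",
      metaboliteId = as.character(metaboliteId),
      sampleId     = as.character(sampleId),
      nCarbons     = as.integer(nCarbons),
      intensities  = as.numeric(intensities))
}

setMethod("show", "IsotopologueSpectrum", function(object) {
  cat("IsotopologueSpectrum:", object@metaboliteId,
      "in", object@sampleId, "\n")
  cat("  ", object@nCarbons, "carbons; intensities M+0..M+",
      object@nCarbons, ":\n", sep = "")
  print(setNames(object@intensities, paste0("M+", 0:object@nCarbons)))
})

#' Natural-abundance-corrected isotopologue distribution
#'
#' Fractions `f0 ... fn` of metabolite molecules carrying exactly
#' 0 ... n tracer-derived labeled carbons, after removal of the natural
#' carbon-13 background. Fractions are non-negative and sum to one.
#'
#' @slot metaboliteId character(1) metabolite identifier.
#' @slot sampleId character(1) sample identifier.
#' @slot nCarbons integer(1) number of carbon atoms.
#' @slot fractions numeric vector of length `nCarbons + 1` in `[0, 1]`
#'   summing to 1 (tolerance 1e-9).
#' @export
setClass("CorrectedDistribution",
  representation(
    metaboliteId = "character",
    sampleId     = "character",
    nCarbons     = "integer",
    fractions    = "numeric"
  )
)

setValidity("CorrectedDistribution", function(object) {
  msg <- character()
  if (length(object@fractions) != object@nCarbons + 1L)
    msg <- c(msg, "'fractions' must have length nCarbons + 1")
  if (any(object@fractions < -1e-12) || any(object@fractions > 1 + 1e-12))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (abs(sum(object@fractions) - 1) > 1e-9)
    msg <- c(msg, "fractions must sum to 1 (tolerance 1e-9)")
  if (length(msg)) msg else TRUE
})

#' Construct a CorrectedDistribution
#'
#' @param metaboliteId,sampleId identifiers.
#' @param nCarbons number of carbon atoms.
#' @param fractions numeric vector of labeled-carbon-count fractions,
#'   length `nCarbons + 1`, summing to 1.
#' @return A [CorrectedDistribution-class] object.
#' @examples
#' CorrectedDistribution("glucose", "s1", 2, c(0.5, 0.3, 0.2))
#' @export
CorrectedDistribution <- function(metaboliteId, sampleId, nCarbons,
                                  fractions) {
  new("CorrectedDistribution",
      metaboliteId = as.character(metaboliteId),
      sampleId     = as.character(sampleId),
      nCarbons     = as.integer(nCarbons),
      fractions    = as.numeric(fractions))
}

setMethod("show", "CorrectedDistribution", function(object) {
  cat("CorrectedDistribution:", object@metaboliteId,
      "in", object@sampleId, "\n")
  print(round(setNames(object@fractions,
                       paste0("f", 0:object@nCarbons)), 6))
})

#' Samples-by-metabolites pool-size matrix
#'
#' A matrix of metabolite pool sizes (ion-count peak intensities) with an
#' explicit normalization state. Legal state transitions are
#' `raw -> median_normalized -> log1p`; [medianNormalize()] and
#' [log1pTransform()] enforce them.
#'
#' @slot values numeric matrix, samples in rows, metabolites in columns,
#'   with dimnames giving sample and metabolite identifiers.
#' @slot state character(1), one of `"raw"`, `"median_normalized"`,
#'   `"log1p"`.
#' @export
setClass("PoolMatrix",
  representation(values = "matrix", state = "character")
)

setValidity("PoolMatrix", function(object) {
  msg <- character()
  if (!object@state %in% c("raw", "median_normalized", "log1p"))
    msg <- c(msg, "state must be raw, median_normalized or log1p")
  if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
    msg <- c(msg, "values must carry sample (row) and metabolite (column) names")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (object@state != "log1p" && any(object@values < 0))
    msg <- c(msg, "negative values are not allowed before log transformation")
  if (length(msg)) msg else TRUE
})

#' Construct a PoolMatrix
#'
#' @param values numeric matrix (samples x metabolites) with dimnames.
#' @param state normalization state, default `"raw"`.
#' @return A [PoolMatrix-class] object.
#' @examples
#' m <- matrix(c(2, 4, 6, 5, 5, 5), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("a", "b", "c")))
#' PoolMatrix(m)
#' @export
PoolMatrix <- function(values, state = "raw") {
  new("PoolMatrix", values = as.matrix(values), state = state)
}

setMethod("show", "PoolMatrix", function(object) {
  cat("PoolMatrix:", nrow(object@values), "samples x",
      ncol(object@values), "metabolites; state =", object@state, "\n")
})

#' Timestamped oxygen-concentration trace for one respirometry well
#'
#' @slot times numeric, strictly increasing times in minutes.
#' @slot o2 numeric oxygen concentrations (umol L^-1), same length.
#' @slot wellVolume numeric(1) well volume in liters.
#' @slot nIndividuals integer(1) individuals in the well (0 for blanks).
#' @slot meta list of grouping labels (treatment, assay temperature, tank).
#' @export
setClass("OxygenTrace",
  representation(
    times        = "numeric",
    o2           = "numeric",
    wellVolume   = "numeric",
    nIndividuals = "integer",
    meta         = "list"
  )
)

setValidity("OxygenTrace", function(object) {
  msg <- character()
  if (length(object@times) != length(object@o2))
    msg <- c(msg, "'times' and 'o2' must have equal length")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be strictly increasing")
  if (object@nIndividuals < 0L)
    msg <- c(msg, "'nIndividuals' must be >= 0")
  if (object@wellVolume <= 0)
    msg <- c(msg, "'wellVolume' must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an OxygenTrace
#'
#' @param times minutes, strictly increasing.
#' @param o2 oxygen concentrations in umol per liter.
#' @param wellVolume well volume in liters (default 80e-6, an 80 uL well).
#' @param nIndividuals number of individuals in the well; 0 marks a blank.
#' @param meta optional list of grouping labels.
#' @return An [OxygenTrace-class] object.
#' @export
OxygenTrace <- function(times, o2, wellVolume = 80e-6, nIndividuals = 0L,
                        meta = list()) {
  new("OxygenTrace", times = as.numeric(times), o2 = as.numeric(o2),
      wellVolume = as.numeric(wellVolume),
      nIndividuals = as.integer(nIndividuals), meta = meta)
}

setMethod("show", "OxygenTrace", function(object) {
  cat("OxygenTrace:", length(object@times), "points over",
      round(diff(range(object@times)), 2), "min;",
      object@nIndividuals, "individuals\n")
})

#' Fitted two-group PLS-DA model
#'
#' NIPALS partial least squares fit of (optionally autoscaled) metabolite
#' data against a one-hot-coded two-level class membership.
#'
#' @slot xWeights p x A matrix of unit-norm X weights per component.
#' @slot xLoadings p x A matrix of X loadings.
#' @slot xScores n x A matrix of X scores (mutually orthogonal).
#' @slot yLoadings 2 x A matrix of Y loadings.
#' @slot explainedXVariance numeric(A), fraction of (scaled) X sum of
#'   squares captured by each X-variate.
#' @slot ssY numeric(A), Y sum of squares captured by each component
#'   (the VIP weights).
#' @slot scaling list with `center` and `scale` vectors used on X.
#' @slot labels factor of sample class labels.
#' @slot variableIds character vector of variable (metabolite) names.
#' @export
setClass("PlsdaModel",
  representation(
    xWeights           = "matrix",
    xLoadings          = "matrix",
    xScores            = "matrix",
    yLoadings          = "matrix",
    explainedXVariance = "numeric",
    ssY                = "numeric",
    scaling            = "list",
    labels             = "factor",
    variableIds        = "character"
  )
)

setMethod("show", "PlsdaModel", function(object) {
  cat("PlsdaModel:", ncol(object@xScores), "components,",
      length(object@variableIds), "variables,",
      nrow(object@xScores), "samples\n")
  cat("  explained X variance:",
      paste0(round(100 * object@explainedXVariance, 1), "%", collapse = ", "),
      "\n")
})
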