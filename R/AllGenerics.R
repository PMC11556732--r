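#' @rdname enrichment
#' @export
setGeneric("enrichment", function(dist, ...) standardGeneric("enrichment"))

#' @rdname carbonSpecificEnrichment
#' @export
setGeneric("carbonSpecificEnrichment",
           function(dist, i, ...) standardGeneric("carbonSpecificEnrichment"))

#' @rdname medianNormalize
#' @export
setGeneric("medianNormalize",
           function(pool, ...) standardGeneric("medianNormalize"))

#' @rdname log1pTransform
#' @export
setGeneric("log1pTransform",
           function(pool, ...) standardGeneric("log1pTransform"))

#' @rdname euclideanDistances
#' @export
setGeneric("euclideanDistances",
           function(pool, ...) standardGeneric("euclideanDistances"))

#' @rdname vipScores
#' @export
setGeneric("vipScores",
           function(model, ...) standardGeneric("vipScores"))

#' @rdname extractRate
#' @export
setGeneric("extractRate",
           function(trace, ...) standardGeneric("extractRate"))

#' Accessors for core containers
#'
#' `poolValues()` returns the samples-by-metabolites matrix of a
#' [PoolMatrix-class]; `poolState()` its normalization state;
#' `sampleIds()` and `metaboliteIds()` the row and column identifiers;
#' `fractions()` the corrected isotopologue fractions of a
#' [CorrectedDistribution-class].
#'
#' @param x a package object.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("poolValues", function(x) standardGeneric("poolValues"))
#' @rdname accessors
#' @export
setGeneric("poolState", function(x) standardGeneric("poolState"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))
#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' @rdname accessors
setMethod("poolValues", "PoolMatrix", function(x) x@values)
#' @rdname accessors
setMethod("poolState", "PoolMatrix", function(x) x@state)
#' @rdname accessors
setMethod("sampleIds", "PoolMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("metaboliteIds", "PoolMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("fractions", "CorrectedDistribution", function(x) x@fractions)
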