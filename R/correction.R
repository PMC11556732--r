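#' Binomial natural-abundance correction matrix
#'
#' Builds the (n+1) x (n+1) column-stochastic matrix `C` mapping the true
#' labeled-carbon-count distribution of an n-carbon metabolite to the
#' observed mass-shift distribution under a carbon-only natural-abundance
#' model. Entry `C[k+1, j+1]` is the probability of observing mass shift
#' M+k given j tracer-labeled carbons: the remaining `n - j` carbons each
#' carry a natural carbon-13 with probability `p13c`, so
#' `C[k+1, j+1] = choose(n-j, k-j) * p13c^(k-j) * (1-p13c)^(n-k)` for
#' `k >= j` and 0 otherwise. Correction for hydrogen, nitrogen, oxygen or
#' sulfur isotopes and resolution-dependent peak merging is out of scope;
#' extending the model amounts to convolving further column kernels here.
#'
#' @param nCarbons number of carbon atoms, a positive integer.
#' @param p13c natural carbon-13 atom fraction, in (0, 0.5). Default
#'   0.0107, the IUPAC representative value.
#' @return A dense `(nCarbons+1) x (nCarbons+1)` matrix whose columns each
#'   sum to 1.
#' @examples
#' buildCorrectionMatrix(1, p13c = 0.01)
#' colSums(buildCorrectionMatrix(6))
#' @export
buildCorrectionMatrix <- function(nCarbons, p13c = 0.0107) {
  if (length(nCarbons) != 1L || is.na(nCarbons) || nCarbons < 1 ||
      nCarbons != round(nCarbons))
    stop("'nCarbons' must be a single positive integer")
  checkP13c(p13c)
  n <- as.integer(nCarbons)
  C <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    k <- j:n
    C[k + 1L, j + 1L] <- stats::dbinom(k - j, size = n - j, prob = p13c)
  }
  dimnames(C) <- list(paste0("M+", 0:n), paste0("labeled", 0:n))
  C
}

checkP13c <- function(p13c) {
  if (length(p13c) != 1L || !is.finite(p13c) || p13c <= 0 || p13c >= 0.5)
    stop("'p13c' must lie in (0, 0.5); got ", format(p13c),
         " (the correction system is ill-conditioned otherwise)")
  invisible(p13c)
}

#' Correct an isotopologue spectrum for natural carbon-13 abundance
#'
#' Solves `observed = C %*% true` for the true labeled-carbon-count
#' fractions by non-negative least squares (so that measurement noise can
#' never produce negative fractions), then renormalizes the solution to
#' sum to one. The observed intensities are scale-free: only their
#' relative magnitudes matter.
#'
#' @param spectrum an [IsotopologueSpectrum-class].
#' @param p13c natural carbon-13 atom fraction, see
#'   [buildCorrectionMatrix()].
#' @return A [CorrectedDistribution-class] with the tracer-only fractions.
#' @examples
#' sp <- IsotopologueSpectrum("x", "s1", 1, c(0.99, 0.01))
#' fractions(correctNaturalAbundance(sp, p13c = 0.01))
#' @export
correctNaturalAbundance <- function(spectrum, p13c = 0.0107) {
  stopifnot(is(spectrum, "IsotopologueSpectrum"))
  validObject(spectrum)
  f <- deconvolveVector(spectrum@intensities, spectrum@nCarbons, p13c)
  CorrectedDistribution(spectrum@metaboliteId, spectrum@sampleId,
                        spectrum@nCarbons, f)
}

deconvolveVector <- function(intensities, nCarbons, p13c,
                             C = buildCorrectionMatrix(nCarbons, p13c)) {
  if (all(intensities == 0))
    stop("degenerate input: all-zero spectrum cannot be corrected")
  total <- sum(intensities)
  fit <- pracma::lsqnonneg(C, intensities / total)
  x <- fit$x
  s <- sum(x)
  if (s <= 0)
    stop("degenerate input: non-negative deconvolution returned zero mass")
  x / s
}

#' Correct a long-format isotopologue table
#'
#' Vectorized companion to [correctNaturalAbundance()]: corrects every
#' (metabolite, sample) spectrum in a long-format table in one call,
#' reusing one correction matrix per carbon count.
#'
#' @param spectra data.frame with columns `metabolite`, `n_carbons`,
#'   `isotopologue` (integer mass shift 0..n), `sample`, `intensity`.
#' @param p13c natural carbon-13 atom fraction.
#' @return A long-format data.frame with columns `metabolite`,
#'   `n_carbons`, `isotopologue`, `sample`, `fraction`.
#' @export
correctSpectra <- function(spectra, p13c = 0.0107) {
  spectra <- validateSpectraTable(spectra)
  checkP13c(p13c)
  out <- lapply(split(spectra, spectra$metabolite, drop = TRUE), function(d) {
    n <- d$n_carbons[1L]
    C <- buildCorrectionMatrix(n, p13c)
    persample <- lapply(split(d, d$sample, drop = TRUE), function(ds) {
      y <- ds$intensity[order(ds$isotopologue)]
      data.frame(metabolite = ds$metabolite[1L], n_carbons = n,
                 isotopologue = 0:n, sample = ds$sample[1L],
                 fraction = deconvolveVector(y, n, p13c, C))
    })
    do.call(rbind, persample)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @describeIn enrichment total atom-fraction enrichment of a corrected
#'   distribution.
setMethod("enrichment", "CorrectedDistribution", function(dist, ...) {
  validObject(dist)
  n <- dist@nCarbons
  sum((0:n) * dist@fractions) / n
})

#' Carbon-13 atom-fraction enrichment
#'
#' The proportion of carbon-13 atoms among all carbon atoms of a
#' metabolite pool: `sum(i * f_i) / n` over the corrected
#' labeled-carbon-count fractions `f_i`. Lies in `[0, 1]`; 0 for an
#' unlabeled pool, 1 for a uniformly fully labeled pool.
#'
#' @param dist a [CorrectedDistribution-class], or (for the table method)
#'   a corrected long-format table from [correctSpectra()].
#' @param ... unused.
#' @return A numeric enrichment in `[0, 1]`.
#' @examples
#' d <- CorrectedDistribution("x", "s", 2, c(0.5, 0.3, 0.2))
#' enrichment(d)  # 0.35
#' @name enrichment
NULL

#' Enrichment of every spectrum in a corrected table
#'
#' @param corrected long-format output of [correctSpectra()].
#' @return data.frame with columns `metabolite`, `sample`, `enrichment`.
#' @export
enrichmentTable <- function(corrected) {
  stopifnot(all(c("metabolite", "n_carbons", "isotopologue", "sample",
                  "fraction") %in% names(corrected)))
  agg <- stats::aggregate(
    cbind(num = corrected$isotopologue * corrected$fraction,
          den = rep(1, nrow(corrected))) ~ metabolite + sample + n_carbons,
    data = corrected, FUN = sum)
  data.frame(metabolite = agg$metabolite, sample = agg$sample,
             enrichment = agg$num / agg$n_carbons)
}

#' Carbon-specific enrichment
#'
#' The fraction of metabolite molecules carrying exactly `i` labeled
#' carbon atoms, i.e. component `f_i` of the corrected distribution.
#'
#' @param dist a [CorrectedDistribution-class].
#' @param i number of labeled carbons, `0 <= i <= nCarbons`.
#' @param ... unused.
#' @return Numeric fraction in `[0, 1]`.
#' @name carbonSpecificEnrichment
NULL

#' @describeIn carbonSpecificEnrichment extract `f_i`.
setMethod("carbonSpecificEnrichment", "CorrectedDistribution",
  function(dist, i, ...) {
    validObject(dist)
    if (length(i) != 1L || is.na(i) || i < 0 || i > dist@nCarbons ||
        i != round(i))
      stop("'i' must be an integer in 0..", dist@nCarbons)
    dist@fractions[i + 1L]
  })
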