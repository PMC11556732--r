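# Internal validation helpers shared by the io readers and the vectorized
# correction path.

validateSpectraTable <- function(spectra) {
  required <- c("metabolite", "n_carbons", "isotopologue", "sample",
                "intensity")
  missing <- setdiff(required, names(spectra))
  if (length(missing))
    stop("spectra table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(spectra$intensity)) || any(spectra$intensity < 0))
    stop("intensities must be finite and non-negative")
  for (m in unique(spectra$metabolite)) {
    d <- spectra[spectra$metabolite == m, ]
    n <- unique(d$n_carbons)
    if (length(n) != 1L)
      stop("metabolite '", m, "' has inconsistent n_carbons")
    for (s in unique(d$sample)) {
      iso <- sort(d$isotopologue[d$sample == s])
      if (!identical(as.integer(iso), 0:as.integer(n)))
        stop("metabolite '", m, "' in sample '", s,
             "': isotopologue rows do not cover 0..", n,
             " exactly once (declared ", n, " carbons)")
    }
  }
  spectra
}

checkSamplesCovered <- function(dataSamples, metadata) {
  orphans <- setdiff(unique(dataSamples), metadata$sample)
  if (length(orphans))
    stop("sample(s) present in data but absent from metadata: ",
         paste(orphans, collapse = ", "))
  invisible(TRUE)
}

# Sample skewness (third standardized moment); returns 0 for (near-)zero
# variance so that exact fits rank as perfectly symmetric.
residSkewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- sum((x - m)^2) / n
  if (s2 < .Machine$double.eps * max(1, m^2)) return(0)
  (sum((x - m)^3) / n) / s2^1.5
}

percentileRank <- function(x) rank(x, ties.method = "average") / length(x)
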