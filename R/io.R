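#' Read a long-format isotopologue CSV
#'
#' Expected columns: `metabolite`, `n_carbons`, `isotopologue` (integer
#' mass shift 0..n), `sample`, `intensity`. Each (metabolite, sample)
#' must cover mass shifts 0..n exactly once; missing columns or carbon
#' counts inconsistent with the isotopologue rows are schema errors.
#'
#' @param path CSV file path.
#' @return Validated long-format data.frame.
#' @export
readIsotopologueCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validateSpectraTable(utils::read.csv(path, stringsAsFactors = FALSE,
                                       check.names = FALSE))
}

#' Write a long-format isotopologue CSV
#'
#' @param spectra long-format spectra data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeIsotopologueCsv <- function(spectra, path) {
  validateSpectraTable(spectra)
  utils::write.csv(spectra, path, row.names = FALSE)
  invisible(path)
}

#' Read a sample-metadata CSV
#'
#' Required columns: `sample`, `treatment`, `isotope`, `light`. Optional
#' grouping columns (`tank`, `batch`) are carried through.
#'
#' @param path CSV file path.
#' @return data.frame of sample metadata.
#' @export
readMetadataCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  md <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample", "treatment", "isotope", "light")
  missing <- setdiff(required, names(md))
  if (length(missing))
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(md$sample))
    stop("duplicated sample identifiers in metadata")
  md
}

#' Read oxygen-trace CSV into OxygenTrace objects
#'
#' Expected columns: `well`, `time_min`, `o2_umol_l`, plus per-well
#' constants `n_individuals` and `well_volume_l` (and any extra columns,
#' kept as metadata).
#'
#' @param path CSV file path.
#' @return Named list of [OxygenTrace-class] objects, one per well.
#' @export
readOxygenCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("well", "time_min", "o2_umol_l", "n_individuals",
                "well_volume_l")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("oxygen table is missing column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(d), required)
  lapply(split(d, d$well), function(w) {
    w <- w[order(w$time_min), ]
    OxygenTrace(times = w$time_min, o2 = w$o2_umol_l,
                wellVolume = w$well_volume_l[1L],
                nIndividuals = w$n_individuals[1L],
                meta = as.list(w[1L, extra, drop = FALSE]))
  })
}
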