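#' Pipeline configuration
#'
#' Settings for [runPipeline()]. Defaults follow the analysis design:
#' VIP selection at 1.0, 999 permutations, natural carbon-13 abundance
#' 0.0107, and rate-extraction alpha 0.4.
#'
#' @param vipThreshold VIP selection threshold.
#' @param nPermutations PERMANOVA permutations.
#' @param seed mandatory integer seed for all permutation procedures.
#' @param p13c natural carbon-13 atom fraction.
#' @param alpha respirometry minimum window fraction.
#' @param outDir optional output directory; when given, tidy CSVs and a
#'   JSON run report are written.
#' @return list of class `RunConfig`.
#' @export
pipelineConfig <- function(vipThreshold = 1.0, nPermutations = 999, seed,
                           p13c = 0.0107, alpha = 0.4, outDir = NULL) {
  if (missing(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' is mandatory")
  checkP13c(p13c)
  structure(list(vipThreshold = vipThreshold,
                 nPermutations = nPermutations, seed = as.integer(seed),
                 p13c = p13c, alpha = alpha, outDir = outDir),
            class = "RunConfig")
}

#' Run the full tracing analysis pipeline
#'
#' Orchestrates the stages on a long-format isotopologue table plus
#' sample metadata: natural-abundance correction; enrichment; pool
#' assembly with median normalization and log(x+1) transform; the
#' label-presence control PERMANOVA (isotope x temperature on
#' illuminated samples); temperature PERMANOVA, PCA, PLS-DA/VIP and fold
#' changes for pool size and for enrichment (labeled illuminated samples
#' only); quadrant classification with pathway report; and the
#' light-versus-dark enrichment validation when dark controls are
#' present. Deterministic given the seed in `config`.
#'
#' @param spectra long-format spectra data.frame (or a CSV path).
#' @param metadata sample metadata data.frame (or a CSV path) with
#'   columns `sample`, `treatment`, `isotope`, `light`.
#' @param config a [pipelineConfig()].
#' @param annotations pathway annotation (default packaged table).
#' @return list of class `PipelineResult` with elements `corrected`,
#'   `enrichment`, `pool` (log1p [PoolMatrix-class]),
#'   `permanovaControl`, `permanovaPool`, `permanovaEnrichment`,
#'   `pcaPool`, `vipPool`, `vipEnrichment`, `quadrants`,
#'   `pathwayReport`, `lightDark` (NULL without dark controls) and
#'   `report` (settings echo). With `config$outDir` set, writes one tidy
#'   CSV per table and `run_report.json`.
#' @export
runPipeline <- function(spectra, metadata, config,
                        annotations = pathwayAnnotations()) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.character(spectra)) spectra <- readIsotopologueCsv(spectra)
  else spectra <- validateSpectraTable(spectra)
  if (is.character(metadata)) metadata <- readMetadataCsv(metadata)
  checkSamplesCovered(spectra$sample, metadata)

  corrected <- correctSpectra(spectra, p13c = config$p13c)
  enr <- enrichmentTable(corrected)

  pool <- poolFromSpectra(spectra)
  poolNorm <- medianNormalize(pool)
  poolLog <- log1pTransform(poolNorm)

  light <- metadata$sample[metadata$light == "light"]
  labeled <- metadata$sample[metadata$light == "light" &
                             metadata$isotope == "13C"]
  if (length(unique(metadata$treatment[metadata$sample %in% labeled])) < 2L)
    stop("stage multivar: both treatments are required among labeled ",
         "illuminated samples")

  md <- metadata
  rownames(md) <- md$sample

  # label-presence control: isotope x temperature on illuminated samples
  permanovaControl <- NULL
  if (length(setdiff(light, labeled)) >= 4L) {
    dCtl <- euclideanDistances(poolValues(poolLog)[light, , drop = FALSE])
    permanovaControl <- permanova(dCtl, md[light, ],
                                  ~ isotope * treatment,
                                  nPerm = config$nPermutations,
                                  seed = config$seed)
  }

  labLog <- poolValues(poolLog)[labeled, , drop = FALSE]
  labNorm <- poolValues(poolNorm)[labeled, , drop = FALSE]
  labels <- factor(md[labeled, "treatment"])
  dPool <- euclideanDistances(labLog)
  permanovaPool <- permanova(dPool, md[labeled, ], ~ treatment,
                             nPerm = config$nPermutations,
                             seed = config$seed + 1L)
  pcaPool <- pcaScores(labLog)

  vipPool <- vipFoldChange(labLog, labels, measureMatrix = labNorm,
                           reference = "ambient",
                           threshold = config$vipThreshold)

  enrLab <- enr[enr$sample %in% labeled, ]
  enrMat <- with(enrLab, tapply(enrichment, list(sample, metabolite), mean))
  enrMat <- enrMat[labeled, , drop = FALSE]
  dEnr <- euclideanDistances(enrMat)
  permanovaEnrichment <- permanova(dEnr, md[labeled, ], ~ treatment,
                                   nPerm = config$nPermutations,
                                   seed = config$seed + 2L)
  vipEnrichment <- vipFoldChange(enrMat, labels,
                                 reference = "ambient",
                                 threshold = config$vipThreshold)

  quad <- quadrantCalls(vipPool, vipEnrichment)
  pw <- suppressWarnings(pathwayReport(quad, annotations))

  lightDark <- NULL
  darkSamples <- metadata$sample[metadata$light == "dark" &
                                 metadata$isotope == "13C"]
  if (length(darkSamples) >= 2L) {
    ldSamples <- c(labeled, darkSamples)
    lightDark <- lightDarkValidation(enr[enr$sample %in% ldSamples, ],
                                     metadata, annotations = annotations)
  }

  report <- list(
    package = "symbioTrace",
    version = as.character(utils::packageVersion("symbioTrace")),
    seed = config$seed, vipThreshold = config$vipThreshold,
    nPermutations = config$nPermutations, p13c = config$p13c,
    nSamples = nrow(metadata), nMetabolites = ncol(labLog),
    foldChangeScale = "median-normalized pools / raw enrichment",
    sumsOfSquares = "sequential (PERMANOVA), Type II (factorial ANOVA)")

  res <- list(corrected = corrected, enrichment = enr, pool = poolLog,
              permanovaControl = permanovaControl,
              permanovaPool = permanovaPool,
              permanovaEnrichment = permanovaEnrichment,
              pcaPool = pcaPool, vipPool = vipPool,
              vipEnrichment = vipEnrichment, quadrants = quad,
              pathwayReport = pw, lightDark = lightDark, report = report)
  class(res) <- "PipelineResult"

  if (!is.null(config$outDir)) writePipelineOutputs(res, config$outDir)
  res
}

writePipelineOutputs <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, name)
    utils::write.csv(d, file.path(outDir, name), row.names = FALSE)
  wr(res$corrected, "corrected_fractions.csv")
  wr(res$enrichment, "enrichment.csv")
  poolLong <- data.frame(
    sample = rep(sampleIds(res$pool), ncol(poolValues(res$pool))),
    metabolite = rep(metaboliteIds(res$pool), each = nrow(poolValues(res$pool))),
    value = as.vector(poolValues(res$pool)),
    state = poolState(res$pool))
  wr(poolLong, "pool_log1p.csv")
  wr(res$permanovaPool$terms, "permanova_pool.csv")
  wr(res$permanovaEnrichment$terms, "permanova_enrichment.csv")
  if (!is.null(res$permanovaControl))
    wr(res$permanovaControl$terms, "permanova_isotope_control.csv")
  wr(res$vipPool, "vip_pool.csv")
  wr(res$vipEnrichment, "vip_enrichment.csv")
  wr(res$quadrants, "quadrant_calls.csv")
  wr(res$pathwayReport, "pathway_report.csv")
  if (!is.null(res$lightDark)) {
    wr(res$lightDark$perMetabolite, "light_dark_validation.csv")
    if (!is.null(res$lightDark$perPathway))
      wr(res$lightDark$perPathway, "light_dark_pathways.csv")
  }
  jsonlite::write_json(res$report, file.path(outDir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("symbioTrace pipeline result\n")
  cat("  samples:", x$report$nSamples, " metabolites:",
      x$report$nMetabolites, "\n")
  cat("  temperature PERMANOVA p (pool):",
      format(x$permanovaPool$terms$p[1L], digits = 3),
      " (enrichment):",
      format(x$permanovaEnrichment$terms$p[1L], digits = 3), "\n")
  cat("  VIP-selected metabolites: pool", sum(x$vipPool$selected),
      "| enrichment", sum(x$vipEnrichment$selected), "\n")
  invisible(x)
}
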