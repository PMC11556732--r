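#' Default metabolite panel emulating the study design
#'
#' One row per metabolite with carbon count, lognormal pool location,
#' between-treatment pool fold change, ambient-treatment carbon-13 atom
#' enrichment in illuminated labeled samples, and the enrichment fold
#' change at high temperature. The defaults mirror the central carbon and
#' nitrogen pathway panel with effect magnitudes in the range the
#' framework is designed to resolve (e.g. a
#' +10% glucose pool at high temperature with unchanged ~0.19 enrichment;
#' +46% glutamine enrichment at constant pool; both metrics roughly
#' doubled for the arginine-glutamine dipeptide) plus unaffected
#' background metabolites so that discriminant analyses see realistic
#' variable structure.
#'
#' @param nBackground number of null background metabolites appended
#'   (default 12).
#' @return data.frame with columns `metabolite`, `n_carbons`,
#'   `pool_mean`, `pool_fc`, `enr_ambient`, `enr_fc`.
#' @export
studyPanel <- function(nBackground = 12) {
  panel <- data.frame(
    metabolite = c(
      "glucose", "glucose-6-phosphate", "fructose-6-phosphate",
      "dihydroxyacetone phosphate", "3-phosphoglycerate", "pyruvate",
      "lactate",
      "ribose-5-phosphate", "xylose-5-phosphate",
      "citrate", "isocitrate", "alpha-ketoglutarate", "succinate",
      "malate",
      "glutamine", "glutamate",
      "n-acetylglutamate", "carbamoyl phosphate", "citrulline",
      "aspartate", "argininosuccinate", "arginine", "ornithine",
      "arginine-glutamine"),
    n_carbons = c(6, 6, 6, 3, 3, 3, 3,
                  5, 5,
                  6, 6, 5, 4, 4,
                  5, 5,
                  7, 1, 6, 4, 10, 6, 5,
                  10),
    pool_mean = c(40, 6, 5, 2, 3, 8, 10,
                  2, 1.5,
                  12, 6, 4, 5, 7,
                  15, 20,
                  2, 0.8, 3, 9, 0.6, 11, 2.5,
                  1.2),
    pool_fc = c(0.10, 0, 0, 0, 0, 0, 0,
                -0.33, -0.38,
                0, 0, 0, 0, 0,
                0, 0.07,
                -0.37, 0.81, -0.38, 0.26, 0, 0, 0,
                1.07),
    enr_ambient = c(0.19, 0.17, 0.16, 0.15, 0.14, 0.15, 0.12,
                    0.10, 0.10,
                    0.254, 0.264, 0.09, 0.153, 0.085,
                    0.05, 0.06,
                    0.02, 0.02, 0.02, 0.05, 0.015, 0.01, 0.01,
                    0.02),
    enr_fc = c(0, -0.13, -0.10, -0.15, -0.12, -0.13, -0.37,
               0, 0,
               -0.11, -0.05, 0, 0, 0,
               0.46, 0.06,
               0, 0, 0.38, 0.08, -0.88, 0, 0.88,
               1.08),
    stringsAsFactors = FALSE)
  if (nBackground > 0) {
    bg <- data.frame(
      metabolite = sprintf("background-%02d", seq_len(nBackground)),
      n_carbons = rep_len(c(3, 4, 5, 6, 7, 8, 9, 10), nBackground),
      pool_mean = rep_len(c(1, 2, 4, 8), nBackground),
      pool_fc = 0, enr_ambient = 0.05, enr_fc = 0,
      stringsAsFactors = FALSE)
    panel <- rbind(panel, bg)
  }
  panel
}

#' Simulation configuration
#'
#' Bundles the generator settings. Defaults reproduce the study
#' conditions: 6 labeled-light and 6 unlabeled-light vials per
#' temperature plus 2 labeled-dark controls per temperature, an atom
#' labeling probability of 0.4 in newly synthesized molecules,
#' multiplicative lognormal intensity noise with CV 0.15, a lognormal
#' per-sample biomass factor, and the natural carbon-13 abundance 0.0107.
#'
#' @param panel metabolite panel, see [studyPanel()].
#' @param nLabeled labeled (13C) illuminated vials per temperature.
#' @param nUnlabeled unlabeled (12C) illuminated vials per temperature.
#' @param nDark labeled dark-control vials per temperature.
#' @param pAtom probability a carbon in a newly synthesized molecule is
#'   labeled; per-metabolite labeled fractions are derived as
#'   `enr / pAtom`.
#' @param noiseCv multiplicative lognormal noise CV on peak intensities.
#' @param biomassCv lognormal CV of the per-sample total-biomass factor
#'   (what median normalization removes).
#' @param p13c natural carbon-13 atom fraction.
#' @param seed mandatory integer seed.
#' @return list of class `SimulationConfig`.
#' @export
simulationConfig <- function(panel = studyPanel(), nLabeled = 6,
                             nUnlabeled = 6, nDark = 2, pAtom = 0.4,
                             noiseCv = 0.15, biomassCv = 0.2,
                             p13c = 0.0107, seed) {
  if (missing(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' is mandatory")
  checkP13c(p13c)
  if (pAtom <= 0 || pAtom > 1) stop("'pAtom' must lie in (0, 1]")
  enrHigh <- panel$enr_ambient * (1 + panel$enr_fc)
  if (any(panel$enr_ambient < 0) || any(enrHigh < 0) ||
      any(panel$enr_ambient > pAtom + 1e-12) || any(enrHigh > pAtom + 1e-12))
    stop("panel enrichments must lie in [0, pAtom] in both treatments ",
         "(labeled fraction = enrichment / pAtom must be a probability)")
  structure(list(panel = panel, nLabeled = nLabeled,
                 nUnlabeled = nUnlabeled, nDark = nDark, pAtom = pAtom,
                 noiseCv = noiseCv, biomassCv = biomassCv, p13c = p13c,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a full isotopologue-tracing dataset
#'
#' For each metabolite and sample, the true labeled-carbon-count
#' distribution is the mixture of a point mass at zero (the unlabeled
#' fraction of the pool) and a `Binomial(n, pAtom)` component (the
#' fraction synthesized from labeled source), so the true enrichment is
#' `labeledFraction * pAtom`. Dark-incubated and unlabeled (12C) samples
#' have labeled fraction zero. The true distribution is convolved with
#' the natural-abundance correction matrix, scaled by a lognormal pool
#' size with treatment fold change, a per-sample biomass factor, and
#' per-peak multiplicative lognormal noise (all noise terms mean 1, so
#' configured fold changes are unbiased targets).
#'
#' @param config a [simulationConfig()].
#' @return list with `spectra` (long-format data.frame: `metabolite`,
#'   `n_carbons`, `isotopologue`, `sample`, `intensity`), `metadata`
#'   (`sample`, `treatment`, `isotope`, `light`, `tank`, `batch`) and
#'   `groundTruth` (per metabolite and treatment: true enrichment, pool
#'   mean, and the configured fold changes).
#' @export
simulateIsotopologueDataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  panel <- config$panel
  groups <- rbind(
    expand.grid(treatment = c("ambient", "high"), isotope = "13C",
                light = "light", rep = seq_len(config$nLabeled),
                stringsAsFactors = FALSE),
    if (config$nUnlabeled > 0)
      expand.grid(treatment = c("ambient", "high"), isotope = "12C",
                  light = "light", rep = seq_len(config$nUnlabeled),
                  stringsAsFactors = FALSE),
    if (config$nDark > 0)
      expand.grid(treatment = c("ambient", "high"), isotope = "13C",
                  light = "dark", rep = seq_len(config$nDark),
                  stringsAsFactors = FALSE))
  metadata <- data.frame(
    sample = sprintf("%s_%s_%s_%02d", groups$treatment, groups$isotope,
                     groups$light, groups$rep),
    treatment = groups$treatment, isotope = groups$isotope,
    light = groups$light,
    tank = ((groups$rep - 1L) %% 6L) + 1L,
    batch = ((groups$rep - 1L) %/% 6L) + 1L,
    stringsAsFactors = FALSE)

  sdLog <- sqrt(log(1 + config$noiseCv^2))
  sdBio <- sqrt(log(1 + config$biomassCv^2))
  biomass <- stats::rlnorm(nrow(metadata), -sdBio^2 / 2, sdBio)

  spectra <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    n <- panel$n_carbons[i]
    C <- buildCorrectionMatrix(n, config$p13c)
    rows <- vector("list", nrow(metadata))
    for (s in seq_len(nrow(metadata))) {
      high <- metadata$treatment[s] == "high"
      labeled <- metadata$isotope[s] == "13C" && metadata$light[s] == "light"
      enr <- if (!labeled) 0 else
        panel$enr_ambient[i] * (1 + if (high) panel$enr_fc[i] else 0)
      lf <- enr / config$pAtom
      true <- (1 - lf) * c(1, rep(0, n)) +
        lf * stats::dbinom(0:n, n, config$pAtom)
      pool <- panel$pool_mean[i] * (1 + if (high) panel$pool_fc[i] else 0)
      obs <- drop(C %*% true) * pool * biomass[s] *
        stats::rlnorm(n + 1L, -sdLog^2 / 2, sdLog)
      rows[[s]] <- data.frame(metabolite = panel$metabolite[i],
                              n_carbons = n, isotopologue = 0:n,
                              sample = metadata$sample[s],
                              intensity = obs,
                              stringsAsFactors = FALSE)
    }
    spectra[[i]] <- do.call(rbind, rows)
  }
  spectra <- do.call(rbind, spectra)
  rownames(spectra) <- NULL

  gt <- data.frame(
    metabolite = rep(panel$metabolite, 2L),
    treatment = rep(c("ambient", "high"), each = nrow(panel)),
    enrichment = c(panel$enr_ambient,
                   panel$enr_ambient * (1 + panel$enr_fc)),
    pool_mean = c(panel$pool_mean, panel$pool_mean * (1 + panel$pool_fc)),
    pool_fc = rep(panel$pool_fc, 2L),
    enr_fc = rep(panel$enr_fc, 2L),
    stringsAsFactors = FALSE)
  list(spectra = spectra, metadata = metadata, groundTruth = gt)
}

#' Simulate a respirometry oxygen trace
#'
#' Linear oxygen decline (or production) with optional curved
#' equilibration transient over the first fraction of the run and
#' Gaussian sensor noise.
#'
#' @param trueSlope target slope in umol L^-1 min^-1.
#' @param intercept starting oxygen concentration (default 250).
#' @param noiseSd Gaussian noise SD in umol L^-1 (default 0.5).
#' @param equilibrationFraction fraction of the run affected by the
#'   transient (default 0, none).
#' @param equilibrationAmp transient amplitude in umol L^-1 (default 4).
#' @param durationMin run length in minutes (default 30).
#' @param cadenceS sampling cadence in seconds (default 15).
#' @param seed optional seed fixing the trace.
#' @param nIndividuals,wellVolume,meta passed to [OxygenTrace()].
#' @return An [OxygenTrace-class]; the generating slope is stored in
#'   `meta$trueSlope`.
#' @export
simulateOxygenTrace <- function(trueSlope, intercept = 250, noiseSd = 0.5,
                                equilibrationFraction = 0,
                                equilibrationAmp = 4,
                                durationMin = 30, cadenceS = 15,
                                seed = NULL, nIndividuals = 6L,
                                wellVolume = 80e-6, meta = list()) {
  if (durationMin <= 0 || cadenceS <= 0)
    stop("duration and cadence must be positive")
  if (!is.null(seed)) set.seed(seed)
  tm <- seq(0, durationMin, by = cadenceS / 60)
  o2 <- intercept + trueSlope * tm
  if (equilibrationFraction > 0) {
    tEq <- equilibrationFraction * durationMin
    o2 <- o2 + equilibrationAmp * exp(-3 * tm / tEq)
  }
  if (noiseSd > 0) o2 <- o2 + stats::rnorm(length(tm), 0, noiseSd)
  meta$trueSlope <- trueSlope
  OxygenTrace(times = tm, o2 = o2, wellVolume = wellVolume,
              nIndividuals = nIndividuals, meta = meta)
}

#' Single-axis effect scenarios for classifier validation
#'
#' Panels in which one focal metabolite carries a known effect on exactly
#' one or both response axes, against a background of metabolites with
#' genuine two-axis effects (so discriminant models have structure to
#' find) and unaffected nulls. Used to verify that the pipeline recovers
#' the intended quadrant call: `"turnover"` (enrichment up, pool
#' constant, quadrant i), `"accumulation"` (pool up, enrichment constant,
#' quadrant iv), `"both"` (both up, quadrant ii).
#'
#' @param scenario one of `"turnover"`, `"accumulation"`, `"both"`.
#' @param fc focal effect magnitude as a fold change (default 0.5, in
#'   the 0.1-1.0 band of effects the framework is designed for).
#' @param nNull number of unaffected background metabolites (default 8).
#' @return A panel data.frame for [simulationConfig()]; the focal
#'   metabolite is named `"focal"`.
#' @export
scenarioPanel <- function(scenario = c("turnover", "accumulation", "both"),
                          fc = 0.5, nNull = 8) {
  scenario <- match.arg(scenario)
  poolFc <- if (scenario %in% c("accumulation", "both")) fc else 0
  enrFc <- if (scenario %in% c("turnover", "both")) fc else 0
  focal <- data.frame(metabolite = "focal", n_carbons = 6, pool_mean = 8,
                      pool_fc = poolFc, enr_ambient = 0.15, enr_fc = enrFc,
                      stringsAsFactors = FALSE)
  # drivers sit at the pool extremes so their treatment effects cannot
  # move the within-sample median (held by the mid-range nulls)
  k <- 8L
  sgn <- rep(c(1, -1), length.out = k)
  informative <- data.frame(
    metabolite = sprintf("driver-%02d", seq_len(k)),
    n_carbons = rep_len(c(4, 5, 6, 7), k),
    pool_mean = rep_len(c(1.5, 25, 2, 30), k),
    pool_fc = sgn * seq(0.25, 0.6, length.out = k),
    enr_ambient = rep_len(c(0.1, 0.15, 0.2), k),
    enr_fc = rev(sgn) * seq(0.25, 0.6, length.out = k),
    stringsAsFactors = FALSE)
  nulls <- if (nNull > 0) data.frame(
    metabolite = sprintf("null-%02d", seq_len(nNull)),
    n_carbons = rep_len(c(3, 5, 6, 8), nNull),
    pool_mean = rep_len(c(5, 6, 7, 8), nNull),
    pool_fc = 0, enr_ambient = 0.08, enr_fc = 0,
    stringsAsFactors = FALSE) else NULL
  rbind(focal, informative, nulls)
}
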