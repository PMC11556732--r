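#' Two-way factorial analysis of variance
#'
#' Least-squares fit of a two-factor model with optional interaction.
#' Sums of squares are Type II (each main effect adjusted for the other
#' main effect, the interaction last), computed by residual-sum-of-squares
#' differences between nested least-squares fits; this reproduces the
#' classical balanced decomposition exactly when the design is balanced
#' and remains defined for perfect (zero-residual) fits.
#'
#' @param response numeric response vector.
#' @param factorA,factorB factors (or coercible) of the same length.
#' @param interaction include the A:B interaction (default TRUE).
#' @return list of class `AnovaTable`: `terms` data.frame (`term`, `df`,
#'   `SS`, `MS`, `F`, `p`), `residual` (df, SS, MS), and `fit` (the
#'   underlying `lm`, for post hoc contrasts).
#' @export
twoWayAnova <- function(response, factorA, factorB, interaction = TRUE) {
  stopifnot(length(response) == length(factorA),
            length(response) == length(factorB))
  d <- data.frame(y = as.numeric(response), A = factor(factorA),
                  B = factor(factorB))
  if (nlevels(d$A) < 2L || nlevels(d$B) < 2L)
    stop("both factors need at least two levels")
  cells <- table(d$A, d$B)
  if (interaction && any(cells == 0))
    stop("empty design cell(s): interaction model is not estimable")
  rss <- function(f) sum(stats::residuals(stats::lm(f, data = d))^2)
  full <- if (interaction) stats::lm(y ~ A * B, data = d)
          else stats::lm(y ~ A + B, data = d)
  if (stats::df.residual(full) < 1L)
    stop("no residual degrees of freedom")
  rssAdd <- rss(y ~ A + B)
  ss <- c(A = rss(y ~ B) - rssAdd, B = rss(y ~ A) - rssAdd)
  df <- c(A = nlevels(d$A) - 1L, B = nlevels(d$B) - 1L)
  if (interaction) {
    ss <- c(ss, `A:B` = rssAdd - sum(stats::residuals(full)^2))
    df <- c(df, `A:B` = (nlevels(d$A) - 1L) * (nlevels(d$B) - 1L))
  }
  ss <- pmax(ss, 0)  # guard tiny negative rounding
  resDf <- stats::df.residual(full)
  resSS <- sum(stats::residuals(full)^2)
  resMS <- resSS / resDf
  ms <- ss / df
  tol <- 1e-12 * max(1, sum(d$y^2))
  Fval <- ifelse(resMS > tol, ms / resMS,
                 ifelse(ss > tol, Inf, NA_real_))
  pval <- ifelse(is.na(Fval), NA_real_,
                 stats::pf(Fval, df, resDf, lower.tail = FALSE))
  structure(list(terms = data.frame(term = names(ss), df = unname(df),
                                    SS = unname(ss), MS = unname(ms),
                                    F = unname(Fval), p = unname(pval),
                                    row.names = NULL),
                 residual = list(df = resDf, SS = resSS, MS = resMS),
                 fit = full),
            class = "AnovaTable")
}

#' @export
print.AnovaTable <- function(x, ...) {
  cat("Two-way ANOVA (Type II sums of squares)\n")
  print(x$terms, digits = 4)
  cat("Residual: df =", x$residual$df, " SS =",
      format(x$residual$SS, digits = 4), "\n")
  invisible(x)
}

#' Estimated-marginal-means post hoc contrasts
#'
#' Pairwise contrasts of one factor, optionally within each level of a
#' second factor, from the cell means of a fitted linear model, with
#' pooled-variance standard errors and t-based p-values. The default
#' family-wise adjustment is Tukey within each `by` level; `"sidak"`,
#' `"fdr"` or `"none"` are accepted.
#'
#' @param fit an `lm` fit or an `AnovaTable` from [twoWayAnova()].
#' @param contrast name of the factor whose levels are compared (`"A"` or
#'   `"B"` for [twoWayAnova()] fits).
#' @param by optional name of the conditioning factor; contrasts are
#'   computed within each of its levels.
#' @param adjust multiplicity adjustment method (default `"tukey"`).
#' @return data.frame with columns `by` (if conditioned), `contrast`,
#'   `estimate`, `se`, `df`, `p` (unadjusted) and `p_adj`. Unestimable
#'   contrasts appear with NA estimates rather than being dropped.
#' @export
marginalMeansContrasts <- function(fit, contrast, by = NULL,
                                   adjust = "tukey") {
  if (inherits(fit, "AnovaTable")) fit <- fit$fit
  spec <- stats::as.formula(paste("~", contrast))
  em <- emmeans::emmeans(fit, specs = spec, by = by)
  adj <- summary(emmeans::contrast(em, method = "pairwise", adjust = adjust))
  raw <- summary(emmeans::contrast(em, method = "pairwise", adjust = "none"))
  out <- data.frame(contrast = adj$contrast, estimate = adj$estimate,
                    se = adj$SE, df = adj$df, p = raw$p.value,
                    p_adj = pmax(adj$p.value, raw$p.value))
  if (!is.null(by)) out <- cbind(by = adj[[by]], out)
  attr(out, "adjust") <- adjust
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement, mapped back to
#' the input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
fdrAdjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Light versus dark labeling validation
#'
#' Verifies that carbon-13 incorporation requires photosynthesis: for
#' each metabolite the mean enrichment in illuminated labeled samples is
#' compared with dark labeled controls. Percent excess is
#' `(light - dark) / light * 100`, so a dark mean of zero gives 100% and
#' the value reads as "X percent higher in the light". Significance comes
#' from a metabolite-by-condition factorial ANOVA with marginal-means
#' contrasts of light vs dark within each metabolite, FDR-adjusted across
#' metabolites.
#'
#' @param enrichmentTable data.frame with columns `metabolite`, `sample`,
#'   `enrichment`.
#' @param metadata data.frame with columns `sample`, `light` (values
#'   `"light"`/`"dark"`) and `isotope` (only `"13C"` samples are used if
#'   the column is present).
#' @param annotations optional pathway annotation for a pathway-level
#'   mean +/- SE summary of percent excess.
#' @return list with `perMetabolite` (columns `metabolite`, `light_mean`,
#'   `dark_mean`, `percent_excess`, `p`, `p_adj`, `flag`), `anova` (the
#'   factorial [twoWayAnova()]), and `perPathway` when annotations are
#'   given (`pathway`, `mean_percent_excess`, `se_percent_excess`, `n`).
#' @export
lightDarkValidation <- function(enrichmentTable, metadata,
                                annotations = NULL) {
  checkSamplesCovered(enrichmentTable$sample, metadata)
  md <- metadata
  if ("isotope" %in% names(md)) md <- md[md$isotope == "13C", ]
  d <- enrichmentTable[enrichmentTable$sample %in% md$sample, ]
  d$light <- md$light[match(d$sample, md$sample)]
  if (!all(c("light", "dark") %in% unique(d$light)))
    stop("both light and dark labeled samples are required")
  aov2 <- twoWayAnova(d$enrichment, d$metabolite, d$light)
  cons <- marginalMeansContrasts(aov2, contrast = "B", by = "A",
                                 adjust = "none")
  gm <- groupMeans(data.frame(metabolite = d$metabolite, sample = d$sample,
                              enrichment = d$enrichment),
                   data.frame(sample = md$sample, light = md$light),
                   factor = "light", valueCol = "enrichment")
  lm_ <- gm[gm$level == "light", ]
  dm_ <- gm[gm$level == "dark", ]
  mets <- sort(unique(d$metabolite))
  lightMean <- lm_$mean[match(mets, lm_$metabolite)]
  darkMean <- dm_$mean[match(mets, dm_$metabolite)]
  excess <- ifelse(lightMean > 0,
                   (lightMean - darkMean) / lightMean * 100, NA_real_)
  p <- cons$p[match(mets, cons$by)]
  per <- data.frame(metabolite = mets, light_mean = lightMean,
                    dark_mean = darkMean, percent_excess = excess,
                    p = p, p_adj = fdrAdjust(p),
                    flag = ifelse(lightMean <= 0,
                                  "light mean <= 0: percent undefined", ""),
                    row.names = NULL)
  out <- list(perMetabolite = per, anova = aov2)
  if (!is.null(annotations)) {
    merged <- merge(annotations, per, by = "metabolite")
    sp <- split(merged$percent_excess, merged$pathway)
    out$perPathway <- data.frame(
      pathway = names(sp),
      mean_percent_excess = vapply(sp, mean, 0, na.rm = TRUE),
      se_percent_excess = vapply(sp, function(v)
        stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))), 0),
      n = vapply(sp, length, 0L), row.names = NULL)
  }
  out
}

#' Peak window of a label-saturation time series
#'
#' For each metabolite, finds the contiguous pair of sampled times whose
#' combined mean enrichment is largest, bracketing the saturation peak.
#' When the maximum sits at the first or last sampled time the terminal
#' window is returned with a `no interior peak` flag; constant series are
#' flagged degenerate.
#'
#' @param timeTable data.frame with columns `metabolite`, `time`
#'   (hours) and `enrichment`; at least 3 distinct times per metabolite.
#' @return data.frame with columns `metabolite`, `t_lo`, `t_hi`,
#'   `peak_time`, `flag`.
#' @examples
#' tt <- data.frame(metabolite = "glucose", time = c(1, 3, 6, 12, 24),
#'                  enrichment = c(0.05, 0.2, 0.21, 0.15, 0.1))
#' labelSaturation(tt)  # window (3, 6)
#' @export
labelSaturation <- function(timeTable) {
  stopifnot(all(c("metabolite", "time", "enrichment") %in% names(timeTable)))
  out <- lapply(split(timeTable, timeTable$metabolite), function(d) {
    mu <- tapply(d$enrichment, d$time, mean)
    t <- as.numeric(names(mu))
    o <- order(t); t <- t[o]; mu <- as.numeric(mu)[o]
    if (length(t) < 3L)
      stop("metabolite '", d$metabolite[1L],
           "': at least 3 time points are required")
    if (diff(range(mu)) < 1e-12)
      return(data.frame(metabolite = d$metabolite[1L], t_lo = NA_real_,
                        t_hi = NA_real_, peak_time = NA_real_,
                        flag = "degenerate: constant series"))
    pairSum <- mu[-length(mu)] + mu[-1L]
    k <- which.max(pairSum)
    peak <- which.max(mu)
    flag <- if (peak == 1L || peak == length(mu)) "no interior peak" else ""
    data.frame(metabolite = d$metabolite[1L], t_lo = t[k], t_hi = t[k + 1L],
               peak_time = t[peak], flag = flag)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
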