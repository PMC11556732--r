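#' Euclidean sample-to-sample distances
#'
#' Pairwise Euclidean distances between samples over metabolite columns of
#' a transformed pool (or enrichment) matrix.
#'
#' @param pool a [PoolMatrix-class] in `log1p` state, or a plain numeric
#'   matrix with sample row names.
#' @param ... unused.
#' @return A `dist` object with sample labels.
#' @name euclideanDistances
NULL

#' @describeIn euclideanDistances distances over a transformed PoolMatrix.
setMethod("euclideanDistances", "PoolMatrix", function(pool, ...) {
  if (pool@state != "log1p")
    stop("euclideanDistances() expects a log1p-transformed PoolMatrix")
  euclideanDistances(pool@values)
})

#' @describeIn euclideanDistances distances over a plain matrix.
setMethod("euclideanDistances", "matrix", function(pool, ...) {
  if (any(!is.finite(pool)))
    stop("missing or non-finite values are not allowed")
  stats::dist(pool, method = "euclidean")
})

#' Permutational multivariate analysis of variance
#'
#' Distance-based PERMANOVA with up to two crossed factors and an optional
#' interaction, computed with sequential (Type I) sums of squares on the
#' Gower-centered distance matrix and free permutation of sample rows
#' (the classical default of `vegan::adonis2`, which performs the
#' computation). The permutation p-value uses the +1 correction,
#' `p = (#{F* >= F} + 1) / (nPerm + 1)`, so it is never zero.
#'
#' @param d a `dist` object (see [euclideanDistances()]).
#' @param design data.frame of factors, rows matching the order of the
#'   distance labels, with a `sample` column or row names identifying
#'   samples.
#' @param formula right-hand-side formula over columns of `design`, e.g.
#'   `~ temperature` or `~ isotope * temperature`.
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed controlling the permutations; required so runs
#'   are reproducible.
#' @return A list of class `PermanovaResult`: `terms` data.frame (`term`,
#'   `df`, `SS`, `R2`, `pseudoF`, `p`), plus `totalSS`, `nPermutations`,
#'   `seed`.
#' @export
permanova <- function(d, design, formula, nPerm = 999, seed) {
  stopifnot(inherits(d, "dist"))
  if (missing(seed) || length(seed) != 1L || is.na(seed))
    stop("an integer 'seed' is required for the permutation test")
  if (nPerm < 1) stop("'nPerm' must be >= 1")
  design <- as.data.frame(design)
  if ("sample" %in% names(design) && !is.null(attr(d, "Labels")))
    design <- design[match(attr(d, "Labels"), design$sample), , drop = FALSE]
  vars <- all.vars(formula)
  for (v in vars) {
    design[[v]] <- factor(design[[v]])
    if (nlevels(design[[v]]) < 2L)
      stop("factor '", v, "' has a single level")
    if (any(table(design[[v]]) < 2L))
      stop("factor '", v, "' has levels with fewer than 2 samples")
  }
  n <- attr(d, "Size")
  modelDf <- sum(vapply(vars, function(v) nlevels(design[[v]]) - 1L, 0L))
  if (n <= modelDf + 1L)
    stop("fewer samples than model degrees of freedom")
  f <- stats::as.formula(paste("d", paste(deparse(formula), collapse = "")))
  set.seed(seed)
  tab <- vegan::adonis2(f, data = design, permutations = nPerm,
                        by = "terms")
  terms <- data.frame(term = rownames(tab), df = tab$Df, SS = tab$SumOfSqs,
                      R2 = tab$R2, pseudoF = tab$F, p = tab$`Pr(>F)`,
                      row.names = NULL)
  total <- terms[terms$term == "Total", ]
  terms <- terms[terms$term != "Total", ]
  structure(list(terms = terms, totalSS = total$SS,
                 nPermutations = nPerm, seed = seed),
            class = "PermanovaResult")
}

#' @export
print.PermanovaResult <- function(x, ...) {
  cat("PERMANOVA (", x$nPermutations, " permutations, seed ", x$seed,
      ")\n", sep = "")
  print(x$terms, digits = 4)
  invisible(x)
}

#' Principal components of a transformed pool matrix
#'
#' Eigen-decomposition of the covariance of centered (optionally
#' unit-variance scaled) data, for visualizing multivariate treatment
#' separation.
#'
#' @param pool a [PoolMatrix-class] in `log1p` state or numeric matrix.
#' @param scale logical, scale columns to unit variance (default FALSE).
#' @return list with `scores` (samples x components, mean zero per
#'   component) and `explained` (variance fractions summing to 1).
#' @export
pcaScores <- function(pool, scale = FALSE) {
  x <- if (is(pool, "PoolMatrix")) poolValues(pool) else as.matrix(pool)
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples")
  if (scale && any(apply(x, 2L, stats::sd) == 0))
    stop("degenerate input: constant columns cannot be unit-variance scaled")
  p <- stats::prcomp(x, center = TRUE, scale. = scale)
  list(scores = p$x, explained = p$sdev^2 / sum(p$sdev^2))
}

#' Two-group PLS-DA by NIPALS
#'
#' Fits a PLS2 model of the (auto-scaled) data matrix against the
#' one-hot-coded two-level class membership using the NIPALS algorithm
#' with deflation of both blocks. The fit is deterministic: components
#' are initialized from the class-membership columns.
#'
#' @param X numeric samples x variables matrix with dimnames.
#' @param labels two-level factor (or coercible) of length `nrow(X)`.
#' @param nComponents number of X-variates (default 2).
#' @param autoscale center and scale columns of X to unit variance
#'   (default TRUE; constant columns are an error when scaling).
#' @param tol NIPALS convergence tolerance on the score vector.
#' @return A [PlsdaModel-class].
#' @export
plsdaFit <- function(X, labels, nComponents = 2, autoscale = TRUE,
                     tol = 1e-10) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("'labels' must have exactly two levels, both present")
  if (length(labels) != nrow(X))
    stop("'labels' length must match nrow(X)")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("V", seq_len(ncol(X)))
  ctr <- colMeans(X)
  scl <- if (autoscale) apply(X, 2L, stats::sd) else rep(1, ncol(X))
  if (any(scl == 0))
    stop("degenerate input: constant columns cannot be autoscaled")
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  Y <- stats::model.matrix(~ labels - 1)
  Y <- sweep(Y, 2L, colMeans(Y))
  totSS <- sum(Xs^2)
  p <- ncol(Xs)
  A <- min(nComponents, nrow(Xs) - 1L, p)

  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, nrow(Xs), A)
  Q <- matrix(0, ncol(Y), A)
  expl <- ssY <- numeric(A)
  Xd <- Xs; Yd <- Y
  for (a in seq_len(A)) {
    if (sum(Xd^2) < 1e-12 * max(1, totSS)) { A <- a - 1L; break }
    u <- Yd[, 1L]
    for (it in seq_len(500L)) {
      w <- drop(crossprod(Xd, u)); w <- w / sqrt(sum(w^2))
      tt <- drop(Xd %*% w)
      q <- drop(crossprod(Yd, tt)) / sum(tt^2)
      uNew <- drop(Yd %*% q) / sum(q^2)
      done <- sqrt(sum((uNew - u)^2)) < tol * max(sqrt(sum(uNew^2)), 1e-300)
      u <- uNew
      if (done) break
    }
    pl <- drop(crossprod(Xd, tt)) / sum(tt^2)
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- tt; Q[, a] <- q
    expl[a] <- sum(tt^2) * sum(pl^2) / totSS
    ssY[a] <- sum(tt^2) * sum(q^2)
    Xd <- Xd - tcrossprod(tt, pl)
    Yd <- Yd - tcrossprod(tt, q)
  }
  if (A < 1L) stop("no PLS component could be extracted")
  keep <- seq_len(A)
  rownames(W) <- rownames(P) <- colnames(X)
  new("PlsdaModel",
      xWeights = W[, keep, drop = FALSE],
      xLoadings = P[, keep, drop = FALSE],
      xScores = Tm[, keep, drop = FALSE],
      yLoadings = Q[, keep, drop = FALSE],
      explainedXVariance = expl[keep],
      ssY = ssY[keep],
      scaling = list(center = ctr, scale = scl),
      labels = labels,
      variableIds = colnames(X))
}

#' Variable importance in projection scores
#'
#' `VIP_j = sqrt(p * sum_a(SSY_a * w_aj^2) / sum_a(SSY_a))` over the `A`
#' fitted components, where `SSY_a` is the class-membership sum of
#' squares explained by component `a` and the weight vectors `w_a` have
#' unit norm. The mean of squared VIPs over variables is exactly 1;
#' variables with `VIP >= threshold` (default 1, ties included) are
#' flagged as discriminating between the two groups.
#'
#' @param model a fitted [PlsdaModel-class].
#' @param threshold selection threshold (default 1.0).
#' @param ... unused.
#' @return data.frame with columns `metabolite`, `vip`, `selected`.
#' @name vipScores
NULL

#' @describeIn vipScores VIP scores of a fitted model.
setMethod("vipScores", "PlsdaModel", function(model, threshold = 1, ...) {
  ssY <- model@ssY
  if (sum(ssY) <= 0)
    stop("degenerate input: no class-membership variance explained")
  W2 <- model@xWeights^2
  p <- length(model@variableIds)
  vip <- sqrt(p * drop(W2 %*% ssY) / sum(ssY))
  data.frame(metabolite = model@variableIds, vip = vip,
             selected = vip >= threshold, row.names = NULL)
})

#' PLS-DA VIP scores with between-treatment fold changes
#'
#' Convenience wrapper running [plsdaFit()] and [vipScores()] on the
#' analysis-scale matrix while computing fold changes from group means on
#' the measurement scale (median-normalized pools or raw enrichment
#' proportions), which keeps fold change interpretable as a relative
#' difference.
#'
#' @param analysisMatrix samples x metabolites matrix used for the
#'   discriminant fit (log-transformed pools or enrichment).
#' @param measureMatrix samples x metabolites matrix on which group means
#'   and fold changes are computed; defaults to `analysisMatrix`.
#' @param labels two-level factor; `reference` names the level used as the
#'   fold-change denominator (ambient).
#' @param reference reference level (default first level).
#' @param threshold VIP selection threshold.
#' @param nComponents number of PLS components (default 2).
#' @return data.frame with columns `metabolite`, `vip`, `selected`,
#'   `meanReference`, `meanOther`, `fc`, plus attribute
#'   `explainedXVariance`.
#' @export
vipFoldChange <- function(analysisMatrix, labels,
                          measureMatrix = analysisMatrix,
                          reference = NULL, threshold = 1,
                          nComponents = 2) {
  labels <- factor(labels)
  if (is.null(reference)) reference <- levels(labels)[1L]
  labels <- stats::relevel(labels, ref = reference)
  fit <- plsdaFit(analysisMatrix, labels, nComponents = nComponents)
  vt <- vipScores(fit, threshold = threshold)
  mRef <- colMeans(measureMatrix[labels == levels(labels)[1L], , drop = FALSE])
  mOth <- colMeans(measureMatrix[labels == levels(labels)[2L], , drop = FALSE])
  mRef <- mRef[vt$metabolite]; mOth <- mOth[vt$metabolite]
  vt$meanReference <- mRef
  vt$meanOther <- mOth
  vt$fc <- foldChange(mRef, mOth)
  attr(vt, "explainedXVariance") <- fit@explainedXVariance
  attr(vt, "model") <- fit
  vt
}
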