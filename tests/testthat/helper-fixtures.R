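# Small programmatic fixtures shared across test files.

# Long-format spectra for one metabolite across samples, from exact
# fraction vectors (no noise): intensities = pool * (C %*% fractions).
makeSpectraTable <- function(metabolite = "met", nCarbons = 2,
                             fractionsBySample, pools = NULL,
                             p13c = 0.0107) {
  C <- buildCorrectionMatrix(nCarbons, p13c)
  if (is.null(pools)) pools <- rep(1, length(fractionsBySample))
  rows <- Map(function(f, s, pool) {
    data.frame(metabolite = metabolite, n_carbons = nCarbons,
               isotopologue = 0:nCarbons, sample = s,
               intensity = pool * drop(C %*% f))
  }, fractionsBySample, names(fractionsBySample), pools)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Random non-negative fraction vector of length n + 1 summing to 1.
randomFractions <- function(n) {
  x <- stats::rexp(n + 1)
  x / sum(x)
}

# Independent brute-force Benjamini-Hochberg step-up, straight from the
# definition: q_(i) = min_{j >= i} m * p_(j) / j, capped at 1.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Sequential projection-matrix ANOVA oracle: SS of each term as the
# increment in projection of y when the term's columns enter the model.
projectionAnovaSS <- function(y, A, B, interaction = TRUE) {
  terms <- list(A = stats::model.matrix(~A), B = stats::model.matrix(~A + B))
  if (interaction) terms$AB <- stats::model.matrix(~A * B)
  proj <- function(X) X %*% solve(crossprod(X), crossprod(X, y))
  fit0 <- proj(matrix(1, length(y), 1))
  ss <- numeric(0)
  prev <- fit0
  for (nm in names(terms)) {
    cur <- proj(terms[[nm]])
    ss[nm] <- sum((cur - prev)^2)
    prev <- cur
  }
  ss["resid"] <- sum((y - prev)^2)
  ss
}
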