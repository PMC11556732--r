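logPool <- function(v) {
  PoolMatrix(v, state = "log1p")
}

test_that("euclidean distances behave geometrically", {
  v <- matrix(c(0, 0, 3, 4), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("x", "y")))
  d <- euclideanDistances(v)
  expect_equal(as.numeric(d), 5)
  expect_equal(as.numeric(euclideanDistances(v[, c(2, 1)])), 5)
  expect_equal(as.numeric(euclideanDistances(rbind(v, a2 = v[1, ])))[2], 0)
  v[1, 1] <- NA
  expect_error(euclideanDistances(v), "non-finite")
})

test_that("permanova partitions SS and detects separation", {
  set.seed(61)
  n <- 12
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(paste0("s", 1:n), NULL))
  g <- rep(c("a", "b"), each = n / 2)
  x[g == "b", 1:3] <- x[g == "b", 1:3] + 4
  design <- data.frame(sample = rownames(x), grp = g)
  res <- permanova(euclideanDistances(x), design, ~ grp, nPerm = 199,
                   seed = 7)
  expect_equal(sum(res$terms$SS), res$totalSS, tolerance = 1e-8)
  expect_lt(res$terms$p[res$terms$term == "grp"], 0.05)
  expect_gt(res$terms$p[res$terms$term == "grp"], 0)
  # identical coordinates across groups: no between-group SS
  y <- rbind(x[1:6, ], x[1:6, ])
  rownames(y) <- paste0("t", 1:12)
  design2 <- data.frame(sample = rownames(y), grp = g)
  res2 <- permanova(euclideanDistances(y), design2, ~ grp, nPerm = 99,
                    seed = 7)
  expect_lt(abs(res2$terms$SS[res2$terms$term == "grp"]), 1e-8)
})

test_that("permanova validates its design", {
  set.seed(62)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("s", 1:10), NULL))
  d <- euclideanDistances(x)
  design <- data.frame(sample = rownames(x), grp = rep("a", 10))
  expect_error(permanova(d, design, ~ grp, seed = 1), "single level")
  expect_error(permanova(d, data.frame(sample = rownames(x),
                                       grp = rep(c("a", "b"), 5)),
                         ~ grp, nPerm = 99), "seed")
})

test_that("pca explains a line with one component and centers scores", {
  x <- cbind(1:10, 2 * (1:10) + 3)
  rownames(x) <- paste0("s", 1:10)
  p <- pcaScores(x)
  expect_equal(p$explained[1], 1, tolerance = 1e-12)
  expect_equal(colMeans(p$scores), rep(0, ncol(p$scores)),
               ignore_attr = TRUE, tolerance = 1e-12)
  x2 <- cbind(x, 5)
  expect_error(pcaScores(x2, scale = TRUE), "constant")
})

test_that("PLS-DA concentrates weight on an informative variable", {
  set.seed(63)
  n <- 24; p <- 10
  g <- factor(rep(c("a", "b"), each = n / 2))
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  X[, 1] <- ifelse(g == "b", 1, -1) + rnorm(n, 0, 0.1)
  fit <- plsdaFit(X, g)
  expect_equal(which.max(abs(fit@xWeights[, 1])), 1L, ignore_attr = TRUE)
  # scores orthogonal across components
  expect_lt(abs(crossprod(fit@xScores[, 1], fit@xScores[, 2])), 1e-8)
  # deterministic refit
  fit2 <- plsdaFit(X, g)
  expect_identical(fit@xScores, fit2@xScores)
  expect_error(plsdaFit(X, rep("a", n)), "two levels")
  vt <- vipScores(fit)
  expect_gt(vt$vip[1], 1)
  expect_equal(mean(vt$vip^2), 1, tolerance = 1e-8)
})

test_that("PLS-DA recovers a known discriminant axis", {
  set.seed(64)
  n <- 24; p <- 20
  axis <- rnorm(p); axis <- axis / sqrt(sum(axis^2))
  g <- factor(rep(c("a", "b"), each = n / 2))
  signal <- outer(ifelse(g == "b", 1.5, -1.5), axis)
  X <- signal + matrix(rnorm(n * p, 0, 0.5), n, p)
  colnames(X) <- paste0("v", 1:p)
  fit <- plsdaFit(X, g, autoscale = FALSE)
  w <- fit@xWeights[, 1]
  cosine <- abs(sum(w * axis)) / sqrt(sum(w^2))
  expect_gt(cosine, 0.95)
})

test_that("identical variables share VIP 1 by symmetry", {
  set.seed(65)
  base <- rnorm(16)
  X <- matrix(rep(base, 5), 16, 5, dimnames = list(NULL, paste0("v", 1:5)))
  g <- factor(rep(c("a", "b"), each = 8))
  fit <- plsdaFit(X, g, nComponents = 1)
  vt <- vipScores(fit)
  expect_equal(vt$vip, rep(1, 5), tolerance = 1e-10)
  # threshold exactly at an achieved score: ties count as selected
  tied <- vipScores(fit, threshold = vt$vip[1])
  expect_true(tied$selected[1])
})

test_that("our PLS-DA matches an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(66)
  n <- 20; p <- 12
  g <- factor(rep(c("a", "b"), each = n / 2))
  X <- matrix(rnorm(n * p), n, p, dimnames = list(paste0("s", 1:n),
                                                  paste0("v", 1:p)))
  X[, 1:3] <- X[, 1:3] + ifelse(g == "b", 1, 0)
  fit <- plsdaFit(X, g)
  ref <- mixOmics::plsda(X, g, ncomp = 2)
  for (a in 1:2) {
    r <- abs(cor(fit@xScores[, a], ref$variates$X[, a]))
    expect_gt(r, 0.999)
  }
  refVip <- mixOmics::vip(ref)
  ours <- vipScores(fit)
  expect_gt(cor(ours$vip, refVip[ours$metabolite, 2]), 0.99)
})

test_that("vipFoldChange reports fold changes on the measurement scale", {
  set.seed(67)
  n <- 12
  g <- factor(rep(c("ambient", "high"), each = n / 2))
  meas <- matrix(rexp(n * 4, 1), n, 4,
                 dimnames = list(paste0("s", 1:n), paste0("m", 1:4)))
  meas[g == "high", 2] <- meas[g == "high", 2] + 3
  vt <- vipFoldChange(log1p(meas), g, measureMatrix = meas,
                      reference = "ambient")
  m2 <- vt[vt$metabolite == "m2", ]
  expect_equal(m2$fc, mean(meas[g == "high", 2]) /
                 mean(meas[g == "ambient", 2]) - 1, tolerance = 1e-12)
})
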