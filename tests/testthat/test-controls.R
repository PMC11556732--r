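test_that("constant responses yield zero effect sums of squares", {
  a <- factor(rep(c("x", "y"), each = 6))
  b <- factor(rep(c("u", "v"), 6))
  tab <- twoWayAnova(rep(3.7, 12), a, b)
  expect_equal(tab$terms$SS, rep(0, 3))
  expect_equal(sum(tab$terms$df) + tab$residual$df, 11)
})

test_that("balanced 2x2 interaction SS matches the closed form", {
  # cell means (0, 0, 0, delta), n per cell, zero noise:
  # interaction SS = n * delta^2 / 4
  delta <- 2.4; n <- 3
  a <- factor(rep(c("a1", "a2"), each = 2 * n))
  b <- factor(rep(rep(c("b1", "b2"), each = n), 2))
  y <- ifelse(a == "a2" & b == "b2", delta, 0)
  tab <- twoWayAnova(y, a, b)
  expect_equal(tab$terms$SS[tab$terms$term == "A:B"], n * delta^2 / 4,
               tolerance = 1e-10)
})

test_that("balanced designs match a projection-matrix oracle", {
  set.seed(81)
  for (rep in 1:5) {
    la <- sample(2:3, 1); lb <- sample(2:3, 1); n <- sample(2:4, 1)
    a <- factor(rep(seq_len(la), each = lb * n))
    b <- factor(rep(rep(seq_len(lb), each = n), la))
    y <- rnorm(length(a))
    tab <- twoWayAnova(y, a, b)
    oracle <- projectionAnovaSS(y, a, b)
    expect_equal(tab$terms$SS, unname(oracle[c("A", "B", "AB")]),
                 tolerance = 1e-8)
    expect_equal(tab$residual$SS, unname(oracle["resid"]), tolerance = 1e-8)
  }
})

test_that("empty cells with interaction are rejected", {
  a <- factor(c("x", "x", "y", "y"))
  b <- factor(c("u", "u", "u", "u"))
  expect_error(twoWayAnova(rnorm(4), a, b), "two levels")
  a <- factor(c("x", "x", "x", "y", "y", "y"))
  b <- factor(c("u", "u", "v", "u", "u", "u"))
  expect_error(twoWayAnova(rnorm(6), a, b), "empty")
})

test_that("marginal-means contrasts reduce to the pooled t-test", {
  set.seed(82)
  g <- factor(rep(c("a", "b"), each = 6))
  y <- rnorm(12) + ifelse(g == "b", 1, 0)
  fit <- lm(y ~ g)
  cons <- marginalMeansContrasts(fit, contrast = "g", adjust = "none")
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(cons$p, tt$p.value, tolerance = 1e-10)
  expect_equal(abs(cons$estimate), abs(diff(tapply(y, g, mean))),
               ignore_attr = TRUE, tolerance = 1e-10)
  # equal cell means: estimate 0, p 1
  y0 <- rep(c(1, 2, 3), 4)
  cons0 <- marginalMeansContrasts(lm(y0 ~ g), contrast = "g",
                                  adjust = "none")
  expect_equal(cons0$estimate, 0, tolerance = 1e-12)
  expect_equal(cons0$p, 1, tolerance = 1e-12)
})

test_that("adjusted p-values never fall below raw p-values", {
  set.seed(83)
  a <- factor(rep(c("m1", "m2", "m3"), each = 8))
  b <- factor(rep(rep(c("l", "d"), each = 4), 3))
  y <- rnorm(24) + as.numeric(a) * (b == "l")
  tab <- twoWayAnova(y, a, b)
  cons <- marginalMeansContrasts(tab, contrast = "B", by = "A",
                                 adjust = "sidak")
  expect_true(all(cons$p_adj >= cons$p - 1e-12))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(fdrAdjust(0.2), 0.2)
  expect_equal(fdrAdjust(rep(1, 5)), rep(1, 5))
  expect_error(fdrAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(84)
  for (rep in 1:10) {
    p <- runif(sample(3:40, 1))
    q <- fdrAdjust(p)
    expect_equal(q, bruteForceBH(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
  }
})

test_that("light vs dark excess uses the light denominator", {
  mets <- c("glucose", "pyruvate")
  samples <- c(paste0("L", 1:3), paste0("D", 1:3))
  md <- data.frame(sample = samples, isotope = "13C",
                   light = rep(c("light", "dark"), each = 3))
  enr <- expand.grid(metabolite = mets, sample = samples,
                     stringsAsFactors = FALSE)
  light <- enr$sample %in% paste0("L", 1:3)
  enr$enrichment <- ifelse(enr$metabolite == "glucose",
                           ifelse(light, 0.19, 0.001),
                           ifelse(light, 0.15, 0))
  # tiny jitter so the ANOVA has residual variance
  set.seed(85)
  enr$enrichment <- enr$enrichment + rnorm(nrow(enr), 0, 1e-6)
  val <- lightDarkValidation(enr, md)
  per <- val$perMetabolite
  gl <- per[per$metabolite == "glucose", ]
  expect_equal(gl$percent_excess, (0.19 - 0.001) / 0.19 * 100,
               tolerance = 1e-2)
  py <- per[per$metabolite == "pyruvate", ]
  expect_equal(py$percent_excess, 100, tolerance = 1e-2)
  expect_true(all(per$p_adj >= per$p - 1e-12))
})

test_that("label saturation finds the bracketing peak window", {
  tt <- data.frame(metabolite = "glucose", time = c(1, 3, 6, 12, 24),
                   enrichment = c(0.05, 0.2, 0.21, 0.15, 0.1))
  res <- labelSaturation(tt)
  expect_equal(c(res$t_lo, res$t_hi), c(3, 6))
  expect_identical(res$flag, "")
  inc <- data.frame(metabolite = "m", time = c(1, 3, 6, 12, 24),
                    enrichment = c(0.01, 0.05, 0.1, 0.2, 0.3))
  res2 <- labelSaturation(inc)
  expect_equal(c(res2$t_lo, res2$t_hi), c(12, 24))
  expect_identical(res2$flag, "no interior peak")
  const <- data.frame(metabolite = "m", time = c(1, 3, 6),
                      enrichment = rep(0.1, 3))
  expect_match(labelSaturation(const)$flag, "degenerate")
  expect_error(labelSaturation(data.frame(metabolite = "m", time = c(1, 3),
                                          enrichment = c(0.1, 0.2))),
               "3 time points")
})
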