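test_that("quadrant classification covers all nine direction states", {
  # directions encoded as (fc sign, selected); stable = unselected
  state <- function(dir) switch(dir,
    "+" = list(fc = 0.5, sel = TRUE),
    "-" = list(fc = -0.5, sel = TRUE),
    "0" = list(fc = 0.1, sel = FALSE))
  expected <- rbind(
    c("+", "+", "ii"),  c("+", "0", "iv"),  c("+", "-", "iv"),
    c("0", "+", "i"),   c("0", "0", "null_call"), c("0", "-", "iv"),
    c("-", "+", "i"),   c("-", "0", "i"),   c("-", "-", "iii"))
  for (r in seq_len(nrow(expected))) {
    p <- state(expected[r, 1]); e <- state(expected[r, 2])
    call <- classifyQuadrant(p$fc, p$sel, e$fc, e$sel)
    expect_identical(call$quadrant, expected[r, 3],
                     label = paste("pool", expected[r, 1], "enr",
                                   expected[r, 2]))
  }
})

test_that("canonical response patterns classify as expected", {
  # glucose-like: pool up and selected, enrichment unselected -> accumulation
  glucose <- classifyQuadrant(0.10, TRUE, 0.01, FALSE, "glucose")
  expect_identical(glucose$quadrant, "iv")
  expect_match(glucose$label, "accumulation")
  # glutamine-like: enrichment up at stable pool -> turnover
  glutamine <- classifyQuadrant(-0.02, FALSE, 0.46, TRUE, "glutamine")
  expect_identical(glutamine$quadrant, "i")
  expect_match(glutamine$label, "turnover")
  # dipeptide-like: both metrics up -> synthesis exceeding downstream use
  dipep <- classifyQuadrant(1.07, TRUE, 1.08, TRUE, "arginine-glutamine")
  expect_identical(dipep$quadrant, "ii")
})

test_that("label swap negates fold changes and mirrors quadrants", {
  set.seed(71)
  mirror <- c(i = "iv", iv = "i", ii = "iii", iii = "ii",
              null_call = "null_call")
  for (rep in 1:30) {
    pf <- round(runif(1, -1, 1), 2); ps <- runif(1) < 0.6
    ef <- round(runif(1, -1, 1), 2); es <- runif(1) < 0.6
    if (pf <= -0.99 || ef <= -0.99 || pf == 0 || ef == 0) next
    fwd <- classifyQuadrant(pf, ps, ef, es)$quadrant
    # swapping treatment labels: fc -> fc' with 1+fc' = 1/(1+fc); sign flips
    rev <- classifyQuadrant(1 / (1 + pf) - 1, ps, 1 / (1 + ef) - 1,
                            es)$quadrant
    expect_identical(rev, unname(mirror[fwd]))
  }
})

test_that("selected metric with zero fold change warns and reads stable", {
  expect_warning(call <- classifyQuadrant(0, TRUE, 0, FALSE), "stable")
  expect_identical(call$quadrant, "null_call")
})

test_that("pathway report expands multi-pathway membership", {
  ann <- pathwayAnnotations()
  glyco <- ann$metabolite[ann$pathway == "glycolysis_central_carbon"]
  expect_length(glyco, 7)
  calls <- classifyQuadrant(
    poolFc = rep(0.10, length(glyco)), poolSelected = rep(TRUE, length(glyco)),
    enrFc = rep(0.05, length(glyco)), enrSelected = rep(FALSE, length(glyco)),
    metaboliteId = glyco)
  rep_ <- pathwayReport(calls, ann)
  expect_equal(sum(rep_$pathway == "glycolysis_central_carbon"), 7)
  # pyruvate is in glycolysis and the TCA cycle
  expect_equal(sum(rep_$metabolite == "pyruvate"), 2)
  gl <- rep_[rep_$metabolite == "glucose", ]
  expect_equal(gl$pool_percent, 10)
  expect_identical(gl$pool_direction, "high")
  expect_identical(gl$enr_direction, "stable")
  expect_true(is.na(gl$enr_percent))
  expect_warning(pathwayReport(classifyQuadrant(0.1, TRUE, 0.1, TRUE,
                                                "unknown-met"), ann),
                 "unannotated")
})

test_that("quadrantCalls joins pool and enrichment VIP tables", {
  pv <- data.frame(metabolite = c("a", "b"), vip = c(1.2, 0.5),
                   selected = c(TRUE, FALSE), fc = c(0.3, 0.1))
  ev <- data.frame(metabolite = c("b", "a"), vip = c(1.5, 0.4),
                   selected = c(TRUE, FALSE), fc = c(0.4, 0.0))
  calls <- quadrantCalls(pv, ev)
  expect_identical(calls$quadrant[calls$metabolite == "a"], "iv")
  expect_identical(calls$quadrant[calls$metabolite == "b"], "i")
  expect_equal(calls$pool_vip, c(1.2, 0.5))
})
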