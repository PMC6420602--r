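grid <- buildGrid()

test_that("truncation keeps the visits at or before the cutoff", {
  s <- flat_series(c(25, 24, 23), times = c(0, 0.4, 1.2), label = "stable")
  t1 <- truncateSeries(s, 1.0)
  expect_equal(nTests(t1), 2L)
  expect_true(isAnalyzable(t1))
  expect_equal(progressionLabel(t1), "stable")

  expect_identical(visitTimes(truncateSeries(s, 5)), visitTimes(s))

  t0 <- truncateSeries(s, 0.2)
  expect_equal(nTests(t0), 1L)
  expect_false(isAnalyzable(t0))
  expect_error(truncateSeries(s, 0), "positive")
})

test_that("truncation is idempotent and monotone", {
  set.seed(6)
  co <- simulateCohort(grid, cohortParams(nEyes = 5L, seed = 6))
  for (s in co@series) {
    for (a in c(0.5, 1.5, 3)) {
      for (b in c(0.8, 2)) {
        lhs <- truncateSeries(truncateSeries(s, a), b)
        rhs <- truncateSeries(s, min(a, b))
        expect_identical(visitTimes(lhs), visitTimes(rhs))
        expect_identical(sensitivities(lhs), sensitivities(rhs))
      }
    }
  }
})

test_that("the final cutoff reproduces the full-study evaluation", {
  co <- simulateCohort(grid, cohortParams(nEyes = 24L, seed = 14))
  models <- list(GI = c("gi_slope", "gi_p", "gi_interaction"), MS = "ms")
  preds <- computePredictors(co, grid, metrics = "trend", nPerm = 199,
                             baseSeed = 3)
  full <- evaluateMetrics(preds, models, withGI = FALSE)
  fits <- attr(full, "fits")
  y <- progressionLabel(co)
  thr <- vapply(names(models), function(nm) {
    keep <- !is.na(attr(full, "probs")[, nm])
    selectThreshold(attr(full, "probs")[keep, nm],
                    y[keep])$threshold
  }, numeric(1))
  maxFu <- max(vapply(co@series, function(s) max(visitTimes(s)), numeric(1)))
  tab <- evaluateCutoffs(co, grid, cutoffs = maxFu, models = models,
                         finalFits = fits, finalThresholds = thr,
                         metrics = "trend", nPerm = 199, baseSeed = 3)
  for (nm in names(models)) {
    row <- tab[tab$model == nm, ]
    frow <- full[full$model == nm, ]
    expect_identical(row$auc, frow$auc)
    expect_identical(row$pauc, frow$pauc)
    expect_equal(row$n_eyes, frow$n)
  }
})

test_that("sens/spec cells equal an independent confusion-matrix count", {
  co <- simulateCohort(grid, cohortParams(nEyes = 24L, seed = 15))
  models <- list(GI = c("gi_slope", "gi_p", "gi_interaction"))
  predsFull <- computePredictors(co, grid, metrics = "trend", nPerm = 199,
                                 baseSeed = 4)
  full <- evaluateMetrics(predsFull, models, withGI = FALSE)
  fit <- attr(full, "fits")$GI
  y <- as.integer(progressionLabel(co) == "progressing")
  thr <- 0.4
  tab <- evaluateCutoffs(co, grid, cutoffs = 1.5, models = models,
                         finalFits = list(GI = fit),
                         finalThresholds = c(GI = thr),
                         metrics = "trend", nPerm = 199, baseSeed = 4)
  predsCut <- computePredictors(truncateSeries(co, 1.5), grid,
                                metrics = "trend", nPerm = 199,
                                baseSeed = 4)
  keep <- complete.cases(predsCut[, models$GI])
  pr <- predictProb(fit, predsCut[keep, ])
  yk <- y[keep]
  expect_equal(tab$sens, sum(pr >= thr & yk == 1) / sum(yk == 1))
  expect_equal(tab$spec, sum(pr < thr & yk == 0) / sum(yk == 0))
  expect_equal(tab$n_eyes, sum(keep))
})

test_that("detection times follow the visit-walk rule", {
  # an eye whose global index only turns steep after the third visit
  tms <- c(0, 0.5, 1, 1.5, 2)
  means <- c(27, 27, 27, 22, 17)
  eye <- flat_series(means, tms, id = "p1", label = "progressing")
  never <- flat_series(rep(27, 5), tms, id = "p2", label = "progressing")
  stableEye <- flat_series(rep(27, 5), tms, id = "s1", label = "stable")
  co <- VFCohort(list(eye, never, stableEye))

  model <- structure(list(coefficients = c(`(Intercept)` = 0,
                                           gi_slope = -2),
                          predictors = "gi_slope"),
                     class = "DiagnosticModel")
  expect_message(
    dt <- timeToFirstDiagnosis(co, grid, model, threshold = 0.9,
                               metrics = "trend", nPerm = 199),
    "ignoring 1 non-progressing")
  d1 <- dt[dt$eye_id == "p1", ]
  # slope over the first 4 visits is steep enough: plogis(-2 * slope) >= .9
  expect_true(d1$detected)
  expect_equal(d1$day, round(1.5 * 365.25))
  expect_gte(d1$prob_at_detection, 0.9)

  d2 <- dt[dt$eye_id == "p2", ]
  expect_false(d2$detected)
  expect_equal(d2$day, round(2 * 365.25))
  expect_equal(attr(dt, "mean_days"), mean(dt$day))
})
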