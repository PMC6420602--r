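test_that("the intercept-only combiner returns the logit of prevalence", {
  y <- c(rep(1, 50), rep(0, 141))
  m <- fitLogistic(NULL, y)
  expect_equal(unname(m$coefficients[1]), log(50 / 141), tolerance = 1e-8)
  expect_equal(unique(round(m$fitted, 12)), round(50 / 191, 12))
  expect_equal(m$aic, 2 * 1 - 2 * m$logLik)
})

test_that("fitted coefficients match an independent Newton solver", {
  set.seed(3)
  for (r in 1:10) {
    n <- 150
    X <- cbind(a = rnorm(n), b = rnorm(n), c = runif(n))
    eta <- -0.5 + X %*% c(1, -0.7, 0.4)
    y <- rbinom(n, 1, plogis(eta))
    if (length(unique(y)) < 2) next
    m <- fitLogistic(X, y)
    expect_equal(unname(m$coefficients), oracle_logistic(X, y),
                 tolerance = 1e-6)
  }
})

test_that("degenerate designs are caught and separation warned about", {
  y <- rep(0:1, 25)
  X <- data.frame(a = rnorm(50))
  X$b <- 2 * X$a
  expect_error(fitLogistic(X, y), "collinear column\\(s\\): b")
  expect_error(fitLogistic(data.frame(a = rnorm(50)), rep(1, 50)),
               "both classes")
  sep <- data.frame(a = c(rnorm(25, -4), rnorm(25, 4)))
  expect_warning(fitLogistic(sep, rep(0:1, each = 25)), "quasi-separation")
  # rows with missing predictors are dropped with a message
  Xm <- data.frame(a = c(NA, rnorm(49)))
  expect_message(m <- fitLogistic(Xm, y), "dropping 1 rows")
  expect_equal(m$n, 49L)
})

test_that("combining with GI tests the added metric by likelihood ratio", {
  pf <- make_predictor_frame(n = 120, seed = 5)
  y <- as.integer(pf$label == "progressing")
  gi <- data.frame(gi_slope = pf$s1)
  expect_error(combineWithGI(gi, data.frame(gi_slope = pf$s1), y),
               "collinear")
  cmb <- combineWithGI(gi, data.frame(extra = pf$s2), y)
  expect_gte(cmb$combined$logLik, cmb$giOnly$logLik)
  expect_true(cmb$pValue >= 0 && cmb$pValue <= 1)

  # a pure-noise added column gives an approximately uniform LRT p
  set.seed(11)
  ps <- replicate(300, {
    yy <- rbinom(80, 1, 0.4)
    if (length(unique(yy)) < 2) return(NA_real_)
    combineWithGI(data.frame(g = rnorm(80) + yy),
                  data.frame(noise = rnorm(80)), yy)$pValue
  })
  ps <- ps[!is.na(ps)]
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("AUC equals the brute-force pairwise oracle", {
  y <- rep(0:1, each = 10)
  expect_equal(rocCurve(c(rnorm(10, 0), rnorm(10, 10)), y)$auc, 1)
  expect_equal(rocCurve(rep(0.3, 20), y)$auc, 0.5)
  set.seed(21)
  for (r in 1:10) {
    probs <- round(runif(20), 1)   # forced ties
    expect_equal(rocCurve(probs, y)$auc, oracle_auc(probs, y),
                 tolerance = 1e-12)
  }
  expect_error(rocCurve(runif(5), rep(1, 5)), "both classes")
})

test_that("normalised pAUC has its analytic anchors and matches quadrature", {
  y <- rep(0:1, each = 30)
  perfect <- c(runif(30, 0, 0.4), runif(30, 0.6, 1))
  expect_equal(pauc(perfect, y), 1)
  expect_equal(pauc(rep(0.5, 60), y), 0.075, tolerance = 1e-12)
  expect_error(pauc(perfect, y, specLo = 1.2), "specLo")

  # quadrature oracle: fine-grid integration of the empirical step ROC
  # (tie-free scores, so the curve is an exact staircase)
  set.seed(4)
  probs <- runif(60)
  r <- rocCurve(probs, y)
  fgrid <- seq(0, 0.15, length.out = 60001)
  tprAt <- approx(r$fpr, r$tpr, xout = fgrid, method = "constant",
                  f = 0, ties = max)$y
  raw <- sum(diff(fgrid) * (head(tprAt, -1) + tail(tprAt, -1)) / 2)
  expect_equal(pauc(probs, y), raw / 0.15, tolerance = 1e-4)
  # bounds: pauc_norm <= auc / bandwidth and in [0, 1]
  for (rr in 1:20) {
    p2 <- runif(60)
    pn <- pauc(p2, y)
    expect_true(pn >= 0 && pn <= 1)
    expect_lte(pn, rocCurve(p2, y)$auc / 0.15 + 1e-12)
  }
})

test_that("paired AUC comparisons detect signal and keep their size", {
  y <- rep(0:1, each = 100)
  set.seed(31)
  strong <- c(rnorm(100, 0), rnorm(100, 2))
  noise <- rnorm(200)
  expect_equal(compareAuc(strong, strong, y), 1)
  expect_lt(compareAuc(strong, noise, y, kind = "auc"), 0.01)
  expect_lt(compareAuc(strong, noise, y, kind = "pauc", nBoot = 500,
                       seed = 2), 0.01)

  # size: two independent noise classifiers, 500 replicates
  set.seed(77)
  rej <- mean(replicate(500, {
    yy <- rep(0:1, each = 60)
    compareAuc(rnorm(120), rnorm(120), yy, kind = "auc") < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  expect_error(compareAuc(strong[-1], noise, y), "length")
})

test_that("metric correlations match the t-distribution formula", {
  set.seed(8)
  M <- cbind(m1 = rnorm(10), m2 = rnorm(10))
  out <- metricCorrelations(M)
  ct <- cor.test(M[, 1], M[, 2])
  expect_equal(out$r[1, 2], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(out$p[1, 2], ct$p.value, tolerance = 1e-12)
  expect_equal(out$r[1, 1], 1)

  M2 <- cbind(x = M[, 1], negx = -M[, 1] * 1.0)
  out2 <- metricCorrelations(M2)
  expect_equal(out2$r[1, 2], -1)
  expect_lt(out2$p[1, 2], 1e-10)
  expect_error(metricCorrelations(cbind(a = rep(1, 10), b = rnorm(10))),
               "zero-variance column\\(s\\): a")
  expect_error(metricCorrelations(M[1:2, ]), "3 eyes")
})

test_that("threshold selection maximises sensitivity above the floor", {
  y <- rep(0:1, each = 20)
  perfect <- c(runif(20, 0, 0.4), runif(20, 0.6, 1))
  sel <- selectThreshold(perfect, y)
  expect_equal(sel$sens, 1)
  expect_equal(sel$spec, 1)

  # exhaustive-scan oracle agreement on noisy instances
  set.seed(41)
  for (r in 1:25) {
    probs <- runif(40)
    sel <- selectThreshold(probs, y, minSpec = 0.85)
    u <- sort(unique(probs))
    cand <- c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
    sens <- sapply(cand, function(t) mean(probs[y == 1] >= t))
    spec <- sapply(cand, function(t) mean(probs[y == 0] < t))
    ok <- spec >= 0.85
    expect_gte(sel$spec, 0.85)
    expect_equal(sel$sens, max(sens[ok]))
    best <- max(spec[ok][sens[ok] == max(sens[ok])])
    expect_equal(sel$spec, best)
  }
})
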