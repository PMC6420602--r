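grid <- buildGrid()

test_that("the global index handles exact and degenerate series", {
  s <- flat_series(c(25, 24, 23))
  gi <- globalIndex(s)
  expect_equal(unname(gi["gi_slope"]), -1)
  expect_equal(unname(gi["gi_p"]), 0)        # exact line, deterioration
  expect_equal(unname(gi["gi_interaction"]), 0)

  s2 <- flat_series(c(25, 25, 25, 25))
  gi2 <- globalIndex(s2)
  expect_equal(unname(gi2["gi_slope"]), 0)
  expect_equal(unname(gi2["gi_p"]), 1)

  expect_warning(gi3 <- globalIndex(flat_series(c(25, 24))), "2 tests")
  expect_true(all(is.na(gi3)))
  one <- VFSeries("e", 0, matrix(25, 52, 1))
  expect_error(globalIndex(one), "at least 2")
})

test_that("noisy global-index fits match the normal-equations oracle", {
  set.seed(42)
  for (r in 1:25) {
    tms <- c(0, sort(runif(7, 0, 3)))
    means <- 26 - 0.8 * tms + rnorm(8, sd = 0.7)
    s <- flat_series(means, tms)
    gi <- globalIndex(s)
    o <- oracle_ols(means, tms, "two")
    expect_equal(unname(gi["gi_slope"]), o$slope, tolerance = 1e-10)
    expect_equal(unname(gi["gi_p"]), o$p, tolerance = 1e-10)
  }
})

test_that("pointwise regressions apply the stated conventions", {
  sens <- matrix(30, 52, 3)
  sens[1, ] <- c(30, 28, 26)
  s <- VFSeries("e", 0:2, sens)
  fit <- pointwiseRegressions(s)
  expect_equal(fit$slope[1], -2)
  expect_equal(fit$slope_p[1], 0)
  expect_equal(fit$slope[2], 0)      # constant location
  expect_equal(fit$slope_p[2], 1)
  expect_true(all(fit$slope_p >= 0 & fit$slope_p <= 1))

  # with only 2 visits every location takes the n < 3 convention
  s2 <- VFSeries("e", c(0, 1), matrix(c(30, 20), 52, 2, byrow = FALSE))
  fit2 <- pointwiseRegressions(s2)
  expect_true(all(fit2$slope == 0) && all(fit2$slope_p == 1))
})

test_that("pointwise fits agree with the oracle across locations", {
  set.seed(7)
  tms <- c(0, sort(runif(6, 0, 2.5)))
  sens <- pmin(pmax(matrix(rnorm(52 * 7, 25, 4), 52, 7), 0), 50)
  s <- VFSeries("e", tms, sens)
  fit <- pointwiseRegressions(s)
  for (j in seq_len(52)) {
    o <- oracle_ols(sens[j, ], tms, "less")
    expect_equal(fit$slope[j], o$slope, tolerance = 1e-10)
    expect_equal(fit$slope_p[j], o$p, tolerance = 1e-10)
  }
})

test_that("order statistics and mean slope follow their definitions", {
  fit <- data.frame(location_id = 1:52, slope = 0, slope_p = 1,
                    n_points = 5)
  fit$slope_p[1:4] <- c(0.001, 0.5, 0.05, 0.2)
  expect_equal(unname(plrOrderStats(fit)), c(0.001, 0.05, 0.2, 0.5))
  fit$slope_p <- rep(1, 52)
  expect_equal(unname(plrOrderStats(fit)), c(1, 1, 1, 1))

  set.seed(1)
  fit$slope_p <- runif(52)
  expect_equal(unname(plrOrderStats(fit)), sort(fit$slope_p)[1:4])

  fit$slope <- c(-2, -1, 0.5, rep(0, 49))
  fit$slope_p <- c(0.005, 0.02, 0.001, rep(0.5, 49))
  expect_equal(meanSlope(fit), (-2 + 0.5) / 2)
  fit$slope_p <- rep(0.5, 52)
  expect_equal(meanSlope(fit), 0)
})

test_that("the PoPLR statistic and exact enumeration behave", {
  # S from known p-values: -ln(0.01) - ln(0.04)
  expect_equal(-log(0.01) - log(0.04), 7.82405, tolerance = 1e-5)

  set.seed(12)
  tms <- c(0, 0.7, 1.6)
  sens <- pmin(pmax(matrix(rnorm(52 * 3, 25, 4), 52, 3), 0), 50)
  s <- VFSeries("e", tms, sens)
  res <- poplr(s, nPerm = 199, seed = 1)
  # T = 3: exact enumeration over all 6 permutations, p = k/6
  k6 <- res[["poplr_p"]] * 6
  expect_equal(k6, round(k6), tolerance = 1e-9)
  expect_true(round(k6) %in% 1:6)

  # brute-force oracle: recompute S for each of the 6 reorderings with lm
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  s_of <- function(ord) {
    tot <- 0
    for (j in 1:52) {
      f <- lm(sens[j, ord] ~ tms)
      tval <- coef(summary(f))[2, 3]
      p <- pt(tval, 1)
      if (is.nan(p)) p <- 1
      if (p < 0.05) tot <- tot - log(p)
    }
    tot
  }
  Sall <- vapply(perms, s_of, numeric(1))
  expect_equal(unname(res["poplr_S"]), Sall[1], tolerance = 1e-8)
  expect_equal(unname(res["poplr_p"]),
               mean(Sall >= Sall[1] - 1e-12), tolerance = 1e-12)
})

test_that("PoPLR and GI are invariant to location relabelling", {
  set.seed(30)
  tms <- c(0, sort(runif(6, 0, 3)))
  sens <- matrix(rnorm(52 * 7, 24, 4), 52, 7)
  sens <- pmin(pmax(sens, 0), 50)
  s <- VFSeries("e", tms, sens)
  perm <- sample(52)
  sp <- VFSeries("e", tms, sens[perm, ])
  expect_equal(poplr(s, 199, 5), poplr(sp, 199, 5))
  expect_equal(globalIndex(s), globalIndex(sp))
  f1 <- pointwiseRegressions(s)
  f2 <- pointwiseRegressions(sp)
  expect_equal(f2$slope, f1$slope[perm])
})

test_that("trendPredictors composes its parts with missing propagation", {
  p <- simulationParams("global_trend", slope = -2, nTests = 4, tau2 = 0,
                        noiseLink = c(0, 0), seed = 9)
  s <- simulateEye(grid, p)
  tp <- trendPredictors(s, nPerm = 199, seed = 1)
  expect_equal(unname(tp["gi_slope"]), -2, tolerance = 1e-10)
  expect_true(tp["p1"] <= tp["p2"] && tp["p2"] <= tp["p3"] &&
                tp["p3"] <= tp["p4"])

  ps <- simulationParams("stable", tau2 = 0, noiseLink = c(0, 0), seed = 9)
  ss <- simulateEye(grid, ps)
  tps <- trendPredictors(ss, nPerm = 199, seed = 1)
  expect_equal(unname(tps[c("p1", "p2", "p3", "p4")]), rep(1, 4))
  expect_equal(unname(tps["ms"]), 0)
  expect_equal(unname(tps["poplr_S"]), 0)

  expect_warning(t2 <- trendPredictors(flat_series(c(25, 24))), "2 tests")
  expect_true(all(is.na(t2)))
})
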