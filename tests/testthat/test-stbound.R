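grid <- buildGrid()

test_that("the precision matrix matches a small-graph hand computation", {
  # 5-node path with hand-set dissimilarities
  z <- c(0.2, 0.5, 0.0, 1.0)
  gph <- toy_graph(z)
  a <- 1.3
  rho <- 0.9
  Q <- precisionMatrix(a, gph, rho)
  w <- exp(-a * z)
  W <- matrix(0, 5, 5)
  for (k in 1:4) W[k, k + 1] <- W[k + 1, k] <- w[k]
  Qhand <- rho * (diag(rowSums(W)) - W) + (1 - rho) * diag(5)
  expect_equal(Q, Qhand, tolerance = 1e-15)
  expect_error(precisionMatrix(0, gph), "positive")
  expect_error(precisionMatrix(-1, gph), "positive")
})

test_that("Q stays positive definite with the (1 - rho) eigenvalue floor", {
  for (a in c(1e-12, 0.5, 8, 24, 120)) {
    Q <- precisionMatrix(max(a, 1e-12), grid, 0.99)
    ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), (1 - 0.99) - 1e-12)
  }
  # alpha -> 0 limit: all weights 1, Q = rho * graph Laplacian + (1-rho) I
  Q0 <- precisionMatrix(1e-12, grid, 0.99)
  A <- matrix(0, 52, 52)
  idx <- match(adjacentPairs(grid)[, 1], retainedIds(grid))
  jdx <- match(adjacentPairs(grid)[, 2], retainedIds(grid))
  A[cbind(idx, jdx)] <- 1
  A[cbind(jdx, idx)] <- 1
  L <- diag(rowSums(A)) - A
  expect_equal(Q0, 0.99 * L + 0.01 * diag(52), tolerance = 1e-9)
})

test_that("the CAR log-likelihood equals the dense-oracle density", {
  set.seed(5)
  # fixed 3-node check plus random graphs up to 6 nodes
  gph <- toy_graph(c(0.3, 0.8))
  y <- c(1.2, -0.5, 2.2)
  ll <- fieldLoglik(y, 0.4, 2.5, 1.7, gph, rho = 0.95)
  expect_equal(ll, oracle_dense_loglik(y, 0.4, 2.5, 1.7, gph, 0.95),
               tolerance = 1e-8)

  for (r in 1:40) {
    n <- sample(3:6, 1)
    gph <- random_graph(n)
    y <- rnorm(n, 20, 5)
    mu <- runif(1, 10, 30)
    tau2 <- runif(1, 0.5, 9)
    a <- exp(runif(1, -2, 3))
    rho <- runif(1, 0.5, 0.995)
    expect_equal(fieldLoglik(y, mu, tau2, a, gph, rho),
                 oracle_dense_loglik(y, mu, tau2, a, gph, rho),
                 tolerance = 1e-8)
  }
})

test_that("the log-likelihood is maximised at the field mean and scales in tau2", {
  gph <- toy_graph(c(0.3, 0.8, 0.1))
  mu <- 25
  atMode <- fieldLoglik(rep(mu, 4), mu, 2, 1, gph)
  set.seed(8)
  for (r in 1:10) {
    expect_gt(atMode, fieldLoglik(mu + rnorm(4, sd = 0.5), mu, 2, 1, gph))
  }
  y <- c(24, 26, 25.5, 23.8)
  l1 <- fieldLoglik(y, mu, 2, 1, gph)
  l2 <- fieldLoglik(y, mu, 4, 1, gph)
  expect_equal(l2, oracle_dense_loglik(y, mu, 4, 1, gph, 0.99),
               tolerance = 1e-8)
  expect_equal(l1 - l2,
               oracle_dense_loglik(y, mu, 2, 1, gph, 0.99) -
                 oracle_dense_loglik(y, mu, 4, 1, gph, 0.99),
               tolerance = 1e-8)
  expect_error(fieldLoglik(c(1, NA, 3, 4), mu, 2, 1, gph), "finite")
})

test_that("the conjugate delta update matches its closed-form conditional", {
  set.seed(13)
  T <- 6
  Theta <- matrix(rnorm(3 * T, c(25, 1.5, 2.5), 0.5), 3, T)
  Sigma <- crossprod(matrix(rnorm(9), 3, 3)) + diag(3)
  SigmaInv <- solve(Sigma)
  tms <- c(0, sort(runif(T - 1, 0, 3)))
  Psi <- exp(-0.8 * abs(outer(tms, tms, "-")))
  PsiInv <- solve(Psi)
  deltaVar <- 1000

  # closed form: precision P = (1'Psi^-1 1) Sigma^-1 + I/v, mean P^-1 b
  cc <- sum(PsiInv)
  P <- cc * SigmaInv + diag(3) / deltaVar
  b <- SigmaInv %*% Theta %*% PsiInv %*% rep(1, T)
  mExp <- solve(P, b)
  vExp <- solve(P)

  nrep <- 6000
  draws <- matrix(NA_real_, 3, nrep)
  set.seed(99)
  for (r in seq_len(nrep)) {
    draws[, r] <- vfprog:::.cpp_draw_delta(Theta, SigmaInv, PsiInv, deltaVar)
  }
  mc <- rowMeans(draws)
  se <- sqrt(diag(vExp) / nrep)
  expect_true(all(abs(mc - mExp) < 3.5 * se))
  expect_equal(cov(t(draws)), vExp, tolerance = 0.1)
})

test_that("fits are seed-reproducible and handle the two-visit minimum", {
  p <- simulationParams("stable", nTests = 4, seed = 31)
  s <- simulateEye(grid, p)
  cfg <- stboundConfig("mini", seed = 17)
  f1 <- fitSTBound(s, grid, cfg)
  f2 <- fitSTBound(s, grid, cfg)
  expect_identical(f1@alpha, f2@alpha)
  expect_identical(f1@cv, f2@cv)
  expect_identical(f1@phi, f2@phi)

  # minimum-input contract: 2 identical tests still produce finite output
  sens <- matrix(25, 52, 2)
  s2 <- VFSeries("twin", c(0, 0.5), sens)
  f3 <- fitSTBound(s2, grid, stboundConfig("mini", seed = 3))
  expect_true(all(is.finite(f3@cv)))
  expect_true(all(is.finite(stboundPredictors(f3))))

  one <- VFSeries("short", 0, matrix(25, 52, 1))
  expect_error(fitSTBound(one, grid, cfg), "minimum of two visits")
})

test_that("the predictor triple is plain arithmetic on the draws", {
  mk <- function(alphaDraws) {
    nd <- nrow(alphaDraws)
    cv <- apply(alphaDraws, 1, function(r) sd(r) / mean(r))
    new("STBoundFit", eyeId = "x", times = seq_len(ncol(alphaDraws)) - 1,
        mu = alphaDraws * 0 + 25, tau2 = alphaDraws * 0 + 1,
        alpha = alphaDraws, phi = rep(1, nd),
        delta = matrix(0, nd, 3), cv = cv,
        acceptance = c(v = 0.3), config = list())
  }
  # every draw alpha = (1, 2, 3): CV = sd(1,2,3)/2 = 0.5, no spread
  f <- mk(matrix(rep(c(1, 2, 3), each = 120), 120, 3))
  p <- stboundPredictors(f)
  expect_equal(unname(p), c(0.5, 0, 0))
  # constant alpha across visits: (0, 0, 0)
  f2 <- mk(matrix(4, 150, 5))
  expect_equal(unname(stboundPredictors(f2)), c(0, 0, 0))
  # random draws against a one-line recomputation oracle
  set.seed(2)
  A <- matrix(exp(rnorm(1000 * 4, 2, 0.4)), 1000, 4)
  f3 <- mk(A)
  cvv <- apply(A, 1, sd) / rowMeans(A)
  p3 <- stboundPredictors(f3)
  expect_equal(unname(p3["cv_mean"]), mean(cvv), tolerance = 1e-12)
  expect_equal(unname(p3["cv_sd"]), sd(cvv), tolerance = 1e-12)
  expect_equal(unname(p3["cv_interaction"]), mean(cvv) * sd(cvv),
               tolerance = 1e-12)
  # the kept-draw floor is enforced
  f4 <- mk(matrix(2, 50, 3))
  expect_error(stboundPredictors(f4), "100 kept draws")
})

test_that("sampled alpha draws respect positivity and the config floor", {
  p <- simulationParams("correlation_shift", nTests = 5, seed = 77)
  s <- simulateEye(grid, p)
  f <- fitSTBound(s, grid, stboundConfig("mini", seed = 5))
  expect_true(all(f@alpha > 0))
  expect_true(all(f@tau2 > 0))
  expect_true(all(f@cv >= 0))
  expect_error(stboundConfig(nKeep = 300, thin = 10), "100 kept draws")
  expect_error(stboundConfig(rho = 1.2), "rho")
})
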