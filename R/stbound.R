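## Normalise a graph argument to (n, ei, ej (0-based), z). Accepts a VFGrid
## or a plain list(pairs = 2-col matrix of 1..n indices, z = numeric, n =
## node count) so the likelihood can be exercised on small toy graphs.
.graph_spec <- function(grid) {
  if (is(grid, "VFGrid")) {
    ids <- retainedIds(grid)
    i <- match(grid@pairs[, 1], ids)
    j <- match(grid@pairs[, 2], ids)
    list(n = length(ids), ei = i - 1L, ej = j - 1L, z = grid@z)
  } else if (is.list(grid) && all(c("pairs", "z", "n") %in% names(grid))) {
    list(n = as.integer(grid$n), ei = as.integer(grid$pairs[, 1]) - 1L,
         ej = as.integer(grid$pairs[, 2]) - 1L, z = as.numeric(grid$z))
  } else {
    stop("grid must be a VFGrid or a list(pairs, z, n)", call. = FALSE)
  }
}

#' Boundary-detection CAR precision matrix
#'
#' Builds the conditional-autoregressive precision
#' \deqn{Q(\alpha) = \rho (D(\alpha) - W(\alpha)) + (1 - \rho) I,}
#' where the adjacency weights are the continuous boundary-detection form
#' \eqn{W_{ij}(\alpha) = \exp(-\alpha z_{ij})} on adjacent pairs (0
#' otherwise), \eqn{D} is the diagonal of row sums of \eqn{W}, and the
#' propriety parameter \eqn{\rho \in (0, 1)} keeps \eqn{Q} symmetric
#' positive definite with smallest eigenvalue at least \eqn{1 - \rho}.
#' Large \eqn{\alpha} shrinks weights across dissimilar (anatomically
#' boundary-crossing) pairs, so \eqn{\alpha} acts as the spatial-smoothness
#' parameter whose variation over visits the STBound predictor measures.
#'
#' @param alpha positive spatial-smoothness parameter.
#' @param grid a [VFGrid-class], or a toy graph as
#'   \code{list(pairs, z, n)} with 1-based node indices in \code{pairs}.
#' @param rho propriety parameter in (0, 1).
#' @return dense symmetric positive-definite matrix.
#' @export
precisionMatrix <- function(alpha, grid, rho = 0.99) {
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (rho <= 0 || rho >= 1) stop("rho must be in (0, 1)", call. = FALSE)
  g <- .graph_spec(grid)
  W <- matrix(0, g$n, g$n)
  w <- exp(-alpha * g$z)
  W[cbind(g$ei + 1L, g$ej + 1L)] <- w
  W[cbind(g$ej + 1L, g$ei + 1L)] <- w
  Q <- -rho * W
  diag(Q) <- rho * rowSums(W) + (1 - rho)
  Q
}

#' Gaussian CAR field log-likelihood
#'
#' Exact multivariate-normal log-density of a field
#' \eqn{y \sim N(\mu 1, \tau^2 Q(\alpha)^{-1})}, evaluated through the
#' Cholesky factorisation of \eqn{Q} (log-determinant from the factor; no
#' explicit inverse).
#'
#' @param y numeric observation vector.
#' @param mu field mean (scalar, dB).
#' @param tau2 positive variance scale (dB^2).
#' @param alpha positive spatial-smoothness parameter.
#' @param grid a [VFGrid-class] or toy-graph list (see
#'   [precisionMatrix()]).
#' @param rho propriety parameter in (0, 1).
#' @return log-density (scalar).
#' @export
fieldLoglik <- function(y, mu, tau2, alpha, grid, rho = 0.99) {
  if (any(!is.finite(y))) stop("y must be finite", call. = FALSE)
  g <- .graph_spec(grid)
  if (length(y) != g$n) stop("y length must match the graph", call. = FALSE)
  .cpp_car_loglik(y, mu, tau2, alpha, g$ei, g$ej, g$z, rho)
}

#' Sampler configuration for the boundary-detection model
#'
#' @param preset \code{"full"} (10,000 burn-in, 10,000 sampling iterations
#'   thinned by 10, i.e. 1,000 kept draws), \code{"reduced"}
#'   (2,000/2,000/4) for simulation studies, or \code{"mini"} (400/400/4)
#'   for pipeline-scale runs; individual arguments override the preset.
#' @param rho propriety parameter in (0, 1), fixed (not sampled).
#' @param nBurn,nKeep,thin burn-in iterations, sampling iterations, and
#'   thinning interval; \code{nKeep / thin} kept draws (at least 100).
#' @param deltaVar prior variance of each component of the level
#'   \eqn{\delta}.
#' @param sigmaDf,sigmaScale inverse-Wishart prior degrees of freedom and
#'   scale for the 3x3 cross-parameter covariance \eqn{\Sigma}.
#' @param scales baseline random-walk proposal standard deviations for
#'   \eqn{(\mu_t, \ln \tau^2_t, \ln \alpha_t)}.
#' @param phiScale initial random-walk scale for the temporal decay.
#' @param adapt adapt proposal scales during burn-in toward acceptance 0.35.
#' @param likelihood \code{"gaussian"} or \code{"tobit"} (left-censoring of
#'   observed 0 dB values, imputed by Gibbs).
#' @param phiBounds optional \code{c(a, b)} for the uniform prior on the
#'   temporal decay \eqn{\phi} (1/years); by default derived from the visit
#'   times so the temporal correlation spans 0.999 at the largest gap down
#'   to 0.01 at the smallest.
#' @param seed integer seed.
#' @return a list of class \code{STBoundConfig}.
#' @export
stboundConfig <- function(preset = c("full", "reduced", "mini"),
                          rho = 0.99, nBurn = NULL, nKeep = NULL,
                          thin = NULL, deltaVar = 1000, sigmaDf = 5,
                          sigmaScale = diag(3),
                          scales = c(1, 0.4, 0.6), phiScale = 0.5,
                          adapt = TRUE,
                          likelihood = c("gaussian", "tobit"),
                          phiBounds = NULL, seed = 1L) {
  preset <- match.arg(preset)
  likelihood <- match.arg(likelihood)
  def <- switch(preset,
                full = c(10000L, 10000L, 10L),
                reduced = c(2000L, 2000L, 4L),
                mini = c(400L, 400L, 4L))
  if (is.null(nBurn)) nBurn <- def[1]
  if (is.null(nKeep)) nKeep <- def[2]
  if (is.null(thin)) thin <- def[3]
  if (rho <= 0 || rho >= 1) stop("rho must be in (0, 1)", call. = FALSE)
  if (nKeep / thin < 100) {
    stop("nKeep / thin must give at least 100 kept draws", call. = FALSE)
  }
  if (!is.null(phiBounds) && phiBounds[1] >= phiBounds[2]) {
    stop("phiBounds must satisfy a < b", call. = FALSE)
  }
  structure(list(rho = rho, nBurn = as.integer(nBurn),
                 nKeep = as.integer(nKeep), thin = as.integer(thin),
                 deltaVar = deltaVar, sigmaDf = sigmaDf,
                 sigmaScale = sigmaScale, scales = scales,
                 phiScale = phiScale, adapt = adapt,
                 likelihood = likelihood, phiBounds = phiBounds,
                 seed = as.integer(seed)),
            class = "STBoundConfig")
}

.phi_bounds <- function(times) {
  gaps <- diff(times)
  maxgap <- max(times) - min(times)
  mingap <- min(gaps)
  c(-log(0.999) / maxgap, -log(0.01) / mingap)
}

#' Fit the spatiotemporal boundary-detection model to one eye
#'
#' Runs the Metropolis-within-Gibbs sampler over the per-visit blocks
#' \eqn{\theta_t = (\mu_t, \ln \tau^2_t, \ln \alpha_t)} with matrix-normal
#' prior \eqn{\Theta \sim MN(\delta 1', \Sigma, \Psi(\phi))},
#' \eqn{\Psi(\phi)_{ts} = \exp(-\phi |v_t - v_s|)}; \eqn{\delta} and
#' \eqn{\Sigma} have conjugate Gibbs updates, \eqn{\phi} and each
#' \eqn{\theta_t} random-walk Metropolis updates with burn-in adaptation.
#' Per kept draw the coefficient of variation of \eqn{\{\alpha_t\}_t}
#' (sample sd over mean) is derived; its posterior mean and sd are the
#' STBound predictor. The model needs a minimum of two visits.
#'
#' @param series a [VFSeries-class] with at least 2 tests.
#' @param grid a [VFGrid-class].
#' @param config a [stboundConfig()] list.
#' @return an [STBoundFit-class].
#' @export
fitSTBound <- function(series, grid, config = stboundConfig()) {
  stopifnot(inherits(config, "STBoundConfig"))
  if (nTests(series) < 2L) {
    stop("STBound requires a minimum of two visits", call. = FALSE)
  }
  g <- .graph_spec(grid)
  Y <- sensitivities(series)
  times <- visitTimes(series)
  bounds <- config$phiBounds
  if (is.null(bounds)) bounds <- .phi_bounds(times)

  ## per-visit profile-ML initialisation: for each candidate alpha the
  ## conditional MLE of tau2 is r'Q r / n, leaving a one-dimensional profile
  ## over ln alpha that is scanned on a fixed grid
  muInit <- colMeans(Y)
  laGrid <- seq(log(0.2), log(150), length.out = 15)
  Qs <- lapply(laGrid, function(la) {
    W <- matrix(0, g$n, g$n)
    w <- exp(-exp(la) * g$z)
    W[cbind(g$ei + 1L, g$ej + 1L)] <- w
    W[cbind(g$ej + 1L, g$ei + 1L)] <- w
    Q <- -config$rho * W
    diag(Q) <- config$rho * rowSums(W) + (1 - config$rho)
    list(Q = Q, ld = 2 * sum(log(diag(chol(Q)))))
  })
  lalphaInit <- ltau2Init <- numeric(length(times))
  for (t in seq_along(times)) {
    r <- Y[, t] - muInit[t]
    prof <- vapply(Qs, function(q) {
      t2 <- max(as.numeric(r %*% q$Q %*% r) / g$n, 1e-3)
      -0.5 * g$n * log(t2) + 0.5 * q$ld
    }, numeric(1))
    best <- which.max(prof)
    lalphaInit[t] <- laGrid[best]
    ltau2Init[t] <- log(max(as.numeric(r %*% Qs[[best]]$Q %*% r) / g$n,
                            1e-3))
  }

  set.seed(config$seed)
  out <- .cpp_stbound_mcmc(Y, times, g$ei, g$ej, g$z, config$rho,
                           config$deltaVar, config$sigmaDf,
                           config$sigmaScale, bounds[1], bounds[2],
                           config$nBurn, config$nKeep, config$thin,
                           config$scales, config$phiScale, config$adapt,
                           config$likelihood == "tobit",
                           muInit, ltau2Init, lalphaInit)

  a <- out$alpha
  cv <- apply(a, 1, function(row) stats::sd(row) / mean(row))
  acc <- c(out$acceptance)
  names(acc) <- c(paste0("visit", seq_along(times)), "phi")
  new("STBoundFit", eyeId = eyeId(series), times = times,
      mu = out$mu, tau2 = out$tau2, alpha = a, phi = c(out$phi),
      delta = out$delta, cv = cv, acceptance = acc,
      config = unclass(config))
}

#' The STBound predictor triple
#'
#' Posterior mean of the per-draw coefficient of variation of the
#' spatial-smoothness parameter across visits, its posterior standard
#' deviation, and their product. The CV is computed per posterior draw
#' (sample sd with \eqn{T - 1} denominator over the per-draw mean of
#' \eqn{\alpha_t}), which is what makes a posterior SD of the CV
#' well-defined.
#'
#' @param fit an [STBoundFit-class] with at least 100 kept draws.
#' @return named numeric vector \code{cv_mean}, \code{cv_sd},
#'   \code{cv_interaction}.
#' @export
setMethod("stboundPredictors", "STBoundFit", function(fit) {
  if (length(fit@cv) < 100L) {
    stop("at least 100 kept draws required", call. = FALSE)
  }
  m <- mean(fit@cv)
  s <- stats::sd(fit@cv)
  c(cv_mean = m, cv_sd = s, cv_interaction = m * s)
})
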