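## Closed-form simple OLS of each row of Y on x, with the degenerate-fit
## conventions used throughout the trend metrics:
##   n < 3                      -> slope 0, p 1
##   zero residual variance     -> p 0 if the slope favours deterioration
##                                 (or any change, two-sided), else p 1
## sided = "less" gives the one-sided p for slope < 0; "two" the two-sided
## slope t-test p.
.row_ols <- function(Y, x, sided = c("less", "two")) {
  sided <- match.arg(sided)
  Y <- rbind(Y)
  n <- length(x)
  if (n < 3L) {
    return(data.frame(slope = rep(0, nrow(Y)), p = rep(1, nrow(Y)),
                      n_points = n))
  }
  xc <- x - mean(x)
  Sxx <- sum(xc^2)
  Yc <- Y - rowMeans(Y)
  slope <- as.numeric(Yc %*% xc) / Sxx
  Syy <- rowSums(Yc^2)
  RSS <- pmax(0, Syy - slope^2 * Sxx)
  df <- n - 2L
  p <- numeric(length(slope))
  degen <- RSS <= 1e-10 * pmax(Syy, 1)
  sig2 <- RSS / df
  se <- sqrt(sig2 / Sxx)
  tt <- ifelse(se > 0, slope / se, 0)
  if (sided == "less") {
    p <- stats::pt(tt, df)
    p[degen] <- ifelse(slope[degen] < 0, 0, 1)
  } else {
    p <- 2 * stats::pt(-abs(tt), df)
    p[degen] <- ifelse(abs(slope[degen]) > 1e-12 * max(abs(slope), 1), 0, 1)
  }
  data.frame(slope = slope, p = pmin(1, pmax(0, p)), n_points = n)
}

#' Global-index regression
#'
#' Averages the 52 retained sensitivities within each test to a single
#' global index, regresses the per-test means on time by ordinary least
#' squares, and returns the slope (dB/year), the two-sided p-value of the
#' slope t-test, and their product. A fit needs at least 3 tests; with
#' exactly 2 the three predictors are returned missing with a warning.
#'
#' @param series a [VFSeries-class].
#' @return named numeric vector \code{gi_slope}, \code{gi_p},
#'   \code{gi_interaction}.
#' @export
globalIndex <- function(series) {
  nT <- nTests(series)
  if (nT < 2L) stop("global index requires at least 2 tests", call. = FALSE)
  if (nT == 2L) {
    warning("global index undefined with exactly 2 tests; returning NA",
            call. = FALSE)
    return(c(gi_slope = NA_real_, gi_p = NA_real_, gi_interaction = NA_real_))
  }
  means <- colMeans(sensitivities(series))
  fit <- .row_ols(matrix(means, nrow = 1), visitTimes(series), "two")
  c(gi_slope = fit$slope, gi_p = fit$p,
    gi_interaction = fit$slope * fit$p)
}

#' Pointwise linear regressions
#'
#' Regresses each retained location's sensitivity on time. The p-value is
#' ONE-SIDED for deterioration (slope < 0), the convention of permutation-
#' based pointwise analyses; locations with fewer than 3 visits or a
#' constant series get slope 0 and p 1, and exact declining lines get p 0
#' so predictors stay defined on short early-cutoff series.
#'
#' @param series a [VFSeries-class].
#' @return data.frame with one row per retained location: \code{location_id},
#'   \code{slope} (dB/year), \code{slope_p} in \eqn{[0, 1]},
#'   \code{n_points}.
#' @export
pointwiseRegressions <- function(series) {
  if (nTests(series) < 2L) {
    stop("pointwise regression requires at least 2 tests", call. = FALSE)
  }
  Y <- sensitivities(series)
  fit <- .row_ols(Y, visitTimes(series), "less")
  data.frame(location_id = as.integer(rownames(Y)), slope = fit$slope,
             slope_p = fit$p, n_points = fit$n_points)
}

#' Order statistics of pointwise p-values
#'
#' The four smallest location-wise deterioration p-values in nondecreasing
#' order. These enter the logistic combiner directly as predictors P1-P4.
#'
#' @param fit output of [pointwiseRegressions()].
#' @return named numeric vector \code{p1}..\code{p4}.
#' @export
plrOrderStats <- function(fit) {
  p <- sort(fit$slope_p)[1:4]
  stats::setNames(p, c("p1", "p2", "p3", "p4"))
}

#' Mean slope of significantly deteriorating locations
#'
#' Arithmetic mean of the location slopes whose deterioration p-value is
#' below 0.01; 0 when no location qualifies (no evidence of change).
#'
#' @param fit output of [pointwiseRegressions()].
#' @return mean slope in dB/year.
#' @export
meanSlope <- function(fit) {
  sel <- fit$slope_p < 0.01
  if (!any(sel)) return(0)
  mean(fit$slope[sel])
}

.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow = rows))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

#' Permutation of pointwise linear regression (PoPLR)
#'
#' The observed statistic is \eqn{S = \sum -\ln p} over locations whose
#' one-sided deterioration p-value is below 0.05. Its null distribution is
#' built by reordering the visit sequence jointly across all locations
#' (times stay fixed; whole test fields are permuted, preserving within-test
#' spatial correlation) and recomputing \eqn{S}. The permutation p-value is
#' \eqn{(1 + \#\{S_{perm} \ge S_{obs}\}) / (n_{perm} + 1)}; when
#' \eqn{T! \le n_{perm}} all \eqn{T!} permutations are enumerated exactly
#' and the p-value is the exact proportion \eqn{\#\{S_{perm} \ge S_{obs}\}/T!}
#' (identity included).
#'
#' @param series a [VFSeries-class] with at least 3 tests.
#' @param nPerm number of random permutations (>= 99) when enumeration is
#'   infeasible.
#' @param seed integer seed for the random permutations.
#' @return named numeric vector \code{poplr_S}, \code{poplr_p}.
#' @export
poplr <- function(series, nPerm = 1999L, seed = 1L) {
  nT <- nTests(series)
  if (nT < 3L) {
    warning("PoPLR undefined with fewer than 3 tests; returning NA",
            call. = FALSE)
    return(c(poplr_S = NA_real_, poplr_p = NA_real_))
  }
  if (nPerm < 99L) stop("nPerm must be >= 99", call. = FALSE)
  Y <- sensitivities(series)
  x <- visitTimes(series)
  xc <- x - mean(x)
  Sxx <- sum(xc^2)
  Yc <- Y - rowMeans(Y)
  Syy <- rowSums(Yc^2)
  df <- nT - 2L

  s_of_perm <- function(CT) {
    ## CT: T x m matrix of permuted centred times (Sxx invariant)
    B <- (Yc %*% CT) / Sxx
    RSS <- pmax(0, as.numeric(Syy - B^2 * Sxx))
    degen <- RSS <= 1e-10 * pmax(Syy, 1)
    se <- sqrt((RSS / df) / Sxx)
    tt <- ifelse(se > 0, as.numeric(B) / se, 0)
    P <- stats::pt(tt, df)
    P[degen] <- ifelse(as.numeric(B)[degen] < 0, 0, 1)
    colSums(matrix(ifelse(P < 0.05, -log(P), 0), nrow = nrow(Yc)))
  }

  S_obs <- s_of_perm(matrix(xc, ncol = 1))
  ## relative tie tolerance so the identity permutation always ties S_obs
  ## (S may be +Inf when a location fits an exact declining line)
  tieTol <- if (is.finite(S_obs)) 1e-8 * max(1, abs(S_obs)) else 0
  exact <- factorial(nT) <= nPerm
  if (exact) {
    perms <- .all_perms(nT)
    CT <- matrix(xc[t(perms)], nrow = nT)
    S_perm <- s_of_perm(CT)
    p <- mean(S_perm >= S_obs - tieTol)
  } else {
    set.seed(seed)
    CT <- vapply(seq_len(nPerm), function(i) xc[sample.int(nT)],
                 numeric(nT))
    S_perm <- s_of_perm(CT)
    p <- (1 + sum(S_perm >= S_obs - tieTol)) / (nPerm + 1)
  }
  c(poplr_S = unname(S_obs), poplr_p = p)
}

#' All trend-based progression predictors for one eye
#'
#' Composition of [globalIndex()], [pointwiseRegressions()],
#' [plrOrderStats()], [meanSlope()] and [poplr()]. Eyes with exactly 2
#' tests return every trend predictor missing (with warnings from the
#' components).
#'
#' @param series a [VFSeries-class].
#' @param nPerm,seed forwarded to [poplr()].
#' @return named numeric vector with components \code{gi_slope},
#'   \code{gi_p}, \code{gi_interaction}, \code{p1}..\code{p4}, \code{ms},
#'   \code{poplr_S}, \code{poplr_p}.
#' @export
trendPredictors <- function(series, nPerm = 1999L, seed = 1L) {
  gi <- globalIndex(series)
  if (nTests(series) < 3L) {
    return(c(gi, p1 = NA_real_, p2 = NA_real_, p3 = NA_real_,
             p4 = NA_real_, ms = NA_real_, poplr_S = NA_real_,
             poplr_p = NA_real_))
  }
  fit <- pointwiseRegressions(series)
  c(gi, plrOrderStats(fit), ms = meanSlope(fit),
    poplr(series, nPerm = nPerm, seed = seed))
}
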