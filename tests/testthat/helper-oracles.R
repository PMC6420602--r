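# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (explicit normal equations, dense inverses, full
# enumeration) so they share no code path with the package implementation.

# simple OLS via explicit normal equations + t CDF
oracle_ols <- function(y, x, sided = c("less", "two")) {
  sided <- match.arg(sided)
  X <- cbind(1, x)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  slope <- beta[2]
  res <- y - X %*% beta
  df <- length(y) - 2
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * solve(XtX)[2, 2])
  tt <- slope / se
  p <- if (sided == "less") pt(tt, df) else 2 * pt(-abs(tt), df)
  list(slope = slope, p = p)
}

# dense multivariate-normal log-density via explicit inverse and determinant
oracle_dense_loglik <- function(y, mu, tau2, alpha, graph, rho) {
  n <- graph$n
  W <- matrix(0, n, n)
  for (k in seq_len(nrow(graph$pairs))) {
    w <- exp(-alpha * graph$z[k])
    W[graph$pairs[k, 1], graph$pairs[k, 2]] <- w
    W[graph$pairs[k, 2], graph$pairs[k, 1]] <- w
  }
  Q <- rho * (diag(rowSums(W)) - W) + (1 - rho) * diag(n)
  Sigma <- tau2 * solve(Q)
  r <- y - mu
  -n / 2 * log(2 * pi) - 0.5 * log(det(Sigma)) -
    0.5 * as.numeric(t(r) %*% solve(Sigma) %*% r)
}

# logistic regression by plain Newton-Raphson from a zero start
oracle_logistic <- function(X, y, maxit = 200) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    score <- t(X) %*% (y - p)
    H <- t(X) %*% (X * W)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(score)) < 1e-10) break
  }
  as.numeric(beta)
}

# AUC by brute-force pairwise comparison, ties one half
oracle_auc <- function(probs, y) {
  pos <- probs[y == 1]
  neg <- probs[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# small toy graph: a path 1-2-3(-...) with supplied dissimilarities
toy_graph <- function(z) {
  n <- length(z) + 1L
  list(pairs = cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L), z = z, n = n)
}

# random connected graph on n <= 6 nodes: a spanning path plus extras
random_graph <- function(n) {
  pairs <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  extra <- extra[extra[, 2] - extra[, 1] > 1, , drop = FALSE]
  if (nrow(extra)) {
    take <- runif(nrow(extra)) < 0.4
    pairs <- rbind(pairs, extra[take, , drop = FALSE])
  }
  list(pairs = pairs, z = runif(nrow(pairs)), n = n)
}

# a zero-noise series with prescribed per-visit global means
flat_series <- function(meanSeq, times = seq_along(meanSeq) - 1,
                        id = "eye1", label = "unknown") {
  sens <- matrix(rep(meanSeq, each = 52), nrow = 52)
  VFSeries(id, times, sens, label)
}

# small labelled synthetic cohort reused by diagnostics tests
make_predictor_frame <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  data.frame(eye_id = sprintf("e%02d", seq_len(n)), label = ifelse(y == 1,
             "progressing", "stable"), s1 = rnorm(n) + y,
             s2 = rnorm(n), stringsAsFactors = FALSE)
}
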