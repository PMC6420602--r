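.as01 <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    if (!all(labels %in% c("stable", "progressing"))) {
      stop("labels must be stable/progressing (or 0/1)", call. = FALSE)
    }
    labels <- as.integer(labels == "progressing")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% 0:1)) stop("labels must be binary", call. = FALSE)
  labels
}

#' Fit a logistic progression combiner
#'
#' Maximum-likelihood logistic regression of the binary clinical progression
#' label on a set of progression predictors, by iteratively reweighted least
#' squares. Rows with missing predictors are dropped (with a message).
#' Rank-deficient designs raise an error naming the collinear columns;
#' quasi-separation (any |coefficient| > 20) raises a warning but the fit is
#' kept. The model's fitted probabilities are the progression metric used
#' throughout the evaluation framework, and
#' \eqn{\mathrm{AIC} = 2k - 2\log L}.
#'
#' @param X data.frame or matrix of numeric predictors (one row per eye);
#'   \code{NULL} or zero columns fits an intercept-only model.
#' @param y binary labels: 0/1, logical, or \code{stable}/
#'   \code{progressing}.
#' @return an object of class \code{DiagnosticModel}: list with
#'   \code{coefficients}, \code{logLik}, \code{aic}, \code{fitted},
#'   \code{predictors}, \code{n}, \code{nDropped}, \code{keptRows}.
#' @export
fitLogistic <- function(X, y) {
  y <- .as01(y)
  if (is.null(X) || (!is.null(ncol(X)) && ncol(X) == 0L)) {
    X <- matrix(numeric(0), nrow = length(y), ncol = 0)
  }
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("predictors must be numeric", call. = FALSE)
  if (ncol(X) && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (nrow(X) != length(y)) stop("X and y sizes differ", call. = FALSE)
  keep <- if (ncol(X)) stats::complete.cases(X) else rep(TRUE, length(y))
  nDropped <- sum(!keep)
  if (nDropped) {
    message("dropping ", nDropped, " rows with missing predictors")
  }
  Xk <- X[keep, , drop = FALSE]
  yk <- y[keep]
  if (length(unique(yk)) < 2L) {
    stop("labels must contain both classes", call. = FALSE)
  }
  M <- cbind(`(Intercept)` = 1, Xk)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::glm.fit(M, yk, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-12,
                                                     maxit = 100))
  coefs <- fit$coefficients
  p <- fit$fitted.values
  logL <- sum(yk * log(p) + (1 - yk) * log1p(-p))
  k <- length(coefs)
  if (any(abs(coefs) > 20)) {
    warning("possible quasi-separation: |coefficient| > 20", call. = FALSE)
  }
  structure(list(coefficients = coefs, logLik = logL, aic = 2 * k - 2 * logL,
                 fitted = p, predictors = colnames(Xk) %||% character(),
                 n = length(yk), nDropped = nDropped, keptRows = which(keep)),
            class = "DiagnosticModel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.DiagnosticModel <- function(x, ...) {
  cat("DiagnosticModel:", length(x$coefficients), "coefficients, n =",
      x$n, "\n  logLik =", format(x$logLik), " AIC =", format(x$aic), "\n")
  print(x$coefficients)
  invisible(x)
}

#' Predicted progression probabilities from a fitted combiner
#'
#' @param model a \code{DiagnosticModel}.
#' @param newdata data.frame/matrix holding the model's predictor columns.
#' @return numeric probabilities in (0, 1); \code{NA} where a predictor is
#'   missing.
#' @export
predictProb <- function(model, newdata) {
  nd <- as.data.frame(newdata)
  if (length(model$predictors) == 0L) {
    return(stats::plogis(rep(model$coefficients[1], nrow(nd))))
  }
  nd <- as.matrix(nd[, model$predictors, drop = FALSE])
  eta <- model$coefficients[1] +
    as.numeric(nd %*% model$coefficients[model$predictors])
  stats::plogis(eta)
}

#' Combine a candidate metric with the global-index model
#'
#' Fits the logistic combiner on the union of the GI predictor columns and
#' the candidate's columns, and tests the candidate's added value over the
#' GI-only model by a likelihood-ratio test with degrees of freedom equal
#' to the number of added predictors. Rows are aligned: only eyes complete
#' for the union of columns enter both fits.
#'
#' @param giPredictors data.frame of the GI columns.
#' @param otherPredictors data.frame of the candidate columns.
#' @param y binary labels.
#' @return list with \code{combined} and \code{giOnly} models,
#'   \code{lrStat}, \code{df}, \code{pValue}.
#' @export
combineWithGI <- function(giPredictors, otherPredictors, y) {
  gi <- as.data.frame(giPredictors)
  ot <- as.data.frame(otherPredictors)
  if (any(names(ot) %in% names(gi))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(intersect(names(ot), names(gi)), collapse = ", "),
         call. = FALSE)
  }
  both <- cbind(gi, ot)
  keep <- stats::complete.cases(both)
  y <- .as01(y)
  combined <- fitLogistic(both[keep, , drop = FALSE], y[keep])
  giOnly <- fitLogistic(gi[keep, , drop = FALSE], y[keep])
  lr <- 2 * (combined$logLik - giOnly$logLik)
  df <- ncol(ot)
  list(combined = combined, giOnly = giOnly, lrStat = lr, df = df,
       pValue = stats::pchisq(max(lr, 0), df, lower.tail = FALSE))
}

#' ROC curve with Mann-Whitney AUC
#'
#' The ROC points are computed over the sorted unique probabilities used as
#' thresholds (predict progressing when probability >= threshold), ties
#' grouped; the AUC is the Mann-Whitney statistic
#' \eqn{U / (n_1 n_0)} with ties counted one half, which equals the
#' trapezoidal area of the tie-handled curve.
#'
#' @param probs predicted probabilities (any monotone score works).
#' @param labels binary labels.
#' @return object of class \code{ROCSummary}: list with \code{fpr},
#'   \code{tpr}, \code{thresholds}, \code{auc}.
#' @export
rocCurve <- function(probs, labels) {
  y <- .as01(labels)
  if (length(probs) != length(y)) stop("length mismatch", call. = FALSE)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required", call. = FALSE)
  r <- rank(probs)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(probs), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(probs >= t & y == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(probs >= t & y == 0), numeric(1))
  structure(list(fpr = c(0, fp / n0, 1), tpr = c(0, tp / n1, 1),
                 thresholds = c(Inf, thr, -Inf), auc = auc),
            class = "ROCSummary")
}

#' @export
print.ROCSummary <- function(x, ...) {
  cat(sprintf("ROCSummary: %d points, AUC = %.4f\n",
              length(x$fpr), x$auc))
  invisible(x)
}

#' Normalised partial AUC over a high-specificity band
#'
#' Raw area under the ROC curve restricted to false-positive rates in
#' \eqn{[0, 1 - \mathrm{spec}_{lo}]} (linear interpolation at the band
#' boundary), divided by the band width \eqn{1 - \mathrm{spec}_{lo}} so a
#' perfect classifier scores 1 and chance scores
#' \eqn{(1 - \mathrm{spec}_{lo}) / 2}. The default band is the clinically
#' relevant specificity range 85-100\%.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels.
#' @param specLo lower specificity bound in (0, 1).
#' @return normalised partial AUC in \eqn{[0, 1]}.
#' @export
pauc <- function(probs, labels, specLo = 0.85) {
  if (specLo <= 0 || specLo >= 1) {
    stop("specLo must be in (0, 1)", call. = FALSE)
  }
  roc <- rocCurve(probs, labels)
  fmax <- 1 - specLo
  fpr <- roc$fpr
  tpr <- roc$tpr
  keep <- fpr <= fmax + 1e-15
  xs <- fpr[keep]
  ys <- tpr[keep]
  if (max(xs) < fmax) {
    ## interpolate the curve at the band boundary
    i <- which(fpr > fmax)[1]
    w <- (fmax - fpr[i - 1]) / (fpr[i] - fpr[i - 1])
    xs <- c(xs, fmax)
    ys <- c(ys, tpr[i - 1] + w * (tpr[i] - tpr[i - 1]))
  }
  raw <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  raw / fmax
}

#' Compare two classifiers' AUC or partial AUC on the same eyes
#'
#' Full AUC: paired DeLong test (two-sided), via \pkg{pROC}. Partial AUC:
#' paired bootstrap over eyes of the difference in normalised pAUC
#' (resamples keeping the pairing; two-sided p from the bootstrap
#' distribution of the difference).
#'
#' @param probsA,probsB predicted probabilities on identical eyes.
#' @param labels binary labels.
#' @param kind \code{"auc"} or \code{"pauc"}.
#' @param specLo pAUC band (see [pauc()]).
#' @param nBoot bootstrap resamples for the pAUC comparison.
#' @param seed seed for the bootstrap.
#' @return two-sided p-value.
#' @export
compareAuc <- function(probsA, probsB, labels, kind = c("auc", "pauc"),
                       specLo = 0.85, nBoot = 2000L, seed = 1L) {
  kind <- match.arg(kind)
  y <- .as01(labels)
  if (length(probsA) != length(probsB) || length(probsA) != length(y)) {
    stop("length mismatch", call. = FALSE)
  }
  if (isTRUE(all.equal(probsA, probsB, tolerance = 0))) return(1)
  if (kind == "auc") {
    ra <- pROC::roc(y, probsA, quiet = TRUE, direction = "<",
                    levels = c(0, 1))
    rb <- pROC::roc(y, probsB, quiet = TRUE, direction = "<",
                    levels = c(0, 1))
    out <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    p <- out$p.value
    if (!is.finite(p)) p <- 1
    return(p)
  }
  set.seed(seed)
  n <- length(y)
  diffs <- rep(NA_real_, nBoot)
  for (b in seq_len(nBoot)) {
    idx <- sample.int(n, replace = TRUE)
    if (length(unique(y[idx])) < 2L) next
    diffs[b] <- pauc(probsA[idx], y[idx], specLo) -
      pauc(probsB[idx], y[idx], specLo)
  }
  diffs <- diffs[!is.na(diffs)]
  pLo <- mean(diffs <= 0)
  pHi <- mean(diffs >= 0)
  min(1, 2 * min(pLo, pHi))
}

#' Pearson correlations between progression metrics
#'
#' Pairwise Pearson correlations of the fitted progression probabilities
#' (or any per-eye metrics), with two-sided p-values from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}}.
#'
#' @param probMatrix numeric matrix or data.frame, eyes x metrics, no
#'   missing entries, at least 3 eyes.
#' @return list with matrices \code{r} (diagonal 1) and \code{p} (diagonal
#'   \code{NA}).
#' @export
metricCorrelations <- function(probMatrix) {
  M <- as.matrix(probMatrix)
  if (nrow(M) < 3L) stop("at least 3 eyes required", call. = FALSE)
  if (anyNA(M)) stop("missing entries not allowed", call. = FALSE)
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(M)[sds == 0], collapse = ", "), call. = FALSE)
  }
  n <- nrow(M)
  r <- stats::cor(M)
  rc <- pmin(1 - 1e-15, pmax(-1 + 1e-15, as.numeric(r)))
  tstat <- rc * sqrt((n - 2) / (1 - rc^2))
  p <- matrix(2 * stats::pt(-abs(tstat), n - 2), ncol(M), ncol(M),
              dimnames = dimnames(r))
  diag(r) <- 1
  diag(p) <- NA_real_
  list(r = r, p = p)
}

#' Clinically motivated threshold: maximise sensitivity at a specificity floor
#'
#' Candidate thresholds are the midpoints between adjacent sorted distinct
#' probabilities plus \eqn{\pm\infty} (predict progressing when probability
#' >= threshold). Among candidates with specificity at least
#' \code{minSpec}, the one maximising sensitivity is returned; ties are
#' broken toward higher specificity, then toward the lower threshold value.
#' \eqn{+\infty} (sensitivity 0, specificity 1) always satisfies the floor,
#' so a threshold always exists.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels.
#' @param minSpec specificity floor (default 0.85).
#' @return list with \code{threshold}, \code{sens}, \code{spec}.
#' @export
selectThreshold <- function(probs, labels, minSpec = 0.85) {
  y <- .as01(labels)
  u <- sort(unique(probs))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required", call. = FALSE)
  sens <- vapply(cand, function(t) sum(probs >= t & y == 1) / n1, numeric(1))
  spec <- vapply(cand, function(t) sum(probs < t & y == 0) / n0, numeric(1))
  ok <- spec >= minSpec
  candOk <- cand[ok]
  sensOk <- sens[ok]
  specOk <- spec[ok]
  ord <- order(-sensOk, -specOk, candOk)
  best <- ord[1]
  list(threshold = candOk[best], sens = sensOk[best], spec = specOk[best])
}
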