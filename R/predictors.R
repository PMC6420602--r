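## Deterministic per-eye seed: polynomial rolling hash of the eye id folded
## with the base seed, kept inside the 32-bit integer range. Depends only on
## the id string, so predictors recomputed on a truncated-but-identical
## series reuse the same seed.
.eye_seed <- function(eyeIdStr, baseSeed) {
  h <- as.double(baseSeed %% 2147483647L)
  for (ch in utf8ToInt(eyeIdStr)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

.trend_cols <- c("gi_slope", "gi_p", "gi_interaction", "p1", "p2", "p3",
                 "p4", "ms", "poplr_S", "poplr_p")
.stbound_cols <- c("cv_mean", "cv_sd", "cv_interaction")

#' Compute all progression predictors for a cohort
#'
#' One row per eye with the trend-based predictors (global index, PLR order
#' statistics, mean slope, PoPLR) and/or the STBound triple. Eyes with too
#' few visits for a metric get \code{NA} in that metric's columns (trend
#' metrics need 3 visits, STBound needs 2). PoPLR and STBound seeds are
#' derived deterministically from each eye's id and \code{baseSeed}, so the
#' table is reproducible and unchanged eyes keep identical values when the
#' cohort around them changes.
#'
#' @param cohort a [VFCohort-class].
#' @param grid a [VFGrid-class].
#' @param metrics subset of \code{c("trend", "stbound")}.
#' @param nPerm PoPLR permutations.
#' @param config an [stboundConfig()] for the STBound fits.
#' @param baseSeed integer master seed.
#' @return data.frame with columns \code{eye_id}, \code{label},
#'   \code{n_tests}, \code{follow_up}, then predictor columns.
#' @export
computePredictors <- function(cohort, grid,
                              metrics = c("trend", "stbound"),
                              nPerm = 1999L,
                              config = stboundConfig("reduced"),
                              baseSeed = 1L) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  rows <- lapply(cohort@series, function(s) {
    out <- data.frame(eye_id = eyeId(s), label = progressionLabel(s),
                      n_tests = nTests(s), follow_up = max(visitTimes(s)))
    sd <- .eye_seed(eyeId(s), baseSeed)
    if ("trend" %in% metrics) {
      tp <- stats::setNames(rep(NA_real_, length(.trend_cols)), .trend_cols)
      if (nTests(s) >= 3L) {
        tp[] <- suppressWarnings(
          trendPredictors(s, nPerm = nPerm, seed = sd))[.trend_cols]
      }
      out <- cbind(out, as.data.frame(as.list(tp)))
    }
    if ("stbound" %in% metrics) {
      sb <- stats::setNames(rep(NA_real_, 3L), .stbound_cols)
      if (nTests(s) >= 2L) {
        cfg <- config
        cfg$seed <- sd
        sb[] <- stboundPredictors(fitSTBound(s, grid, cfg))
      }
      out <- cbind(out, as.data.frame(as.list(sb)))
    }
    out
  })
  do.call(rbind, rows)
}

#' The standard model set of the evaluation framework
#'
#' Named list mapping each diagnostic model to its predictor columns: GI
#' (slope, p, interaction), MS, P1-P4, PoPLR (permutation p-value by
#' default; the statistic S is also computed and can be substituted), and
#' the STBound triple.
#'
#' @param poplrPredictor \code{"poplr_p"} (default) or \code{"poplr_S"}.
#' @param includeSTBound include the STBound model.
#' @return named list of character vectors of predictor columns.
#' @export
defaultModels <- function(poplrPredictor = c("poplr_p", "poplr_S"),
                          includeSTBound = TRUE) {
  poplrPredictor <- match.arg(poplrPredictor)
  m <- list(GI = c("gi_slope", "gi_p", "gi_interaction"),
            MS = "ms",
            P1 = "p1", P2 = "p2", P3 = "p3", P4 = "p4",
            PoPLR = poplrPredictor)
  if (includeSTBound) m$STBound <- .stbound_cols
  m
}

#' Diagnostic evaluation of a predictor table
#'
#' For each model in \code{models}, fits the logistic combiner on the
#' model's predictor columns (rows with missing predictors dropped
#' listwise per model) and reports AIC, AUC, normalised pAUC, and the
#' marginal likelihood-ratio p-value against the intercept-only model on
#' the same rows. When \code{withGI} is set, every non-GI model is also
#' combined with the GI columns and the added-metric likelihood-ratio
#' p-value plus the combined model's AIC/AUC/pAUC are reported.
#'
#' @param predictors data.frame from [computePredictors()] (must include a
#'   \code{label} column or \code{labels} must be given).
#' @param models named list of predictor column sets (see
#'   [defaultModels()]).
#' @param labels optional labels overriding \code{predictors$label}.
#' @param specLo pAUC specificity floor.
#' @param withGI also evaluate each model combined with GI.
#' @return data.frame, one row per model, with columns \code{model},
#'   \code{n}, \code{aic}, \code{auc}, \code{pauc}, \code{p_marginal} and
#'   (if \code{withGI}) \code{aic_with_gi}, \code{auc_with_gi},
#'   \code{pauc_with_gi}, \code{p_added_to_gi}. The fitted models are
#'   attached as attribute \code{"fits"} and their fitted probabilities as
#'   attribute \code{"probs"} (eyes x models, NA where dropped).
#' @export
evaluateMetrics <- function(predictors, models = defaultModels(),
                            labels = NULL, specLo = 0.85, withGI = TRUE) {
  if (is.null(labels)) labels <- predictors$label
  y <- .as01(labels)
  giCols <- c("gi_slope", "gi_p", "gi_interaction")
  out <- vector("list", length(models))
  fits <- list()
  probs <- matrix(NA_real_, nrow = nrow(predictors),
                  ncol = length(models),
                  dimnames = list(predictors$eye_id, names(models)))
  for (k in seq_along(models)) {
    nm <- names(models)[k]
    cols <- models[[k]]
    X <- predictors[, cols, drop = FALSE]
    keep <- stats::complete.cases(X)
    fit <- fitLogistic(X[keep, , drop = FALSE], y[keep])
    null <- fitLogistic(NULL, y[keep])
    pMarg <- stats::pchisq(max(0, 2 * (fit$logLik - null$logLik)),
                           df = length(cols), lower.tail = FALSE)
    probs[keep, k] <- fit$fitted
    fits[[nm]] <- fit
    row <- data.frame(model = nm, n = fit$n, aic = fit$aic,
                      auc = rocCurve(fit$fitted, y[keep])$auc,
                      pauc = pauc(fit$fitted, y[keep], specLo),
                      p_marginal = pMarg)
    if (withGI) {
      if (nm == "GI" || all(cols %in% giCols)) {
        row$aic_with_gi <- NA_real_
        row$auc_with_gi <- NA_real_
        row$pauc_with_gi <- NA_real_
        row$p_added_to_gi <- NA_real_
      } else {
        keep2 <- stats::complete.cases(predictors[, c(giCols, cols)])
        cmb <- combineWithGI(predictors[keep2, giCols, drop = FALSE],
                             predictors[keep2, cols, drop = FALSE],
                             y[keep2])
        row$aic_with_gi <- cmb$combined$aic
        row$auc_with_gi <- rocCurve(cmb$combined$fitted, y[keep2])$auc
        row$pauc_with_gi <- pauc(cmb$combined$fitted, y[keep2], specLo)
        row$p_added_to_gi <- cmb$pValue
        fits[[paste0("GI+", nm)]] <- cmb$combined
      }
    }
    out[[k]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "fits") <- fits
  attr(res, "probs") <- probs
  res
}
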