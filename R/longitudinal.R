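#' Truncate a series (or cohort) at a follow-up cutoff
#'
#' Keeps the tests at times less than or equal to the cutoff; the label is
#' unchanged. Truncation is idempotent and monotone:
#' \code{truncateSeries(truncateSeries(s, a), b)} equals
#' \code{truncateSeries(s, min(a, b))}. A truncated series may hold a
#' single visit, in which case it is flagged unanalysable by
#' [isAnalyzable()].
#'
#' @param x a [VFSeries-class] or [VFCohort-class].
#' @param cutoffYears positive cutoff in years from baseline.
#' @return object of the same class as \code{x}.
#' @rdname truncateSeries
#' @export
setMethod("truncateSeries", "VFSeries", function(x, cutoffYears) {
  if (cutoffYears <= 0) stop("cutoff must be positive", call. = FALSE)
  keep <- x@times <= cutoffYears + 1e-12
  new("VFSeries", eyeId = x@eyeId, times = x@times[keep],
      sens = x@sens[, keep, drop = FALSE], label = x@label)
})

#' @rdname truncateSeries
#' @export
setMethod("truncateSeries", "VFCohort", function(x, cutoffYears) {
  VFCohort(lapply(x@series, truncateSeries, cutoffYears = cutoffYears))
})

.model_min_visits <- function(cols) {
  if (all(cols %in% .stbound_cols)) 2L else 3L
}

#' Early-detection trajectories at half-year cutoffs
#'
#' Re-runs the whole predictor-and-evaluation pipeline on series truncated
#' at each cutoff, against the final-visit clinical labels. AUC and pAUC at
#' a cutoff come from logistic models REFIT on that cutoff's predictors,
#' imitating a reader who evaluates discrimination with the data in hand;
#' sensitivity and specificity apply the FINAL-study coefficients and
#' thresholds to the cutoff predictors, imitating the clinical rule fixed
#' at the end of the study. Eyes below a metric's minimum visit count at a
#' cutoff (3 for trend metrics, 2 for STBound) are excluded from that
#' metric's summary, with the retained count reported. A cutoff at which a
#' class vanishes (or a fit fails) reports missing cells rather than
#' raising.
#'
#' @param cohort labelled [VFCohort-class] (full series).
#' @param grid a [VFGrid-class].
#' @param cutoffs numeric vector of cutoff years, e.g.
#'   \code{seq(0.5, 4.5, by = 0.5)}.
#' @param models named list of predictor column sets (see
#'   [defaultModels()]); combined sets such as GI+STBound can be expressed
#'   directly, e.g. \code{c("gi_slope", ..., "cv_mean", ...)}.
#' @param finalFits named list of \code{DiagnosticModel} objects fitted on
#'   the full study, one per model in \code{models}.
#' @param finalThresholds named numeric vector of full-study probability
#'   thresholds, one per model.
#' @param metrics,nPerm,config,baseSeed forwarded to
#'   [computePredictors()].
#' @param specLo pAUC specificity floor.
#' @return data.frame with one row per cutoff x model: \code{cutoff_years},
#'   \code{model}, \code{n_eyes}, \code{auc}, \code{pauc}, \code{sens},
#'   \code{spec}.
#' @export
evaluateCutoffs <- function(cohort, grid, cutoffs, models, finalFits,
                            finalThresholds,
                            metrics = c("trend", "stbound"),
                            nPerm = 1999L,
                            config = stboundConfig("mini"),
                            baseSeed = 1L, specLo = 0.85) {
  y <- .as01(progressionLabel(cohort))
  rows <- list()
  for (ct in cutoffs) {
    trunc <- truncateSeries(cohort, ct)
    preds <- computePredictors(trunc, grid, metrics = metrics,
                               nPerm = nPerm, config = config,
                               baseSeed = baseSeed)
    for (nm in names(models)) {
      cols <- models[[nm]]
      X <- preds[, cols, drop = FALSE]
      keep <- stats::complete.cases(X)
      nKeep <- sum(keep)
      auc <- paucv <- sens <- spec <- NA_real_
      if (nKeep >= 3L && length(unique(y[keep])) == 2L) {
        refit <- tryCatch(fitLogistic(X[keep, , drop = FALSE], y[keep]),
                          error = function(e) NULL)
        if (!is.null(refit)) {
          auc <- rocCurve(refit$fitted, y[keep])$auc
          paucv <- pauc(refit$fitted, y[keep], specLo)
        }
        fin <- finalFits[[nm]]
        thr <- finalThresholds[[nm]]
        if (!is.null(fin) && !is.null(thr)) {
          pr <- predictProb(fin, preds[keep, , drop = FALSE])
          yk <- y[keep]
          if (any(yk == 1)) sens <- sum(pr >= thr & yk == 1) / sum(yk == 1)
          if (any(yk == 0)) spec <- sum(pr < thr & yk == 0) / sum(yk == 0)
        }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(cutoff_years = ct, model = nm, n_eyes = nKeep,
                   auc = auc, pauc = paucv, sens = sens, spec = spec)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Time to first diagnosis for progressing eyes
#'
#' Walks each progressing eye's visits in order; at every visit with enough
#' history for the model's metrics, recomputes the predictors on the data
#' up to that visit, applies the final-study coefficients, and flags
#' diagnosis the first time the predicted probability reaches the
#' threshold. The flagged visit's day is \code{round(t * 365.25)}; eyes the
#' model never diagnoses carry the last visit's day with
#' \code{detected = FALSE}. Non-progressing eyes are ignored with a
#' message.
#'
#' @param cohort labelled [VFCohort-class].
#' @param grid a [VFGrid-class].
#' @param model a \code{DiagnosticModel} fitted on the completed study.
#' @param threshold full-study probability threshold.
#' @param metrics,nPerm,config,baseSeed forwarded to
#'   [computePredictors()].
#' @return data.frame of class \code{DetectionTimes} with one row per
#'   progressing eye: \code{eye_id}, \code{day}, \code{detected},
#'   \code{prob_at_detection}; mean days in attribute \code{"mean_days"}.
#' @export
timeToFirstDiagnosis <- function(cohort, grid, model, threshold,
                                 metrics = c("trend", "stbound"),
                                 nPerm = 1999L,
                                 config = stboundConfig("mini"),
                                 baseSeed = 1L) {
  labs <- progressionLabel(cohort)
  nOther <- sum(labs != "progressing")
  if (nOther) {
    message("ignoring ", nOther, " non-progressing eyes")
  }
  eyes <- cohort@series[labs == "progressing"]
  minv <- .model_min_visits(model$predictors)
  need <- c("trend"[any(model$predictors %in% .trend_cols)],
            "stbound"[any(model$predictors %in% .stbound_cols)])
  rows <- lapply(eyes, function(s) {
    tms <- visitTimes(s)
    day <- round(max(tms) * 365.25)
    detected <- FALSE
    probAt <- NA_real_
    for (k in seq_along(tms)) {
      if (k < minv) next
      sub <- truncateSeries(s, if (k == length(tms)) max(tms) else tms[k])
      pr <- computePredictors(VFCohort(list(sub)), grid, metrics = need,
                              nPerm = nPerm, config = config,
                              baseSeed = baseSeed)
      p <- predictProb(model, pr)
      if (is.finite(p) && p >= threshold) {
        day <- round(tms[k] * 365.25)
        detected <- TRUE
        probAt <- p
        break
      }
    }
    data.frame(eye_id = eyeId(s), day = day, detected = detected,
               prob_at_detection = probAt)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mean_days") <- mean(out$day)
  class(out) <- c("DetectionTimes", class(out))
  out
}
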