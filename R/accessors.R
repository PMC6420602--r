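#' Accessors for visual-field series and cohorts
#'
#' @param x a [VFSeries-class] or [VFCohort-class] object.
#' @return \code{eyeId} the eye identifier; \code{visitTimes} the visit times
#'   in years; \code{sensitivities} the 52 x T dB matrix;
#'   \code{progressionLabel} the clinical label; \code{nTests} the number of
#'   visits; \code{isAnalyzable} whether the series has the two visits every
#'   metric minimally needs.
#' @name VFSeries-accessors
NULL

#' @rdname VFSeries-accessors
setMethod("eyeId", "VFSeries", function(x) x@eyeId)

#' @rdname VFSeries-accessors
setMethod("visitTimes", "VFSeries", function(x) x@times)

#' @rdname VFSeries-accessors
setMethod("sensitivities", "VFSeries", function(x) x@sens)

#' @rdname VFSeries-accessors
setMethod("progressionLabel", "VFSeries", function(x) {
  as.character(x@label)
})

#' @rdname VFSeries-accessors
setMethod("nTests", "VFSeries", function(x) length(x@times))

#' @rdname VFSeries-accessors
setMethod("isAnalyzable", "VFSeries", function(x) length(x@times) >= 2L)

#' @rdname VFSeries-accessors
setMethod("eyeId", "VFCohort", function(x) {
  vapply(x@series, function(s) s@eyeId, character(1))
})

#' @rdname VFSeries-accessors
setMethod("progressionLabel", "VFCohort", function(x) {
  vapply(x@series, function(s) as.character(s@label), character(1))
})

#' @describeIn VFCohort-utils number of eyes.
#' @export
setMethod("length", "VFCohort", function(x) length(x@series))

#' Cohort utilities
#'
#' @param x a [VFCohort-class].
#' @param i index or eye id.
#' @name VFCohort-utils
#' @aliases [[,VFCohort-method
#' @export
setMethod("[[", "VFCohort", function(x, i) {
  if (is.character(i)) {
    hit <- match(i, eyeId(x))
    if (is.na(hit)) stop("no eye with id '", i, "'", call. = FALSE)
    i <- hit
  }
  x@series[[i]]
})

#' Accessors for the 24-2 grid
#'
#' @param x a [VFGrid-class] object.
#' @return \code{retainedIds} the 52 modelled location ids;
#'   \code{blindSpotIds} the 2 excluded ids; \code{ghAngles} the optic-disc
#'   entry angle (degrees) named by retained location id;
#'   \code{adjacentPairs} the two-column matrix of adjacent retained ids.
#' @name VFGrid-accessors
NULL

#' @rdname VFGrid-accessors
setMethod("retainedIds", "VFGrid", function(x) {
  x@locations$location_id[!x@locations$is_blind_spot]
})

#' @rdname VFGrid-accessors
setMethod("blindSpotIds", "VFGrid", function(x) {
  x@locations$location_id[x@locations$is_blind_spot]
})

#' @rdname VFGrid-accessors
setMethod("ghAngles", "VFGrid", function(x) {
  keep <- !x@locations$is_blind_spot
  stats::setNames(x@locations$gh_angle[keep], x@locations$location_id[keep])
})

#' @rdname VFGrid-accessors
setMethod("adjacentPairs", "VFGrid", function(x) x@pairs)

setMethod("show", "VFGrid", function(object) {
  cat("VFGrid (24-2):", nrow(object@locations), "locations,",
      sum(object@locations$is_blind_spot), "blind spot,",
      nrow(object@pairs), sprintf("adjacent pairs (%s rule)\n", object@rule))
})

setMethod("show", "VFSeries", function(object) {
  cat(sprintf("VFSeries '%s': %d tests over %.2f years, label = %s\n",
              object@eyeId, length(object@times), max(object@times),
              as.character(object@label)))
})

setMethod("show", "VFCohort", function(object) {
  labs <- progressionLabel(object)
  cat(sprintf(
    "VFCohort: %d eyes (%d stable, %d progressing, %d unknown)\n",
    length(object@series), sum(labs == "stable"),
    sum(labs == "progressing"), sum(labs == "unknown")))
})

setMethod("show", "STBoundFit", function(object) {
  p <- stboundPredictors(object)
  cat(sprintf(
    "STBoundFit '%s': %d kept draws, %d visits; cv_mean = %.4f, cv_sd = %.4f\n",
    object@eyeId, length(object@cv), length(object@times),
    p[["cv_mean"]], p[["cv_sd"]]))
})

#' Construct a visual-field series
#'
#' @param eyeId eye identifier.
#' @param times visit times in years from baseline, strictly increasing,
#'   starting at 0.
#' @param sens 52 x T matrix of dB sensitivities (rows in retained-location
#'   order), or a T x 52 matrix which is transposed.
#' @param label \code{"stable"}, \code{"progressing"} or \code{"unknown"}.
#' @return a [VFSeries-class].
#' @export
VFSeries <- function(eyeId, times, sens, label = "unknown") {
  sens <- as.matrix(sens)
  if (nrow(sens) != 52L && ncol(sens) == 52L) sens <- t(sens)
  if (is.null(rownames(sens))) {
    lay <- .grid242_layout()
    rownames(sens) <- lay$location_id[!lay$is_blind_spot]
  }
  new("VFSeries", eyeId = as.character(eyeId), times = as.numeric(times),
      sens = sens, label = factor(label, levels = .label_levels))
}

#' Construct a cohort from a list of series
#'
#' @param series list of [VFSeries-class] objects.
#' @return a [VFCohort-class].
#' @export
VFCohort <- function(series) new("VFCohort", series = series)
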