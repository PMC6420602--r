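#' @import methods
NULL

#' The 24-2 visual-field test lattice
#'
#' An S4 container for the Humphrey 24-2 test-point grid: point coordinates
#' in degrees of visual angle, blind-spot exclusions, optic-disc entry angles
#' for the retained points, an adjacency graph over the retained points and
#' the anatomical dissimilarity \eqn{z_{ij}} attached to each adjacent pair.
#'
#' @slot locations data.frame with one row per grid point (54 rows) and
#'   columns \code{location_id}, \code{x}, \code{y}, \code{is_blind_spot},
#'   \code{gh_angle} (degrees in \eqn{[0, 360)}; \code{NA} at blind spots).
#' @slot pairs two-column integer matrix of adjacent retained location ids,
#'   each unordered pair stored once with \code{pairs[, 1] < pairs[, 2]}.
#' @slot z numeric vector of dissimilarities in \eqn{[0, 1]}, one per row of
#'   \code{pairs}, normalised so the grid maximum is exactly 1.
#' @slot rule adjacency rule used, \code{"queen"} or \code{"rook"}.
#' @seealso [buildGrid()], [pairDissimilarity()]
#' @export
setClass("VFGrid",
  representation(
    locations = "data.frame",
    pairs = "matrix",
    z = "numeric",
    rule = "character"
  )
)

setValidity("VFGrid", function(object) {
  loc <- object@locations
  msg <- character()
  if (nrow(loc) != 54L) msg <- c(msg, "grid must have exactly 54 locations")
  if (sum(loc$is_blind_spot) != 2L) {
    msg <- c(msg, "exactly 2 locations must be flagged as blind spot")
  }
  retained <- loc$location_id[!loc$is_blind_spot]
  if (!all(object@pairs %in% retained)) {
    msg <- c(msg, "adjacency pairs must reference retained locations only")
  }
  if (any(object@pairs[, 1] >= object@pairs[, 2])) {
    msg <- c(msg, "pairs must be stored with first id < second id")
  }
  if (length(object@z) != nrow(object@pairs)) {
    msg <- c(msg, "one dissimilarity per adjacent pair required")
  }
  if (length(object@z) && (any(object@z < 0) || any(object@z > 1))) {
    msg <- c(msg, "dissimilarities must lie in [0, 1]")
  }
  if (length(object@z) && abs(max(object@z) - 1) > 1e-12) {
    msg <- c(msg, "dissimilarities must be normalised to max 1")
  }
  if (length(msg)) msg else TRUE
})

#' One eye's longitudinal visual-field series
#'
#' Ordered perimetry tests for a single eye: visit times in years from
#' baseline and the differential light sensitivities (dB) at the 52 retained
#' 24-2 locations, plus an optional clinical progression label.
#'
#' A series with a single visit is a valid object (it arises naturally when
#' truncating at an early cutoff) but is flagged unanalysable by
#' [isAnalyzable()]; every progression metric requires at least two visits.
#'
#' @slot eyeId character scalar identifier.
#' @slot times numeric vector of visit times (years), strictly increasing,
#'   first visit at 0.
#' @slot sens numeric matrix, 52 retained locations x visits, dB in
#'   \eqn{[0, 50]}; rownames are the retained location ids.
#' @slot label factor with levels \code{stable}, \code{progressing},
#'   \code{unknown}.
#' @export
setClass("VFSeries",
  representation(
    eyeId = "character",
    times = "numeric",
    sens = "matrix",
    label = "factor"
  )
)

.label_levels <- c("stable", "progressing", "unknown")

setValidity("VFSeries", function(object) {
  msg <- character()
  if (length(object@eyeId) != 1L) msg <- c(msg, "eyeId must be a scalar")
  nT <- length(object@times)
  if (nT < 1L) msg <- c(msg, "at least one test required")
  if (nT >= 1L && abs(object@times[1L]) > 1e-12) {
    msg <- c(msg, "first visit time must be 0")
  }
  if (nT > 1L && any(diff(object@times) <= 0)) {
    msg <- c(msg, "visit times must be strictly increasing")
  }
  if (ncol(object@sens) != nT) {
    msg <- c(msg, "one sensitivity column per visit required")
  }
  if (nrow(object@sens) != 52L) {
    msg <- c(msg, "sensitivity vectors must cover the 52 retained locations")
  }
  if (anyNA(object@sens)) msg <- c(msg, "missing sensitivities not allowed")
  else if (any(object@sens < 0) || any(object@sens > 50)) {
    msg <- c(msg, "sensitivities must lie in [0, 50] dB")
  }
  if (!identical(levels(object@label), .label_levels)) {
    msg <- c(msg, "label levels must be stable/progressing/unknown")
  }
  if (length(msg)) msg else TRUE
})

#' A cohort of visual-field series
#'
#' @slot series list of [VFSeries-class] objects with unique eye ids.
#' @export
setClass("VFCohort", representation(series = "list"))

setValidity("VFCohort", function(object) {
  msg <- character()
  ok <- vapply(object@series, is, logical(1), class2 = "VFSeries")
  if (!all(ok)) msg <- c(msg, "all elements must be VFSeries objects")
  ids <- vapply(object@series, function(s) s@eyeId, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "eye ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Posterior samples from the spatiotemporal boundary-detection model
#'
#' Kept MCMC draws of the per-visit level \eqn{\mu_t} (dB), spatial variance
#' \eqn{\tau^2_t} (dB\eqn{^2}) and spatial-smoothness parameter
#' \eqn{\alpha_t} (unitless, positive), the temporal decay \eqn{\phi}, the
#' cross-parameter level \eqn{\delta} and covariance \eqn{\Sigma}, and the
#' per-draw coefficient of variation of \eqn{\{\alpha_t\}_t} that carries the
#' STBound predictor.
#'
#' @slot eyeId character scalar.
#' @slot times visit times the model was fitted to.
#' @slot mu,tau2,alpha numeric matrices, kept draws x visits.
#' @slot phi numeric vector of kept draws.
#' @slot delta numeric matrix, kept draws x 3.
#' @slot cv numeric vector: per-draw CV of \eqn{\alpha_t} across visits
#'   (sample sd with \eqn{T-1} denominator over the per-draw mean).
#' @slot acceptance named numeric vector of Metropolis acceptance rates.
#' @slot config list of sampler settings used.
#' @seealso [fitSTBound()], [stboundPredictors()]
#' @export
setClass("STBoundFit",
  representation(
    eyeId = "character",
    times = "numeric",
    mu = "matrix",
    tau2 = "matrix",
    alpha = "matrix",
    phi = "numeric",
    delta = "matrix",
    cv = "numeric",
    acceptance = "numeric",
    config = "list"
  )
)

setValidity("STBoundFit", function(object) {
  msg <- character()
  if (any(object@alpha <= 0)) msg <- c(msg, "alpha draws must be positive")
  if (any(object@tau2 <= 0)) msg <- c(msg, "tau2 draws must be positive")
  if (any(object@cv < 0)) msg <- c(msg, "per-draw CV must be non-negative")
  dims <- c(nrow(object@mu), nrow(object@tau2), nrow(object@alpha))
  if (length(unique(dims)) != 1L || dims[1L] != length(object@cv)) {
    msg <- c(msg, "draw dimensions must agree across parameters")
  }
  if (length(msg)) msg else TRUE
})
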