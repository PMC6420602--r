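#' @rdname VFSeries-accessors
#' @export
setGeneric("eyeId", function(x) standardGeneric("eyeId"))

#' @rdname VFSeries-accessors
#' @export
setGeneric("visitTimes", function(x) standardGeneric("visitTimes"))

#' @rdname VFSeries-accessors
#' @export
setGeneric("sensitivities", function(x) standardGeneric("sensitivities"))

#' @rdname VFSeries-accessors
#' @export
setGeneric("progressionLabel", function(x) standardGeneric("progressionLabel"))

#' @rdname VFSeries-accessors
#' @export
setGeneric("nTests", function(x) standardGeneric("nTests"))

#' @rdname VFSeries-accessors
#' @export
setGeneric("isAnalyzable", function(x) standardGeneric("isAnalyzable"))

#' @rdname VFGrid-accessors
#' @export
setGeneric("retainedIds", function(x) standardGeneric("retainedIds"))

#' @rdname VFGrid-accessors
#' @export
setGeneric("blindSpotIds", function(x) standardGeneric("blindSpotIds"))

#' @rdname VFGrid-accessors
#' @export
setGeneric("ghAngles", function(x) standardGeneric("ghAngles"))

#' @rdname VFGrid-accessors
#' @export
setGeneric("adjacentPairs", function(x) standardGeneric("adjacentPairs"))

#' @rdname pairDissimilarity
#' @export
setGeneric("pairDissimilarity", function(grid) {
  standardGeneric("pairDissimilarity")
})

#' @rdname truncateSeries
#' @export
setGeneric("truncateSeries", function(x, cutoffYears) {
  standardGeneric("truncateSeries")
})

#' @rdname stboundPredictors
#' @export
setGeneric("stboundPredictors", function(fit) {
  standardGeneric("stboundPredictors")
})
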