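#' @rdname DTIData-accessors
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @rdname DTIData-accessors
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))

#' @rdname DTIData-accessors
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @rdname DTIData-accessors
#' @export
setGeneric("drugSim", function(x) standardGeneric("drugSim"))

#' @rdname DTIData-accessors
#' @export
setGeneric("targetSim", function(x) standardGeneric("targetSim"))

#' @rdname DTIData-accessors
#' @export
setGeneric("drugSim<-", function(x, value) standardGeneric("drugSim<-"))

#' @rdname DTIData-accessors
#' @export
setGeneric("targetSim<-", function(x, value) standardGeneric("targetSim<-"))

#' @rdname DTIData-accessors
#' @export
setGeneric("observedPairs", function(x) standardGeneric("observedPairs"))

#' @rdname datasetStats
#' @export
setGeneric("datasetStats", function(x, ...) standardGeneric("datasetStats"))

#' @rdname fitLapMC
#' @export
setGeneric("fitLapMC", function(x, ...) standardGeneric("fitLapMC"))

#' @rdname ALMFit-accessors
#' @export
setGeneric("predictedScores", function(x) standardGeneric("predictedScores"))

#' @rdname ALMFit-accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
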