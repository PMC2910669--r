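#' @name betaSift-accessors
#' @title Accessors for betaSift classes
#' @description Accessor generics for [EEGEpoch-class], [IMFSet-class],
#'   [SpatialTemplate-class], [TrialResult-class] and [SessionSummary-class]
#'   objects. Use these rather than reaching into slots.
#' @param x an object.
#' @return The corresponding slot value (see the individual methods).
NULL

#' @rdname betaSift-accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname betaSift-accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname betaSift-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname betaSift-accessors
#' @export
setGeneric("t0Offset", function(x) standardGeneric("t0Offset"))

#' @rdname betaSift-accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname betaSift-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname betaSift-accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' @rdname betaSift-accessors
#' @export
setGeneric("nIMF", function(x) standardGeneric("nIMF"))

#' @rdname betaSift-accessors
#' @export
setGeneric("imfMatrix", function(x) standardGeneric("imfMatrix"))

#' @rdname betaSift-accessors
#' @export
setGeneric("imfResidue", function(x) standardGeneric("imfResidue"))

#' @rdname betaSift-accessors
#' @export
setGeneric("sourceSignal", function(x) standardGeneric("sourceSignal"))

#' @rdname betaSift-accessors
#' @export
setGeneric("templateWeights", function(x) standardGeneric("templateWeights"))

#' @rdname betaSift-accessors
#' @export
setGeneric("ciLabel", function(x) standardGeneric("ciLabel"))

#' @rdname betaSift-accessors
#' @export
setGeneric("bandLimits", function(x) standardGeneric("bandLimits"))

#' @rdname betaSift-accessors
#' @export
setGeneric("qcFlag", function(x) standardGeneric("qcFlag"))

#' @rdname betaSift-accessors
#' @export
setGeneric("brAmplitude", function(x) standardGeneric("brAmplitude"))

#' @rdname betaSift-accessors
#' @export
setGeneric("brLatency", function(x) standardGeneric("brLatency"))

#' @rdname betaSift-accessors
#' @export
setGeneric("trialTable", function(x) standardGeneric("trialTable"))
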