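#' @rdname betaSift-accessors
#' @aliases epochData,EEGEpoch-method
setMethod("epochData", "EEGEpoch", function(x) {
  d <- x@data
  rownames(d) <- x@channelLabels
  d
})

#' @rdname betaSift-accessors
setMethod("channelLabels", "EEGEpoch", function(x) x@channelLabels)

#' @rdname betaSift-accessors
setMethod("channelLabels", "SpatialTemplate", function(x) x@channelLabels)

#' @rdname betaSift-accessors
setMethod("channelLabels", "SubjectERS", function(x) x@channelLabels)

#' @rdname betaSift-accessors
setMethod("samplingRate", "EEGEpoch", function(x) x@fs)

#' @rdname betaSift-accessors
setMethod("t0Offset", "EEGEpoch", function(x) x@t0Offset)

#' @rdname betaSift-accessors
setMethod("nChannels", "EEGEpoch", function(x) nrow(x@data))

#' @rdname betaSift-accessors
setMethod("nSamples", "EEGEpoch", function(x) ncol(x@data))

#' @rdname betaSift-accessors
setMethod("timeAxis", "EEGEpoch", function(x) {
  x@t0Offset + (seq_len(ncol(x@data)) - 1L) / x@fs
})

#' @rdname betaSift-accessors
setMethod("nIMF", "IMFSet", function(x) nrow(x@imfs))

#' @rdname betaSift-accessors
setMethod("imfMatrix", "IMFSet", function(x) x@imfs)

#' @rdname betaSift-accessors
setMethod("imfResidue", "IMFSet", function(x) x@residue)

#' @rdname betaSift-accessors
setMethod("sourceSignal", "IMFSet", function(x) x@sourceSignal)

#' @rdname betaSift-accessors
setMethod("templateWeights", "SpatialTemplate", function(x) {
  w <- x@weights
  names(w) <- x@channelLabels
  w
})

#' @rdname betaSift-accessors
setMethod("ciLabel", "SpatialTemplate", function(x) x@ciLabel)

#' @rdname betaSift-accessors
setMethod("bandLimits", "BandSpec", function(x) c(x@fLo, x@fHi))

#' @rdname betaSift-accessors
setMethod("qcFlag", "TrialResult", function(x) x@qcFlag)

#' @rdname betaSift-accessors
setMethod("brAmplitude", "TrialResult", function(x) x@brAmplitude)

#' @rdname betaSift-accessors
setMethod("brLatency", "TrialResult", function(x) x@brLatency)

#' @rdname betaSift-accessors
setMethod("trialTable", "SessionSummary", function(x) x@trialTable)

setMethod("show", "EEGEpoch", function(object) {
  cat(sprintf(
    "EEGEpoch: %d channels x %d samples, fs = %g Hz, t in [%g, %g) s\n",
    nrow(object@data), ncol(object@data), object@fs, object@t0Offset,
    object@t0Offset + ncol(object@data) / object@fs))
  cat("  channels:", paste(head(object@channelLabels, 8L), collapse = " "),
      if (length(object@channelLabels) > 8L) "...", "\n")
})

setMethod("show", "IMFSet", function(object) {
  cat(sprintf("IMFSet: %d IMFs + residue over %d samples (eps = %g)\n",
              nrow(object@imfs), length(object@sourceSignal),
              object@stoppageEps))
  if (nrow(object@imfs) > 0L)
    cat("  sift iterations:", paste(object@siftIters, collapse = " "), "\n")
})

setMethod("show", "BandSpec", function(object) {
  cat(sprintf("BandSpec: [%g, %g] Hz\n", object@fLo, object@fHi))
})

setMethod("show", "SpatialTemplate", function(object) {
  cat(sprintf("SpatialTemplate: %d channels, CI = %s\n",
              length(object@weights), object@ciLabel))
  w <- round(object@weights, 3)
  names(w) <- object@channelLabels
  print(head(w, 10L))
  if (length(w) > 10L) cat("  ...\n")
})

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment (exact 1-D 3-means):\n  centroids:")
  print(round(object@centroids, 4))
  cat("  labels:", paste(object@labels, collapse = " "), "\n")
  cat(sprintf("  objective: %g\n", object@objective))
})

setMethod("show", "SubjectERS", function(object) {
  cat(sprintf(
    "SubjectERS: %d channels, band [%g, %g] Hz, %d trials averaged\n",
    length(object@br), object@band@fLo, object@band@fHi, object@nTrials))
  i <- which.max(object@br)
  cat(sprintf("  peak BR %.3g uV at %s\n", object@br[i],
              object@channelLabels[i]))
})

setMethod("show", "TrialResult", function(object) {
  cat(sprintf("TrialResult [%s]\n", object@qcFlag))
  if (object@qcFlag == "ok") {
    cat(sprintf("  selected IMFs: {%s} of %d\n",
                paste(object@selectedIMFs, collapse = ", "),
                length(object@correlations)))
    cat(sprintf("  band: [%g, %g] Hz\n", object@band@fLo, object@band@fHi))
    cat(sprintf("  BR = %.3g uV at %s, latency %.3g s\n",
                object@brAmplitude, object@brChannel, object@brLatency))
  }
})

setMethod("show", "SessionSummary", function(object) {
  cat(sprintf("SessionSummary: %d trials, %.0f%% usable\n",
              nrow(object@trialTable), 100 * object@usableFraction))
  cat(sprintf("  single-trial BR: %.3g +/- %.3g uV, latency %.3g +/- %.3g s\n",
              object@brMean, object@brSd, object@latencyMean,
              object@latencySd))
  cat(sprintf("  conventional BR: %.3g uV\n", object@conventionalBr))
  cat(sprintf("  Wilcoxon signed-rank: V = %g, p = %.3g\n",
              object@statistic, object@pValue))
})
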