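#' EEGEpoch: one event-locked multichannel EEG epoch
#'
#' Container for a single epoch of M channels by N samples (microvolts),
#' with channel labels, sampling rate and the time (in seconds, relative to
#' the event) of the first sample. Sample index `k` (1-based) maps to time
#' `t0Offset + (k - 1) / fs`; analysis windows are half-open `[start, end)`.
#'
#' @slot data numeric matrix, M channels x N samples, microvolts.
#' @slot channelLabels character vector of length M (10-20 names, e.g. "C3").
#' @slot fs sampling rate in Hz.
#' @slot t0Offset time in seconds of sample 1 relative to the event
#'   (negative = pre-event).
#'
#' @seealso [EEGEpoch()], [windowSlice()], [readEpoch()]
#' @exportClass EEGEpoch
setClass("EEGEpoch",
  slots = c(
    data = "matrix",
    channelLabels = "character",
    fs = "numeric",
    t0Offset = "numeric"
  )
)

setValidity("EEGEpoch", function(object) {
  msg <- character(0)
  d <- object@data
  if (!is.numeric(d)) msg <- c(msg, "data must be a numeric matrix")
  if (nrow(d) < 2L) msg <- c(msg, "need at least 2 channels (M >= 2)")
  if (ncol(d) < 2L) msg <- c(msg, "need at least 2 samples (N >= 2)")
  if (length(object@channelLabels) != nrow(d))
    msg <- c(msg, "exactly one channel label per data row is required")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@t0Offset) != 1L || !is.finite(object@t0Offset))
    msg <- c(msg, "t0Offset must be a single finite number")
  if (is.numeric(d) && anyNA(d)) msg <- c(msg, "all samples must be finite")
  if (is.numeric(d) && !anyNA(d) && !all(is.finite(d)))
    msg <- c(msg, "all samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGEpoch
#'
#' @param data numeric matrix, channels in rows, samples in columns
#'   (microvolts).
#' @param channelLabels character vector naming the rows.
#' @param fs sampling rate, Hz.
#' @param t0Offset time of the first sample relative to the event, seconds.
#' @return A validated [EEGEpoch-class] object.
#' @examples
#' ep <- EEGEpoch(matrix(rnorm(8), 2, 4), c("C3", "C4"), fs = 4, t0Offset = 0)
#' nSamples(ep)
#' @export
EEGEpoch <- function(data, channelLabels, fs, t0Offset = 0) {
  dimnames(data) <- NULL
  new("EEGEpoch", data = data, channelLabels = as.character(channelLabels),
      fs = as.numeric(fs), t0Offset = as.numeric(t0Offset))
}

#' IMFSet: empirical mode decomposition of one signal
#'
#' Ordered intrinsic mode functions `c_1..c_J` (rows of `imfs`, highest
#' characteristic frequency first) plus the monotonic residue `r(t)` for a
#' decomposed source signal `x(t)`. Completeness (`colSums(imfs) + residue
#' == source` to relative L2 error 1e-8) is enforced by the validity check.
#'
#' @slot imfs numeric matrix, J x N (possibly zero rows).
#' @slot residue numeric vector of length N.
#' @slot sourceSignal the decomposed vector.
#' @slot stoppageEps sifting stoppage criterion used.
#' @slot siftIters integer vector, sifting iterations per IMF.
#' @slot capped logical vector, TRUE where the sifting iteration cap was hit.
#'
#' @seealso [emdDecompose()]
#' @exportClass IMFSet
setClass("IMFSet",
  slots = c(
    imfs = "matrix",
    residue = "numeric",
    sourceSignal = "numeric",
    stoppageEps = "numeric",
    siftIters = "integer",
    capped = "logical"
  )
)

setValidity("IMFSet", function(object) {
  msg <- character(0)
  n <- length(object@sourceSignal)
  if (length(object@residue) != n)
    msg <- c(msg, "residue must have the length of the source signal")
  if (nrow(object@imfs) > 0L && ncol(object@imfs) != n)
    msg <- c(msg, "every IMF must have the length of the source signal")
  if (length(object@siftIters) != nrow(object@imfs))
    msg <- c(msg, "one sift-iteration count per IMF is required")
  if (length(object@stoppageEps) != 1L || object@stoppageEps <= 0)
    msg <- c(msg, "stoppageEps must be a single positive number")
  if (!length(msg)) {
    recon <- object@residue
    if (nrow(object@imfs) > 0L) recon <- recon + colSums(object@imfs)
    num <- sqrt(sum((recon - object@sourceSignal)^2))
    den <- sqrt(sum(object@sourceSignal^2))
    if (num > 1e-8 * max(den, .Machine$double.eps))
      msg <- c(msg, "IMFs + residue do not reproduce the source (rel. L2 > 1e-8)")
  }
  if (length(msg)) msg else TRUE
})

#' BandSpec: a contiguous frequency interval
#'
#' @slot fLo,fHi band edges in Hz, `0 < fLo < fHi`.
#' @seealso [bandSpec()], [trialBand()]
#' @exportClass BandSpec
setClass("BandSpec", slots = c(fLo = "numeric", fHi = "numeric"))

setValidity("BandSpec", function(object) {
  if (length(object@fLo) != 1L || length(object@fHi) != 1L ||
      !is.finite(object@fLo) || !is.finite(object@fHi))
    return("band edges must be single finite numbers")
  if (object@fLo <= 0 || object@fLo >= object@fHi)
    return("band edges must satisfy 0 < fLo < fHi")
  TRUE
})

#' Construct a BandSpec
#'
#' @param fLo,fHi band edges in Hz.
#' @return A [BandSpec-class] object.
#' @examples
#' bandSpec(15, 20)
#' @export
bandSpec <- function(fLo, fHi) {
  new("BandSpec", fLo = as.numeric(fLo), fHi = as.numeric(fHi))
}

#' SpatialTemplate: per-channel weights for IMF selection
#'
#' One weight per channel (conventional-ERS beta rebounds, microvolts, or
#' any non-constant pattern) plus the montage labels and the channel of
#' interest. Matching against IMF spatial maps uses Pearson correlation, so
#' the template scale is irrelevant and it is stored unnormalized.
#'
#' @slot weights numeric vector, one weight per channel.
#' @slot channelLabels character vector matching the montage.
#' @slot ciLabel the channel of interest (e.g. "C3").
#' @seealso [buildTemplate()], [templateCorrelation()]
#' @exportClass SpatialTemplate
setClass("SpatialTemplate",
  slots = c(weights = "numeric", channelLabels = "character",
            ciLabel = "character")
)

setValidity("SpatialTemplate", function(object) {
  msg <- character(0)
  if (length(object@weights) != length(object@channelLabels))
    msg <- c(msg, "one weight per channel label is required")
  if (!all(is.finite(object@weights)))
    msg <- c(msg, "weights must be finite")
  if (length(object@weights) >= 2L && var(object@weights) <= 0)
    msg <- c(msg, "template must not be constant (correlation undefined)")
  if (length(object@ciLabel) != 1L ||
      !(object@ciLabel %in% object@channelLabels))
    msg <- c(msg, "ciLabel must name one of the template channels")
  if (length(msg)) msg else TRUE
})

#' Construct a SpatialTemplate
#'
#' @param weights numeric vector of per-channel weights.
#' @param channelLabels character vector, same length as `weights`.
#' @param ciLabel channel of interest label.
#' @return A [SpatialTemplate-class] object.
#' @export
spatialTemplate <- function(weights, channelLabels, ciLabel = "C3") {
  new("SpatialTemplate", weights = as.numeric(weights),
      channelLabels = as.character(channelLabels),
      ciLabel = as.character(ciLabel))
}

#' ClusterAssignment: exact 1-D 3-means partition of template correlations
#'
#' @slot labels character vector ("high", "middle", "low") per value, in the
#'   input order.
#' @slot centroids named numeric vector of the three cluster means, in
#'   decreasing order (high, middle, low).
#' @slot objective final within-cluster sum of squared deviations.
#' @seealso [clusterCorrelations()]
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
  slots = c(labels = "character", centroids = "numeric",
            objective = "numeric")
)

setValidity("ClusterAssignment", function(object) {
  msg <- character(0)
  if (length(object@centroids) != 3L)
    msg <- c(msg, "exactly three centroids are required")
  if (!identical(names(object@centroids), c("high", "middle", "low")))
    msg <- c(msg, "centroids must be named high, middle, low")
  if (length(object@centroids) == 3L && any(diff(object@centroids) > 0))
    msg <- c(msg, "centroids must be in non-increasing order (high to low)")
  if (!all(object@labels %in% c("high", "middle", "low")))
    msg <- c(msg, "labels must be high/middle/low")
  if (length(msg)) msg else TRUE
})

#' SubjectERS: conventional event-related synchronization for one subject
#'
#' Cross-trial averaged band-limited amplitude envelopes per channel, the
#' task-specific beta band used, and the per-channel beta rebound (max of
#' the averaged envelope in the post-movement window minus its mean in the
#' reference window).
#'
#' @slot avgEnvelope numeric matrix, M channels x N samples (microvolts).
#' @slot band the task-specific [BandSpec-class].
#' @slot br numeric vector of per-channel beta rebounds, microvolts.
#' @slot channelLabels montage labels.
#' @slot fs sampling rate, Hz.
#' @slot t0Offset epoch start relative to the event, seconds.
#' @slot nTrials number of trials averaged.
#' @seealso [conventionalERS()], [buildTemplate()]
#' @exportClass SubjectERS
setClass("SubjectERS",
  slots = c(avgEnvelope = "matrix", band = "BandSpec", br = "numeric",
            channelLabels = "character", fs = "numeric",
            t0Offset = "numeric", nTrials = "integer")
)

setValidity("SubjectERS", function(object) {
  msg <- character(0)
  if (length(object@br) != length(object@channelLabels))
    msg <- c(msg, "one BR value per channel is required")
  if (object@nTrials < 1L) msg <- c(msg, "nTrials must be >= 1")
  if (length(msg)) msg else TRUE
})

#' TrialResult: the single-trial extraction outcome
#'
#' Selected IMF indices, all template correlations, the trial-specific band,
#' the reconstructed signal(s), the amplitude envelope at the reported
#' channel, the beta rebound and its latency, and a QC flag. `qcFlag` is one
#' of `"ok"`, `"artifact"`, `"no-band"`, `"degenerate-selection"`; on any
#' flag other than `"ok"` the numeric results are `NA`.
#'
#' @slot selectedIMFs integer indices of the sensorimotor-related IMFs.
#' @slot correlations template correlations rho_1..rho_J.
#' @slot band [BandSpec-class] or `NULL`.
#' @slot reconstructed reconstructed signal: numeric vector (CI mode) or
#'   M x N matrix (multichannel mode), or `NULL`.
#' @slot envelope amplitude envelope m(t) at the reported channel, or `NULL`.
#' @slot brAmplitude beta rebound, microvolts (may be negative).
#' @slot brLatency envelope peak time, seconds relative to the event.
#' @slot brChannel label of the channel with maximum beta-band reactivity.
#' @slot qcFlag quality-control flag.
#' @slot diagnostics list of per-trial decisions (cluster assignment,
#'   thresholds, edge-unreliable span, ...).
#' @seealso [extractSingleTrial()]
#' @exportClass TrialResult
setClass("TrialResult",
  slots = c(selectedIMFs = "integer", correlations = "numeric",
            band = "ANY", reconstructed = "ANY", envelope = "ANY",
            brAmplitude = "numeric", brLatency = "numeric",
            brChannel = "character", qcFlag = "character",
            diagnostics = "list")
)

setValidity("TrialResult", function(object) {
  ok <- c("ok", "artifact", "no-band", "degenerate-selection")
  if (length(object@qcFlag) != 1L || !(object@qcFlag %in% ok))
    return(sprintf("qcFlag must be one of %s", paste(ok, collapse = ", ")))
  TRUE
})

#' SessionSummary: per-session results and the paired comparison
#'
#' Per-trial results table, QC accounting, summary statistics of the
#' single-trial beta rebounds, the conventional averaged-ERS beta rebound on
#' the same trials, and the one-sample Wilcoxon signed-rank test of the
#' single-trial BRs against the conventional value.
#'
#' @slot trialTable data.frame with one row per trial (id, QC flag, selected
#'   IMFs, band edges, BR, latency, channel).
#' @slot usableFraction fraction of trials with QC flag "ok".
#' @slot brMean,brSd,latencyMean,latencySd summary statistics over usable
#'   trials (microvolts / seconds).
#' @slot conventionalBr conventional averaged-ERS beta rebound, microvolts.
#' @slot conventionalLatency latency of the conventional envelope peak, s.
#' @slot taskBand the task-specific [BandSpec-class] of the conventional
#'   pipeline.
#' @slot statistic,pValue Wilcoxon signed-rank statistic V and p-value.
#' @slot qcCounts named integer vector of QC flag counts.
#' @slot envelopes list of per-trial AM envelopes of the usable trials
#'   (populated when requested; see [runSession()]).
#' @seealso [runSession()]
#' @exportClass SessionSummary
setClass("SessionSummary",
  slots = c(trialTable = "data.frame", usableFraction = "numeric",
            brMean = "numeric", brSd = "numeric", latencyMean = "numeric",
            latencySd = "numeric", conventionalBr = "numeric",
            conventionalLatency = "numeric", taskBand = "ANY",
            statistic = "numeric", pValue = "numeric",
            qcCounts = "integer", envelopes = "list")
)

setValidity("SessionSummary", function(object) {
  if (object@usableFraction < 0 || object@usableFraction > 1)
    return("usableFraction must lie in [0, 1]")
  TRUE
})
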