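# Conventional event-related-synchronization (ERS) pipeline: task-specific
# band over many trials, cross-trial averaged envelopes, per-channel beta
# rebounds, and the cross-subject spatial template.

.checkUniformMontage <- function(trials) {
  labs <- channelLabels(trials[[1]])
  fs <- samplingRate(trials[[1]])
  t0 <- t0Offset(trials[[1]])
  n <- nSamples(trials[[1]])
  for (tr in trials) {
    if (!identical(channelLabels(tr), labs) || samplingRate(tr) != fs ||
        t0Offset(tr) != t0 || nSamples(tr) != n)
      stop("all trials must share montage, sampling rate and epoch geometry",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Task-specific beta band from many trials
#'
#' Averages the reference-window and post-movement-window amplitude spectra
#' at the channel of interest across trials (about 100 event-related trials
#' in typical use), then applies the same supra-threshold rule as
#' [trialBand()] to the averaged spectra. Cross-trial averaging suppresses
#' the noise in each 1-s spectrum, so the task band is the stable,
#' subject-level counterpart of the trial-specific band.
#'
#' @param trials list of [EEGEpoch-class] objects (>= 2, same montage).
#' @param ciLabel channel-of-interest label.
#' @param post,ref analysis windows, seconds (half-open).
#' @inheritParams trialBand
#' @return A [BandSpec-class].
#' @export
taskBand <- function(trials, ciLabel = "C3", post = c(0.5, 1.5),
                     ref = c(-3.5, -2.5), search = c(13, 30),
                     rule = c("two_sd", "zscore"), minBandHz = 2,
                     sdScope = c("search", "full"),
                     scaleEstimator = c("mad", "sd")) {
  rule <- match.arg(rule)
  sdScope <- match.arg(sdScope)
  scaleEstimator <- match.arg(scaleEstimator)
  if (length(trials) < 2L)
    stop("need at least 2 trials to determine a task band", call. = FALSE)
  .checkUniformMontage(trials)
  fs <- samplingRate(trials[[1]])
  refAmp <- postAmp <- NULL
  for (tr in trials) {
    sr <- amplitudeSpectrum(windowSlice(tr, ref, ciLabel)[1, ], fs)
    sp <- amplitudeSpectrum(windowSlice(tr, post, ciLabel)[1, ], fs)
    refAmp <- if (is.null(refAmp)) sr$amplitude else refAmp + sr$amplitude
    postAmp <- if (is.null(postAmp)) sp$amplitude else postAmp + sp$amplitude
    freqs <- sr$freqs
  }
  refAmp <- refAmp / length(trials)
  postAmp <- postAmp / length(trials)
  d <- postAmp - refAmp
  inSearch <- freqs >= search[1] & freqs <= search[2]
  v <- d[if (sdScope == "search") inSearch else TRUE]
  s <- if (scaleEstimator == "mad") 1.4826 * mad(v, constant = 1) else sd(v)
  thr <- if (rule == "two_sd") 2 * s else 3.09 * s
  ds <- list(freqs = freqs, diff = d, threshold = thr,
             passBins = inSearch & d > thr)
  band <- .bandFromMask(ds, search, minBandHz)
  if (is.null(band))
    stop("no supra-threshold bins: no task-specific band; template cannot be built",
         call. = FALSE)
  band
}

#' Conventional ERS for one subject
#'
#' Band-pass filters every channel of every trial within the task-specific
#' beta band, rectifies with the AM method ([amEnvelope()]), averages the
#' envelopes across trials, and computes the per-channel beta rebound: the
#' maximum of the averaged envelope in the post-movement window minus its
#' mean over the reference window, each channel using its own extrema
#' within the common time bounds.
#'
#' @param trials nonempty list of [EEGEpoch-class] objects (same montage).
#' @param band the task-specific [BandSpec-class].
#' @param post,ref analysis windows, seconds (half-open).
#' @param filterOrder band-pass filter order, see [bandpassFilter()].
#' @return A [SubjectERS-class].
#' @export
conventionalERS <- function(trials, band, post = c(0.5, 1.5),
                            ref = c(-3.5, -2.5), filterOrder = 4L) {
  if (length(trials) < 1L) stop("need at least one trial", call. = FALSE)
  stopifnot(is(band, "BandSpec"))
  .checkUniformMontage(trials)
  fs <- samplingRate(trials[[1]])
  t0 <- t0Offset(trials[[1]])
  labs <- channelLabels(trials[[1]])
  acc <- matrix(0, nChannels(trials[[1]]), nSamples(trials[[1]]))
  for (tr in trials) {
    filt <- t(vapply(seq_len(nrow(tr@data)), function(i)
      bandpassFilter(tr@data[i, ], fs, band, filterOrder),
      numeric(ncol(tr@data))))
    acc <- acc + .amEnvelopeRows(filt)
  }
  acc <- acc / length(trials)
  idxPost <- .windowIndices(ncol(acc), fs, t0, post)
  idxRef <- .windowIndices(ncol(acc), fs, t0, ref)
  br <- apply(acc[, idxPost, drop = FALSE], 1L, max) -
    rowMeans(acc[, idxRef, drop = FALSE])
  new("SubjectERS", avgEnvelope = acc, band = band, br = as.numeric(br),
      channelLabels = labs, fs = fs, t0Offset = t0,
      nTrials = length(trials))
}

#' Build the spatial template from per-subject conventional ERS
#'
#' Element-wise mean of the per-subject beta-rebound vectors (e.g. 4
#' subjects of about 100 trials each). The template is stored unnormalized
#' in microvolts; Pearson matching downstream makes the scale irrelevant.
#' Fewer than 20 trials per subject triggers a warning, not an error.
#'
#' @param subjectErs nonempty list of [SubjectERS-class] objects with
#'   matching montages.
#' @param ciLabel channel-of-interest label recorded in the template.
#' @return A [SpatialTemplate-class].
#' @export
buildTemplate <- function(subjectErs, ciLabel = "C3") {
  if (length(subjectErs) < 1L)
    stop("need at least one subject", call. = FALSE)
  labs <- channelLabels(subjectErs[[1]])
  for (s in subjectErs) {
    stopifnot(is(s, "SubjectERS"))
    if (!identical(channelLabels(s), labs))
      stop("subjects have mismatching montages (labels must match in order)",
           call. = FALSE)
    if (s@nTrials < 20L)
      warning(sprintf("subject averaged over only %d trials; template may be unstable",
                      s@nTrials))
  }
  w <- rowMeans(vapply(subjectErs, function(s) s@br, numeric(length(labs))))
  spatialTemplate(w, labs, ciLabel)
}

#' Write a spatial template to a delimited text file
#'
#' Format: a metadata comment line naming the CI channel, a header row,
#' then one `channel<TAB>weight` pair per line.
#'
#' @param template a [SpatialTemplate-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTemplate <- function(template, path) {
  stopifnot(is(template, "SpatialTemplate"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# ci_label\t%s", template@ciLabel), con)
  writeLines("channel\tweight", con)
  writeLines(sprintf("%s\t%.17g", template@channelLabels,
                     template@weights), con)
  invisible(path)
}

#' Read a spatial template written by [writeTemplate()]
#'
#' @param path file path.
#' @return A [SpatialTemplate-class].
#' @export
readTemplate <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1], "# ci_label"))
    stop("malformed template file: missing '# ci_label' metadata line",
         call. = FALSE)
  ci <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][2]
  tab <- read.table(text = lines[-1], header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("channel", "weight") %in% names(tab)))
    stop("malformed template file: need 'channel' and 'weight' columns",
         call. = FALSE)
  spatialTemplate(tab$weight, tab$channel, ci)
}
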