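# Amplitude-modulation (AM) envelopes via the Hilbert transform and
# quantification of the single-trial post-movement beta rebound.

# Analytic signal by the frequency-domain method: zero the negative
# frequencies, double the positive ones.
.analyticSignal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n %/% 2L + 1L)] <- 1
    h[2L:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) %/% 2L)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# batched AM envelopes of matrix rows via a single matrix FFT pair
.amEnvelopeRows <- function(m) {
  n <- ncol(m)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n %/% 2L + 1L)] <- 1
    h[2L:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) %/% 2L)] <- 2
  }
  Fm <- mvfft(t(m))
  t(Mod(mvfft(Fm * h, inverse = TRUE) / n))
}

#' AM envelope of a band-limited signal
#'
#' `m(t) = sqrt(M_BP(t)^2 + H(M_BP(t))^2)`, the magnitude of the analytic
#' signal, with `H` the Hilbert transform. The envelope is non-negative and
#' dominates `|M_BP(t)|` at every sample. Compute it over the full epoch
#' rather than an analysis window so edge transients stay outside the
#' windows of interest; the outer 0.25 s are edge-unreliable.
#'
#' @param mBp numeric vector (band-pass filtered signal, microvolts).
#' @return numeric envelope vector, same length.
#' @examples
#' max(abs(amEnvelope(3 * sin(2 * pi * 20 * seq(0, 1, 1e-3)))[100:900] - 3))
#' @export
amEnvelope <- function(mBp) {
  mBp <- as.numeric(mBp)
  if (!all(is.finite(mBp))) stop("input must be finite", call. = FALSE)
  if (length(mBp) < 2L) return(abs(mBp))
  Mod(.analyticSignal(mBp))
}

#' Beta rebound of one envelope
#'
#' The maximum of the AM envelope inside the post-movement window minus the
#' mean over the reference window. Ties in the maximum break toward the
#' earliest sample; the result may be negative (no rectification to zero).
#'
#' @param envelope numeric envelope vector (microvolts).
#' @param fs sampling rate, Hz.
#' @param t0Offset event-relative time of the first sample, seconds.
#' @param post post-movement window `c(start, end)`, seconds, half-open.
#' @param ref reference window `c(start, end)`, seconds, half-open.
#' @return list with `brAmplitude` (microvolts), `brLatency` (seconds
#'   relative to the event), `refMean` and `envelope`.
#' @export
betaRebound <- function(envelope, fs, t0Offset, post = c(0.5, 1.5),
                        ref = c(-3.5, -2.5)) {
  envelope <- as.numeric(envelope)
  n <- length(envelope)
  idxPost <- .windowIndices(n, fs, t0Offset, post)
  idxRef <- .windowIndices(n, fs, t0Offset, ref)
  refMean <- mean(envelope[idxRef])
  iMax <- idxPost[which.max(envelope[idxPost])]
  list(brAmplitude = envelope[iMax] - refMean,
       brLatency = t0Offset + (iMax - 1L) / fs,
       refMean = refMean, envelope = envelope)
}

#' Channel with maximum beta-band reactivity
#'
#' Scans per-channel envelopes, computes the beta rebound of each, and
#' returns the channel maximizing it -- only that channel's value is
#' reported as the trial's beta rebound. Deterministic tie-break by channel
#' order.
#'
#' @param envelopes channels-by-samples matrix of AM envelopes.
#' @param labels channel labels, one per row.
#' @inheritParams betaRebound
#' @return list with `channel`, `brAmplitude`, `brLatency`, `refMean`,
#'   `perChannelBr` (named vector) and `envelope` (the winning row).
#' @export
maxReactiveChannel <- function(envelopes, labels, fs, t0Offset,
                               post = c(0.5, 1.5), ref = c(-3.5, -2.5)) {
  if (!is.matrix(envelopes) || nrow(envelopes) < 1L)
    stop("envelopes must be a nonempty channels-by-samples matrix",
         call. = FALSE)
  if (length(labels) != nrow(envelopes))
    stop("one label per envelope row is required", call. = FALSE)
  n <- ncol(envelopes)
  idxPost <- .windowIndices(n, fs, t0Offset, post)
  idxRef <- .windowIndices(n, fs, t0Offset, ref)
  refMeans <- rowMeans(envelopes[, idxRef, drop = FALSE])
  maxPost <- apply(envelopes[, idxPost, drop = FALSE], 1L, max)
  brs <- maxPost - refMeans
  names(brs) <- labels
  i <- which.max(brs)  # first maximum: channel-order tie-break
  env <- envelopes[i, ]
  iMax <- idxPost[which.max(env[idxPost])]
  list(channel = labels[i], brAmplitude = brs[[i]],
       brLatency = t0Offset + (iMax - 1L) / fs, refMean = refMeans[[i]],
       perChannelBr = brs, envelope = env)
}
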