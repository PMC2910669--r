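# Empirical mode decomposition by sifting. The numerical core (extrema with
# the plateau rule, mirror-extended natural-spline envelopes, the sift loop)
# is compiled C++; these wrappers validate inputs and build the S4 result.

.checkSignal <- function(signal, minLen = 3L) {
  if (!is.numeric(signal) || length(signal) < minLen)
    stop(sprintf("signal must be a numeric vector of length >= %d", minLen),
         call. = FALSE)
  if (!all(is.finite(signal)))
    stop("signal must be finite", call. = FALSE)
  as.numeric(signal)
}

#' Locate local extrema with the plateau rule
#'
#' A maximum (minimum) is a sample strictly greater (smaller) than both
#' neighbours; a run of equal samples contributes one extremum at the run
#' midpoint, ties broken toward the lower index.
#'
#' @param signal finite numeric vector, length >= 3.
#' @return list with strictly increasing integer vectors `maxima` and
#'   `minima` (either may be empty).
#' @examples
#' findExtrema(c(0, 1, 1, 0))$maxima  # 2: plateau midpoint
#' @export
findExtrema <- function(signal) {
  .cppFindExtrema(.checkSignal(signal))
}

#' Mean of the upper and lower spline envelopes
#'
#' Connects the local maxima and minima by natural cubic splines after
#' mirror-extending two extrema about each end of the signal (standard EMD
#' practice that suppresses end swings), and returns the average of the two
#' envelopes. When the signal carries no usable oscillation (no maximum or
#' no minimum) the function returns `NULL`, which tells the caller to stop
#' sifting: the working signal is a monotonic residue.
#'
#' @param signal finite numeric vector.
#' @param extrema optional precomputed [findExtrema()] result.
#' @return numeric vector of `length(signal)`, or `NULL`.
#' @export
meanEnvelope <- function(signal, extrema = findExtrema(signal)) {
  signal <- .checkSignal(signal)
  .cppMeanEnvelope(signal, as.integer(extrema$maxima),
                   as.integer(extrema$minima))
}

#' Check the intrinsic-mode-function definition
#'
#' TRUE iff the counts of local extrema and zero-crossings differ by at most
#' one and the mean envelope stays within `tol` times the signal's
#' peak-to-peak range of zero.
#'
#' @param signal finite numeric vector.
#' @param tol mean-envelope tolerance as a fraction of peak-to-peak.
#' @return logical scalar.
#' @examples
#' isIMF(sin(2 * pi * 10 * seq(0, 1, by = 1e-3)))
#' @export
isIMF <- function(signal, tol = 0.05) {
  .cppIsIMF(.checkSignal(signal), tol)
}

#' Extract one intrinsic mode function by sifting
#'
#' Iterates `h_k = h_{k-1} - meanEnvelope(h_{k-1})` until the stoppage
#' statistic `SD_k = ||h_{k-1} - h_k||^2 / ||h_{k-1}||^2` falls below `eps`
#' and the working signal passes the IMF definition check ([isIMF()] with
#' tolerance 0.05), or until `maxSiftIters` is reached.
#'
#' @param signal finite numeric vector.
#' @param eps positive stoppage criterion; 0.2 is the classic sifting value.
#' @param maxSiftIters hard cap on sifting iterations.
#' @return list with `imf` (numeric vector), `nIters`, `sdLast` and
#'   `capped` (TRUE when the cap terminated an unconverged sift).
#' @export
extractIMF <- function(signal, eps = 0.2, maxSiftIters = 100L) {
  signal <- .checkSignal(signal)
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("eps must be a single positive number", call. = FALSE)
  if (maxSiftIters < 1L)
    stop("maxSiftIters must be >= 1", call. = FALSE)
  .cppExtractIMF(signal, eps, as.integer(maxSiftIters), 0.05)
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions plus a monotonic
#' residue by repeated sifting: each extracted IMF is subtracted from the
#' working residue until the residue is monotonic (fewer than two interior
#' extrema, or all successive differences of one sign within
#' `1e-12 * peak-to-peak`) or `maxImfs` is reached. The recursion is exact,
#' so the IMFs plus residue reproduce the input to floating-point accuracy,
#' and the decomposition is deterministic.
#'
#' @param signal finite numeric vector, length >= 8.
#' @param eps sifting stoppage criterion, see [extractIMF()].
#' @param maxImfs safety cap on the number of IMFs.
#' @param maxSiftIters safety cap on sifting iterations per IMF.
#' @return An [IMFSet-class]; constant or monotonic input yields zero IMFs
#'   with `residue == signal`.
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' d <- emdDecompose(sin(2 * pi * 20 * t) + sin(2 * pi * 2 * t))
#' nIMF(d)
#' @export
emdDecompose <- function(signal, eps = 0.2, maxImfs = 16L,
                         maxSiftIters = 100L) {
  signal <- .checkSignal(signal, minLen = 8L)
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("eps must be a single positive number", call. = FALSE)
  res <- .cppEmd(signal, eps, as.integer(maxImfs),
                 as.integer(maxSiftIters), 0.05)
  new("IMFSet", imfs = res$imfs, residue = as.numeric(res$residue),
      sourceSignal = signal, stoppageEps = eps,
      siftIters = as.integer(res$siftIters),
      capped = as.logical(res$capped))
}
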