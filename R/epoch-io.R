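# Epoch container IO and window/convention arithmetic.
#
# The native container is a plain-text format: a small tab-separated header
# (fs, t0_offset, dimensions, labels) followed by one tab-separated row of
# samples per channel, printed with "%.17g" so that doubles round-trip
# bit-exactly. EDF (European Data Format) is supported read-only.

.headerMagic <- "# betaSift epoch v1"

#' Write an epoch to the native plain-text container
#'
#' @param epoch an [EEGEpoch-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readEpoch()]
#' @export
writeEpoch <- function(epoch, path) {
  stopifnot(is(epoch, "EEGEpoch"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    .headerMagic,
    sprintf("fs\t%.17g", epoch@fs),
    sprintf("t0_offset\t%.17g", epoch@t0Offset),
    sprintf("channels\t%d", nrow(epoch@data)),
    sprintf("samples\t%d", ncol(epoch@data)),
    paste(c("labels", epoch@channelLabels), collapse = "\t")
  ), con)
  for (i in seq_len(nrow(epoch@data)))
    writeLines(paste(sprintf("%.17g", epoch@data[i, ]), collapse = "\t"), con)
  invisible(path)
}

.parseHeaderField <- function(lines, key, lineNo) {
  parts <- strsplit(lines[lineNo], "\t", fixed = TRUE)[[1]]
  if (length(parts) < 2L || parts[1] != key)
    stop(sprintf("malformed epoch file: expected field '%s' on line %d",
                 key, lineNo), call. = FALSE)
  parts[-1]
}

.readNativeEpoch <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7L || lines[1] != .headerMagic)
    stop("malformed epoch file: missing header magic line", call. = FALSE)
  fs <- as.numeric(.parseHeaderField(lines, "fs", 2L)[1])
  t0 <- as.numeric(.parseHeaderField(lines, "t0_offset", 3L)[1])
  m <- as.integer(.parseHeaderField(lines, "channels", 4L)[1])
  n <- as.integer(.parseHeaderField(lines, "samples", 5L)[1])
  labels <- .parseHeaderField(lines, "labels", 6L)
  if (anyNA(c(fs, t0, m, n)))
    stop("malformed epoch file: non-numeric fs/t0_offset/channels/samples",
         call. = FALSE)
  if (length(labels) != m)
    stop(sprintf(
      "malformed epoch file: field 'labels' has %d entries but 'channels' is %d",
      length(labels), m), call. = FALSE)
  if (length(lines) != 6L + m)
    stop(sprintf("malformed epoch file: expected %d data rows, found %d",
                 m, length(lines) - 6L), call. = FALSE)
  data <- matrix(NA_real_, m, n)
  for (i in seq_len(m)) {
    row <- as.numeric(strsplit(lines[6L + i], "\t", fixed = TRUE)[[1]])
    if (length(row) != n)
      stop(sprintf(
        "malformed epoch file: data row %d has %d samples, expected %d",
        i, length(row), n), call. = FALSE)
    data[i, ] <- row
  }
  if (!all(is.finite(data)))
    stop("epoch validation error: non-finite samples in data block",
         call. = FALSE)
  EEGEpoch(data, labels, fs, t0)
}

.edfNum <- function(raw, from, width, what) {
  txt <- trimws(rawToChar(raw[from:(from + width - 1L)]))
  val <- suppressWarnings(as.numeric(txt))
  if (is.na(val))
    stop(sprintf("malformed EDF file: field '%s' is not numeric ('%s')",
                 what, txt), call. = FALSE)
  val
}

.edfText <- function(raw, from, width) {
  trimws(rawToChar(raw[from:(from + width - 1L)]))
}

# Minimal EDF / EDF+C reader: 256-byte fixed header, per-signal header
# arrays, then int16 little-endian data records with per-signal physical
# scaling. All signals must share one sampling rate to form an epoch matrix.
.readEDFEpoch <- function(path, t0Offset = 0) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 256L) stop("malformed EDF file: truncated fixed header",
                               call. = FALSE)
  nRec <- as.integer(.edfNum(raw, 237L, 8L, "number of data records"))
  recDur <- .edfNum(raw, 245L, 8L, "record duration")
  ns <- as.integer(.edfNum(raw, 253L, 4L, "number of signals"))
  if (ns < 1L) stop("malformed EDF file: no signals", call. = FALSE)
  hdrBytes <- as.integer(.edfNum(raw, 185L, 8L, "header bytes"))
  if (hdrBytes != 256L + 256L * ns)
    stop("malformed EDF file: header byte count does not match signal count",
         call. = FALSE)
  sig <- function(width, offset) {
    base <- 256L + offset * ns
    vapply(seq_len(ns) - 1L, function(i)
      .edfText(raw, base + i * width + 1L, width), "")
  }
  labels <- sig(16L, 0L)
  physMin <- as.numeric(sig(8L, 16L + 80L + 8L))
  physMax <- as.numeric(sig(8L, 16L + 80L + 8L + 8L))
  digMin <- as.numeric(sig(8L, 16L + 80L + 8L + 16L))
  digMax <- as.numeric(sig(8L, 16L + 80L + 8L + 24L))
  spr <- as.integer(sig(8L, 16L + 80L + 8L + 32L + 80L))
  if (anyNA(c(physMin, physMax, digMin, digMax, spr)))
    stop("malformed EDF file: non-numeric signal header field", call. = FALSE)
  if (length(unique(spr)) != 1L)
    stop("EDF file has signals with differing sampling rates; cannot form an epoch matrix",
         call. = FALSE)
  if (recDur <= 0) stop("malformed EDF file: non-positive record duration",
                        call. = FALSE)
  fs <- spr[1] / recDur
  need <- hdrBytes + 2L * nRec * ns * spr[1]
  if (length(raw) < need)
    stop("malformed EDF file: data block shorter than header promises",
         call. = FALSE)
  ints <- readBin(raw[(hdrBytes + 1L):need], "integer", size = 2L,
                  n = nRec * ns * spr[1], endian = "little", signed = TRUE)
  data <- matrix(NA_real_, ns, nRec * spr[1])
  # records are interleaved: record r holds spr samples of each signal
  arr <- array(ints, dim = c(spr[1], ns, nRec))
  for (i in seq_len(ns)) {
    dig <- as.vector(arr[, i, ])
    gain <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
    data[i, ] <- (dig - digMin[i]) * gain + physMin[i]
  }
  if (!all(is.finite(data)))
    stop("epoch validation error: non-finite samples after EDF scaling",
         call. = FALSE)
  EEGEpoch(data, labels, fs, t0Offset)
}

#' Read an epoch from disk
#'
#' Reads the native plain-text container (written by [writeEpoch()], which
#' round-trips bit-exactly) or an EDF file (read-only; all signals must
#' share one sampling rate). EDF does not store the event anchor, so
#' `t0Offset` must be supplied for EDF input.
#'
#' @param path file path.
#' @param format `"matrix"` (native container) or `"edf"`.
#' @param t0Offset event-relative time of the first sample, seconds; used
#'   for EDF input only.
#' @return A validated [EEGEpoch-class].
#' @examples
#' ep <- EEGEpoch(matrix(rnorm(20), 2, 10), c("C3", "C4"), fs = 10,
#'                t0Offset = -0.5)
#' f <- tempfile(fileext = ".tsv")
#' writeEpoch(ep, f)
#' identical(epochData(readEpoch(f)), epochData(ep))
#' @export
readEpoch <- function(path, format = c("matrix", "edf"), t0Offset = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  switch(format,
         matrix = .readNativeEpoch(path),
         edf = .readEDFEpoch(path, t0Offset))
}

# Half-open window [start, end) -> 1-based sample index range.
# Sample k has event-relative time t0 + (k-1)/fs.
.windowIndices <- function(nSamples, fs, t0, win) {
  if (length(win) != 2L || !all(is.finite(win)) || win[1] >= win[2])
    stop("window must be c(start, end) with start < end", call. = FALSE)
  tol <- 1e-6
  span <- c(t0, t0 + nSamples / fs)
  if (win[1] < span[1] - tol / fs || win[2] > span[2] + tol / fs)
    stop(sprintf(
      "window [%g, %g) lies outside the epoch span [%g, %g)",
      win[1], win[2], span[1], span[2]), call. = FALSE)
  kStart <- as.integer(ceiling((win[1] - t0) * fs - tol)) + 1L
  kEnd <- as.integer(ceiling((win[2] - t0) * fs - tol))
  if (kStart > kEnd)
    stop("window contains no samples", call. = FALSE)
  seq.int(max(1L, kStart), min(nSamples, kEnd))
}

#' Slice an epoch by a half-open time window
#'
#' Returns the samples whose event-relative time `t` satisfies
#' `start <= t < end`. At `fs = 1000` a 1-second window always yields
#' exactly 1000 samples regardless of position.
#'
#' @param epoch an [EEGEpoch-class].
#' @param win numeric `c(start, end)` in seconds relative to the event;
#'   half-open `[start, end)`; must lie inside the epoch span.
#' @param channels optional character vector restricting the rows.
#' @return matrix of the selected samples (channels x window samples).
#' @examples
#' ep <- EEGEpoch(matrix(0, 2, 7000), c("C3", "C4"), fs = 1000,
#'                t0Offset = -4)
#' ncol(windowSlice(ep, c(-3.5, -2.5)))  # 1000
#' @export
windowSlice <- function(epoch, win, channels = NULL) {
  stopifnot(is(epoch, "EEGEpoch"))
  idx <- .windowIndices(ncol(epoch@data), epoch@fs, epoch@t0Offset, win)
  rows <- seq_len(nrow(epoch@data))
  if (!is.null(channels)) {
    rows <- match(channels, epoch@channelLabels)
    if (anyNA(rows))
      stop(sprintf("channel(s) not in montage: %s",
                   paste(channels[is.na(rows)], collapse = ", ")),
           call. = FALSE)
  }
  out <- epoch@data[rows, idx, drop = FALSE]
  rownames(out) <- epoch@channelLabels[rows]
  out
}

#' Keep or drop an epoch by its EOG peak amplitude
#'
#' Implements the artifact gate: an epoch is dropped when any EOG channel's
#' peak absolute amplitude reaches the threshold (epochs are retained only
#' while EOG stays below 100 microvolts by default).
#'
#' @param epoch an [EEGEpoch-class].
#' @param eogLabels character vector of EOG channel labels; defaults to all
#'   labels containing "EOG".
#' @param thresholdUv rejection threshold in microvolts.
#' @return `TRUE` to keep the epoch, `FALSE` to drop it.
#' @export
rejectArtifactEpoch <- function(epoch, eogLabels = NULL, thresholdUv = 100) {
  stopifnot(is(epoch, "EEGEpoch"))
  if (is.null(eogLabels))
    eogLabels <- grep("EOG", epoch@channelLabels, value = TRUE)
  if (length(eogLabels) == 0L)
    stop("no EOG channels named; cannot apply the artifact gate",
         call. = FALSE)
  rows <- match(eogLabels, epoch@channelLabels)
  if (anyNA(rows))
    stop(sprintf("EOG label(s) missing from montage: %s",
                 paste(eogLabels[is.na(rows)], collapse = ", ")),
         call. = FALSE)
  peak <- max(abs(epoch@data[rows, , drop = FALSE]))
  peak < thresholdUv
}
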