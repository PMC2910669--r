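# Shared fixtures and independent reference implementations used as
# oracles against the package's compiled paths.

quickEpoch <- function(data, labels = NULL, fs = 1000, t0 = -4) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  EEGEpoch(data, labels, fs, t0)
}

# Pure-R mean envelope: mirror-extend two extrema about each end, natural
# cubic splines via stats::spline. Independent of the C++ sifting core.
refMeanEnvelope <- function(x, ext = findExtrema(x)) {
  n <- length(x)
  if (length(ext$maxima) < 1L || length(ext$minima) < 1L) return(NULL)
  one <- function(idx) {
    k <- length(idx)
    ne <- min(2L, k)
    xs <- c(rev(2 - idx[seq_len(ne)]), idx,
            rev(2 * n - idx[seq.int(k - ne + 1L, k)]))
    ys <- c(rev(x[idx[seq_len(ne)]]), x[idx],
            rev(x[idx[seq.int(k - ne + 1L, k)]]))
    o <- order(xs)
    xs <- xs[o]
    ys <- ys[o]
    d <- !duplicated(xs)
    stats::spline(xs[d], ys[d], xout = seq_len(n), method = "natural")$y
  }
  (one(ext$maxima) + one(ext$minima)) / 2
}

# Independent exhaustive 3-means oracles for 1-D values.
# (a) all contiguous partitions of the sorted values;
# (b) full enumeration of every 3-label assignment (small J only).
refKmeans3Contiguous <- function(v) {
  o <- order(v)
  s <- v[o]
  J <- length(v)
  best <- Inf
  bestGrp <- NULL
  for (i in 1:(J - 2)) {
    for (j in (i + 1):(J - 1)) {
      parts <- list(s[1:i], s[(i + 1):j], s[(j + 1):J])
      obj <- sum(vapply(parts, function(p) sum((p - mean(p))^2), 0))
      if (obj < best) {
        best <- obj
        grp <- integer(J)
        grp[o[1:i]] <- 1L
        grp[o[(i + 1):j]] <- 2L
        grp[o[(j + 1):J]] <- 3L
        bestGrp <- grp
      }
    }
  }
  list(group = bestGrp, objective = best)
}

refKmeans3Full <- function(v) {
  J <- length(v)
  stopifnot(J <= 9)
  grid <- expand.grid(rep(list(1:3), J))
  best <- Inf
  bestGrp <- NULL
  for (r in seq_len(nrow(grid))) {
    g <- as.integer(grid[r, ])
    if (length(unique(g)) != 3L) next
    obj <- sum(vapply(1:3, function(k) {
      p <- v[g == k]
      sum((p - mean(p))^2)
    }, 0))
    if (obj < best) {
      best <- obj
      bestGrp <- g
    }
  }
  list(group = bestGrp, objective = best)
}

# canonical form of a 3-partition: list of sorted index sets ordered by
# their smallest member, so label permutations compare equal
canonicalPartition <- function(group) {
  sets <- split(seq_along(group), group)
  sets <- lapply(sets, sort)
  unname(sets[order(vapply(sets, min, 0L))])
}

# Independent byte-level EDF writer (fixed 256-byte header, per-signal
# header arrays, int16 little-endian records), used as the oracle for the
# package's EDF reader.
writeReferenceEDF <- function(path, data, labels, fs, physMin = -500,
                              physMax = 500) {
  ns <- nrow(data)
  n <- ncol(data)
  recDur <- 1
  spr <- as.integer(fs * recDur)
  nRec <- n %/% spr
  stopifnot(nRec * spr == n)
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("patient", 80), pad("recording", 80),
                pad("01.01.20", 8), pad("00.00.00", 8),
                pad(256 + 256 * ns, 8), pad("", 44), pad(nRec, 8),
                pad(recDur, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- c(paste0(pad(labels, 16), collapse = ""),
              paste0(rep(pad("transducer", 80), ns), collapse = ""),
              paste0(rep(pad("uV", 8), ns), collapse = ""),
              paste0(rep(pad(physMin, 8), ns), collapse = ""),
              paste0(rep(pad(physMax, 8), ns), collapse = ""),
              paste0(rep(pad(-32768, 8), ns), collapse = ""),
              paste0(rep(pad(32767, 8), ns), collapse = ""),
              paste0(rep(pad("", 80), ns), collapse = ""),
              paste0(rep(pad(spr, 8), ns), collapse = ""),
              paste0(rep(pad("", 32), ns), collapse = ""))
  writeChar(paste0(fields, collapse = ""), con, eos = NULL)
  gain <- (physMax - physMin) / (32767 - (-32768))
  dig <- round((data - physMin) / gain) + (-32768)
  dig <- pmin(pmax(dig, -32768), 32767)
  for (r in seq_len(nRec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}
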