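# Event-locked multichannel EEG simulator with known ground truth: a focal
# sensorimotor beta source with pre-movement suppression and a jittered
# post-movement rebound, spatially mixed 1/f background, line noise,
# drifts, and occasional ocular artifacts.

#' Default 32-channel montage
#'
#' A 10-20 superset of 30 EEG positions plus bipolar VEOG/HEOG.
#'
#' @return character vector of 32 labels.
#' @export
defaultMontage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FT7", "FC3", "FCz", "FC4", "FT8",
    "T7", "C3", "Cz", "C4", "T8",
    "TP7", "CP3", "CPz", "CP4", "TP8",
    "P7", "P3", "Pz", "P4", "P8",
    "O1", "Oz", "O2", "VEOG", "HEOG")
}

# schematic top-view scalp coordinates (unit head radius); EOG channels
# have no scalp position and get zero forward weight
.montageCoords <- function() {
  m <- rbind(
    Fp1 = c(-0.31, 0.90), Fp2 = c(0.31, 0.90),
    F7 = c(-0.80, 0.55), F3 = c(-0.40, 0.55), Fz = c(0, 0.55),
    F4 = c(0.40, 0.55), F8 = c(0.80, 0.55),
    FT7 = c(-0.90, 0.28), FC3 = c(-0.45, 0.28), FCz = c(0, 0.28),
    FC4 = c(0.45, 0.28), FT8 = c(0.90, 0.28),
    T7 = c(-1, 0), C3 = c(-0.5, 0), Cz = c(0, 0), C4 = c(0.5, 0),
    T8 = c(1, 0),
    TP7 = c(-0.90, -0.28), CP3 = c(-0.45, -0.28), CPz = c(0, -0.28),
    CP4 = c(0.45, -0.28), TP8 = c(0.90, -0.28),
    P7 = c(-0.80, -0.55), P3 = c(-0.40, -0.55), Pz = c(0, -0.55),
    P4 = c(0.40, -0.55), P8 = c(0.80, -0.55),
    O1 = c(-0.31, -0.90), Oz = c(0, -0.90), O2 = c(0.31, -0.90))
  colnames(m) <- c("x", "y")
  m
}

#' Focal forward weights for a scalp source
#'
#' Non-negative coupling of a focal cortical source into each channel:
#' a Gaussian fall-off with scalp distance from the focus (near-zero
#' contralaterally), 1 at the focus, 0 at EOG channels and any label
#' without a schematic position.
#'
#' @param montage character vector of channel labels.
#' @param focus label of the focal channel.
#' @param sigma spatial spread of the fall-off (unit head radius).
#' @return named non-negative numeric vector, one weight per channel.
#' @export
focalForwardWeights <- function(montage = defaultMontage(), focus = "C3",
                                sigma = 0.35) {
  xy <- .montageCoords()
  if (!(focus %in% rownames(xy)))
    stop(sprintf("no scalp position known for focus '%s'", focus),
         call. = FALSE)
  f <- xy[focus, ]
  w <- vapply(montage, function(lab) {
    if (!(lab %in% rownames(xy))) return(0)
    d2 <- sum((xy[lab, ] - f)^2)
    exp(-d2 / (2 * sigma^2))
  }, 0)
  names(w) <- montage
  w
}

#' Simulation configuration
#'
#' Bundles the montage, epoch geometry, source model, forward weights and
#' noise model, with defaults emulating a self-paced finger-lifting session:
#' a C3-focal beta source (a multi-tone carrier spanning a 4-Hz band around
#' 20 Hz at unit mean envelope; `bandHz = 0` gives a pure sinusoid whose
#' envelope is exactly the amplitude modulator) with 2 uV baseline
#' amplitude, suppression over the 2 s before movement,
#' and a Gaussian rebound bump (SD 0.3 s) of twice the baseline at a
#' latency jittered across trials (SD 0.45 s); spatially mixed 1/f^1.7
#' background band-limited to the acquisition band, 60 Hz line noise,
#' sub-0.5 Hz drifts and occasional 150 uV ocular artifacts.
#'
#' @param montage channel labels.
#' @param fs sampling rate, Hz.
#' @param span epoch span `c(start, end)` in seconds, half-open.
#' @param nTrials number of trials in a session.
#' @param source named list overriding source-model fields (see Details).
#' @param noise named list overriding noise-model fields (see Details).
#' @param forwardWeights per-channel source coupling; defaults to
#'   [focalForwardWeights()] at C3.
#' @param seed integer seed; each trial derives its own stream from
#'   `(seed, trialIndex)`, so trials are reproducible individually.
#' @details Source fields: `centerHz`, `bandHz`, `baselineUv`,
#'   `reboundGain` (bump peak = gain x baseline), `latencyMeanS`,
#'   `latencySdS`, `bumpSdS`, `suppressionGain`, `suppressionWindowS`,
#'   `freqJitterSdHz`, `ampJitterRel`. Noise fields: `alpha`
#'   (power-law exponent), `bgRmsUv`, `bgBandHz`, `sharedFraction`,
#'   `nSharedPatterns`, `lineHz`, `lineAmpUv`, `driftCutoffHz`,
#'   `driftRmsUv`, `artifactProb`, `artifactAmpUv`.
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(montage = defaultMontage(), fs = 1000,
                      span = c(-4, 3), nTrials = 100,
                      source = list(), noise = list(),
                      forwardWeights = NULL, seed = 1) {
  src <- list(centerHz = 20, bandHz = 4, baselineUv = 2, reboundGain = 2,
              latencyMeanS = 1.2, latencySdS = 0.45, bumpSdS = 0.3,
              suppressionGain = 0.5, suppressionWindowS = c(-2, 0),
              freqJitterSdHz = 1.5, ampJitterRel = 0.1)
  bad <- setdiff(names(source), names(src))
  if (length(bad)) stop(sprintf("unknown source field(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  src[names(source)] <- source
  nz <- list(alpha = 1.7, bgRmsUv = 5, bgBandHz = c(0.5, 100),
             sharedFraction = 0.6, nSharedPatterns = 8L,
             lineHz = 60, lineAmpUv = 2, driftCutoffHz = 0.5,
             driftRmsUv = 10, artifactProb = 0.05, artifactAmpUv = 150)
  bad <- setdiff(names(noise), names(nz))
  if (length(bad)) stop(sprintf("unknown noise field(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  nz[names(noise)] <- noise
  if (is.null(forwardWeights)) forwardWeights <- focalForwardWeights(montage)
  cfg <- list(montage = montage, fs = fs, span = span,
              nTrials = as.integer(nTrials), source = src, noise = nz,
              forwardWeights = forwardWeights, seed = as.integer(seed))
  .validateSimConfig(cfg)
  cfg
}

.validateSimConfig <- function(cfg) {
  with(cfg, {
    if (fs <= 0 || span[1] >= span[2])
      stop("invalid configuration: need fs > 0 and span start < end",
           call. = FALSE)
    if (length(forwardWeights) != length(montage) || any(forwardWeights < 0))
      stop("forward weights must be non-negative, one per channel",
           call. = FALSE)
    amps <- c(source$baselineUv, source$reboundGain, noise$bgRmsUv,
              noise$lineAmpUv, noise$driftRmsUv, noise$artifactAmpUv)
    if (any(amps < 0))
      stop("invalid configuration: amplitudes must be >= 0", call. = FALSE)
    if (noise$artifactProb < 0 || noise$artifactProb > 1)
      stop("invalid configuration: artifact probability must lie in [0, 1]",
           call. = FALSE)
    lo <- source$centerHz - source$bandHz / 2
    hi <- source$centerHz + source$bandHz / 2
    if (lo <= 0 || hi >= fs / 2)
      stop("invalid configuration: source band must lie inside (0, fs/2)",
           call. = FALSE)
  })
  invisible(TRUE)
}

# k independent power-law (1/f^alpha) Gaussian noise rows, band-limited,
# unit RMS each; batched through one matrix FFT pair
.colouredNoise <- function(k, n, fs, alpha, bandHz) {
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  g <- numeric(n)
  inb <- f > 0 & f <= bandHz[2]
  g[inb] <- pmax(f[inb], bandHz[1])^(-alpha / 2)
  X <- mvfft(matrix(rnorm(k * n), n, k))
  y <- Re(mvfft(X * g, inverse = TRUE)) / n
  t(y) / apply(y, 2L, sd)
}

# k independent Gaussian low-pass noise rows below cutoffHz, unit RMS
# (slow drift)
.driftNoise <- function(k, n, fs, cutoffHz) {
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  g <- exp(-(f / cutoffHz)^2)
  g[1] <- 0
  X <- mvfft(matrix(rnorm(k * n), n, k))
  y <- Re(mvfft(X * g, inverse = TRUE)) / n
  t(y) / apply(y, 2L, sd)
}

.trialSeed <- function(seed, trialIndex) {
  as.integer((as.double(seed %% 50021L) * 40009 +
                as.double(trialIndex) * 7919) %% 2147483629)
}

.artifactCoupling <- function(montage) {
  w <- rep(0.02, length(montage))
  w[grepl("EOG", montage)] <- 1
  w[montage %in% c("Fp1", "Fp2")] <- 0.4
  w[montage %in% c("F7", "F3", "Fz", "F4", "F8")] <- 0.2
  names(w) <- montage
  w
}

#' Simulate one event-locked trial
#'
#' The epoch is `forwardWeights (x) source + background + line + drift
#' (+ ocular artifact with the configured probability)`. The source is a
#' narrowband carrier spanning `bandHz` around the trial's jittered center
#' frequency (equal-amplitude random-phase tones at 2-Hz spacing covering
#' both band edges, unit mean Hilbert envelope; a pure sinusoid when
#' `bandHz = 0`) whose amplitude
#' modulator holds a baseline level, is suppressed over the pre-movement
#' window, and carries a Gaussian rebound bump at the trial's jittered
#' latency. Deterministic given `(cfg$seed, trialIndex)`.
#'
#' The ground-truth record reports the source band actually injected, the
#' true rebound amplitude as the estimator defines it (maximum of the
#' modulator over the post-movement window minus its mean over the
#' reference window, at the focal channel) and the true peak latency.
#'
#' @param cfg a [simConfig()] list.
#' @param trialIndex 1-based trial number.
#' @param post,ref analysis windows used for the ground-truth rebound.
#' @return list with `epoch` ([EEGEpoch-class]), `truth` (one-row
#'   data.frame: trial, centerHz, bandLo, bandHi, latencyDrawn (the raw
#'   jittered bump latency), latencyTrue (modulator argmax in the post
#'   window), brTrue, artifact), `source` and `modulator` (numeric
#'   vectors).
#' @export
simulateTrial <- function(cfg, trialIndex = 1L, post = c(0.5, 1.5),
                          ref = c(-3.5, -2.5)) {
  .validateSimConfig(cfg)
  set.seed(.trialSeed(cfg$seed, trialIndex))
  fs <- cfg$fs
  n <- as.integer(round((cfg$span[2] - cfg$span[1]) * fs))
  t <- cfg$span[1] + (seq_len(n) - 1L) / fs
  src <- cfg$source
  M <- length(cfg$montage)

  # trial-level jitters
  fc <- src$centerHz + rnorm(1, 0, src$freqJitterSdHz)
  fc <- min(max(fc, src$bandHz / 2 + 1), fs / 2 - src$bandHz / 2 - 1)
  lat <- src$latencyMeanS + rnorm(1, 0, src$latencySdS)
  lat <- min(max(lat, cfg$span[1] + 0.5), cfg$span[2] - 0.2)
  ampScale <- exp(rnorm(1, 0, src$ampJitterRel))

  # amplitude modulator: baseline, pre-movement suppression, rebound bump
  supp <- numeric(n)
  sw <- src$suppressionWindowS
  inSupp <- t >= sw[1] & t < sw[2]
  supp[inSupp] <- sin(pi * (t[inSupp] - sw[1]) / (sw[2] - sw[1]))^2
  modulator <- src$baselineUv * (1 - src$suppressionGain * supp) +
    src$baselineUv * src$reboundGain * ampScale *
      exp(-(t - lat)^2 / (2 * src$bumpSdS^2))

  # carrier spanning the configured band: equal-amplitude random-phase
  # tones at >= 2 Hz spacing (two spectral-resolution bins of the 1-s
  # analysis windows, so the band's edge bins carry exactly one tone and
  # cannot be nulled by inter-tone interference), normalized to unit mean
  # Hilbert envelope; bandHz = 0 gives a pure sinusoid whose envelope is
  # exactly the modulator
  if (src$baselineUv > 0 || src$reboundGain > 0) {
    nTones <- max(1L, floor(src$bandHz / 2) + 1L)
    tones <- if (nTones == 1L) fc else
      seq(fc - src$bandHz / 2, fc + src$bandHz / 2, length.out = nTones)
    raw <- rowSums(vapply(tones,
                          function(f) cos(2 * pi * f * t + runif(1, 0, 2 * pi)),
                          numeric(n)))
    carrier <- raw / mean(Mod(.analyticSignal(raw)))
    source <- modulator * carrier
  } else {
    source <- numeric(n)
  }

  data <- outer(as.numeric(cfg$forwardWeights), source)

  nz <- cfg$noise
  if (nz$bgRmsUv > 0) {
    K <- nz$nSharedPatterns
    shared <- matrix(0, M, n)
    if (nz$sharedFraction > 0 && K > 0) {
      G <- matrix(rnorm(M * K), M, K)
      G <- G / sqrt(rowSums(G^2))
      shared <- G %*% .colouredNoise(K, n, fs, nz$alpha, nz$bgBandHz)
    }
    indep <- .colouredNoise(M, n, fs, nz$alpha, nz$bgBandHz)
    data <- data + nz$bgRmsUv * (sqrt(nz$sharedFraction) * shared +
                                   sqrt(1 - nz$sharedFraction) * indep)
  }
  if (nz$lineAmpUv > 0) {
    line <- sin(2 * pi * nz$lineHz * t + runif(1, 0, 2 * pi))
    data <- data + outer(nz$lineAmpUv * runif(M, 0.5, 1.5), line)
  }
  if (nz$driftRmsUv > 0)
    data <- data + nz$driftRmsUv * .driftNoise(M, n, fs, nz$driftCutoffHz)
  artifact <- runif(1) < nz$artifactProb
  if (artifact) {
    tc <- runif(1, cfg$span[1] + 0.5, cfg$span[2] - 0.5)
    shape <- nz$artifactAmpUv * sample(c(-1, 1), 1) *
      exp(-(t - tc)^2 / (2 * 0.15^2))
    data <- data + outer(.artifactCoupling(cfg$montage), shape)
  }

  epoch <- EEGEpoch(data, cfg$montage, fs, cfg$span[1])
  idxPost <- .windowIndices(n, fs, cfg$span[1], post)
  idxRef <- .windowIndices(n, fs, cfg$span[1], ref)
  iPk <- idxPost[which.max(modulator[idxPost])]
  truth <- data.frame(
    trial = as.integer(trialIndex), centerHz = fc,
    bandLo = fc - src$bandHz / 2, bandHi = fc + src$bandHz / 2,
    latencyDrawn = lat,
    latencyTrue = cfg$span[1] + (iPk - 1L) / fs,
    brTrue = modulator[iPk] - mean(modulator[idxRef]),
    artifact = artifact)
  list(epoch = epoch, truth = truth, source = source, modulator = modulator)
}

#' Simulate a session of independent trials
#'
#' @param cfg a [simConfig()] list.
#' @param keepSources keep the per-trial source and modulator waveforms
#'   (memory permitting).
#' @inheritParams simulateTrial
#' @return list with `epochs` (list of [EEGEpoch-class]), `truth`
#'   (data.frame, one row per trial), `forwardWeights`, and -- when
#'   `keepSources` -- `sources` and `modulators` (lists of vectors).
#' @export
simulateSession <- function(cfg, keepSources = FALSE, post = c(0.5, 1.5),
                            ref = c(-3.5, -2.5)) {
  .validateSimConfig(cfg)
  if (cfg$nTrials < 1L) stop("nTrials must be >= 1", call. = FALSE)
  epochs <- vector("list", cfg$nTrials)
  sources <- if (keepSources) vector("list", cfg$nTrials)
  modulators <- if (keepSources) vector("list", cfg$nTrials)
  rows <- vector("list", cfg$nTrials)
  for (i in seq_len(cfg$nTrials)) {
    tr <- simulateTrial(cfg, i, post, ref)
    epochs[[i]] <- tr$epoch
    rows[[i]] <- tr$truth
    if (keepSources) {
      sources[[i]] <- tr$source
      modulators[[i]] <- tr$modulator
    }
  }
  out <- list(epochs = epochs, truth = do.call(rbind, rows),
              forwardWeights = cfg$forwardWeights)
  if (keepSources) {
    out$sources <- sources
    out$modulators <- modulators
  }
  out
}
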