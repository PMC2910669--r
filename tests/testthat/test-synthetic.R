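test_that("trials are bit-identical under (seed, trialIndex) and differ
           across seeds", {
  cfg <- simConfig(fs = 250, nTrials = 2, seed = 9)
  a <- simulateTrial(cfg, 1L)
  b <- simulateTrial(cfg, 1L)
  expect_identical(a$epoch@data, b$epoch@data)
  expect_identical(a$truth, b$truth)
  cfg2 <- simConfig(fs = 250, nTrials = 2, seed = 10)
  c <- simulateTrial(cfg2, 1L)
  expect_false(identical(a$epoch@data, c$epoch@data))
})

test_that("all-zero amplitudes give an all-zero epoch", {
  cfg <- simConfig(fs = 250, nTrials = 1,
                   source = list(baselineUv = 0, reboundGain = 0),
                   noise = list(bgRmsUv = 0, lineAmpUv = 0, driftRmsUv = 0,
                                artifactProb = 0))
  tr <- simulateTrial(cfg, 1L)
  expect_true(all(tr$epoch@data == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(source = list(centerHz = 600)), "fs/2")
  expect_error(simConfig(noise = list(artifactProb = 1.5)), "probability")
  expect_error(simConfig(noise = list(bgRmsUv = -1)), "amplitudes")
  expect_error(simConfig(source = list(unknownKnob = 1)), "unknown")
})

test_that("the post-window beta-range periodogram peaks inside the source
           band and exceeds the reference window", {
  cfg <- simConfig(seed = 23, nTrials = 1,
                   source = list(freqJitterSdHz = 0, latencyMeanS = 1,
                                 latencySdS = 0))
  tr <- simulateTrial(cfg, 1L)
  x <- epochData(tr$epoch)["C3", ]
  post <- x[4501:5500]
  ref <- x[501:1500]
  # independent periodogram route
  pg <- stats::spec.pgram(stats::ts(post, frequency = 1000), plot = FALSE,
                          taper = 0.1)
  beta <- pg$freq >= 13 & pg$freq <= 30
  pk <- pg$freq[beta][which.max(pg$spec[beta])]
  expect_gte(pk, tr$truth$bandLo - 0.5)
  expect_lte(pk, tr$truth$bandHi + 0.5)
  pgr <- stats::spec.pgram(stats::ts(ref, frequency = 1000), plot = FALSE,
                           taper = 0.1)
  betaR <- pgr$freq >= tr$truth$bandLo & pgr$freq <= tr$truth$bandHi
  betaP <- pg$freq >= tr$truth$bandLo & pg$freq <= tr$truth$bandHi
  expect_gt(sum(pg$spec[betaP]), sum(pgr$spec[betaR]))
})

test_that("session-level jitter and artifact statistics match their
           configuration", {
  cfg <- simConfig(fs = 250, nTrials = 150, seed = 3,
                   noise = list(artifactProb = 0.2))
  ses <- simulateSession(cfg)
  expect_equal(nrow(ses$truth), 150L)
  latSd <- sd(ses$truth$latencyDrawn)
  expect_gte(latSd, 0.36)
  expect_lte(latSd, 0.54)
  frac <- mean(ses$truth$artifact)
  expect_gte(frac, 0.13)
  expect_lte(frac, 0.27)
})

test_that("a single-trial session yields one epoch and one truth row", {
  cfg <- simConfig(fs = 250, nTrials = 1, seed = 2)
  ses <- simulateSession(cfg, keepSources = TRUE)
  expect_length(ses$epochs, 1L)
  expect_equal(nrow(ses$truth), 1L)
  expect_length(ses$sources, 1L)
})

test_that("the injected source is recoverable from the noise-free signal", {
  cfg <- simConfig(seed = 19, nTrials = 1,
                   noise = list(bgRmsUv = 0, lineAmpUv = 0, driftRmsUv = 0,
                                artifactProb = 0))
  ses <- simulateSession(cfg, keepSources = TRUE)
  x <- epochData(ses$epochs[[1]])["C3", ]
  d <- emdDecompose(x)
  cors <- abs(apply(imfMatrix(d), 1, cor, y = ses$sources[[1]]))
  expect_gt(max(cors), 0.95)
})
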