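makeMiniTrials <- function(nTrials = 3, seed = 77, scale = 1) {
  cfg <- simConfig(montage = c("C3", "FC3", "CP3", "Cz", "C4", "VEOG"),
                   forwardWeights = c(1, 0.6, 0.6, 0.3, 0.02, 0),
                   fs = 250, span = c(-4, 3), nTrials = nTrials,
                   source = list(latencySdS = 0.1, freqJitterSdHz = 0),
                   noise = list(artifactProb = 0, lineAmpUv = 1,
                                bgRmsUv = 2, driftRmsUv = 4),
                   seed = seed)
  ses <- simulateSession(cfg)
  if (scale != 1)
    ses$epochs <- lapply(ses$epochs, function(e)
      EEGEpoch(e@data * scale, channelLabels(e), samplingRate(e),
               t0Offset(e)))
  ses
}

test_that("conventional ERS on one trial equals the per-channel single-trial
           envelope pipeline", {
  ses <- makeMiniTrials(1)
  band <- bandSpec(18, 22)
  ers <- conventionalERS(ses$epochs, band)
  ep <- ses$epochs[[1]]
  manual <- amEnvelope(bandpassFilter(ep@data[1, ], 250, band))
  expect_equal(ers@avgEnvelope[1, ], manual, tolerance = 1e-10)
  manualBr <- betaRebound(manual, 250, -4)$brAmplitude
  expect_equal(ers@br[1], manualBr)
})

test_that("all-zero trials give zero beta rebounds", {
  zero <- quickEpoch(matrix(0, 2, 1750), c("C3", "Cz"), fs = 250, t0 = -4)
  ers <- conventionalERS(list(zero, zero), bandSpec(18, 22))
  expect_equal(ers@br, c(0, 0))
})

test_that("task band requires a rebound and enough trials", {
  set.seed(12)
  null <- lapply(1:3, function(i)
    quickEpoch(matrix(rnorm(2 * 1750), 2, 1750), c("C3", "Cz"), fs = 250,
               t0 = -4))
  expect_error(taskBand(null, "C3"), "no task-specific band|supra-threshold")
  expect_error(taskBand(null[1], "C3"), "at least 2")
})

test_that("task band recovers the injected band from averaged spectra", {
  ses <- makeMiniTrials(20, seed = 41)
  tb <- taskBand(ses$epochs, "C3")
  lim <- bandLimits(tb)
  expect_lte(abs(lim[1] - 18), 1)
  expect_lte(abs(lim[2] - 22), 1)
})

test_that("template building: identity, montage mismatch, low-trial warning", {
  ses <- makeMiniTrials(2)
  band <- bandSpec(18, 22)
  ers <- suppressWarnings(conventionalERS(ses$epochs, band))
  expect_warning(tpl <- buildTemplate(list(ers)), "only 2 trials")
  expect_equal(unname(templateWeights(tpl)), ers@br)

  ers2 <- ers
  ers2@channelLabels <- rev(ers2@channelLabels)
  expect_error(suppressWarnings(buildTemplate(list(ers, ers2))), "montage")
})

test_that("scaling all trials scales the template and leaves matching
           correlations unchanged", {
  band <- bandSpec(18, 22)
  ses1 <- makeMiniTrials(4, seed = 55)
  ses2 <- makeMiniTrials(4, seed = 55, scale = 3)
  t1 <- suppressWarnings(buildTemplate(list(conventionalERS(ses1$epochs, band))))
  t2 <- suppressWarnings(buildTemplate(list(conventionalERS(ses2$epochs, band))))
  expect_equal(t2@weights, 3 * t1@weights, tolerance = 1e-8)
  m <- runif(length(t1@weights))
  names(m) <- t1@channelLabels
  expect_equal(templateCorrelation(m, t1), templateCorrelation(m, t2),
               tolerance = 1e-8)
})

test_that("template files round-trip through the delimited text format", {
  tpl <- spatialTemplate(c(1.25, 0.5, 0.125), c("C3", "FC3", "Cz"), "C3")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTemplate(tpl, f)
  back <- readTemplate(f)
  expect_identical(back@weights, tpl@weights)
  expect_identical(back@channelLabels, tpl@channelLabels)
  expect_identical(ciLabel(back), "C3")
  expect_error(readTemplate(withr::local_tempfile(lines = "junk")),
               "ci_label")
})
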