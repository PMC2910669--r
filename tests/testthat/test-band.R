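test_that("amplitude spectrum is unit-calibrated at bin frequencies", {
  t <- seq(0, 1 - 1e-3, by = 1e-3)
  sp <- amplitudeSpectrum(sin(2 * pi * 20 * t), 1000)
  expect_equal(sp$amplitude[sp$freqs == 20], 1, tolerance = 0.01)
  expect_lt(max(sp$amplitude[abs(sp$freqs - 20) > 2]), 0.01)

  z <- amplitudeSpectrum(rep(0, 1000), 1000)
  expect_true(all(z$amplitude == 0))
  expect_error(amplitudeSpectrum(rnorm(32), 1000), "short")
})

test_that("off-bin tones show bounded leakage under the Hann taper", {
  t <- seq(0, 1 - 1e-3, by = 1e-3)
  sp <- amplitudeSpectrum(sin(2 * pi * 20.5 * t), 1000)
  pk <- sp$freqs[which.max(sp$amplitude)]
  expect_gte(pk, 20)
  expect_lte(pk, 21)
  expect_gte(max(sp$amplitude), 0.6)
  expect_lte(max(sp$amplitude), 1.0)
})

test_that("identical windows yield no detected band", {
  set.seed(2)
  x <- rnorm(1000)
  expect_null(trialBand(x, x, 1000))
})

test_that("an injected contrast is detected and respects the search range", {
  t <- seq(0, 1 - 1e-3, by = 1e-3)
  ref <- sin(2 * pi * 19 * t) + sin(2 * pi * 21 * t) + 0.2 * rnorm(1000)
  post <- 3 * sin(2 * pi * 19 * t) + 3 * sin(2 * pi * 21 * t) +
    0.2 * rnorm(1000)
  b <- trialBand(ref, post, 1000)
  expect_false(is.null(b))
  lim <- bandLimits(b)
  expect_gte(lim[1], 13)
  expect_lte(lim[2], 30)
  expect_lte(lim[1], 19)
  expect_gte(lim[2], 21)
  expect_gte(lim[2] - lim[1], 2)  # minimum band width enforced
})

test_that("band detection is invariant to a common positive rescaling", {
  set.seed(14)
  t <- seq(0, 1 - 1e-3, by = 1e-3)
  ref <- sin(2 * pi * 20 * t) + 0.3 * rnorm(1000)
  post <- 3 * sin(2 * pi * 20 * t) + 0.3 * rnorm(1000)
  b1 <- trialBand(ref, post, 1000)
  b2 <- trialBand(37.5 * ref, 37.5 * post, 1000)
  expect_equal(bandLimits(b1), bandLimits(b2))
})

test_that("the z-score rule is strictly stricter than the 2-SD rule", {
  set.seed(6)
  nDet <- c(two_sd = 0L, zscore = 0L)
  for (i in 1:40) {
    ref <- rnorm(1000)
    post <- rnorm(1000)
    for (rule in names(nDet)) {
      ds <- differentialSpectrum(ref, post, 1000, rule = rule)
      nDet[rule] <- nDet[rule] + as.integer(any(ds$passBins))
      if (rule == "zscore") {
        two <- differentialSpectrum(ref, post, 1000, rule = "two_sd")
        expect_true(all(which(ds$passBins) %in% which(two$passBins)))
      }
    }
  }
  expect_lte(nDet["zscore"], nDet["two_sd"])
})

test_that("zero-phase band-pass keeps the passband and kills one octave out", {
  fs <- 1000
  t <- seq(0, 7 - 1e-3, by = 1e-3)
  band <- bandSpec(15, 25)
  inband <- sin(2 * pi * 20 * t)
  y <- bandpassFilter(inband, fs, band)
  interior <- seq(251, 6750)  # away from the outer 0.25 s
  expect_lt(max(abs(y[interior] - inband[interior])) / 1, 0.1)

  out <- sin(2 * pi * 50 * t)  # one octave above the upper edge
  yo <- bandpassFilter(out, fs, band)
  att <- 20 * log10(sd(yo[interior]) / sd(out[interior]))
  expect_lt(att, -30)

  expect_error(bandpassFilter(inband, fs, c(25, 15)), "band")
  expect_error(bandpassFilter(inband, fs, c(100, 600)), "band")
})

test_that("forward-backward filtering has a symmetric impulse response", {
  x <- numeric(4001)
  x[2001] <- 1
  y <- bandpassFilter(x, 1000, bandSpec(15, 20))
  asym <- max(abs(y[2:2000] - rev(y[2002:4000]))) / max(abs(y))
  expect_lt(asym, 1e-6)
})
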