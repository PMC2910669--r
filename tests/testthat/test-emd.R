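test_that("extrema detection matches closed forms and the plateau rule", {
  t <- seq(0, 1 - 1e-3, by = 1e-3)
  ext <- findExtrema(sin(2 * pi * 5 * t))
  expect_length(ext$maxima, 5L)
  expect_length(ext$minima, 5L)
  expect_true(all(diff(ext$maxima) > 0))

  ramp <- findExtrema(seq_len(100) + 0)
  expect_length(ramp$maxima, 0L)
  expect_length(ramp$minima, 0L)

  expect_equal(findExtrema(c(0, 1, 1, 0))$maxima, 2L)      # even plateau: lower
  expect_equal(findExtrema(c(0, 1, 1, 1, 0))$maxima, 3L)   # odd plateau: middle
  expect_equal(findExtrema(c(1, 0, 0, 1))$minima, 2L)
})

test_that("mean envelope is near zero for sinusoids and tracks offsets", {
  t <- seq(0, 2 - 1e-3, by = 1e-3)
  A <- 3
  me <- meanEnvelope(A * sin(2 * pi * 10 * t))
  interior <- seq(101, 1900)  # away from the outer 5%
  expect_lt(max(abs(me[interior])), 0.02 * A)

  me2 <- meanEnvelope(sin(2 * pi * 10 * t) + 7)
  expect_lt(max(abs(me2[interior] - 7)), 0.06)

  expect_null(meanEnvelope(c(0, 1, 0, -0.5, -0.8)[c(1, 2, 3)]))  # 1 max, 0 min
  expect_null(meanEnvelope(seq(0, 1, length.out = 50)))
})

test_that("compiled envelope equals the pure-R natural-spline reference", {
  set.seed(11)
  for (i in 1:8) {
    x <- cumsum(rnorm(400)) + sin(2 * pi * 7 * seq_len(400) / 400) * i
    expect_equal(meanEnvelope(x), refMeanEnvelope(x), tolerance = 1e-10)
  }
})

test_that("sifting converges in one pass for a signal that is already an IMF", {
  t <- seq(0, 1 - 1e-3, by = 1e-3)
  x <- sin(2 * pi * 10 * t)
  e <- extractIMF(x)
  expect_equal(e$nIters, 1L)
  expect_lt(max(abs(e$imf - x)), 0.02)
})

test_that("sifting separates the fast tone of a two-tone mixture", {
  t <- seq(0, 7 - 1e-3, by = 1e-3)
  e <- extractIMF(sin(2 * pi * 20 * t) + sin(2 * pi * 2 * t))
  interior <- seq(351, 6650)
  expect_gt(cor(e$imf[interior], sin(2 * pi * 20 * t)[interior]), 0.95)
})

test_that("non-positive stoppage criterion is a configuration error", {
  expect_error(extractIMF(rnorm(100), eps = 0), "positive")
  expect_error(extractIMF(rnorm(100), eps = -1), "positive")
  expect_error(emdDecompose(rnorm(100), eps = 0), "positive")
})

test_that("IMF definition check accepts canonical IMFs and rejects offsets", {
  t <- seq(0, 1 - 1e-3, by = 1e-3)
  expect_true(isIMF(sin(2 * pi * 10 * t)))
  expect_false(isIMF(sin(2 * pi * 10 * t) + 5))  # no zero-crossings
  expect_false(isIMF(seq(0, 1, length.out = 100)))
})

test_that("monotonic and constant inputs decompose to zero IMFs", {
  ramp <- seq(0, 1, length.out = 200)
  d <- emdDecompose(ramp)
  expect_equal(nIMF(d), 0L)
  expect_equal(imfResidue(d), ramp)

  dc <- emdDecompose(rep(2.5, 100))
  expect_equal(nIMF(dc), 0L)
  expect_equal(imfResidue(dc), rep(2.5, 100))
})

test_that("decomposition recovers two tones plus trend with a clean residue", {
  t <- seq(0, 7 - 1e-3, by = 1e-3)
  x <- sin(2 * pi * 20 * t) + sin(2 * pi * 2 * t) + 0.5 * t
  d <- emdDecompose(x)
  expect_gte(nIMF(d), 2L)
  interior <- seq(351, 6650)
  expect_gt(cor(imfMatrix(d)[1, interior], sin(2 * pi * 20 * t)[interior]),
            0.9)
  expect_gt(cor(imfMatrix(d)[2, interior], sin(2 * pi * 2 * t)[interior]),
            0.9)
  # the trend lives in the slow components beyond the two tones plus residue
  trendRec <- imfResidue(d)
  if (nIMF(d) > 2L) trendRec <- trendRec + colSums(imfMatrix(d)[-(1:2), , drop = FALSE])
  expect_gt(cor(trendRec[interior], t[interior]), 0.99)
})

test_that("decomposition is complete, deterministic, and emits true IMFs", {
  set.seed(99)
  for (i in 1:6) {
    x <- rnorm(1500) + cumsum(rnorm(1500, sd = 0.1))
    d <- emdDecompose(x)
    rec <- imfResidue(d)
    if (nIMF(d) > 0L) rec <- rec + colSums(imfMatrix(d))
    expect_lte(sqrt(sum((rec - x)^2) / sum(x^2)), 1e-8)
    for (j in seq_len(nIMF(d)))
      expect_true(isIMF(imfMatrix(d)[j, ]),
                  info = sprintf("case %d, IMF %d", i, j))
    d2 <- emdDecompose(x)
    expect_identical(imfMatrix(d), imfMatrix(d2))
    expect_identical(imfResidue(d), imfResidue(d2))
  }
})

test_that("IMF extrema counts decrease down the decomposition", {
  set.seed(5)
  for (i in 1:4) {
    d <- emdDecompose(rnorm(2000))
    nExt <- vapply(seq_len(nIMF(d)), function(j) {
      e <- findExtrema(imfMatrix(d)[j, ])
      length(e$maxima) + length(e$minima)
    }, 0L)
    if (length(nExt) > 1L)
      expect_true(all(diff(nExt) <= 1L))  # ordering within the +-1 slack
  }
})
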