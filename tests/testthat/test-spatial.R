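test_that("spatial map is the per-channel correlation with the IMF", {
  set.seed(3)
  imf <- sin(2 * pi * 15 * seq(0, 1 - 1e-3, 1e-3))
  d <- rbind(imf, rnorm(1000), -imf + rnorm(1000, sd = 0.01))
  ep <- quickEpoch(d, c("C3", "Cz", "C4"), fs = 1000, t0 = 0)
  m <- spatialMap(ep, imf)
  expect_equal(unname(m["C3"]), 1.0)
  expect_true(all(m >= -1 & m <= 1))
  expect_lt(m["C4"], -0.99)
})

test_that("zero-variance channels and IMFs are degenerate inputs", {
  d <- rbind(rnorm(100), rep(1, 100))
  ep <- quickEpoch(d, c("C3", "flat"), fs = 100, t0 = 0)
  expect_error(spatialMap(ep, rnorm(100)), "flat")
  ep2 <- quickEpoch(rbind(rnorm(100), rnorm(100)), fs = 100, t0 = 0)
  expect_error(spatialMap(ep2, rep(0, 100)), "zero variance")
})

test_that("spatial maps recover the sign pattern of forward weights", {
  set.seed(21)
  n <- 2000
  imf <- sin(2 * pi * 20 * seq_len(n) / 1000)
  w <- c(1, 0.6, 0.3, -0.4, 0.05, -0.8)
  snr <- sqrt(10)
  d <- outer(w, imf) + matrix(rnorm(6 * n, sd = sd(imf) / snr), 6, n)
  ep <- quickEpoch(d, fs = 1000, t0 = 0)
  m <- spatialMap(ep, imf)
  expect_true(all(sign(m) == sign(w)))
  expect_gt(cor(m, w, method = "spearman"), 0.9)
})

test_that("template correlation honors identity, antisymmetry, and alignment", {
  w <- c(1, 0.5, 0.2, 0.05)
  tpl <- spatialTemplate(w, c("C3", "FC3", "CP3", "Cz"), "C3")
  expect_equal(templateCorrelation(w, tpl), 1.0)
  expect_equal(templateCorrelation(-w, tpl), -1.0)
  named <- c(Cz = 0.05, C3 = 1, CP3 = 0.2, FC3 = 0.5)  # shuffled, named
  expect_equal(templateCorrelation(named, tpl), 1.0)
  expect_error(templateCorrelation(rep(1, 4), tpl), "degenerate|constant")
})

test_that("template correlation is invariant to affine rescaling", {
  set.seed(8)
  tpl <- spatialTemplate(runif(10), paste0("c", 1:10), "c1")
  m <- rnorm(10)
  base <- templateCorrelation(m, tpl)
  for (i in 1:10) {
    a <- runif(1, 0.1, 5)
    b <- rnorm(1, sd = 3)
    expect_equal(templateCorrelation(a * m + b, tpl), base)
  }
})

test_that("worked correlation example clusters IMF3 and IMF4 as high", {
  rho <- c(0.24, 0.35, 0.62, 0.81, 0.30, -0.03, 0.24, 0.33, 0.40)
  a <- clusterCorrelations(rho)
  expect_equal(which(a@labels == "high"), c(3L, 4L))
  expect_equal(min(rho[a@labels == "high"]), 0.62)
  expect_equal(unname(a@centroids["high"]), mean(c(0.62, 0.81)))
})

test_that("perfectly separated values give a zero-objective partition", {
  a <- clusterCorrelations(c(1, 1, 1, 0, 0, 0, -1, -1, -1))
  expect_equal(a@labels,
               rep(c("high", "middle", "low"), each = 3))
  expect_equal(a@objective, 0)
  expect_true(all(diff(a@centroids) < 0))
})

test_that("1-D 3-means equals independent exhaustive oracles", {
  set.seed(17)
  for (i in 1:40) {
    J <- sample(3:12, 1)
    v <- round(runif(J, -1, 1), 3)
    if (length(unique(v)) < 3) next
    a <- clusterCorrelations(v)
    ref <- refKmeans3Contiguous(v)
    expect_equal(a@objective, ref$objective, tolerance = 1e-12)
    expect_identical(canonicalPartition(match(a@labels, c("low", "middle", "high"))),
                     canonicalPartition(ref$group))
    if (J <= 8) {
      full <- refKmeans3Full(v)
      expect_equal(a@objective, full$objective, tolerance = 1e-12)
    }
  }
})

test_that("degenerate correlation sets raise selection errors", {
  expect_error(clusterCorrelations(rep(0.5, 5)), "identical")
  expect_error(clusterCorrelations(c(0.1, 0.2)), "at least 3")
  expect_s3_class(tryCatch(clusterCorrelations(rep(1, 4)), error = identity),
                  "betaSiftSelectionError")
})

# small fixture: epoch driven by two orthogonal oscillations, one aligned
# with a C3-focal template
makeSelectionFixture <- function(withNoise = TRUE, J2 = FALSE) {
  set.seed(31)
  n <- 2000
  t <- seq_len(n) / 1000
  s1 <- sin(2 * pi * 20 * t)            # template-aligned
  s2 <- sin(2 * pi * 3 * t)             # widespread
  w <- c(1, 0.7, 0.4, 0.1, 0.05)
  labels <- c("C3", "FC3", "CP3", "Cz", "Pz")
  d <- outer(w, s1) + outer(rep(1, 5), s2)
  if (withNoise) d <- d + matrix(rnorm(5 * n, sd = 0.1), 5, n)
  ep <- quickEpoch(d, labels, fs = 1000, t0 = 0)
  imfs <- if (J2) rbind(s1, s2) else rbind(s1, s2, 0.3 * sin(2 * pi * 47 * t))
  src <- colSums(imfs)
  iset <- new("IMFSet", imfs = imfs, residue = rep(0, n), sourceSignal = src,
              stoppageEps = 0.2, siftIters = rep(1L, nrow(imfs)),
              capped = rep(FALSE, nrow(imfs)))
  tpl <- spatialTemplate(w, labels, "C3")
  list(ep = ep, iset = iset, tpl = tpl, s1 = s1, s2 = s2)
}

test_that("selection keeps the template-aligned IMF and supports fallback", {
  fx <- makeSelectionFixture()
  sel <- selectIMFs(fx$iset, fx$ep, fx$tpl)
  expect_true(1L %in% sel$selected)
  expect_false(sel$fallback)

  fx2 <- makeSelectionFixture(J2 = TRUE)
  sel2 <- selectIMFs(fx2$iset, fx2$ep, fx2$tpl)
  expect_true(sel2$fallback)
  expect_equal(sel2$selected, 1L)
})

test_that("reconstruction obeys completeness and rejects empty selections", {
  fx <- makeSelectionFixture(withNoise = FALSE)
  all3 <- reconstructSignal(fx$iset, 1:3, mode = "ci")
  expect_equal(all3 + fx$iset@residue, fx$iset@sourceSignal,
               tolerance = 1e-12)
  expect_error(reconstructSignal(fx$iset, integer(0)), "empty")
  expect_error(reconstructSignal(fx$iset, 7L), "1..3", fixed = TRUE)
})

test_that("multichannel reconstruction of the aligned IMF suppresses the
           widespread component at the CI", {
  fx <- makeSelectionFixture()
  rec <- reconstructSignal(fx$iset, 1L, fx$ep, mode = "multichannel")
  expect_equal(dim(rec), dim(fx$ep@data))
  power <- function(x, f) {
    n <- length(x)
    fr <- (0:(n - 1)) / n * 1000
    Mod(fft(x)[which.min(abs(fr - f))])^2
  }
  raw <- fx$ep@data[1, ]
  att <- 10 * log10(power(rec[1, ], 3) / power(raw, 3))
  expect_lt(att, -20)
  keep <- 10 * log10(power(rec[1, ], 20) / power(raw, 20))
  expect_gt(keep, -1)
})
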