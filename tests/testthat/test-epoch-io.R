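test_that("native container round-trips arbitrary finite epochs exactly", {
  set.seed(42)
  ep <- quickEpoch(matrix(rnorm(8 * 300) * 50, 8, 300), fs = 250, t0 = -0.6)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEpoch(ep, f)
  back <- readEpoch(f)
  expect_identical(back@data, ep@data)
  expect_identical(channelLabels(back), channelLabels(ep))
  expect_identical(samplingRate(back), samplingRate(ep))
  expect_identical(t0Offset(back), t0Offset(ep))
})

test_that("malformed and non-finite epoch files are rejected with a named field", {
  f <- withr::local_tempfile(fileext = ".tsv")
  ep <- quickEpoch(matrix(1:20 + 0.5, 4, 5), fs = 5, t0 = 0)
  writeEpoch(ep, f)
  lines <- readLines(f)
  writeLines(c(lines[1], "wrong\t5", lines[3:length(lines)]), f)
  expect_error(readEpoch(f), "fs")

  writeLines(sub("^labels\tch1", "labels\tdup", lines), f)  # duplicate label
  lines2 <- readLines(f)
  lines2[6] <- "labels\tdup\tdup\tch3\tch4"
  writeLines(lines2, f)
  expect_error(readEpoch(f), "unique")

  lines[7] <- sub("^[^\t]*", "NaN", lines[7])
  writeLines(lines, f)
  expect_error(readEpoch(f), "finite")

  expect_error(readEpoch(tempfile()), "not found")
})

test_that("EDF reader agrees with an independent EDF writer within quantization", {
  set.seed(7)
  fs <- 1000
  data <- matrix(rnorm(32 * 2 * fs, sd = 40), 32, 2 * fs)
  labels <- sprintf("S%02d", 1:32)
  f <- withr::local_tempfile(fileext = ".edf")
  writeReferenceEDF(f, data, labels, fs)
  ep <- readEpoch(f, format = "edf", t0Offset = -1)
  expect_equal(samplingRate(ep), 1000)
  expect_equal(nChannels(ep), 32L)
  expect_identical(channelLabels(ep), labels)
  expect_equal(t0Offset(ep), -1)
  quant <- 1000 / 65535  # one digitization step of the +-500 uV range
  expect_lt(max(abs(ep@data - data)), quant)
})

test_that("EDF reader rejects inconsistent or truncated files", {
  f <- withr::local_tempfile(fileext = ".edf")
  writeReferenceEDF(f, matrix(0, 2, 200), c("a", "b"), fs = 100)
  raw <- readBin(f, "raw", file.size(f))
  writeBin(raw[1:400], f)  # truncate the data block
  expect_error(readEpoch(f, format = "edf"), "header|truncat|shorter")
})

test_that("half-open window slicing follows the sample-index arithmetic", {
  ep <- quickEpoch(matrix(seq_len(2 * 7000) + 0, 2, 7000), fs = 1000,
                   t0 = -4)
  seg <- windowSlice(ep, c(-3.5, -2.5))
  expect_equal(ncol(seg), 1000L)
  expect_equal(unname(seg[1, 1]), ep@data[1, 501])  # starts at index 501 (0-based 500)
  seg2 <- windowSlice(ep, c(0.5, 1.5))
  expect_equal(ncol(seg2), 1000L)
  expect_equal(unname(seg2[1, 1]), ep@data[1, 4501])
  expect_error(windowSlice(ep, c(2.5, 3.5)), "outside")
})

test_that("1-s windows yield exactly fs samples at any position", {
  ep <- quickEpoch(matrix(0, 2, 7000), fs = 1000, t0 = -4)
  for (start in c(-4, -3.2, -1.777, 0, 0.5, 1.999)) {
    expect_equal(ncol(windowSlice(ep, c(start, start + 1))), 1000L,
                 info = sprintf("start = %g", start))
  }
})

test_that("EOG artifact gate drops at the threshold and flags missing labels", {
  mk <- function(peak) {
    d <- matrix(0, 3, 100)
    d[3, 50] <- peak
    quickEpoch(d, c("C3", "C4", "VEOG"), fs = 100, t0 = 0)
  }
  expect_true(rejectArtifactEpoch(mk(99.9)))
  expect_false(rejectArtifactEpoch(mk(150)))
  expect_false(rejectArtifactEpoch(mk(100)))  # boundary: >= threshold drops
  expect_error(rejectArtifactEpoch(mk(0), eogLabels = "HEOG"), "missing")
  noEog <- quickEpoch(matrix(0, 2, 50), c("C3", "C4"), fs = 50, t0 = 0)
  expect_error(rejectArtifactEpoch(noEog), "EOG")
})
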