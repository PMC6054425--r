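test_that("flatfield normalization handles identity, scaling and clipping", {
  ff <- matrix(10, 3, 3)
  imgs <- array(10, c(3, 3, 4))
  m <- normalizeConcentration(RawImageStack(imgs, ff, 1), sourcePixel = c(1, 1))
  expect_true(all(frames(m) == 1))

  m2 <- normalizeConcentration(RawImageStack(imgs, ff, 2), sourcePixel = c(1, 1))
  expect_true(all(frames(m2) == 0.5))

  # over-subtracted background clips to zero
  imgs[2, 2, 1] <- -3
  m3 <- normalizeConcentration(RawImageStack(imgs, ff, 1), sourcePixel = c(1, 1))
  expect_identical(frames(m3)[2, 2, 1], 0)
  expect_identical(frames(m3)[2, 2, 2], 1)
})

test_that("normalization is homogeneous in the image intensities", {
  set.seed(3)
  ff <- matrix(runif(12, 5, 10), 3, 4)
  imgs <- array(runif(48, 0, 5), c(3, 4, 4))
  m1 <- normalizeConcentration(RawImageStack(imgs, ff, 1))
  m7 <- suppressWarnings(
    normalizeConcentration(RawImageStack(imgs * 7, ff, 1)))
  expect_equal(frames(m7), frames(m1) * 7, tolerance = 1e-12)
})

test_that("nonpositive flatfield pixels are masked, not infinite", {
  ff <- matrix(10, 3, 3); ff[1, 3] <- 0
  m <- normalizeConcentration(RawImageStack(array(10, c(3, 3, 2)), ff, 1))
  expect_false(validMask(m)[1, 3])
  expect_true(all(is.finite(frames(m))))
  expect_identical(frames(m)[1, 3, 1], 0)
})

test_that("stack validation rejects inconsistent shapes and bad calibration", {
  expect_error(RawImageStack(array(1, c(3, 3, 2)), matrix(1, 2, 2)),
               "flatfield")
  expect_error(RawImageStack(array(1, c(3, 3, 2)), matrix(1, 3, 3), -1),
               "calibrationCoefficient")
})

test_that("movie container round-trips bit-exactly, metadata included", {
  set.seed(11)
  m <- PlumeMovie(array(runif(120) * 3, c(4, 5, 6)), frameRate = 15,
                  pixelSize = 0.74, sourcePixel = c(2L, 3L),
                  validMask = matrix(c(TRUE, FALSE)[1 + (runif(20) < .2)], 4, 5),
                  label = "fast_flow_analog")
  f <- tempfile(fileext = ".pmv")
  writeMovie(m, f)
  m2 <- readMovie(f)
  expect_identical(frames(m2), frames(m))
  expect_identical(frameRate(m2), frameRate(m))
  expect_identical(pixelSize(m2), pixelSize(m))
  expect_identical(sourcePixel(m2), sourcePixel(m))
  expect_identical(validMask(m2), validMask(m))
  expect_identical(movieLabel(m2), movieLabel(m))

  # single-frame movie keeps its 3-d shape
  m1 <- PlumeMovie(matrix(runif(6), 2, 3), 15, 0.74, c(1L, 1L))
  f1 <- tempfile(); writeMovie(m1, f1)
  expect_identical(dim(frames(readMovie(f1))), c(2L, 3L, 1L))
})

test_that("malformed movie containers fail with the offending field named", {
  f <- tempfile()
  writeLines("not a movie", f)
  expect_error(readMovie(f), "magic")

  # corrupt the header: drop frame_rate_hz
  m <- PlumeMovie(array(1, c(2, 2, 2)), 15, 0.74, c(1L, 1L))
  f2 <- tempfile(); writeMovie(m, f2)
  raw <- readBin(f2, "raw", file.size(f2))
  hlen <- readBin(raw[7:10], "integer", size = 4, endian = "little")
  hdr <- rawToChar(raw[11:(10 + hlen)])
  hdr2 <- sub("frame_rate_hz", "framerate_oops", hdr)
  con <- file(f2, "wb")
  writeBin(raw[1:6], con)
  writeBin(nchar(hdr2), con, size = 4L, endian = "little")
  writeBin(charToRaw(hdr2), con)
  writeBin(raw[(11 + hlen):length(raw)], con)
  close(con)
  expect_error(readMovie(f2), "frame_rate_hz")
})

test_that("grid coordinates map to pixels by the stated convention", {
  m <- PlumeMovie(array(1, c(100, 100, 2)), 15, pixelSize = 0.74,
                  sourcePixel = c(50L, 20L))
  g <- SamplingGrid(rbind(c(2.2, 0), c(0, 0)), jitterRadius = 0L)
  pix <- gridToPixelIndices(g, m)
  expect_identical(pix[1, ], c(row = 50L, col = 20L + 30L))  # round(22/0.74)
  expect_identical(pix[2, ], c(row = 50L, col = 20L))        # origin

  # rigid translation: every pixel shifts by exactly the offset
  pixOff <- gridToPixelIndices(g, m, offset = c(3L, 3L))
  expect_identical(pixOff - pix, cbind(row = c(3L, 3L), col = c(3L, 3L)))
  # pairwise displacements are offset-invariant
  expect_identical(diff(pix[, "col"]), diff(pixOff[, "col"]))
})

test_that("out-of-bounds and masked placements raise placement errors", {
  m <- PlumeMovie(array(1, c(10, 10, 2)), 15, 10, c(5L, 5L))
  g <- SamplingGrid(rbind(c(30, 0), c(0, 0)), jitterRadius = 0L)
  expect_error(gridToPixelIndices(g, m), "outside the frame")

  mask <- matrix(TRUE, 10, 10); mask[5, 7] <- FALSE
  m2 <- PlumeMovie(array(1, c(10, 10, 2)), 15, 10, c(5L, 5L),
                   validMask = mask)
  g2 <- SamplingGrid(rbind(c(2, 0), c(0, 0)), jitterRadius = 0L)
  expect_error(gridToPixelIndices(g2, m2), "masked")
})

test_that("preset grids carry 16 locations each and round-trip through CSV", {
  gn <- gridPreset("narrow"); gw <- gridPreset("wide")
  expect_identical(nrow(gridPoints(gn)), 16L)
  expect_identical(nrow(gridPoints(gw)), 16L)
  expect_setequal(unique(gridPoints(gn)[, "x_cm"]), c(2.2, 5.9, 9.6, 13.3))
  expect_setequal(unique(gridPoints(gw)[, "y_cm"]), c(-2.6, -1.1, 1.1, 2.6))
  expect_true(any(jitterOffsets(gn)[, 1] == 0 & jitterOffsets(gn)[, 2] == 0))

  f <- tempfile(fileext = ".csv")
  writeGridCSV(gn, f)
  g2 <- readGridCSV(f)
  expect_equal(gridPoints(g2), gridPoints(gn))

  # shipped preset file agrees with the in-code presets
  shipped <- system.file("extdata", "grid_presets.csv", package = "plumeMI")
  expect_equal(gridPoints(readGridCSV(shipped, "wide")), gridPoints(gw))
  expect_error(readGridCSV(shipped, "nope"), "no grid named")
})
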