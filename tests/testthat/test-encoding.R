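test_that("equalized boundaries land at the expected quantile cutpoints", {
  b1 <- equalizedBoundaries(0:99, 1)
  expect_equal(cutpoints(b1), 49.5)

  b2 <- equalizedBoundaries(0:99, 2)
  expect_equal(cutpoints(b2), c(24.5, 49.5, 74.5))

  # massive ties collapse to a single separating cutpoint
  bt <- equalizedBoundaries(c(rep(0, 90), rep(1, 10)), 2)
  expect_length(cutpoints(bt), 1L)
  expect_gt(cutpoints(bt), 0)
  expect_lte(cutpoints(bt), 1)
  expect_identical(effectiveBins(bt), 2L)

  expect_error(equalizedBoundaries(0:99, 0), "nBits")
})

test_that("equalized bins have occupancies equal within one sample on
           tie-free data", {
  set.seed(21)
  for (nBits in 1:4) {
    x <- rlnorm(4096)
    b <- equalizedBoundaries(x, nBits)
    occ <- tabulate(discretize(x, b) + 1L, nbins = effectiveBins(b))
    expect_lte(max(occ) - min(occ), 1L)
  }
})

test_that("discretize follows the upper-bin-on-ties convention and is
           monotone", {
  b <- BinBoundaries(0.5)
  expect_identical(discretize(0.3, b), 0L)
  expect_identical(discretize(0.7, b), 1L)
  expect_identical(discretize(0.5, b), 1L)  # tie goes up

  b3 <- BinBoundaries(c(0.2, 0.5, 0.8))
  expect_identical(discretize(c(0.1, 0.35, 0.65, 0.9), b3), c(0L, 1L, 2L, 3L))

  set.seed(8)
  x <- sort(runif(200, -1, 2))
  expect_true(all(diff(discretize(x, b3)) >= 0))
})

test_that("greedy search separates separable locations and breaks ties low", {
  samp <- list(rep(0.1, 50), rep(0.9, 50))
  b <- greedyBoundaries(samp, 1, candidateCount = 32L)
  cand <- plumeMI:::.greedyCandidates(unlist(samp), 32L)
  mi <- vapply(cand, function(cv) {
    cnt <- t(vapply(samp, function(s) c(sum(s < cv), sum(s >= cv)),
                    numeric(2)))
    pluginMutualInformation(cnt)
  }, numeric(1))
  # perfect 1-bit code, and the tie-break picks the lowest maximizing value
  expect_equal(max(mi), 1)
  expect_equal(cutpoints(b), min(cand[mi == max(mi)]))
})

test_that("first greedy cut equals the exhaustive single-cut optimum", {
  for (r in 1:20) {
    set.seed(r)
    samp <- lapply(1:4, function(i) rlnorm(200, meanlog = i / 2, sdlog = 1))
    b <- greedyBoundaries(samp, 1, candidateCount = 64L)
    # independent oracle: brute force over the identical candidate set
    cand <- plumeMI:::.greedyCandidates(unlist(samp), 64L)
    mi <- vapply(cand, function(cv) {
      cnt <- t(vapply(samp, function(s) c(sum(s < cv), sum(s >= cv)),
                      numeric(2)))
      pluginMutualInformation(cnt)
    }, numeric(1))
    expect_equal(cutpoints(b), cand[which.max(mi)])
  }
})

test_that("greedy MI is non-decreasing in the number of cuts", {
  set.seed(5)
  samp <- lapply(1:4, function(i) rlnorm(300, i / 3, 0.8))
  mis <- vapply(1:4, function(nb) {
    b <- greedyBoundaries(samp, nb, 128L)
    cnt <- t(vapply(samp, function(s) {
      tabulate(discretize(s, b) + 1L, nbins = effectiveBins(b))
    }, numeric(effectiveBins(b))))
    pluginMutualInformation(cnt)
  }, numeric(1))
  expect_true(all(diff(mis) >= -1e-12))
})

test_that("sample blocks honor sensor geometry and temporal spacing", {
  m <- tinyMovie(H = 8L, W = 8L, TT = 30L)
  g <- SamplingGrid(rbind(c(2, 2), c(1, 1)), jitterRadius = 0L)

  # transverse pair straddles the grid point at +/- spacing/2 along rows
  sch <- EncodingScheme(1, rSpat = 2L, sensorSpacing = 4L)
  blk <- extractSampleBlock(m, g, sch)
  pix <- gridToPixelIndices(g, m)
  fr <- frames(m)
  expect_equal(blk@draws[[1]][, 1, 1],
               fr[pix[1, 1] - 2L, pix[1, 2], ])
  expect_equal(blk@draws[[1]][, 2, 1],
               fr[pix[1, 1] + 2L, pix[1, 2], ])

  # longitudinal pair straddles along columns
  schL <- EncodingScheme(1, rSpat = 2L, sensorSpacing = 4L,
                         sensorOrientation = "longitudinal")
  blkL <- extractSampleBlock(m, g, schL)
  expect_equal(blkL@draws[[1]][, 1, 1], fr[pix[1, 1], pix[1, 2] - 2L, ])

  # the tabulated delay: 1.6 s at 15 Hz is 24 frames
  expect_identical(EncodingScheme(5, rTemp = 2L)@interSampleFrames, 24L)

  # two temporal samples at interval d use frames t and t + d, sliding
  schT <- EncodingScheme(1, rTemp = 2L, interSampleFrames = 7L)
  blkT <- extractSampleBlock(m, g, schT)
  expect_identical(dim(blkT@draws[[1]]), c(30L - 7L, 1L, 2L))
  expect_equal(blkT@draws[[1]][, 1, 2], fr[pix[1, 1], pix[1, 2], 8:30])

  # identity sampling: one value per frame
  blk1 <- extractSampleBlock(m, g, EncodingScheme(1))
  expect_equal(blk1@draws[[2]][, 1, 1], fr[pix[2, 1], pix[2, 2], ])

  # sensors pushed off the frame raise a placement error
  gEdge <- SamplingGrid(rbind(c(0, -1), c(2, 2)), jitterRadius = 0L)
  expect_error(extractSampleBlock(m, gEdge,
                                  EncodingScheme(1, rSpat = 2L,
                                                 sensorSpacing = 40L)),
               "outside the frame")
})

test_that("word formation distinguishes labeled/ordered codes and collapses
           their multiset variants", {
  # two draws with swapped sensor readings
  arr <- array(0, c(2, 2, 1))
  arr[1, , 1] <- c(0.9, 0.1)
  arr[2, , 1] <- c(0.1, 0.9)
  blk <- SampleBlock(list(arr))
  b <- BinBoundaries(0.5)

  lab <- formWords(blk, b, EncodingScheme(1, rSpat = 2L))[[1]]
  expect_false(lab[1] == lab[2])
  unl <- formWords(blk, b, EncodingScheme(1, rSpat = 2L,
                                          sensorLabeled = FALSE))[[1]]
  expect_identical(unl[1], unl[2])

  # ordered triples (1,0,1) vs (0,1,1): distinct ordered, equal as multisets
  arrT <- array(0, c(2, 1, 3))
  arrT[1, 1, ] <- c(0.9, 0.1, 0.9)
  arrT[2, 1, ] <- c(0.1, 0.9, 0.9)
  blkT <- SampleBlock(list(arrT))
  ordW <- formWords(blkT, b, EncodingScheme(1, rTemp = 3L))[[1]]
  expect_false(ordW[1] == ordW[2])
  ignW <- formWords(blkT, b, EncodingScheme(1, rTemp = 3L,
                                            timeOrdered = FALSE))[[1]]
  expect_identical(ignW[1], ignW[2])

  # single sample: the word is the bin index
  arr1 <- array(c(0.1, 0.9), c(2, 1, 1))
  w1 <- formWords(SampleBlock(list(arr1)), b, EncodingScheme(1))[[1]]
  expect_identical(w1, c("0", "1"))
})

test_that("multiset collapsing sorts tokens numerically, not as bare
           strings", {
  # 12 bins: indices 9 and 10 would misorder under naive string sort
  b <- BinBoundaries(seq(0.5, 10.5, by = 1))
  arr <- array(0, c(2, 1, 2))
  arr[1, 1, ] <- c(10, 9)
  arr[2, 1, ] <- c(9, 10)
  w <- formWords(SampleBlock(list(arr)), b,
                 EncodingScheme(4, rTemp = 2L, timeOrdered = FALSE))[[1]]
  expect_identical(w[1], w[2])
})

test_that("word tabulation equalizes draw counts and schemes round-trip
           through YAML", {
  counts <- wordCounts(list(c("a", "b", "a", "b"), c("a", "a", "b")))
  expect_identical(drawsPerLocation(counts), 3)

  sch <- EncodingScheme(3, rSpat = 2L, rTemp = 2L, binning = "greedy",
                        sensorOrientation = "longitudinal",
                        interSampleFrames = 12L, sensorLabeled = FALSE)
  f <- tempfile(fileext = ".yaml")
  writeEncodingScheme(sch, f)
  sch2 <- readEncodingScheme(f)
  expect_identical(totalBits(sch2), totalBits(sch))
  expect_identical(sch2@sensorOrientation, "longitudinal")
  expect_identical(sch2@sensorLabeled, FALSE)

  fx <- EncodingScheme(1, binning = "fixed", boundaries = BinBoundaries(0.3))
  f2 <- tempfile(fileext = ".yaml")
  writeEncodingScheme(fx, f2)
  expect_equal(cutpoints(readEncodingScheme(f2)@boundaries), 0.3)

  wf <- tempfile(fileext = ".csv")
  wordsToCSV(list(c("0", "1"), c("1", "1")), wf)
  df <- read.csv(wf, colClasses = c("integer", "integer", "character"))
  expect_identical(nrow(df), 4L)
  expect_identical(df$word[1], "0")
})
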