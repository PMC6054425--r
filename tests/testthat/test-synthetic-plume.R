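test_that("both generators are deterministic under a fixed seed", {
  p <- presetScenario("fast_flow_analog")
  p@durationS <- 4
  expect_identical(frames(simulatePuffPlume(p)), frames(simulatePuffPlume(p)))

  sp <- SurrogateFieldParams(matrix(0.3, 3, 3), nFrames = 300L, seed = 4L)
  expect_identical(frames(simulateSurrogateField(sp)),
                   frames(simulateSurrogateField(sp)))
})

test_that("time-averaged centerline concentration decreases downstream
           when the meander is off", {
  p <- PuffPlumeParams(meanderAmplitude = 0, puffGrowthRate = 0.1,
                       puffMassDecayRate = 0.3, durationS = 60,
                       noiseSd = 0, seed = 2L)
  m <- simulatePuffPlume(p)
  sp <- sourcePixel(m)
  meanField <- apply(frames(m)[sp[1], , ], 1, mean)
  r0px <- ceiling(3 * p@initialPuffRadius * 10 / p@pixelSizeMm)
  beyond <- (sp[2] + r0px):dim(frames(m))[2]
  # strictly decreasing within 1% of the source value
  expect_true(max(diff(meanField[beyond])) < 0.01)
})

test_that("doubling the release rate doubles the pre-normalization mean", {
  ratios <- vapply(1:5, function(s) {
    m1 <- simulatePuffPlume(PuffPlumeParams(puffReleaseRate = 5,
                                            durationS = 40, noiseSd = 0,
                                            seed = s), normalize = FALSE)
    m2 <- simulatePuffPlume(PuffPlumeParams(puffReleaseRate = 10,
                                            durationS = 40, noiseSd = 0,
                                            seed = s + 100L),
                            normalize = FALSE)
    mean(frames(m2)) / mean(frames(m1))
  }, numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.1)
})

test_that("a parameter set yielding zero puffs warns and returns zeros", {
  p <- PuffPlumeParams(puffReleaseRate = 1e-6, durationS = 2, noiseSd = 0,
                       seed = 1L)
  expect_warning(m <- simulatePuffPlume(p), "no puffs")
  expect_true(all(frames(m) == 0))
})

test_that("surrogate marginals: q == 0 gives a silent movie and configured
           q is recovered within the 99% binomial interval", {
  p0 <- SurrogateFieldParams(matrix(0, 2, 2), nFrames = 500L, seed = 1L)
  expect_true(all(frames(simulateSurrogateField(p0)) == 0))

  # near-independent frames: state decorrelates well inside one frame
  for (s in 1:3) {
    p <- SurrogateFieldParams(matrix(0.3, 2, 2), whiffMeanS = 0.02,
                              blankMeanS = 0.02 * 7 / 3,
                              nFrames = 10000L, seed = s)
    qhat <- mean(frames(simulateSurrogateField(p))[1, 1, ] > 0)
    ci <- 0.3 + c(-1, 1) * qnorm(0.995) * sqrt(0.3 * 0.7 / 10000)
    expect_gt(qhat, ci[1])
    expect_lt(qhat, ci[2])
  }
})

test_that("zero correlation length makes distant pixels independent;
           a large one shares their switching", {
  p <- SurrogateFieldParams(matrix(0.3, 2, 2), whiffMeanS = 0.05,
                            blankMeanS = 0.05 * 7 / 3,
                            nFrames = 10000L, seed = 7L,
                            correlationLengthCm = 0)
  fr <- frames(simulateSurrogateField(p))
  expect_lt(abs(cor(fr[1, 1, ] > 0, fr[2, 2, ] > 0)), 0.05)

  pc <- SurrogateFieldParams(matrix(0.3, 2, 2), nFrames = 3000L, seed = 7L,
                             correlationLengthCm = 10, pixelSizeMm = 2.5)
  frc <- frames(simulateSurrogateField(pc))
  expect_gt(cor(frc[1, 1, ] > 0, frc[2, 2, ] > 0), 0.3)
})

test_that("nonzero surrogate amplitudes follow the configured log-normal", {
  p <- SurrogateFieldParams(matrix(0.5, 1, 1), whiffMeanS = 0.04,
                            blankMeanS = 0.04, amplitudeMedianField = 1.5,
                            amplitudeSdlog = 0.5, nFrames = 10000L,
                            seed = 12L)
  x <- frames(simulateSurrogateField(p))[1, 1, ]
  x <- x[x > 0]
  # consecutive frames can share a whiff (same held amplitude); KS needs
  # unique event amplitudes
  x <- x[c(TRUE, diff(x) != 0)]
  ks <- suppressWarnings(
    ks.test(x, function(q) plnorm(q, meanlog = log(1.5), sdlog = 0.5)))
  expect_gt(ks$p.value, 0.01)
})

test_that("preset scenarios match the tabulated wind speeds and reject
           unknown names", {
  expect_identical(presetScenario("fast_flow_analog")@meanWindSpeed, 10)
  expect_identical(presetScenario("slow_flow_analog")@meanWindSpeed, 5)
  expect_identical(presetScenario("boundary_flow_analog")@meanWindSpeed, 10)
  expect_gt(presetScenario("boundary_flow_analog")@puffGrowthRate,
            presetScenario("fast_flow_analog")@puffGrowthRate)
  expect_error(presetScenario("turbo"), "fast_flow_analog")
})

test_that("centerline intermittency decreases downstream on the presets", {
  for (nm in c("fast_flow_analog", "slow_flow_analog")) {
    p <- presetScenario(nm, seed = 3L)
    p@durationS <- 60
    m <- simulatePuffPlume(p)
    sp <- sourcePixel(m)
    whiffFrac <- apply(frames(m)[sp[1], , ] > 0.01, 1, mean)
    near <- whiffFrac[sp[2] + 10L]
    far <- whiffFrac[sp[2] + 80L]
    expect_gt(near, far)
  }
})

test_that("scenario parameters round-trip through YAML", {
  p <- presetScenario("slow_flow_analog", seed = 9L)
  f <- tempfile(fileext = ".yaml")
  writeScenarioYAML(p, f)
  p2 <- readScenarioYAML(f)
  for (s in methods::slotNames(p)) {
    expect_equal(methods::slot(p2, s), methods::slot(p, s), info = s)
  }
})

test_that("surrogate validation rejects q above the stationary whiff
           probability", {
  expect_error(
    SurrogateFieldParams(matrix(0.9, 2, 2), whiffMeanS = 1, blankMeanS = 1),
    "stationary whiff probability")
})
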