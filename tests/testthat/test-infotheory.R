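test_that("entropy matches closed forms and validates input", {
  expect_identical(shannonEntropy(rep(1, 16)), 4)
  expect_identical(shannonEntropy(c(1, 1, 1, 1)), 2)
  expect_equal(shannonEntropy(c(0.8, 0.2)),
               -(0.8 * log2(0.8) + 0.2 * log2(0.2)), tolerance = 1e-12)
  expect_identical(shannonEntropy(c(1, 0, 0)), 0)
  expect_error(shannonEntropy(c(0.5, -0.1)), "nonnegative")
  expect_error(shannonEntropy(c(0, 0)), "all zero")
})

test_that("plug-in MI matches closed forms on canonical tables", {
  expect_equal(pluginMutualInformation(rbind(c(40, 10), c(10, 40))),
               1 + 0.8 * log2(0.8) + 0.2 * log2(0.2), tolerance = 1e-12)
  # identical rows: independence
  expect_identical(pluginMutualInformation(rbind(c(3, 7), c(3, 7))), 0)
  # noiseless channel saturates log2 |L|
  expect_identical(pluginMutualInformation(diag(16) * 5), 4)
  expect_error(pluginMutualInformation(rbind(c(1, 2), c(2, 2))),
               "unequal row sums")
  expect_error(pluginMutualInformation(rbind(c(-1, 2), c(2, -1))),
               "nonnegative")
})

test_that("the conditional-entropy form equals the symmetric joint form", {
  set.seed(31)
  for (r in 1:20) {
    n <- sample(3:8, 1)
    w <- sample(2:10, 1)
    cnt <- matrix(rpois(n * w, 3), n, w)
    cnt[, 1] <- cnt[, 1] + max(rowSums(cnt)) - rowSums(cnt)  # equalize rows
    # independent oracle: direct sum over the joint
    pj <- cnt / sum(cnt)
    pl <- rowSums(pj); pm <- colSums(pj)
    ref <- 0
    for (i in seq_len(n)) for (j in seq_len(w)) {
      if (pj[i, j] > 0) {
        ref <- ref + pj[i, j] * log2(pj[i, j] / (pl[i] * pm[j]))
      }
    }
    expect_equal(pluginMutualInformation(cnt), ref, tolerance = 1e-12)
  }
})

test_that("merging word symbols never increases MI (exhaustive merges)", {
  set.seed(13)
  for (r in 1:10) {
    w <- sample(3:8, 1)
    cnt <- matrix(rpois(4 * w, 4), 4, w)
    cnt[, 1] <- cnt[, 1] + max(rowSums(cnt)) - rowSums(cnt)
    base <- pluginMutualInformation(cnt)
    for (i in seq_len(w - 1)) for (j in (i + 1):w) {
      merged <- cnt[, -j, drop = FALSE]
      merged[, i] <- cnt[, i] + cnt[, j]
      expect_lte(pluginMutualInformation(merged), base + 1e-12)
    }
  }
})

test_that("plug-in MI is upwardly biased for a nondegenerate joint", {
  mis <- vapply(1:100, function(s) {
    set.seed(s)
    w <- knownJointWords(n = 60, seed = s)
    pluginMutualInformation(wordCounts(w))
  }, numeric(1))
  expect_gte(mean(mis), TRUE_MI_2x2)
})

test_that("degenerate extrapolation with fractions = {1} returns the raw
           estimate with zero slope", {
  w <- knownJointWords(n = 100, seed = 2)
  e <- debiasByExtrapolation(w, fractions = 1, repetitions = 1L, seed = 1L)
  expect_identical(miDebiased(e), miRaw(e))
  expect_identical(biasSlope(e), 0)
})

test_that("extrapolation drives the independent-channel estimate to zero
           and its slope matches the first-order bias within a factor of 2", {
  raws <- debs <- slopes <- numeric(10)
  for (s in 1:10) {
    w <- independentWords(seed = s)
    e <- debiasByExtrapolation(w, seed = s)
    raws[s] <- miRaw(e); debs[s] <- miDebiased(e); slopes[s] <- biasSlope(e)
  }
  expect_true(all(raws > 0.02))
  expect_true(all(debs < 0.01))
  # analytic first-order bias slope: (|W|-1)(|L|-1)/(2 ln 2) bits * samples
  analytic <- 15 * 15 / (2 * log(2))
  expect_true(all(slopes / analytic > 0.5 & slopes / analytic < 2))
})

test_that("extrapolation is deterministic given a seed and validates
           fractions", {
  w <- knownJointWords(n = 120, seed = 5)
  e1 <- debiasByExtrapolation(w, seed = 42L)
  e2 <- debiasByExtrapolation(w, seed = 42L)
  expect_identical(subsetPoints(e1), subsetPoints(e2))
  expect_error(debiasByExtrapolation(w, fractions = c(0.5, 0.25)),
               "contain 1")
  expect_error(debiasByExtrapolation(w, fractions = c(1, 2)), "\\(0, 1\\]")
  expect_error(debiasByExtrapolation(list(rep("a", 4), rep("b", 4)),
                                     fractions = c(1, 0.1)),
               "fewer than one draw")
})

test_that("word-distribution entropy bounds and collapses as expected", {
  expect_identical(wordDistributionEntropy(list(rep("3-1", 50))), 0)

  set.seed(6)
  w <- replicate(4, vapply(1:80, function(i) {
    paste(sample(0:3, 3, replace = TRUE), collapse = "-")
  }, character(1)), simplify = FALSE)
  expect_lte(wordDistributionEntropy(w, ignoreOrder = TRUE),
             wordDistributionEntropy(w) + 1e-12)

  # 3-bit equalized single-sample code on tie-free data: entropy ~ 3 bits
  x <- rlnorm(16000)
  b <- equalizedBoundaries(x, 3)
  words <- list(as.character(discretize(x, b)))
  expect_equal(wordDistributionEntropy(words), 3, tolerance = 0.01)
})

test_that("count tables round-trip through CSV", {
  cnt <- LocationSymbolCounts(rbind(c(5, 3, 2), c(1, 4, 5)),
                              wordIds = c("0", "1", "2"))
  f <- tempfile(fileext = ".csv")
  countsToCSV(cnt, f)
  cnt2 <- countsFromCSV(f)
  expect_equal(countsMatrix(cnt2), countsMatrix(cnt),
               ignore_attr = TRUE)
  expect_identical(cnt2@wordIds, cnt@wordIds)
})
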