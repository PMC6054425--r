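# Orchestration of the analysis families: MI sweeps over coding schemes,
# threshold curves, sensor allocation tables, interval curves, and jitter
# envelopes.

# single-sample concentrations at the grid points, per location
.singleSampleValues <- function(movie, grid, offset = c(0L, 0L)) {
  pix <- gridToPixelIndices(grid, movie, offset)
  lapply(seq_len(nrow(pix)), function(i) {
    movie@frames[pix[i, 1], pix[i, 2], ]
  })
}

# boundary design on single-sample statistics (pooled for equalization,
# per-location for the greedy search), as used by every multi-sample scheme
.designBoundaries <- function(movie, grid, scheme, offset = c(0L, 0L),
                              candidateCount = 512L) {
  if (scheme@binning == "fixed") return(scheme@boundaries)
  samples <- .singleSampleValues(movie, grid, offset)
  if (scheme@binning == "equalize") {
    equalizedBoundaries(unlist(samples, use.names = FALSE), scheme@nBits)
  } else {
    greedyBoundaries(samples, scheme@nBits, candidateCount)
  }
}

# alphabet-size bias guard: hard error when the naive alphabet exceeds the
# draw count, warning when it exceeds a tenth of it
.biasGuard <- function(totalBits, draws) {
  alphabet <- 2^totalBits
  if (alphabet > draws) {
    stop(sprintf(
      "alphabet of 2^%d words exceeds %d draws/location; estimates would be meaningless",
      totalBits, draws), call. = FALSE)
  }
  if (alphabet > draws / 10) {
    warning(sprintf(
      "alphabet of 2^%d words exceeds draws/location / 10 (%d draws); plug-in MI will be strongly biased",
      totalBits, draws), call. = FALSE)
  }
  invisible(alphabet)
}

#' Encode a movie at one grid placement and estimate location information
#'
#' Designs bin boundaries (on single-sample statistics at this placement,
#' unless supplied), extracts the sample block, forms code words, applies
#' the alphabet-size bias guard, and estimates MI with 1/N extrapolation.
#' Following the convention that single-bit codes are reported raw, the
#' debiasing step is applied only to schemes using more than one total bit.
#'
#' @param movie a \code{\link{PlumeMovie}}
#' @param grid a \code{\link{SamplingGrid}}
#' @param scheme an \code{\link{EncodingScheme}}
#' @param offset rigid (dx, dy) pixel shift
#' @param boundaries optional \code{\link{BinBoundaries}} overriding design
#' @param debias run the 1/N extrapolation
#' @param fractions,repetitions,seed passed to
#'   \code{\link{debiasByExtrapolation}}
#' @param candidateCount candidates for greedy boundary design
#' @return a list with elements \code{estimate} (\code{\link{MIEstimate}}),
#'   \code{words}, \code{counts}, \code{boundaries}
#' @export
schemeMI <- function(movie, grid, scheme, offset = c(0L, 0L),
                     boundaries = NULL, debias = TRUE,
                     fractions = c(1, 1/2, 1/4, 1/8), repetitions = 10L,
                     seed = 1L, candidateCount = 512L) {
  if (is.null(boundaries)) {
    boundaries <- .designBoundaries(movie, grid, scheme, offset,
                                    candidateCount)
  }
  block <- extractSampleBlock(movie, grid, scheme, offset)
  .biasGuard(totalBits(scheme), drawsPerLocation(block))
  words <- formWords(block, boundaries, scheme)
  counts <- wordCounts(words)
  if (debias && totalBits(scheme) > 1L) {
    est <- debiasByExtrapolation(words, fractions, repetitions, seed)
  } else {
    mi <- pluginMutualInformation(counts)
    est <- MIEstimate(miRaw = mi, miDebiased = mi, miExtrapolated = mi,
                      biasSlope = 0,
                      subsetPoints = data.frame(invN = 1 / sum(counts@counts),
                                                mi = mi),
                      nTotal = sum(counts@counts))
  }
  list(estimate = est, words = words, counts = counts,
       boundaries = boundaries)
}

#' Run an analysis at every rigid jitter placement
#'
#' Repeats a per-placement analysis at every offset (dx, dy) with dx, dy in
#' -radius..radius pixels ((2 radius + 1)^2 placements, the center
#' included) and reports, for every metric the analysis returns, the center
#' value and the min/max envelope over all placements.
#'
#' @param movie a \code{\link{PlumeMovie}}
#' @param grid a \code{\link{SamplingGrid}}
#' @param analysisFun function(offset) returning a named numeric vector
#' @param jitterRadius nonnegative integer radius in pixels
#' @return data.frame with columns metric, center, jitterMin, jitterMax,
#'   nPlacements
#' @export
jitteredAnalysis <- function(movie, grid, analysisFun, jitterRadius = 3L) {
  offsets <- .jitterOffsetGrid(jitterRadius)
  vals <- lapply(seq_len(nrow(offsets)), function(i) {
    off <- c(offsets[i, 1], offsets[i, 2])
    tryCatch(analysisFun(off), error = function(e) {
      stop(sprintf("placement (dx=%d, dy=%d) failed: %s",
                   off[1], off[2], conditionMessage(e)), call. = FALSE)
    })
  })
  center <- vals[[which(offsets[, 1] == 0 & offsets[, 2] == 0)]]
  m <- do.call(rbind, vals)
  data.frame(metric = names(center), center = unname(center),
             jitterMin = apply(m, 2, min), jitterMax = apply(m, 2, max),
             nPlacements = nrow(offsets), row.names = NULL)
}

# jitter-envelope debiasing: slope fitted once at the center placement,
# slope/N subtracted at the other placements (per-placement refits behind
# the perPlacementDebias flag)
.placementMI <- function(movie, grid, scheme, offset, centerSlope,
                         freezeBoundaries = NULL, debias = TRUE,
                         fractions = c(1, 1/2, 1/4, 1/8),
                         repetitions = 10L, seed = 1L,
                         candidateCount = 512L, perPlacementDebias = FALSE) {
  if (perPlacementDebias) {
    res <- schemeMI(movie, grid, scheme, offset,
                    boundaries = freezeBoundaries, debias = debias,
                    fractions = fractions, repetitions = repetitions,
                    seed = seed, candidateCount = candidateCount)
    return(miDebiased(res$estimate))
  }
  res <- schemeMI(movie, grid, scheme, offset, boundaries = freezeBoundaries,
                  debias = FALSE, candidateCount = candidateCount)
  raw <- miRaw(res$estimate)
  if (debias && totalBits(scheme) > 1L) {
    max(0, raw - centerSlope / res$estimate@nTotal)
  } else {
    raw
  }
}

#' MI as a function of bits per sample, for one resource family
#'
#' Sweeps the bits-per-sample budget for one of the three allocation
#' families: all bits to a single sample ("single", S(n;1,1)), bits
#' applied to two spatially separated sensors ("spatial", S(n;2,1), which
#' additionally reports the sensor-unlabeled variant), or to two temporal
#' samples ("temporal", S(n;1,2)). Boundaries are recomputed per jitter
#' placement (set \code{freezeBoundaries = TRUE} to reuse the center
#' design); the 1/N bias slope is fitted at the center placement and
#' subtracted at jittered placements.
#'
#' @param movie a \code{\link{PlumeMovie}}
#' @param grid a \code{\link{SamplingGrid}}
#' @param family "single", "spatial" or "temporal"
#' @param nBitsRange integer vector of per-sample bit budgets
#' @param binning "equalize" or "greedy"
#' @param jitterRadius jitter envelope radius (0 disables the envelope)
#' @param debias subtract the fitted 1/N bias (schemes with > 1 total bit)
#' @param freezeBoundaries reuse the center-placement boundary design at
#'   jittered placements
#' @param fractions,repetitions,seed subset-extrapolation controls
#' @param candidateCount greedy candidate count
#' @param interSampleFrames temporal spacing for the "temporal" family
#' @param sensorSpacing,sensorOrientation sensor geometry for "spatial"
#' @return data.frame, one row per (nBits, labeled) combination, with raw,
#'   debiased and jitter-envelope MI in bits
#' @export
sweepConcentrationBits <- function(movie, grid,
                                   family = c("single", "spatial", "temporal"),
                                   nBitsRange = 1:6, binning = "equalize",
                                   jitterRadius = 3L, debias = TRUE,
                                   freezeBoundaries = FALSE,
                                   fractions = c(1, 1/2, 1/4, 1/8),
                                   repetitions = 10L, seed = 1L,
                                   candidateCount = 512L,
                                   interSampleFrames = 24L,
                                   sensorSpacing = 4L,
                                   sensorOrientation = "transverse") {
  family <- match.arg(family)
  rSpat <- if (family == "spatial") 2L else 1L
  rTemp <- if (family == "temporal") 2L else 1L
  offsets <- .jitterOffsetGrid(jitterRadius)
  rows <- list()
  for (n in nBitsRange) {
    scheme <- EncodingScheme(n, rSpat = rSpat, rTemp = rTemp,
                             binning = binning,
                             sensorSpacing = sensorSpacing,
                             sensorOrientation = sensorOrientation,
                             interSampleFrames = interSampleFrames)
    center <- schemeMI(movie, grid, scheme, c(0L, 0L), debias = debias,
                       fractions = fractions, repetitions = repetitions,
                       seed = seed, candidateCount = candidateCount)
    slope <- biasSlope(center$estimate)
    centerBnd <- if (freezeBoundaries) center$boundaries else NULL
    variants <- if (family == "spatial") c(TRUE, FALSE) else TRUE
    for (lab in variants) {
      sch <- scheme
      sch@sensorLabeled <- lab
      if (lab) {
        centerDeb <- miDebiased(center$estimate)
        centerRaw <- miRaw(center$estimate)
        slopeU <- slope
      } else {
        wordsU <- formWords(extractSampleBlock(movie, grid, sch, c(0L, 0L)),
                            center$boundaries, sch)
        if (debias && totalBits(sch) > 1L) {
          estU <- debiasByExtrapolation(wordsU, fractions, repetitions, seed)
          centerDeb <- miDebiased(estU); centerRaw <- miRaw(estU)
          slopeU <- biasSlope(estU)
        } else {
          centerRaw <- pluginMutualInformation(wordCounts(wordsU))
          centerDeb <- centerRaw
          slopeU <- 0
        }
      }
      useSlope <- slopeU
      envVals <- vapply(seq_len(nrow(offsets)), function(i) {
        off <- c(offsets[i, 1], offsets[i, 2])
        if (all(off == 0L)) return(centerDeb)
        .placementMI(movie, grid, sch, off, useSlope,
                     freezeBoundaries = centerBnd, debias = debias,
                     candidateCount = candidateCount)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        grid = gridName(grid), family = family, nBits = n,
        totalBits = n * rSpat * rTemp, binning = binning, labeled = lab,
        draws = drawsPerLocation(center$counts),
        miRaw = centerRaw, miDebiased = centerDeb, biasSlope = useSlope,
        jitterMin = min(envVals), jitterMax = max(envVals))
    }
  }
  do.call(rbind, rows)
}

#' MI of a binarized single sample as a function of the threshold
#'
#' Computes the plug-in location information of the one-bit single-sample
#' code over a range of binarization thresholds, and reports the pooled
#' median (the histogram-equalization cutpoint), the MI at that median, and
#' the information-maximizing threshold. Thresholds default to the pooled
#' quantile candidate set also used by the greedy boundary search, so the
#' arg-max threshold coincides with the first greedy cut.
#'
#' @param movie a \code{\link{PlumeMovie}}
#' @param grid a \code{\link{SamplingGrid}}
#' @param thresholds numeric vector; default = pooled quantile candidates
#' @param offset rigid (dx, dy) pixel shift
#' @param candidateCount size of the default threshold set
#' @return list with elements \code{curve} (data.frame threshold, mi),
#'   \code{pooledMedian}, \code{miAtMedian}, \code{optimalThreshold},
#'   \code{miAtOptimal}
#' @export
binarizationThresholdSweep <- function(movie, grid, thresholds = NULL,
                                       offset = c(0L, 0L),
                                       candidateCount = 512L) {
  samples <- .singleSampleValues(movie, grid, offset)
  pooled <- unlist(samples, use.names = FALSE)
  if (is.null(thresholds)) {
    thresholds <- .greedyCandidates(pooled, candidateCount)
  }
  total <- lengths(samples)
  miAt <- function(thr) {
    lower <- vapply(samples, function(s) sum(s < thr), numeric(1))
    .miUniformPrior(cbind(lower, total - lower))
  }
  mi <- vapply(thresholds, miAt, numeric(1))
  med <- stats::median(pooled)
  best <- which.max(mi)
  list(curve = data.frame(threshold = thresholds, mi = mi),
       pooledMedian = med, miAtMedian = miAt(med),
       optimalThreshold = thresholds[best], miAtOptimal = mi[best])
}

#' Fixed-budget allocation of eight bits to two sensors
#'
#' Compares the allocations S(4;2,1), S(2;2,2) and S(1;2,4) -- all using
#' eight total bits across two sensors -- for both sensor orientations
#' (transverse and longitudinal to the mean flow) and both binning methods,
#' with center values and jitter envelopes.
#'
#' @param movie a \code{\link{PlumeMovie}}
#' @param grid a \code{\link{SamplingGrid}}
#' @param binnings subset of c("equalize", "greedy")
#' @param jitterRadius jitter envelope radius
#' @param debias,fractions,repetitions,seed,candidateCount as elsewhere
#' @param interSampleFrames temporal spacing for multi-time allocations
#' @param sensorSpacing sensor separation (pixels)
#' @return data.frame, one row per allocation x orientation x binning
#' @export
twoSensorAllocationComparison <- function(movie, grid,
                                          binnings = c("equalize", "greedy"),
                                          jitterRadius = 3L, debias = TRUE,
                                          fractions = c(1, 1/2, 1/4, 1/8),
                                          repetitions = 10L, seed = 1L,
                                          candidateCount = 512L,
                                          interSampleFrames = 24L,
                                          sensorSpacing = 4L) {
  alloc <- list(c(4L, 1L), c(2L, 2L), c(1L, 4L))  # (nBits, rTemp), rSpat = 2
  offsets <- .jitterOffsetGrid(jitterRadius)
  rows <- list()
  for (binning in binnings) {
    for (orient in c("transverse", "longitudinal")) {
      for (a in alloc) {
        scheme <- EncodingScheme(a[1], rSpat = 2L, rTemp = a[2],
                                 binning = binning,
                                 sensorSpacing = sensorSpacing,
                                 sensorOrientation = orient,
                                 interSampleFrames = interSampleFrames)
        center <- schemeMI(movie, grid, scheme, c(0L, 0L), debias = debias,
                           fractions = fractions,
                           repetitions = repetitions, seed = seed,
                           candidateCount = candidateCount)
        slope <- biasSlope(center$estimate)
        envVals <- vapply(seq_len(nrow(offsets)), function(i) {
          off <- c(offsets[i, 1], offsets[i, 2])
          if (all(off == 0L)) return(miDebiased(center$estimate))
          .placementMI(movie, grid, scheme, off, slope, debias = debias,
                       candidateCount = candidateCount)
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          grid = gridName(grid),
          scheme = sprintf("S(%d%s;2,%d)", a[1],
                           if (binning == "greedy") "*" else "", a[2]),
          nBits = a[1], rTemp = a[2], totalBits = 8L,
          binning = binning, orientation = orient,
          miRaw = miRaw(center$estimate),
          miDebiased = miDebiased(center$estimate),
          jitterMin = min(envVals), jitterMax = max(envVals))
      }
    }
  }
  do.call(rbind, rows)
}

#' Two-sample MI as a function of the inter-sample interval, and tau80
#'
#' Evaluates the two-temporal-sample scheme S(nBits;1,2) over a range of
#' inter-sample intervals. The asymptote is estimated as the mean MI over
#' the top quartile of probed intervals; tau80 is the smallest probed
#' interval whose MI reaches 80 percent of that asymptote (definition
#' "asymptote", the default) or 80 percent of the second sample's
#' incremental information over a single sample (definition "incremental").
#' When no probed interval reaches the criterion the result is flagged
#' unresolved rather than raising an error.
#'
#' @param movie a \code{\link{PlumeMovie}}
#' @param grid a \code{\link{SamplingGrid}}
#' @param intervalsFrames integer intervals in frames (0 = duplicate frame)
#' @param nBitsPerSample bits per sample (default 5)
#' @param offset rigid placement shift
#' @param definition "asymptote" or "incremental"
#' @param binning,debias,fractions,repetitions,seed,candidateCount as elsewhere
#' @return a \code{\link{Tau80Result}}
#' @export
miVsInterval <- function(movie, grid, intervalsFrames, nBitsPerSample = 5L,
                         offset = c(0L, 0L),
                         definition = c("asymptote", "incremental"),
                         binning = "equalize", debias = TRUE,
                         fractions = c(1, 1/2, 1/4, 1/8),
                         repetitions = 10L, seed = 1L,
                         candidateCount = 512L) {
  definition <- match.arg(definition)
  intervalsFrames <- sort(unique(as.integer(intervalsFrames)))
  proto <- EncodingScheme(nBitsPerSample, rTemp = 2L, binning = binning)
  bnd <- .designBoundaries(movie, grid, proto, offset, candidateCount)
  mi <- vapply(intervalsFrames, function(dlt) {
    sch <- EncodingScheme(nBitsPerSample, rTemp = 2L, binning = "fixed",
                          boundaries = bnd, interSampleFrames = dlt)
    res <- schemeMI(movie, grid, sch, offset, boundaries = bnd,
                    debias = debias, fractions = fractions,
                    repetitions = repetitions, seed = seed)
    miDebiased(res$estimate)
  }, numeric(1))
  K <- length(intervalsFrames)
  topQ <- seq.int(K - ceiling(K / 4) + 1L, K)
  asym <- mean(mi[topQ])
  if (definition == "asymptote") {
    target <- 0.8 * asym
  } else {
    sch1 <- EncodingScheme(nBitsPerSample, binning = "fixed",
                           boundaries = bnd)
    res1 <- schemeMI(movie, grid, sch1, offset, boundaries = bnd,
                     debias = debias, fractions = fractions,
                     repetitions = repetitions, seed = seed)
    mi1 <- miDebiased(res1$estimate)
    target <- mi1 + 0.8 * (asym - mi1)
  }
  hit <- which(mi >= target)
  resolved <- length(hit) > 0L
  tau80 <- if (resolved) {
    intervalsFrames[hit[1]] / frameRate(movie)
  } else NA_real_
  new("Tau80Result",
      table = data.frame(intervalFrames = intervalsFrames,
                         intervalS = intervalsFrames / frameRate(movie),
                         mi = mi),
      asymptote = asym, tau80 = tau80, resolved = resolved,
      definition = definition)
}

.divisors <- function(n) Filter(function(d) n %% d == 0, seq_len(n))

#' Fixed-budget allocation of bits across consecutive temporal samples
#'
#' Compares strategies that split a fixed total bit budget (default ten)
#' between concentration resolution and the number of consecutive samples
#' at a single sensor: S(10;1,1), S(5;1,2), S(2;1,5), S(1;1,10), plus the
#' greedy-binarized S(1*;1,10). For each allocation it reports the ordered
#' and order-ignored MI and the corresponding pooled code-word entropies
#' (the lossless-compression bounds). When the movie is too short for the
#' full budget the budget is reduced (with a message) to the largest
#' feasible total with the same allocation structure.
#'
#' @param movie a \code{\link{PlumeMovie}}
#' @param grid a \code{\link{SamplingGrid}}
#' @param totalBitsTarget total coding bits per word
#' @param offset rigid placement shift
#' @param interSampleFrames temporal spacing in frames
#' @param debias,fractions,repetitions,seed,candidateCount as elsewhere
#' @return data.frame, one row per allocation
#' @export
temporalAllocationComparison <- function(movie, grid, totalBitsTarget = 10L,
                                         offset = c(0L, 0L),
                                         interSampleFrames = 24L,
                                         debias = TRUE,
                                         fractions = c(1, 1/2, 1/4, 1/8),
                                         repetitions = 10L, seed = 1L,
                                         candidateCount = 512L) {
  tb <- as.integer(totalBitsTarget)
  maxRT <- max(.divisors(tb))
  nAvail <- nFrames(movie) - (maxRT - 1L) * interSampleFrames
  while (tb > 1L && 2^tb > nAvail) tb <- tb - 1L
  if (tb < totalBitsTarget) {
    message(sprintf(
      "data supports at most 2^%d words for %d draws; running at %d total bits",
      tb, nAvail, tb))
  }
  rts <- .divisors(tb)
  allocs <- lapply(rts, function(rt) list(nBits = tb %/% rt, rTemp = rt,
                                          binning = "equalize"))
  allocs[[length(allocs) + 1L]] <- list(nBits = 1L, rTemp = tb,
                                        binning = "greedy")
  rows <- lapply(allocs, function(a) {
    scheme <- EncodingScheme(a$nBits, rTemp = a$rTemp, binning = a$binning,
                             interSampleFrames = interSampleFrames)
    bnd <- .designBoundaries(movie, grid, scheme, offset, candidateCount)
    block <- extractSampleBlock(movie, grid, scheme, offset)
    .biasGuard(totalBits(scheme), drawsPerLocation(block))
    wOrd <- formWords(block, bnd, scheme)
    schU <- scheme; schU@timeOrdered <- FALSE
    wIgn <- formWords(block, bnd, schU)
    estOf <- function(w) {
      if (debias && totalBits(scheme) > 1L) {
        debiasByExtrapolation(w, fractions, repetitions, seed)
      } else {
        mi <- pluginMutualInformation(wordCounts(w))
        MIEstimate(mi, mi, mi, 0, data.frame(invN = NA, mi = mi),
                   length(w[[1]]) * length(w))
      }
    }
    eOrd <- estOf(wOrd); eIgn <- estOf(wIgn)
    data.frame(
      grid = gridName(grid),
      scheme = sprintf("S(%d%s;1,%d)", a$nBits,
                       if (a$binning == "greedy") "*" else "", a$rTemp),
      nBits = a$nBits, rTemp = a$rTemp, totalBits = tb,
      binning = a$binning,
      miOrderedRaw = miRaw(eOrd), miOrdered = miDebiased(eOrd),
      miIgnoredRaw = miRaw(eIgn), miIgnored = miDebiased(eIgn),
      entropyOrdered = wordDistributionEntropy(wOrd),
      entropyIgnored = wordDistributionEntropy(wOrd, ignoreOrder = TRUE))
  })
  do.call(rbind, rows)
}

#' Export / import a location x word count table as CSV
#'
#' Rows are locations, columns are word identifiers.
#'
#' @param counts a \code{\link{LocationSymbolCounts}}
#' @param path CSV file path
#' @return \code{countsFromCSV} returns a \code{\link{LocationSymbolCounts}}
#' @export
countsToCSV <- function(counts, path) {
  stopifnot(is(counts, "LocationSymbolCounts"))
  df <- as.data.frame(counts@counts)
  names(df) <- counts@wordIds
  utils::write.csv(cbind(location = seq_len(nrow(df)), df), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname countsToCSV
#' @export
countsFromCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  LocationSymbolCounts(as.matrix(df[, -1, drop = FALSE]),
                       wordIds = names(df)[-1])
}
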