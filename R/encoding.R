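# Quantizer design and code-word formation.
#
# Cutpoint convention used throughout: a value's bin index is the number of
# cutpoints less than or equal to it (a value equal to a cutpoint falls in
# the upper bin). Quantile cutpoints are placed at the midpoint between the
# sample at the quantile rank and the next strictly larger distinct value,
# so that on tie-free data bin occupancies are equal to within one sample
# and massive ties (e.g. a spike of zeros) collapse to a single separating
# cutpoint rather than a degenerate one.

# midpoint-convention quantile cutpoint at rank ceiling(n * p); NA when the
# rank value is the maximum (no distinct larger value to separate from)
.quantileCut <- function(sortedX, p) {
  n <- length(sortedX)
  r <- min(n, max(1L, ceiling(n * p)))
  v <- sortedX[r]
  upper <- sortedX[sortedX > v]
  if (length(upper) == 0L) return(NA_real_)
  (v + upper[1]) / 2
}

#' Histogram-equalized bin boundaries
#'
#' Places 2^nBits - 1 cutpoints at the k/2^nBits quantiles of the pooled
#' single-sample distribution (all grid locations pooled), so that the
#' marginal word distribution p(m) is as uniform as ties permit. Exact
#' duplicate cutpoints arising from ties are removed, reducing the
#' effective bin count.
#'
#' @param pooledSamples numeric vector of single-sample concentrations
#'   pooled over all grid locations
#' @param nBits bits per sample (>= 1); number of bins is 2^nBits
#' @return a \code{\link{BinBoundaries}} with method "equalize"
#' @export
#' @examples
#' b <- equalizedBoundaries(0:99, 1)
#' cutpoints(b)  # 49.5, the median under the midpoint convention
equalizedBoundaries <- function(pooledSamples, nBits) {
  if (length(nBits) != 1L || nBits < 1) {
    stop("nBits must be a single integer >= 1", call. = FALSE)
  }
  pooledSamples <- as.numeric(pooledSamples)
  if (length(pooledSamples) == 0L || anyNA(pooledSamples)) {
    stop("pooledSamples must be nonempty and free of NA", call. = FALSE)
  }
  x <- sort(pooledSamples)
  B <- 2^as.integer(nBits)
  cuts <- vapply(seq_len(B - 1L), function(k) .quantileCut(x, k / B),
                 numeric(1))
  cuts <- unique(cuts[!is.na(cuts)])
  if (length(cuts) == 0L) {
    stop("all samples are identical; no separating cutpoint exists",
         call. = FALSE)
  }
  BinBoundaries(cuts, nBitsDesign = as.integer(nBits), method = "equalize")
}

# candidate cutpoints for the greedy search: quantile-midpoint positions of
# the pooled sample (robust to the heavy skew of plume concentrations)
.greedyCandidates <- function(pooled, candidateCount) {
  x <- sort(as.numeric(pooled))
  cand <- vapply(seq_len(candidateCount),
                 function(j) .quantileCut(x, j / (candidateCount + 1L)),
                 numeric(1))
  sort(unique(cand[!is.na(cand)]))
}

# uniform-location-prior plug-in MI from a locations x bins count matrix;
# tolerates unequal row sums (each row is normalized to p(m | l))
.miUniformPrior <- function(cnt) {
  rs <- rowSums(cnt)
  if (any(rs == 0)) return(0)
  pml <- cnt / rs
  pm <- colMeans(pml)
  hM <- -sum(ifelse(pm > 0, pm * log2(pm), 0))
  hMl <- -rowSums(ifelse(pml > 0, pml * log2(pml), 0))
  max(0, hM - mean(hMl))
}

#' Greedy information-maximizing bin boundaries
#'
#' Iterative cutpoint selection: candidates are quantile positions of the
#' pooled sample (default 512); the first cutpoint is the candidate
#' maximizing the plug-in location information I(L; M) of the binarized
#' code (an exhaustive search over the candidate set), and each subsequent
#' cutpoint maximizes I(L; M) holding previous cutpoints fixed -- a binary
#' subdivision of one existing bin. Stops after 2^nBits - 1 cutpoints or
#' when candidates are exhausted. Ties are broken toward the lowest
#' candidate value, making the search deterministic.
#'
#' @param samplesByLocation list (one numeric vector per grid location) of
#'   single-sample concentrations
#' @param nBits bits per sample
#' @param candidateCount number of candidate quantile positions
#' @return a \code{\link{BinBoundaries}} with method "greedy"
#' @export
greedyBoundaries <- function(samplesByLocation, nBits, candidateCount = 512L) {
  if (!is.list(samplesByLocation) || length(samplesByLocation) < 2L ||
      any(!vapply(samplesByLocation, length, integer(1)))) {
    stop("samplesByLocation must be a list of >= 2 nonempty sample vectors",
         call. = FALSE)
  }
  if (nBits < 1) stop("nBits must be >= 1", call. = FALSE)
  pooled <- unlist(samplesByLocation, use.names = FALSE)
  cand <- .greedyCandidates(pooled, as.integer(candidateCount))
  nC <- length(cand)
  nL <- length(samplesByLocation)
  # cum[l, j] = number of samples at location l that are < cand[j]
  # (bin index convention: value == cutpoint goes to the upper bin)
  cum <- matrix(vapply(cand, function(cv) {
    vapply(samplesByLocation, function(s) sum(s < cv), numeric(1))
  }, numeric(nL)), nrow = nL, ncol = nC)
  tot <- vapply(samplesByLocation, length, numeric(1))

  miOfCutSet <- function(idx) {
    idx <- sort(idx)
    cc <- cbind(cum[, idx, drop = FALSE], tot)
    bins <- cc - cbind(0, cc[, -ncol(cc), drop = FALSE])
    .miUniformPrior(bins)
  }

  chosen <- integer(0)
  nCuts <- 2^as.integer(nBits) - 1L
  for (step in seq_len(nCuts)) {
    avail <- setdiff(seq_len(nC), chosen)
    if (!length(avail)) break
    mis <- vapply(avail, function(j) miOfCutSet(c(chosen, j)), numeric(1))
    best <- avail[which.max(mis)]  # which.max: first (lowest value) on ties
    chosen <- c(chosen, best)
  }
  BinBoundaries(cand[sort(chosen)], nBitsDesign = as.integer(nBits),
                method = "greedy")
}

#' Discretize concentrations into bin indices
#'
#' Bin index = number of cutpoints less than or equal to the value; a value
#' exactly equal to a cutpoint goes to the upper bin. Indices run from 0 to
#' the number of cutpoints. The map is monotone: a larger concentration
#' never gets a smaller index.
#'
#' @param values numeric vector/array of concentrations
#' @param boundaries a \code{\link{BinBoundaries}}
#' @return integer bin indices with the shape of \code{values}
#' @export
#' @examples
#' discretize(c(0.1, 0.35, 0.65, 0.9), BinBoundaries(c(0.2, 0.5, 0.8)))
discretize <- function(values, boundaries) {
  stopifnot(is(boundaries, "BinBoundaries"))
  idx <- findInterval(values, boundaries@cutpoints)
  if (!is.null(dim(values))) dim(idx) <- dim(values)
  idx
}

#' Extract raw concentration draws for an encoding scheme
#'
#' For each grid location, gathers every admissible draw: an rSpat x rTemp
#' matrix of concentrations. Two-sensor schemes place the sensors
#' symmetrically about the grid point, separated by \code{sensorSpacing}
#' pixels along rows (transverse) or columns (longitudinal). Temporal draws
#' use frames t, t + d, ..., t + (rTemp - 1) d with d = interSampleFrames,
#' sliding over every admissible start frame (overlapping draws). Draw
#' counts are equalized across locations by truncation.
#'
#' @param movie a \code{\link{PlumeMovie}}
#' @param grid a \code{\link{SamplingGrid}}
#' @param scheme an \code{\link{EncodingScheme}}
#' @param offset rigid (dx, dy) pixel shift of the whole grid
#' @return a \code{\link{SampleBlock}}
#' @export
extractSampleBlock <- function(movie, grid, scheme, offset = c(0L, 0L)) {
  stopifnot(is(movie, "PlumeMovie"), is(grid, "SamplingGrid"),
            is(scheme, "EncodingScheme"))
  pix <- gridToPixelIndices(grid, movie, offset)
  d <- dim(movie@frames)
  S <- scheme@rSpat
  sensorPix <- function(r, c, i) {
    if (S == 1L) return(cbind(row = r, col = c))
    lo <- floor(scheme@sensorSpacing / 2)
    hi <- scheme@sensorSpacing - lo
    if (scheme@sensorOrientation == "transverse") {
      out <- cbind(row = c(r - lo, r + hi), col = c(c, c))
    } else {
      out <- cbind(row = c(r, r), col = c(c - lo, c + hi))
    }
    if (any(out[, 1] < 1 | out[, 1] > d[1] | out[, 2] < 1 | out[, 2] > d[2]))
      stop(sprintf(
        "sensor pair for grid point %d at offset (%d, %d) maps outside the frame",
        i, offset[1], offset[2]), call. = FALSE)
    if (any(!movie@validMask[out]))
      stop(sprintf(
        "sensor pair for grid point %d at offset (%d, %d) maps to a masked pixel",
        i, offset[1], offset[2]), call. = FALSE)
    out
  }
  TT <- d[3]
  delta <- scheme@interSampleFrames
  span <- (scheme@rTemp - 1L) * delta
  nDraw <- TT - span
  if (nDraw < 1L) {
    stop("movie too short for rTemp = ", scheme@rTemp,
         " samples at interval ", delta, " frames", call. = FALSE)
  }
  starts <- seq_len(nDraw)
  draws <- vector("list", nrow(pix))
  for (i in seq_len(nrow(pix))) {
    sp <- sensorPix(pix[i, 1], pix[i, 2], i)
    arr <- array(0, c(nDraw, S, scheme@rTemp))
    for (s in seq_len(S)) {
      ts <- movie@frames[sp[s, 1], sp[s, 2], ]
      for (j in seq_len(scheme@rTemp)) {
        arr[, s, j] <- ts[starts + (j - 1L) * delta]
      }
    }
    draws[[i]] <- arr
  }
  SampleBlock(draws)
}

#' Form discrete code words from a sample block
#'
#' Discretizes every draw with the given boundaries (always designed on
#' single-sample statistics) and composes the bin indices into a code word.
#' With labeled sensors and ordered time the word is the full ordered
#' tuple; with unlabeled sensors the sensor pair at each time is replaced
#' by its sorted multiset; with time order ignored the sequence of
#' (possibly multiset) time tokens is replaced by its sorted multiset.
#' Unlabeled/orderless words are deterministic functions of the
#' labeled/ordered words, so by the data-processing inequality they can
#' never carry more location information.
#'
#' @param block a \code{\link{SampleBlock}}
#' @param boundaries a \code{\link{BinBoundaries}}
#' @param scheme an \code{\link{EncodingScheme}} (its sensorLabeled /
#'   timeOrdered flags control the collapsing)
#' @return list (one per location) of character word vectors
#' @export
formWords <- function(block, boundaries, scheme) {
  stopifnot(is(block, "SampleBlock"), is(boundaries, "BinBoundaries"),
            is(scheme, "EncodingScheme"))
  width <- nchar(as.character(length(boundaries@cutpoints)))
  lapply(block@draws, function(arr) {
    bins <- discretize(arr, boundaries)
    nDraw <- dim(bins)[1]; S <- dim(bins)[2]; Tt <- dim(bins)[3]
    if (!scheme@sensorLabeled && S == 2L) {
      lo <- pmin(bins[, 1, , drop = FALSE], bins[, 2, , drop = FALSE])
      hi <- pmax(bins[, 1, , drop = FALSE], bins[, 2, , drop = FALSE])
      bins[, 1, ] <- lo
      bins[, 2, ] <- hi
    }
    # one fixed-width string token per (draw, time): the sensor tuple
    tok <- matrix("", nDraw, Tt)
    for (j in seq_len(Tt)) {
      m <- matrix(.padTokens(matrix(bins[, , j], nDraw, S), width), nDraw, S)
      if (S > 1L) {
        tok[, j] <- do.call(paste, c(split(m, col(m)), sep = "."))
      } else {
        tok[, j] <- m[, 1]
      }
    }
    if (!scheme@timeOrdered && Tt > 1L) {
      tok <- t(apply(tok, 1L, sort))
    }
    if (Tt > 1L) {
      do.call(paste, c(split(tok, col(tok)), sep = "-"))
    } else {
      tok[, 1]
    }
  })
}

#' Tabulate code words into a location x word count table
#'
#' @param wordSeqs list (one per location) of word vectors; unequal lengths
#'   are truncated to the minimum so the location prior stays uniform
#' @return a \code{\link{LocationSymbolCounts}}
#' @export
wordCounts <- function(wordSeqs) {
  nmin <- min(lengths(wordSeqs))
  wordSeqs <- lapply(wordSeqs, function(w) w[seq_len(nmin)])
  alphabet <- sort(unique(unlist(wordSeqs, use.names = FALSE)))
  cnt <- t(vapply(wordSeqs, function(w) {
    tabulate(match(w, alphabet), nbins = length(alphabet))
  }, numeric(length(alphabet))))
  if (length(alphabet) == 1L) cnt <- matrix(cnt, ncol = 1L)
  LocationSymbolCounts(cnt, wordIds = alphabet)
}

#' Export per-location word sequences as CSV
#'
#' Long format for inspection: columns \code{location}, \code{draw_index},
#' \code{word}.
#'
#' @param wordSeqs list (one per location) of word vectors
#' @param path CSV file path
#' @return invisibly, \code{path}
#' @export
wordsToCSV <- function(wordSeqs, path) {
  df <- do.call(rbind, lapply(seq_along(wordSeqs), function(l) {
    data.frame(location = l, draw_index = seq_along(wordSeqs[[l]]),
               word = wordSeqs[[l]])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / deserialize an encoding scheme as YAML
#'
#' @param scheme an \code{\link{EncodingScheme}}
#' @param path YAML file path
#' @return \code{readEncodingScheme} returns an \code{\link{EncodingScheme}}
#' @export
writeEncodingScheme <- function(scheme, path) {
  stopifnot(is(scheme, "EncodingScheme"))
  vals <- list(nBits = scheme@nBits, rSpat = scheme@rSpat,
               rTemp = scheme@rTemp, binning = scheme@binning,
               sensorSpacing = scheme@sensorSpacing,
               sensorOrientation = scheme@sensorOrientation,
               interSampleFrames = scheme@interSampleFrames,
               sensorLabeled = scheme@sensorLabeled,
               timeOrdered = scheme@timeOrdered)
  if (is(scheme@boundaries, "BinBoundaries")) {
    vals$boundaries <- as.numeric(scheme@boundaries@cutpoints)
  }
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writeEncodingScheme
#' @export
readEncodingScheme <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$boundaries)) {
    vals$boundaries <- BinBoundaries(as.numeric(vals$boundaries))
    vals$binning <- "fixed"
  }
  do.call(EncodingScheme, vals)
}
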