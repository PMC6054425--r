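#' PlumeMovie: a normalized odor-concentration movie
#'
#' Container for a planar concentration field c(y, x, t), normalized so that
#' concentration is expressed as a fraction of the source concentration.
#' Frames are stored height x width x time (R column-major layout; per-pixel
#' time series are contiguous slices \code{frames(m)[r, c, ]}).
#'
#' @slot frames numeric array, height x width x time, finite and >= 0
#' @slot frameRate acquisition rate in frames/second
#' @slot pixelSize pixel pitch in mm/pixel
#' @slot sourcePixel integer (row, col) of the odor inlet
#' @slot validMask logical height x width matrix; FALSE marks pixels that
#'   must not be sampled (e.g. nonpositive flatfield)
#' @slot label free-text description
#'
#' @param frames,frameRate,pixelSize,sourcePixel,validMask,label see slots
#' @return \code{PlumeMovie()} returns a validated \code{PlumeMovie} object.
#' @export
#' @examples
#' m <- PlumeMovie(array(runif(24), c(2, 3, 4)), frameRate = 15,
#'                 pixelSize = 0.74, sourcePixel = c(1L, 1L))
#' nFrames(m)
setClass("PlumeMovie",
  representation(frames = "array", frameRate = "numeric",
                 pixelSize = "numeric", sourcePixel = "integer",
                 validMask = "matrix", label = "character"))

setValidity("PlumeMovie", function(object) {
  f <- object@frames
  if (length(dim(f)) != 3L) return("frames must be a 3-d array (H x W x T)")
  if (dim(f)[3] < 1L) return("movie must contain at least one frame")
  if (anyNA(f) || any(!is.finite(f))) return("frames contain non-finite values")
  if (any(f < 0)) return("frames contain negative concentrations")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    return("frameRate must be a single positive number")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  sp <- object@sourcePixel
  if (length(sp) != 2L || any(sp < 1L) || sp[1] > dim(f)[1] || sp[2] > dim(f)[2])
    return("sourcePixel must be an in-bounds (row, col) pair")
  if (!identical(dim(object@validMask), dim(f)[1:2]))
    return("validMask must be an H x W logical matrix")
  TRUE
})

#' @rdname PlumeMovie-class
#' @export
PlumeMovie <- function(frames, frameRate, pixelSize, sourcePixel,
                       validMask = NULL, label = "") {
  frames <- as.array(frames)
  if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  if (is.null(validMask)) {
    validMask <- matrix(TRUE, nrow = dim(frames)[1], ncol = dim(frames)[2])
  }
  new("PlumeMovie", frames = frames, frameRate = as.numeric(frameRate),
      pixelSize = as.numeric(pixelSize),
      sourcePixel = as.integer(sourcePixel),
      validMask = validMask, label = as.character(label)[1])
}

setMethod("frames", "PlumeMovie", function(object) object@frames)
setMethod("frameRate", "PlumeMovie", function(object) object@frameRate)
setMethod("pixelSize", "PlumeMovie", function(object) object@pixelSize)
setMethod("sourcePixel", "PlumeMovie", function(object) object@sourcePixel)
setMethod("validMask", "PlumeMovie", function(object) object@validMask)
setMethod("movieLabel", "PlumeMovie", function(object) object@label)
setMethod("nFrames", "PlumeMovie", function(object) dim(object@frames)[3])

setMethod("show", "PlumeMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("PlumeMovie '%s': %d x %d px, %d frames @ %.3g Hz, %.3g mm/px\n",
              object@label, d[1], d[2], d[3], object@frameRate,
              object@pixelSize))
  cat(sprintf("  source pixel (row, col) = (%d, %d); mean c = %.4g, max c = %.4g\n",
              object@sourcePixel[1], object@sourcePixel[2],
              mean(object@frames), max(object@frames)))
})

#' RawImageStack: background-subtracted camera images plus flatfield
#'
#' Holds the raw ingredients of flatfield normalization: background-subtracted
#' camera intensities I(y, x, t), the background-subtracted flatfield image
#' F(y, x), and the source calibration coefficient a_c used to express
#' concentration as a fraction of the source concentration.
#'
#' @slot images numeric array, height x width x time
#' @slot flatfield numeric height x width matrix
#' @slot calibrationCoefficient positive scalar a_c
#' @param images,flatfield,calibrationCoefficient see slots
#' @return a validated \code{RawImageStack}
#' @export
setClass("RawImageStack",
  representation(images = "array", flatfield = "matrix",
                 calibrationCoefficient = "numeric"))

setValidity("RawImageStack", function(object) {
  if (length(dim(object@images)) != 3L)
    return("images must be a 3-d array (H x W x T)")
  if (!identical(dim(object@flatfield), dim(object@images)[1:2]))
    return("flatfield dimensions must match image frames")
  if (length(object@calibrationCoefficient) != 1L ||
      !is.finite(object@calibrationCoefficient) ||
      object@calibrationCoefficient <= 0)
    return("calibrationCoefficient must be a single positive number")
  TRUE
})

#' @rdname RawImageStack-class
#' @export
RawImageStack <- function(images, flatfield, calibrationCoefficient = 1) {
  images <- as.array(images)
  if (length(dim(images)) == 2L) dim(images) <- c(dim(images), 1L)
  new("RawImageStack", images = images, flatfield = as.matrix(flatfield),
      calibrationCoefficient = as.numeric(calibrationCoefficient))
}

#' SamplingGrid: candidate sampling locations relative to the source
#'
#' An ordered set of locations (x downstream, y transverse, both in cm from
#' the odor inlet) over which the navigator's uniform location prior is
#' defined, together with the rigid pixel jitter offsets used for robustness
#' envelopes.
#'
#' @slot points numeric matrix with columns \code{x_cm}, \code{y_cm}
#' @slot name grid identifier
#' @slot jitterOffsets integer matrix with columns \code{dx}, \code{dy}
#'   (pixels); always contains the identity offset (0, 0)
#' @param points,name see slots
#' @param jitterRadius nonnegative integer; offsets are all (dx, dy) with
#'   dx, dy in \code{-jitterRadius:jitterRadius}
#' @return a validated \code{SamplingGrid}
#' @export
#' @examples
#' g <- gridPreset("narrow")
#' nrow(gridPoints(g))  # 16 locations
setClass("SamplingGrid",
  representation(points = "matrix", name = "character",
                 jitterOffsets = "matrix"))

setValidity("SamplingGrid", function(object) {
  p <- object@points
  if (ncol(p) != 2L) return("points must have two columns (x_cm, y_cm)")
  if (nrow(unique(p)) < 2L) return("grid needs at least 2 distinct points")
  if (anyNA(p) || any(!is.finite(p))) return("grid points must be finite")
  jo <- object@jitterOffsets
  if (ncol(jo) != 2L) return("jitterOffsets must have two columns (dx, dy)")
  if (!any(jo[, 1] == 0L & jo[, 2] == 0L))
    return("jitterOffsets must contain the identity offset (0, 0)")
  TRUE
})

.jitterOffsetGrid <- function(radius) {
  radius <- as.integer(radius)
  stopifnot(radius >= 0L)
  as.matrix(expand.grid(dx = -radius:radius, dy = -radius:radius))
}

#' @rdname SamplingGrid-class
#' @export
SamplingGrid <- function(points, name = "grid", jitterRadius = 3L) {
  points <- as.matrix(points)
  dimnames(points) <- list(NULL, c("x_cm", "y_cm"))
  storage.mode(points) <- "double"
  new("SamplingGrid", points = points, name = as.character(name)[1],
      jitterOffsets = .jitterOffsetGrid(jitterRadius))
}

setMethod("gridPoints", "SamplingGrid", function(object) object@points)
setMethod("gridName", "SamplingGrid", function(object) object@name)
setMethod("jitterOffsets", "SamplingGrid", function(object) object@jitterOffsets)

setMethod("show", "SamplingGrid", function(object) {
  cat(sprintf("SamplingGrid '%s': %d locations, %d jitter placements\n",
              object@name, nrow(object@points), nrow(object@jitterOffsets)))
  cat(sprintf("  x range [%.2g, %.2g] cm, y range [%.2g, %.2g] cm\n",
              min(object@points[, 1]), max(object@points[, 1]),
              min(object@points[, 2]), max(object@points[, 2])))
})

#' BinBoundaries: concentration quantizer cutpoints
#'
#' Strictly increasing cutpoints partitioning the concentration axis into
#' bins. A value is assigned bin index = number of cutpoints less than or
#' equal to it (values equal to a cutpoint fall in the upper bin), so k
#' cutpoints define k + 1 bins. When quantile ties collapse duplicate
#' cutpoints, the effective bin count is smaller than the design target
#' 2^nBitsDesign; the design target is recorded.
#'
#' @slot cutpoints strictly increasing finite numeric vector
#' @slot nBitsDesign the bits-per-sample the boundary set was designed for
#' @slot method one of "equalize", "greedy", "fixed"
#' @param cutpoints,nBitsDesign,method see slots
#' @return a validated \code{BinBoundaries}
#' @export
setClass("BinBoundaries",
  representation(cutpoints = "numeric", nBitsDesign = "integer",
                 method = "character"))

setValidity("BinBoundaries", function(object) {
  cp <- object@cutpoints
  if (length(cp) == 0L) return("at least one cutpoint is required")
  if (anyNA(cp) || any(!is.finite(cp))) return("cutpoints must be finite")
  if (is.unsorted(cp, strictly = TRUE))
    return("cutpoints must be strictly increasing")
  TRUE
})

#' @rdname BinBoundaries-class
#' @export
BinBoundaries <- function(cutpoints, nBitsDesign = NULL, method = "fixed") {
  cutpoints <- sort(unique(as.numeric(cutpoints)))
  if (is.null(nBitsDesign)) {
    nBitsDesign <- as.integer(ceiling(log2(length(cutpoints) + 1L)))
  }
  new("BinBoundaries", cutpoints = cutpoints,
      nBitsDesign = as.integer(nBitsDesign), method = as.character(method)[1])
}

setMethod("cutpoints", "BinBoundaries", function(object) object@cutpoints)
setMethod("effectiveBins", "BinBoundaries",
          function(object) length(object@cutpoints) + 1L)

setMethod("show", "BinBoundaries", function(object) {
  cat(sprintf("BinBoundaries (%s): %d cutpoints -> %d bins (design %d bits)\n",
              object@method, length(object@cutpoints), effectiveBins(object),
              object@nBitsDesign))
})

#' EncodingScheme: S(nBits; rSpat, rTemp) and its realization details
#'
#' An encoding strategy discretizes each odor sample into 2^nBits levels and
#' applies that discretization to rSpat spatial sensors at rTemp points in
#' time, for a total of nBits * rSpat * rTemp coding bits per code word.
#' Binning "equalize" places cutpoints at equal quantiles of the pooled
#' single-sample distribution (histogram equalization); "greedy" maximizes
#' location information cut by cut; "fixed" uses user-supplied boundaries.
#'
#' @slot nBits bits per sample (>= 1)
#' @slot rSpat number of spatial sensors (1 or 2)
#' @slot rTemp number of temporal samples (>= 1)
#' @slot binning "equalize", "greedy" or "fixed"
#' @slot boundaries a \code{BinBoundaries} (required iff binning == "fixed"),
#'   otherwise may be an empty list placeholder
#' @slot sensorSpacing sensor separation in pixels (two-sensor schemes)
#' @slot sensorOrientation "transverse" (across flow, along rows) or
#'   "longitudinal" (along flow, along columns)
#' @slot interSampleFrames frames between consecutive temporal samples
#'   (0 duplicates the same frame; default 24 frames = 1.6 s at 15 Hz)
#' @slot sensorLabeled keep track of which sensor produced which sample?
#' @slot timeOrdered keep the temporal order of samples?
#' @param nBits,rSpat,rTemp,binning,boundaries,sensorSpacing,sensorOrientation,interSampleFrames,sensorLabeled,timeOrdered see slots
#' @return a validated \code{EncodingScheme}
#' @export
#' @examples
#' EncodingScheme(5, rTemp = 2)         # S(5;1,2)
#' EncodingScheme(4, rSpat = 2)         # S(4;2,1)
setClass("EncodingScheme",
  representation(nBits = "integer", rSpat = "integer", rTemp = "integer",
                 binning = "character", boundaries = "ANY",
                 sensorSpacing = "integer", sensorOrientation = "character",
                 interSampleFrames = "integer", sensorLabeled = "logical",
                 timeOrdered = "logical"))

setValidity("EncodingScheme", function(object) {
  if (object@nBits < 1L) return("nBits must be >= 1")
  if (!object@rSpat %in% c(1L, 2L)) return("rSpat must be 1 or 2")
  if (object@rTemp < 1L) return("rTemp must be >= 1")
  if (!object@binning %in% c("equalize", "greedy", "fixed"))
    return("binning must be 'equalize', 'greedy' or 'fixed'")
  if (object@binning == "fixed" && !is(object@boundaries, "BinBoundaries"))
    return("binning 'fixed' requires a BinBoundaries object")
  if (!object@sensorOrientation %in% c("transverse", "longitudinal"))
    return("sensorOrientation must be 'transverse' or 'longitudinal'")
  if (object@interSampleFrames < 0L)
    return("interSampleFrames must be >= 0")
  if (object@sensorSpacing < 1L) return("sensorSpacing must be >= 1 pixel")
  TRUE
})

#' @rdname EncodingScheme-class
#' @export
EncodingScheme <- function(nBits, rSpat = 1L, rTemp = 1L,
                           binning = "equalize", boundaries = NULL,
                           sensorSpacing = 4L,
                           sensorOrientation = "transverse",
                           interSampleFrames = 24L,
                           sensorLabeled = TRUE, timeOrdered = TRUE) {
  if (!is.null(boundaries) && identical(binning, "equalize")) binning <- "fixed"
  new("EncodingScheme", nBits = as.integer(nBits), rSpat = as.integer(rSpat),
      rTemp = as.integer(rTemp), binning = binning,
      boundaries = boundaries, sensorSpacing = as.integer(sensorSpacing),
      sensorOrientation = as.character(sensorOrientation)[1],
      interSampleFrames = as.integer(interSampleFrames),
      sensorLabeled = isTRUE(sensorLabeled), timeOrdered = isTRUE(timeOrdered))
}

setMethod("nBits", "EncodingScheme", function(object) object@nBits)
setMethod("totalBits", "EncodingScheme",
          function(object) object@nBits * object@rSpat * object@rTemp)

setMethod("show", "EncodingScheme", function(object) {
  star <- if (object@binning == "greedy") "*" else ""
  cat(sprintf("EncodingScheme S(%d%s;%d,%d): %d total bits, binning = %s\n",
              object@nBits, star, object@rSpat, object@rTemp,
              totalBits(object), object@binning))
  if (object@rSpat > 1L)
    cat(sprintf("  sensors: spacing %d px, %s, %s\n", object@sensorSpacing,
                object@sensorOrientation,
                if (object@sensorLabeled) "labeled" else "unlabeled"))
  if (object@rTemp > 1L)
    cat(sprintf("  temporal: interval %d frames, %s\n",
                object@interSampleFrames,
                if (object@timeOrdered) "ordered" else "order-ignored"))
})

#' SampleBlock: raw concentration draws per location
#'
#' For each grid location, an array of draws; each draw is an rSpat x rTemp
#' matrix of concentrations. Draw counts are equal across locations
#' (enforced by truncation to the minimum).
#'
#' @slot draws list (one per location) of nDraw x rSpat x rTemp arrays
#' @slot locationIds character vector of location identifiers
#' @param draws,locationIds see slots
#' @return a validated \code{SampleBlock}
#' @export
setClass("SampleBlock",
  representation(draws = "list", locationIds = "character"))

setValidity("SampleBlock", function(object) {
  if (length(object@draws) < 1L) return("draws must be nonempty")
  dims <- vapply(object@draws, function(a) dim(a), integer(3))
  if (length(unique(dims[1, ])) != 1L)
    return("draw counts must be equal across locations")
  if (any(vapply(object@draws, function(a) any(a < 0) || anyNA(a), logical(1))))
    return("all sampled concentrations must be finite and >= 0")
  if (length(object@locationIds) != length(object@draws))
    return("locationIds length must match draws")
  TRUE
})

SampleBlock <- function(draws, locationIds = NULL) {
  nmin <- min(vapply(draws, function(a) dim(a)[1], integer(1)))
  draws <- lapply(draws, function(a) a[seq_len(nmin), , , drop = FALSE])
  if (is.null(locationIds)) locationIds <- sprintf("L%02d", seq_along(draws))
  new("SampleBlock", draws = draws, locationIds = as.character(locationIds))
}

setMethod("drawsPerLocation", "SampleBlock",
          function(object) dim(object@draws[[1]])[1])

setMethod("show", "SampleBlock", function(object) {
  d <- dim(object@draws[[1]])
  cat(sprintf("SampleBlock: %d locations x %d draws (each %d x %d)\n",
              length(object@draws), d[1], d[2], d[3]))
})

#' LocationSymbolCounts: joint counts of code words per location
#'
#' The empirical basis of p(m | l), p(m) and, via Bayes' rule, p(l | m):
#' a locations x words table of nonnegative integer counts with equal row
#' sums (so the uniform location prior holds by construction).
#'
#' @slot counts integer matrix, locations x words
#' @slot wordIds character vector naming the word alphabet (columns)
#' @param counts,wordIds see slots
#' @return a validated \code{LocationSymbolCounts}
#' @export
setClass("LocationSymbolCounts",
  representation(counts = "matrix", wordIds = "character"))

setValidity("LocationSymbolCounts", function(object) {
  cnt <- object@counts
  if (any(cnt < 0) || anyNA(cnt)) return("counts must be nonnegative")
  if (any(cnt != round(cnt))) return("counts must be integers")
  rs <- rowSums(cnt)
  if (length(unique(rs)) != 1L)
    return("row sums must be equal (uniform location prior)")
  if (rs[1] == 0) return("counts must not be all zero")
  if (length(object@wordIds) != ncol(cnt))
    return("wordIds must name the columns")
  TRUE
})

#' @rdname LocationSymbolCounts-class
#' @export
LocationSymbolCounts <- function(counts, wordIds = NULL) {
  counts <- as.matrix(counts)
  if (is.null(wordIds)) {
    wordIds <- colnames(counts)
    if (is.null(wordIds)) wordIds <- sprintf("w%d", seq_len(ncol(counts)))
  }
  colnames(counts) <- wordIds
  storage.mode(counts) <- "double"
  new("LocationSymbolCounts", counts = counts,
      wordIds = as.character(wordIds))
}

setMethod("countsMatrix", "LocationSymbolCounts", function(object) object@counts)
setMethod("drawsPerLocation", "LocationSymbolCounts",
          function(object) unname(rowSums(object@counts)[1]))

setMethod("show", "LocationSymbolCounts", function(object) {
  cat(sprintf("LocationSymbolCounts: %d locations x %d words, %g draws/location\n",
              nrow(object@counts), ncol(object@counts),
              drawsPerLocation(object)))
})

#' MIEstimate: plug-in mutual information with 1/N bias extrapolation
#'
#' Holds the raw plug-in mutual information, the subset diagnostics used for
#' the 1/N series fit, the fitted bias slope, the unconstrained extrapolation
#' intercept, and the reported debiased value (intercept clamped to
#' [0, miRaw], since the plug-in bias is upward and information is
#' nonnegative).
#'
#' @slot miRaw raw plug-in MI in bits
#' @slot miDebiased clamped extrapolation intercept, bits
#' @slot miExtrapolated unclamped least-squares intercept, bits
#' @slot biasSlope fitted slope of MI against 1/N (bits * samples)
#' @slot subsetPoints data.frame with columns invN, mi
#' @slot nTotal total number of samples at full data
#' @export
setClass("MIEstimate",
  representation(miRaw = "numeric", miDebiased = "numeric",
                 miExtrapolated = "numeric", biasSlope = "numeric",
                 subsetPoints = "data.frame", nTotal = "numeric"))

MIEstimate <- function(miRaw, miDebiased, miExtrapolated, biasSlope,
                       subsetPoints, nTotal) {
  new("MIEstimate", miRaw = miRaw, miDebiased = miDebiased,
      miExtrapolated = miExtrapolated, biasSlope = biasSlope,
      subsetPoints = subsetPoints, nTotal = nTotal)
}

setMethod("miRaw", "MIEstimate", function(object) object@miRaw)
setMethod("miDebiased", "MIEstimate", function(object) object@miDebiased)
setMethod("miExtrapolated", "MIEstimate", function(object) object@miExtrapolated)
setMethod("biasSlope", "MIEstimate", function(object) object@biasSlope)
setMethod("subsetPoints", "MIEstimate", function(object) object@subsetPoints)

setMethod("show", "MIEstimate", function(object) {
  cat(sprintf("MIEstimate: raw %.4f bits, debiased %.4f bits (slope %.3g, N = %g)\n",
              object@miRaw, object@miDebiased, object@biasSlope,
              object@nTotal))
})

#' Tau80Result: two-sample MI as a function of inter-sample interval
#'
#' Table of mutual information for a two-temporal-sample scheme over a range
#' of inter-sample intervals, the estimated large-interval asymptote, and
#' tau80, the smallest probed interval whose MI reaches 80 percent of the
#' asymptote (definition "asymptote") or 80 percent of the incremental
#' information of the second sample (definition "incremental").
#'
#' @slot table data.frame with columns intervalFrames, intervalS, mi
#' @slot asymptote estimated asymptotic MI in bits
#' @slot tau80 seconds; NA when unresolved
#' @slot resolved FALSE when no probed interval reaches the criterion
#' @slot definition "asymptote" or "incremental"
#' @export
setClass("Tau80Result",
  representation(table = "data.frame", asymptote = "numeric",
                 tau80 = "numeric", resolved = "logical",
                 definition = "character"))

setMethod("show", "Tau80Result", function(object) {
  cat(sprintf("Tau80Result (%s): asymptote %.4f bits, tau80 = %s\n",
              object@definition, object@asymptote,
              if (object@resolved) sprintf("%.3g s", object@tau80)
              else "unresolved"))
})
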