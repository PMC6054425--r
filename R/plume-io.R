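#' Flatfield/background normalization of raw plume images
#'
#' Converts background-subtracted camera intensities into normalized
#' concentrations, c = I / (a_c * F), where F is the background-subtracted
#' flatfield and a_c calibrates against the source concentration. Negative
#' results (over-subtracted background noise) are clipped to 0. Pixels with
#' nonpositive flatfield cannot be normalized and are marked invalid in the
#' movie's mask; sampling them downstream is an error rather than a silent
#' NaN.
#'
#' @param stack a \code{\link{RawImageStack}}
#' @param frameRate acquisition rate (Hz) to record in the movie
#' @param pixelSize pixel pitch (mm/pixel)
#' @param sourcePixel integer (row, col) of the odor inlet
#' @param label free-text label for the movie
#' @return a \code{\link{PlumeMovie}}. Concentrations above 1 are permitted
#'   (instantaneous fluctuations can exceed the source-normalized mean) and
#'   reported with a warning.
#' @export
#' @examples
#' st <- RawImageStack(array(10, c(2, 2, 3)), matrix(10, 2, 2), 1)
#' m <- normalizeConcentration(st, 15, 0.74, c(1L, 1L))
#' all(frames(m) == 1)
normalizeConcentration <- function(stack, frameRate = 15, pixelSize = 0.74,
                                   sourcePixel = NULL, label = "") {
  stopifnot(is(stack, "RawImageStack"))
  ff <- stack@flatfield
  bad <- !(is.finite(ff) & ff > 0)
  d <- dim(stack@images)
  denom <- ff * stack@calibrationCoefficient
  denom[bad] <- 1  # placeholder; masked below
  conc <- stack@images / array(denom, d)
  conc[conc < 0] <- 0
  if (any(bad)) {
    conc[array(bad, d)] <- 0
  }
  nAbove <- sum(conc > 1)
  if (nAbove > 0) {
    warning(sprintf(
      "%d pixel-frames exceed the source-normalized concentration 1 (max %.3g)",
      nAbove, max(conc)), call. = FALSE)
  }
  if (is.null(sourcePixel)) sourcePixel <- c(1L, 1L)
  PlumeMovie(conc, frameRate = frameRate, pixelSize = pixelSize,
             sourcePixel = sourcePixel, validMask = !bad, label = label)
}

.PLMV_MAGIC <- charToRaw("PLMV1\n")

#' Write / read a concentration movie
#'
#' Self-describing single-file container: a magic string, a JSON header
#' carrying acquisition metadata and array dimensions, the validity mask,
#' and the frames as little-endian 64-bit floats. The round trip is
#' bit-exact in both frames and metadata.
#'
#' @param movie a \code{\link{PlumeMovie}}
#' @param path file path to write to / read from
#' @return \code{readMovie} returns a \code{\link{PlumeMovie}};
#'   \code{writeMovie} invisibly returns \code{path}.
#' @export
#' @examples
#' m <- PlumeMovie(array(runif(8), c(2, 2, 2)), 15, 0.74, c(1L, 1L))
#' f <- tempfile(fileext = ".pmv")
#' writeMovie(m, f)
#' identical(frames(readMovie(f)), frames(m))
writeMovie <- function(movie, path) {
  stopifnot(is(movie, "PlumeMovie"))
  d <- dim(movie@frames)
  hdr <- list(frame_rate_hz = movie@frameRate,
              pixel_size_mm = movie@pixelSize,
              source_row = movie@sourcePixel[1],
              source_col = movie@sourcePixel[2],
              label = movie@label,
              dim = d)
  hraw <- charToRaw(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.PLMV_MAGIC, con)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(as.raw(movie@validMask), con)
  writeBin(as.vector(movie@frames), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname writeMovie
#' @export
readMovie <- function(path) {
  if (!file.exists(path)) stop("no such movie file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = length(.PLMV_MAGIC))
  if (!identical(magic, .PLMV_MAGIC)) {
    stop("malformed movie container: bad magic string", call. = FALSE)
  }
  hlen <- readBin(con, "integer", size = 4L, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)))
  for (fld in c("frame_rate_hz", "pixel_size_mm", "source_row",
                "source_col", "label", "dim")) {
    if (is.null(hdr[[fld]])) {
      stop("malformed movie container: missing header field '", fld, "'",
           call. = FALSE)
    }
  }
  d <- as.integer(hdr$dim)
  mask <- readBin(con, "raw", n = d[1] * d[2])
  fr <- readBin(con, "double", n = prod(d), size = 8L, endian = "little")
  if (length(fr) != prod(d)) {
    stop("malformed movie container: truncated frames payload", call. = FALSE)
  }
  PlumeMovie(array(fr, d), frameRate = hdr$frame_rate_hz,
             pixelSize = hdr$pixel_size_mm,
             sourcePixel = c(hdr$source_row, hdr$source_col),
             validMask = matrix(as.logical(mask), d[1], d[2]),
             label = hdr$label)
}

#' Map grid coordinates (cm from source) to pixel indices
#'
#' Convention: column = source column + round(x_cm * 10 / pixelSize),
#' row = source row + round(y_cm * 10 / pixelSize), rounding half away from
#' zero; the whole grid is then shifted rigidly by \code{offset} = (dx, dy)
#' pixels (dx along columns, dy along rows). Mapping outside the frame or
#' onto a masked-invalid pixel is a placement error naming the point.
#'
#' @param grid a \code{\link{SamplingGrid}}
#' @param movie a \code{\link{PlumeMovie}} providing pixel pitch, source
#'   pixel and the validity mask
#' @param offset integer (dx, dy) rigid pixel shift
#' @return integer matrix with columns \code{row}, \code{col}, one row per
#'   grid point
#' @export
gridToPixelIndices <- function(grid, movie, offset = c(0L, 0L)) {
  stopifnot(is(grid, "SamplingGrid"), is(movie, "PlumeMovie"))
  p <- grid@points
  px <- movie@pixelSize
  cols <- movie@sourcePixel[2] + .roundHalfAway(p[, 1] * 10 / px) + offset[1]
  rows <- movie@sourcePixel[1] + .roundHalfAway(p[, 2] * 10 / px) + offset[2]
  d <- dim(movie@frames)
  for (i in seq_len(nrow(p))) {
    if (rows[i] < 1 || rows[i] > d[1] || cols[i] < 1 || cols[i] > d[2]) {
      stop(sprintf(
        "grid point (%.3g, %.3g) cm at offset (%d, %d) maps outside the frame",
        p[i, 1], p[i, 2], offset[1], offset[2]), call. = FALSE)
    }
    if (!movie@validMask[rows[i], cols[i]]) {
      stop(sprintf(
        "grid point (%.3g, %.3g) cm at offset (%d, %d) maps to a masked pixel",
        p[i, 1], p[i, 2], offset[1], offset[2]), call. = FALSE)
    }
  }
  cbind(row = as.integer(rows), col = as.integer(cols))
}

#' Preset sampling grids
#'
#' Two 4 x 4 grids of 16 locations each: a narrow grid close to the source
#' (x in 2.2-13.3 cm, y in +/- 4.4 cm) and a wide grid reaching further
#' downstream (x in 5.6-22.2 cm, y in +/- 2.6 cm), both relative to the odor
#' inlet.
#'
#' @param name "narrow" or "wide"
#' @param jitterRadius jitter radius in pixels for robustness envelopes
#' @return a \code{\link{SamplingGrid}} of 16 locations
#' @export
gridPreset <- function(name = c("narrow", "wide"), jitterRadius = 3L) {
  name <- match.arg(name)
  xy <- switch(name,
    narrow = expand.grid(x_cm = c(2.2, 5.9, 9.6, 13.3),
                         y_cm = c(-4.4, -1.5, 1.5, 4.4)),
    wide = expand.grid(x_cm = c(5.6, 11.1, 16.7, 22.2),
                       y_cm = c(-2.6, -1.1, 1.1, 2.6)))
  SamplingGrid(as.matrix(xy), name = name, jitterRadius = jitterRadius)
}

#' Read / write sampling grids as CSV
#'
#' CSV columns: \code{name}, \code{x_cm}, \code{y_cm}. A file may contain
#' several named grids; \code{readGridCSV} extracts one.
#'
#' @param path CSV file path
#' @param name grid to extract (default: the first name in the file)
#' @param grid a \code{\link{SamplingGrid}} to append/write
#' @param jitterRadius jitter radius for the returned grid
#' @param append append to an existing file rather than overwrite
#' @return \code{readGridCSV} returns a \code{\link{SamplingGrid}}
#' @export
readGridCSV <- function(path, name = NULL, jitterRadius = 3L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x_cm", "y_cm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("grid CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(name)) name <- df$name[1]
  df <- df[df$name == name, , drop = FALSE]
  if (nrow(df) == 0L) stop("no grid named '", name, "' in ", path,
                           call. = FALSE)
  SamplingGrid(as.matrix(df[, c("x_cm", "y_cm")]), name = name,
               jitterRadius = jitterRadius)
}

#' @rdname readGridCSV
#' @export
writeGridCSV <- function(grid, path, append = FALSE) {
  stopifnot(is(grid, "SamplingGrid"))
  df <- data.frame(name = grid@name, x_cm = grid@points[, 1],
                   y_cm = grid@points[, 2])
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, quote = FALSE)
  invisible(path)
}
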