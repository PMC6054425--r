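# fixtures built in code: tiny movies, grids and word sequences with known
# statistics

# deterministic little movie: H x W x T with a left-to-right gradient plus a
# per-frame ramp, source at (2, 2)
tinyMovie <- function(H = 6L, W = 8L, TT = 10L) {
  fr <- array(0, c(H, W, TT))
  for (t in seq_len(TT)) {
    fr[, , t] <- outer(seq_len(H) / H, seq_len(W) / W) * t / TT
  }
  PlumeMovie(fr, frameRate = 15, pixelSize = 10, sourcePixel = c(2L, 2L),
             label = "tiny")
}

# grid whose points land exactly on pixel centers of a 10 mm/pixel movie:
# point (x, y) cm -> pixel (sourceRow + y, sourceCol + x)
pixelGrid <- function(xs, ys, jitterRadius = 0L) {
  pts <- as.matrix(expand.grid(x_cm = xs, y_cm = ys))
  SamplingGrid(pts, name = "pixelgrid", jitterRadius = jitterRadius)
}

# surrogate movie on a 4 x 4 field with a q gradient across the 16 pixels;
# 10 mm pixels so pixelGrid(0:3, 0:3) addresses each pixel, source (1, 1)
surrogateFixture <- function(nFrames = 4000L, seed = 1L,
                             qmax = 0.45, whiff = 2, blank = 2,
                             correlationLengthCm = 0) {
  q <- matrix(seq(0.05, qmax, length.out = 16), 4, 4)
  med <- matrix(seq(0.5, 2, length.out = 16), 4, 4)
  simulateSurrogateField(SurrogateFieldParams(
    q, whiffMeanS = whiff, blankMeanS = blank,
    amplitudeMedianField = med, correlationLengthCm = correlationLengthCm,
    nFrames = nFrames, pixelSizeMm = 10, sourcePixel = c(1L, 1L),
    seed = seed))
}

# word sequences for an independent channel: every location draws uniformly
# from `nWords` symbols
independentWords <- function(nLoc = 16L, nWords = 16L, n = 200L, seed = 1L) {
  set.seed(seed)
  replicate(nLoc, as.character(sample.int(nWords, n, replace = TRUE)),
            simplify = FALSE)
}

# word sequences from the 2 x 2 joint [[0.4, 0.1], [0.1, 0.4]]:
# location 1 emits word "1" w.p. 0.2, location 2 w.p. 0.8; true MI is
# 1 - Hb(0.2) = 0.2780719 bits
knownJointWords <- function(n = 250L, seed = 1L) {
  set.seed(seed)
  list(as.character(stats::rbinom(n, 1, 0.2)),
       as.character(stats::rbinom(n, 1, 0.8)))
}

TRUE_MI_2x2 <- 1 + 0.8 * log2(0.8) + 0.2 * log2(0.2)  # 1 - Hb(0.2)
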