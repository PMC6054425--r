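#' PuffPlumeParams: parameters of the Gaussian-puff plume generator
#'
#' Desk-scale stand-in for planar concentration recordings of a turbulent
#' plume. Discrete odor puffs are released at the source at a fixed rate,
#' advected downstream at the mean wind speed plus a shared
#' Ornstein-Uhlenbeck crosswind meander, while their radius grows linearly
#' with age and their mass decays exponentially. The instantaneous
#' concentration field is the sum of Gaussian puff kernels. The model makes
#' no claim of Navier-Stokes fidelity; it is seedable and reproduces the
#' positively skewed, intermittent concentration statistics the analysis
#' assumes.
#'
#' @slot domainWidthCm,domainHeightCm imaged area (cm)
#' @slot durationS movie duration (s)
#' @slot frameRate frames/s
#' @slot pixelSizeMm pixel pitch (mm)
#' @slot meanWindSpeed downstream advection speed (cm/s)
#' @slot meanderAmplitude stationary s.d. of the crosswind meander (cm/s)
#' @slot meanderTimescale relaxation time of the meander (s)
#' @slot puffReleaseRate Poisson release rate (puffs/s)
#' @slot initialPuffRadius Gaussian radius at release (cm)
#' @slot puffGrowthRate radius growth (cm/s)
#' @slot puffMassDecayRate exponential mass decay (1/s)
#' @slot sourceOffsetCm source distance from the upstream frame edge (cm)
#' @slot noiseSd additive sensor-noise s.d. in source-normalized
#'   concentration units (emulates the camera-noise floor of planar
#'   fluorescence imaging; negative noisy values are clipped to 0, the
#'   same convention the flatfield normalization applies to
#'   over-subtracted backgrounds)
#' @slot seed RNG seed; identical seed implies identical movie
#' @slot label free text
#' @param domainWidthCm,domainHeightCm,durationS,frameRate,pixelSizeMm,meanWindSpeed,meanderAmplitude,meanderTimescale,puffReleaseRate,initialPuffRadius,puffGrowthRate,puffMassDecayRate,sourceOffsetCm,noiseSd,seed,label see slots
#' @return a validated \code{PuffPlumeParams}
#' @export
setClass("PuffPlumeParams",
  representation(domainWidthCm = "numeric", domainHeightCm = "numeric",
                 durationS = "numeric", frameRate = "numeric",
                 pixelSizeMm = "numeric", meanWindSpeed = "numeric",
                 meanderAmplitude = "numeric", meanderTimescale = "numeric",
                 puffReleaseRate = "numeric", initialPuffRadius = "numeric",
                 puffGrowthRate = "numeric", puffMassDecayRate = "numeric",
                 sourceOffsetCm = "numeric", noiseSd = "numeric",
                 seed = "integer", label = "character"))

setValidity("PuffPlumeParams", function(object) {
  pos <- c(domainWidthCm = object@domainWidthCm,
           domainHeightCm = object@domainHeightCm,
           durationS = object@durationS, frameRate = object@frameRate,
           pixelSizeMm = object@pixelSizeMm,
           meanWindSpeed = object@meanWindSpeed,
           meanderTimescale = object@meanderTimescale,
           puffReleaseRate = object@puffReleaseRate,
           initialPuffRadius = object@initialPuffRadius,
           sourceOffsetCm = object@sourceOffsetCm)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    return(paste("these parameters must be positive:",
                 paste(names(pos)[!(is.finite(pos) & pos > 0)],
                       collapse = ", ")))
  }
  if (object@meanderAmplitude < 0 || object@puffGrowthRate < 0 ||
      object@puffMassDecayRate < 0 || object@noiseSd < 0)
    return("meanderAmplitude, puffGrowthRate, puffMassDecayRate and noiseSd must be >= 0")
  if (object@durationS * object@frameRate < 2)
    return("duration * frameRate must be >= 2 frames")
  TRUE
})

#' @rdname PuffPlumeParams-class
#' @export
PuffPlumeParams <- function(domainWidthCm = 30, domainHeightCm = 16,
                            durationS = 240, frameRate = 15,
                            pixelSizeMm = 2.5, meanWindSpeed = 10,
                            meanderAmplitude = 2, meanderTimescale = 1,
                            puffReleaseRate = 5, initialPuffRadius = 0.4,
                            puffGrowthRate = 0.6, puffMassDecayRate = 0.15,
                            sourceOffsetCm = 2, noiseSd = 0.01,
                            seed = 1L, label = "puff") {
  new("PuffPlumeParams", domainWidthCm = domainWidthCm,
      domainHeightCm = domainHeightCm, durationS = durationS,
      frameRate = frameRate, pixelSizeMm = pixelSizeMm,
      meanWindSpeed = meanWindSpeed, meanderAmplitude = meanderAmplitude,
      meanderTimescale = meanderTimescale, puffReleaseRate = puffReleaseRate,
      initialPuffRadius = initialPuffRadius, puffGrowthRate = puffGrowthRate,
      puffMassDecayRate = puffMassDecayRate, sourceOffsetCm = sourceOffsetCm,
      noiseSd = noiseSd, seed = as.integer(seed), label = label)
}

#' Simulate a Gaussian-puff plume movie
#'
#' @param params a \code{\link{PuffPlumeParams}}
#' @param normalize rescale so the time-averaged concentration at the source
#'   pixel is 1 (shares units with flatfield-normalized imports). Set FALSE
#'   to keep raw kernel units.
#' @return a \code{\link{PlumeMovie}}; if no puff enters the domain, a
#'   warning is issued and an all-zero movie returned.
#' @export
#' @examples
#' p <- presetScenario("fast_flow_analog")
#' p@durationS <- 4
#' m <- simulatePuffPlume(p)
simulatePuffPlume <- function(params, normalize = TRUE) {
  stopifnot(is(params, "PuffPlumeParams"))
  validObject(params)
  px <- params@pixelSizeMm
  H <- max(2L, round(params@domainHeightCm * 10 / px))
  W <- max(2L, round(params@domainWidthCm * 10 / px))
  TT <- round(params@durationS * params@frameRate)
  dt <- 1 / params@frameRate
  srcRow <- as.integer(.roundHalfAway((H + 1) / 2))
  srcCol <- max(1L, as.integer(.roundHalfAway(params@sourceOffsetCm * 10 / px)))
  u <- params@meanWindSpeed

  # warm-up long enough that the oldest surviving puff predates frame 1
  transit <- params@domainWidthCm / u
  warmup <- 1.5 * transit

  framesArr <- array(0, c(H, W, TT))
  .withSeed(params@seed, {
    nGridSteps <- ceiling((params@durationS + warmup) / dt) + 1L
    # shared OU crosswind meander velocity, exact discretization
    tau <- params@meanderTimescale
    a <- exp(-dt / tau)
    vsd <- params@meanderAmplitude
    v <- numeric(nGridSteps)
    if (vsd > 0) {
      v[1] <- rnorm(1, 0, vsd)
      innov <- rnorm(nGridSteps - 1L, 0, vsd * sqrt(1 - a^2))
      for (k in 2:nGridSteps) v[k] <- a * v[k - 1L] + innov[k - 1L]
    }
    Y <- cumsum(v) * dt  # integrated crosswind displacement (cm)

    nPuff <- rpois(1, params@puffReleaseRate * (params@durationS + warmup))
    if (nPuff == 0L) {
      warning("no puffs released in the simulated interval; returning an all-zero movie",
              call. = FALSE)
    } else {
      release <- sort(runif(nPuff, -warmup, params@durationS))
      relIdx <- pmin(nGridSteps,
                     pmax(1L, floor((release + warmup) / dt) + 1L))
      rowIdx <- seq_len(H)
      colIdx <- seq_len(W)
      for (i in seq_len(TT)) {
        t <- (i - 1L) * dt
        gi <- min(nGridSteps, floor((t + warmup) / dt) + 1L)
        age <- t - release
        sigma <- params@initialPuffRadius + params@puffGrowthRate * age
        xCm <- params@sourceOffsetCm + u * age
        mass <- exp(-params@puffMassDecayRate * age)
        keep <- which(age >= 0 &
                      mass > 1e-4 &
                      (xCm - 3 * sigma) * 10 / px <= W)
        if (!length(keep)) next
        fr <- framesArr[, , i]
        for (k in keep) {
          sPx <- sigma[k] * 10 / px
          c0 <- srcCol + (xCm[k] - params@sourceOffsetCm) * 10 / px
          r0 <- srcRow + (Y[gi] - Y[relIdx[k]]) * 10 / px
          rlo <- max(1L, floor(r0 - 4 * sPx)); rhi <- min(H, ceiling(r0 + 4 * sPx))
          clo <- max(1L, floor(c0 - 4 * sPx)); chi <- min(W, ceiling(c0 + 4 * sPx))
          if (rlo > rhi || clo > chi) next
          rw <- rlo:rhi
          cw <- clo:chi
          amp <- mass[k] / (2 * pi * sigma[k]^2)
          gr <- exp(-(rw - r0)^2 / (2 * sPx^2))
          gc <- exp(-(cw - c0)^2 / (2 * sPx^2))
          fr[rw, cw] <- fr[rw, cw] + amp * outer(gr, gc)
        }
        framesArr[, , i] <- fr
      }
    }
    # sensor-noise floor, scaled to the noise-free source-mean signal;
    # negative noisy values are clipped like over-subtracted backgrounds
    srcSignal <- mean(framesArr[srcRow, srcCol, ])
    if (params@noiseSd > 0 && srcSignal > 0) {
      framesArr <- framesArr +
        rnorm(length(framesArr), 0, params@noiseSd * srcSignal)
      framesArr[framesArr < 0] <- 0
    }
  })
  if (normalize) {
    srcMean <- mean(framesArr[srcRow, srcCol, ])
    if (srcMean > 0) framesArr <- framesArr / srcMean
  }
  PlumeMovie(framesArr, frameRate = params@frameRate, pixelSize = px,
             sourcePixel = c(srcRow, srcCol), label = params@label)
}

#' SurrogateFieldParams: analytically tractable on/off whiff surrogate
#'
#' Each pixel's time series is a two-state renewal process: "blank"
#' (concentration 0) and "whiff" (a log-normal amplitude held for the whiff
#' duration). Whiff and blank durations are exponential, so the on/off
#' process is Markov with autocorrelation time
#' tau_c = whiffMean * blankMean / (whiffMean + blankMean). Switching is
#' shared across pixels within square blocks of side correlationLengthCm;
#' per-pixel whiff probabilities q below the block's stationary on
#' probability are realized by thinning whiff events pixel-wise. Marginals
#' are therefore known in closed form, which is what makes this generator
#' the default fixture for unit tests of the estimators.
#'
#' @slot qField H x W matrix of per-pixel whiff probabilities P(c > 0)
#' @slot whiffMeanS,blankMeanS mean whiff/blank durations (s)
#' @slot amplitudeMedianField H x W matrix of log-normal medians
#' @slot amplitudeSdlog log-normal sdlog of whiff amplitudes
#' @slot correlationLengthCm side of the shared-switching block (cm); 0
#'   makes every pixel independent
#' @slot nFrames,frameRate,pixelSizeMm,sourcePixel,seed,label bookkeeping
#' @param qField,whiffMeanS,blankMeanS,amplitudeMedianField,amplitudeSdlog,correlationLengthCm,nFrames,frameRate,pixelSizeMm,sourcePixel,seed,label see slots
#' @return a validated \code{SurrogateFieldParams}
#' @export
setClass("SurrogateFieldParams",
  representation(qField = "matrix", whiffMeanS = "numeric",
                 blankMeanS = "numeric", amplitudeMedianField = "matrix",
                 amplitudeSdlog = "numeric", correlationLengthCm = "numeric",
                 nFrames = "integer", frameRate = "numeric",
                 pixelSizeMm = "numeric", sourcePixel = "integer",
                 seed = "integer", label = "character"))

setValidity("SurrogateFieldParams", function(object) {
  q <- object@qField
  if (anyNA(q) || any(q < 0) || any(q > 1)) return("qField must lie in [0, 1]")
  if (object@whiffMeanS <= 0 || object@blankMeanS <= 0)
    return("whiff and blank mean durations must be positive")
  pOn <- object@whiffMeanS / (object@whiffMeanS + object@blankMeanS)
  if (max(q) > pOn + 1e-12)
    return(sprintf(
      "max qField (%.3g) exceeds the stationary whiff probability %.3g implied by the durations",
      max(q), pOn))
  if (!identical(dim(object@amplitudeMedianField), dim(q)))
    return("amplitudeMedianField must match qField dimensions")
  if (object@correlationLengthCm < 0) return("correlationLengthCm must be >= 0")
  if (object@nFrames < 2L) return("nFrames must be >= 2")
  if (object@frameRate <= 0 || object@pixelSizeMm <= 0)
    return("frameRate and pixelSizeMm must be positive")
  TRUE
})

#' @rdname SurrogateFieldParams-class
#' @export
SurrogateFieldParams <- function(qField, whiffMeanS = 2, blankMeanS = 2,
                                 amplitudeMedianField = NULL,
                                 amplitudeSdlog = 0.5,
                                 correlationLengthCm = 0,
                                 nFrames = 1000L, frameRate = 15,
                                 pixelSizeMm = 2.5, sourcePixel = c(1L, 1L),
                                 seed = 1L, label = "surrogate") {
  qField <- as.matrix(qField)
  if (is.null(amplitudeMedianField)) {
    amplitudeMedianField <- matrix(1, nrow(qField), ncol(qField))
  } else if (length(amplitudeMedianField) == 1L) {
    amplitudeMedianField <- matrix(amplitudeMedianField,
                                   nrow(qField), ncol(qField))
  }
  new("SurrogateFieldParams", qField = qField, whiffMeanS = whiffMeanS,
      blankMeanS = blankMeanS,
      amplitudeMedianField = as.matrix(amplitudeMedianField),
      amplitudeSdlog = amplitudeSdlog,
      correlationLengthCm = correlationLengthCm,
      nFrames = as.integer(nFrames), frameRate = frameRate,
      pixelSizeMm = pixelSizeMm, sourcePixel = as.integer(sourcePixel),
      seed = as.integer(seed), label = label)
}

#' Simulate the on/off whiff surrogate field
#'
#' @param params a \code{\link{SurrogateFieldParams}}
#' @return a \code{\link{PlumeMovie}} whose per-pixel marginal P(c > 0)
#'   equals the configured qField (within binomial sampling error)
#' @export
#' @examples
#' p <- SurrogateFieldParams(matrix(0.3, 2, 2), nFrames = 200L)
#' m <- simulateSurrogateField(p)
simulateSurrogateField <- function(params) {
  stopifnot(is(params, "SurrogateFieldParams"))
  validObject(params)
  H <- nrow(params@qField); W <- ncol(params@qField)
  TT <- params@nFrames
  dt <- 1 / params@frameRate
  pOn <- params@whiffMeanS / (params@whiffMeanS + params@blankMeanS)
  side <- if (params@correlationLengthCm <= 0) 1L else
    max(1L, as.integer(round(params@correlationLengthCm * 10 /
                             params@pixelSizeMm)))
  blockOf <- function(i) (i - 1L) %/% side
  framesArr <- array(0, c(H, W, TT))
  .withSeed(params@seed, {
    blocks <- unique(data.frame(br = blockOf(rep(seq_len(H), W)),
                                bc = blockOf(rep(seq_len(W), each = H))))
    for (b in seq_len(nrow(blocks))) {
      rows <- which(blockOf(seq_len(H)) == blocks$br[b])
      cols <- which(blockOf(seq_len(W)) == blocks$bc[b])
      qs <- params@qField[rows, cols, drop = FALSE]
      if (all(qs == 0)) next
      meds <- params@amplitudeMedianField[rows, cols, drop = FALSE]
      nPix <- length(qs)
      # alternating exponential renewal for the block state
      t <- 0
      on <- runif(1) < pOn
      horizon <- TT * dt
      while (t < horizon) {
        dur <- rexp(1, 1 / (if (on) params@whiffMeanS else params@blankMeanS))
        if (on) {
          # frames whose center time (i - 0.5) dt falls inside the whiff:
          # the movie point-samples the state, as snapshot imaging does
          i0 <- max(1L, ceiling(t / dt + 0.5))
          i1 <- min(TT, ceiling((t + dur) / dt + 0.5) - 1L)
          if (i0 <= i1 && i0 <= TT) {
            act <- runif(nPix) < as.vector(qs) / pOn
            if (any(act)) {
              amp <- numeric(nPix)
              amp[act] <- stats::rlnorm(sum(act),
                                        meanlog = log(as.vector(meds)[act]),
                                        sdlog = params@amplitudeSdlog)
              idx <- which(act)
              pr <- rep(rows, length(cols))[idx]
              pc <- rep(cols, each = length(rows))[idx]
              for (j in seq_along(idx)) {
                framesArr[pr[j], pc[j], i0:i1] <- amp[idx[j]]
              }
            }
          }
        }
        t <- t + dur
        on <- !on
      }
    }
  })
  PlumeMovie(framesArr, frameRate = params@frameRate,
             pixelSize = params@pixelSizeMm,
             sourcePixel = params@sourcePixel, label = params@label)
}

#' Preset plume scenarios
#'
#' Three qualitative regimes mirroring the wind-tunnel conditions the
#' analysis is designed around: a 10 cm/s free-stream analog, a 5 cm/s
#' analog, and a "boundary-flow-like" analog at 10 cm/s with larger puff
#' growth and weaker meander, i.e. a more diffusive, less intermittent
#' field whose information-vs-threshold curve is flatter.
#'
#' @param name one of "fast_flow_analog", "slow_flow_analog",
#'   "boundary_flow_analog"
#' @param seed RNG seed stored in the returned parameters
#' @return a \code{\link{PuffPlumeParams}}
#' @export
presetScenario <- function(name, seed = 1L) {
  presets <- list(
    fast_flow_analog = list(meanWindSpeed = 10, meanderAmplitude = 3,
                            meanderTimescale = 1, puffReleaseRate = 5,
                            initialPuffRadius = 0.4, puffGrowthRate = 0.3,
                            puffMassDecayRate = 0.15),
    slow_flow_analog = list(meanWindSpeed = 5, meanderAmplitude = 2,
                            meanderTimescale = 1.5, puffReleaseRate = 5,
                            initialPuffRadius = 0.4, puffGrowthRate = 0.25,
                            puffMassDecayRate = 0.1),
    boundary_flow_analog = list(meanWindSpeed = 10, meanderAmplitude = 0.8,
                                meanderTimescale = 1.5, puffReleaseRate = 10,
                                initialPuffRadius = 1.0, puffGrowthRate = 1.2,
                                puffMassDecayRate = 0.05))
  if (!name %in% names(presets)) {
    stop("unknown scenario '", name, "'; valid names: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  p <- presets[[name]]
  PuffPlumeParams(meanWindSpeed = p$meanWindSpeed,
                  meanderAmplitude = p$meanderAmplitude,
                  meanderTimescale = p$meanderTimescale,
                  puffReleaseRate = p$puffReleaseRate,
                  initialPuffRadius = p$initialPuffRadius,
                  puffGrowthRate = p$puffGrowthRate,
                  puffMassDecayRate = p$puffMassDecayRate,
                  seed = seed, label = name)
}

#' Read / write scenario parameters as YAML
#'
#' @param params a \code{\link{PuffPlumeParams}}
#' @param path YAML file path
#' @return \code{readScenarioYAML} returns a \code{\link{PuffPlumeParams}}
#' @export
writeScenarioYAML <- function(params, path) {
  stopifnot(is(params, "PuffPlumeParams"))
  sl <- methods::slotNames(params)
  vals <- lapply(sl, function(s) methods::slot(params, s))
  names(vals) <- sl
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writeScenarioYAML
#' @export
readScenarioYAML <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(PuffPlumeParams, vals)
}
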