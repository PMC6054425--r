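# Plug-in entropy / mutual information and 1/N bias extrapolation.

#' Shannon entropy in bits
#'
#' Plug-in entropy -sum p log2 p with the convention 0 * log 0 = 0. Input
#' may be a probability vector (sums to 1 within 1e-9) or a vector of
#' nonnegative counts, which is normalized first.
#'
#' @param x nonnegative numeric vector of probabilities or counts
#' @return entropy in bits
#' @export
#' @examples
#' shannonEntropy(rep(1, 16))      # 4 bits
#' shannonEntropy(c(0.8, 0.2))     # 0.721928 bits
shannonEntropy <- function(x) {
  if (anyNA(x) || any(x < 0)) {
    stop("entropy input must be nonnegative and free of NA", call. = FALSE)
  }
  s <- sum(x)
  if (s == 0) stop("entropy input must not be all zero", call. = FALSE)
  p <- x / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Plug-in mutual information between location and code word
#'
#' Evaluates I(L; M) = H(L) - sum_m p(m) H(L | m) directly from the
#' empirical location x word count table, with a uniform prior over
#' locations enforced by the equal-row-sum invariant of the table. The
#' result equals the symmetric form
#' sum p(l, m) log2[p(l, m) / (p(l) p(m))].
#'
#' @param x a \code{\link{LocationSymbolCounts}} or a nonnegative matrix
#'   with equal row sums (rows = locations, columns = words)
#' @return mutual information in bits; bounded by log2(number of locations)
#'   and by the word-marginal entropy
#' @export
#' @examples
#' pluginMutualInformation(rbind(c(40, 10), c(10, 40)))  # 0.2780719
pluginMutualInformation <- function(x) {
  cnt <- if (is(x, "LocationSymbolCounts")) x@counts else as.matrix(x)
  if (anyNA(cnt) || any(cnt < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  rs <- rowSums(cnt)
  if (max(rs) - min(rs) > 1e-9) {
    stop("unequal row sums: the location prior would not be uniform",
         call. = FALSE)
  }
  if (rs[1] == 0) stop("count table is all zero", call. = FALSE)
  nL <- nrow(cnt)
  hL <- log2(nL)
  pm <- colSums(cnt) / sum(cnt)
  # p(l | m) by Bayes' rule from p(m | l) and the uniform prior
  pml <- cnt / rs
  hLgivenM <- vapply(seq_len(ncol(cnt)), function(m) {
    if (pm[m] == 0) return(0)
    plm <- pml[, m] / (nL * pm[m])
    plm <- plm[plm > 0]
    -sum(plm * log2(plm))
  }, numeric(1))
  max(0, hL - sum(pm * hLgivenM))
}

# plug-in MI from per-location word sequences truncated to n draws each
.miFromSubset <- function(wordSeqs, idxList) {
  sub <- mapply(function(w, i) w[i], wordSeqs, idxList, SIMPLIFY = FALSE)
  alphabet <- unique(unlist(sub, use.names = FALSE))
  cnt <- t(vapply(sub, function(w) {
    tabulate(match(w, alphabet), nbins = length(alphabet))
  }, numeric(length(alphabet))))
  if (length(alphabet) == 1L) cnt <- matrix(cnt, ncol = 1L)
  pluginMutualInformation(cnt)
}

#' Finite-sample bias correction by 1/N extrapolation
#'
#' The plug-in MI estimator is upwardly biased, to first order linearly in
#' 1/N. This routine re-estimates MI on random subsets of the draws at each
#' requested fraction (without replacement, averaged over repetitions),
#' fits a least-squares line of MI against 1/N, and reports the intercept
#' as the bias-corrected information. The reported \code{miDebiased} is the
#' intercept clamped to [0, miRaw]; the unclamped intercept is kept in
#' \code{miExtrapolated} for diagnostics.
#'
#' @param wordSeqs list (one per location) of word vectors
#' @param fractions subset fractions in (0, 1]; must contain 1
#' @param repetitions random subsets per fraction (fraction 1 is computed
#'   once, deterministically)
#' @param seed RNG seed for the subset draws
#' @return an \code{\link{MIEstimate}}
#' @export
debiasByExtrapolation <- function(wordSeqs, fractions = c(1, 1/2, 1/4, 1/8),
                                  repetitions = 10L, seed = 1L) {
  if (!all(fractions > 0 & fractions <= 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  if (!any(fractions == 1)) {
    stop("fractions must contain 1 (the full data)", call. = FALSE)
  }
  if (repetitions < 1L) stop("repetitions must be >= 1", call. = FALSE)
  n <- min(lengths(wordSeqs))
  wordSeqs <- lapply(wordSeqs, function(w) w[seq_len(n)])
  if (any(fractions * n < 1)) {
    stop("some fraction leaves fewer than one draw per location",
         call. = FALSE)
  }
  nL <- length(wordSeqs)
  fractions <- sort(unique(fractions), decreasing = TRUE)
  pts <- .withSeed(seed, {
    do.call(rbind, lapply(fractions, function(f) {
      nf <- max(1L, round(f * n))
      if (nf == n) {
        mi <- .miFromSubset(wordSeqs, replicate(nL, seq_len(n),
                                                simplify = FALSE))
      } else {
        mi <- mean(vapply(seq_len(repetitions), function(r) {
          idx <- replicate(nL, sample.int(n, nf), simplify = FALSE)
          .miFromSubset(wordSeqs, idx)
        }, numeric(1)))
      }
      c(invN = 1 / (nf * nL), mi = mi)
    }))
  })
  pts <- as.data.frame(pts)
  miFull <- pts$mi[pts$invN == min(pts$invN)][1]
  if (length(unique(pts$invN)) < 2L) {
    slope <- 0
    intercept <- miFull
  } else {
    fit <- stats::lm(mi ~ invN, data = pts)
    intercept <- unname(stats::coef(fit)[1])
    slope <- unname(stats::coef(fit)[2])
  }
  MIEstimate(miRaw = miFull,
             miDebiased = min(max(intercept, 0), miFull),
             miExtrapolated = intercept,
             biasSlope = slope,
             subsetPoints = pts,
             nTotal = n * nL)
}

#' Entropy of the pooled code-word distribution
#'
#' Entropy in bits/word of the empirical distribution of code words pooled
#' across all locations: the lossless-compression bound for the code. With
#' \code{ignoreOrder = TRUE} the temporal sequence inside each word is
#' first collapsed to its sorted multiset, quantifying the additional
#' compression available when temporal order is discarded.
#'
#' @param wordSeqs list (one per location) of word vectors
#' @param ignoreOrder collapse each word's time tokens to a sorted multiset
#' @return entropy in bits per word
#' @export
wordDistributionEntropy <- function(wordSeqs, ignoreOrder = FALSE) {
  w <- unlist(wordSeqs, use.names = FALSE)
  if (length(w) == 0L) stop("word sequences are empty", call. = FALSE)
  if (ignoreOrder) {
    w <- vapply(strsplit(w, "-", fixed = TRUE),
                function(tk) paste(sort(tk), collapse = "-"), character(1))
  }
  shannonEntropy(table(w))
}
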