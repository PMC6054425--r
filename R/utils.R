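# internal helpers shared across modules

# round half away from zero (base round() rounds half to even)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# evaluate expr with a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

.assertScalarPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single finite positive number", name),
         call. = FALSE)
  }
  invisible(x)
}

# fixed-width zero-padded token so lexicographic string order equals
# numeric order when sorting multiset codes
.padTokens <- function(idx, width) {
  formatC(idx, width = width, flag = "0", format = "d")
}
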