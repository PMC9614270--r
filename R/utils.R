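# Internal helpers shared across modules.

# Deterministically derive a stage seed from a master seed and a tag, keeping
# the result in the 31-bit range R integers require.
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483647)
}

# Evaluate expr with a locally set RNG state, restoring the caller's state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

hannWindow <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Centered running mean with edge shrinkage, via cumulative sums.
runningMean <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n == 0L) return(x)
  half <- width %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

clip01 <- function(x) pmin(1, pmax(0, x))

# Maximal runs of TRUE in a logical vector: matrix with columns start, end
# (inclusive sample indices) and length.
trueRuns <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# FFT-friendly length (products of 2,3,5) >= n.
fastLength <- function(n) stats::nextn(n, factors = c(2, 3, 5))
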