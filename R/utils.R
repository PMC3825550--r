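# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_input <- function(...) stop(..., call. = FALSE)

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_input(sprintf("`%s` must be a single positive finite number", name))
  invisible(x)
}

# Prominence of each local maximum of `y`: height above the higher of the two
# deepest valleys separating it from a larger peak (or the signal edge).
peak_prominences <- function(y, idx) {
  vapply(idx, function(i) {
    left <- y[seq_len(i)]
    right <- y[i:length(y)]
    higher_l <- which(left > y[i])
    base_l <- if (length(higher_l)) min(left[(max(higher_l)):i]) else min(left)
    higher_r <- which(right > y[i])
    base_r <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    y[i] - max(base_l, base_r)
  }, numeric(1))
}

# Deterministic local-maximum detection with a prominence filter.
# Plateaus count once, at their earliest sample. `min_prominence` is an
# absolute threshold on the same scale as `y`.
find_peaks <- function(y, min_prominence = 0) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) return(integer(0))
  prom <- peak_prominences(y, cand)
  cand[prom >= min_prominence]
}

# Gaussian smoothing of a 1-D signal (reflected boundaries), sigma in samples.
gauss_smooth <- function(y, sigma) {
  if (sigma <= 0) return(y)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(y)
  pad <- c(y[pmin(n, (r + 1):2)], y, y[pmax(1, (n - 1):(n - r))])
  as.numeric(stats::filter(pad, k, sides = 2)[(r + 1):(r + n)])
}

# Quadratic (three-point) refinement of an extremum at integer index i of y
# sampled at uniform spacing h starting at x0. Returns c(x, y) of the vertex.
refine_quadratic <- function(x0, h, y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(c(x0 + (i - 1) * h, y[i]))
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(c(x0 + (i - 1) * h, y2))
  delta <- 0.5 * (y1 - y3) / denom
  delta <- max(-0.5, min(0.5, delta))
  c(x0 + (i - 1 + delta) * h, y2 - 0.25 * (y1 - y3) * delta)
}
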