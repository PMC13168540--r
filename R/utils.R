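# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Minimum-image displacement for one periodic dimension.
min_image <- function(d, L) d - L * round(d / L)

# Moving average with an odd window; edges use the available shorter window.
moving_average <- function(x, window) {
  if (window < 1L || window %% 2L != 1L)
    stop("'window' must be a positive odd integer", call. = FALSE)
  if (window == 1L) return(x)
  n <- length(x)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

# Standard error of the mean of a series by block averaging.
block_se <- function(x, n_blocks = 5L) {
  n <- length(x)
  if (n < n_blocks) n_blocks <- max(1L, n)
  if (n_blocks < 2L) return(NA_real_)
  idx <- cut(seq_len(n), breaks = n_blocks, labels = FALSE)
  bm <- tapply(x, idx, mean)
  stats::sd(bm) / sqrt(n_blocks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
}
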