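# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index, staying well
# below .Machine$integer.max so derived seeds remain valid R integers.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  # double arithmetic: products exceed .Machine$integer.max but stay
  # exact below 2^53, and the result fits a 32-bit R integer
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 7919) %%
               2147483629)
}

stop_arg <- function(...) stop(..., call. = FALSE)

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

# Quadratic (parabolic) refinement of a discrete peak: given three samples
# y at x - dx, x, x + dx with y2 the largest, return the vertex offset in
# units of dx, clamped to [-0.5, 0.5].
parabolic_offset <- function(y1, y2, y3) {
  denom <- y1 - 2 * y2 + y3
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(0)
  off <- 0.5 * (y1 - y3) / denom
  max(-0.5, min(0.5, off))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
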