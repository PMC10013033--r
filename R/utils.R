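#' @keywords internal
"_PACKAGE"

# Geometric mean with the empty-product convention (returns 1 for length 0).
# A single zero entry makes the product zero, which is a valid value here
# (a constant channel has zero fluctuation).
geom_mean <- function(x) {
  if (length(x) == 0L) return(1)
  if (any(x < 0)) stop("geometric mean requires non-negative values")
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

# Deterministic per-subject seed derived from a study seed. Kept strictly
# below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + 7919 * as.double(index)) %% 2147483647)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_in <- function(x, name, lower, upper, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_invalid("'%s' must be a single finite number", name)
  ok <- if (open) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok)
    stop_invalid("'%s' = %g is outside %s%g, %g%s", name, x,
                 if (open) "(" else "[", lower, upper, if (open) ")" else "]")
  invisible(x)
}

# Spectral radius of a square matrix.
spectral_radius <- function(A) {
  max(Mod(eigen(A, only.values = TRUE)$values))
}

# Map a time in ms (relative to stimulus onset) onto the nearest sample of a
# uniform time axis.
ms_to_index <- function(t_ms, time_axis) {
  idx <- which.min(abs(time_axis - t_ms))
  idx
}

# Indices of time_axis falling in [w1, w2) (inclusive start, exclusive end).
window_indices <- function(time_axis, window) {
  which(time_axis >= window[1] & time_axis < window[2])
}
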