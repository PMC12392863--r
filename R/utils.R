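# Internal numeric helpers shared across modules.

# sin(x)/x with the removable singularity filled by its series.
sinc <- function(x) {
  out <- rep(1, length(x))
  big <- abs(x) >= 1e-8
  out[big] <- sin(x[big]) / x[big]
  small <- !big & x != 0
  out[small] <- 1 - x[small]^2 / 6
  out
}

# Wrap an angle in degrees to (-180, 180]; -180 maps to +180 (same rotation).
wrap_angle <- function(deg) {
  w <- deg %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state; seed = NULL uses the current stream.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

stop_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
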