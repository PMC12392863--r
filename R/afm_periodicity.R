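#' Height profile container
#'
#' A 1-D fibril height trace sampled uniformly along the fibril contour,
#' both axes in nanometres. At least 32 samples are required and the
#' sampling must be uniform to within a relative tolerance of 1e-6.
#'
#' @param position positions along the trace, nm.
#' @param height heights, nm.
#' @return an object of class `height_profile` (a data frame).
#' @export
height_profile <- function(position, height) {
  position <- as.numeric(position); height <- as.numeric(height)
  if (length(position) != length(height))
    stop("position and height must have equal length", call. = FALSE)
  if (length(position) < 32)
    stop("a height profile needs at least 32 samples", call. = FALSE)
  dx <- diff(position)
  if (any(dx <= 0) ||
      (max(dx) - min(dx)) > 1e-6 * mean(dx))
    stop("positions must be uniformly spaced and increasing", call. = FALSE)
  structure(data.frame(position = position, height = height),
            class = c("height_profile", "data.frame"))
}

#' Read a 2-column height profile
#'
#' Whitespace-, comma- or tab-separated text with position and height in
#' nm; `#` comment lines and non-numeric headers are skipped.
#'
#' @param path file path.
#' @return a [height_profile()].
#' @export
read_height_profile <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(trimws(lines), "[[:space:],]+")
  ok <- vapply(fields, function(f)
    length(f) >= 2 && !anyNA(suppressWarnings(as.numeric(f[1:2]))), logical(1))
  mat <- t(vapply(fields[ok], function(f)
    as.numeric(f[1:2]), numeric(2)))
  height_profile(mat[, 1], mat[, 2])
}

#' Estimate the dominant periodicity of a height profile
#'
#' The profile is detrended (mean and linear trend removed), tapered with a
#' Hann window, zero-padded by `pad_factor`, and Fourier transformed. The
#' dominant non-zero-frequency peak of the power spectrum is refined by
#' parabolic interpolation of log-power across the peak and its neighbours;
#' the period is the reciprocal of the refined frequency. A peak is only
#' reported when its power exceeds `k_sig` times the median spectral power
#' (and when the implied period is at most half the profile length);
#' otherwise the estimate is "no period".
#'
#' @param p a [height_profile()].
#' @param k_sig significance ratio of peak power to median spectral power
#'   required to report a period (default 5).
#' @param pad_factor zero-padding factor for the FFT (default 4).
#' @return an object of class `period_estimate` with `period_nm` (or `NA`
#'   when no significant peak exists), `peak_power_ratio`, and spectrum
#'   metadata (`freq`, `power`, `df`).
#' @export
estimate_period <- function(p, k_sig = 5, pad_factor = 4) {
  stopifnot(inherits(p, "height_profile"))
  n <- nrow(p)
  dx <- mean(diff(p$position))
  h <- stats::residuals(stats::lm(height ~ position, data = p))
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))  # Hann taper
  hw <- h * w
  N <- pad_factor * n
  spec <- stats::fft(c(hw, rep(0, N - n)))
  nf <- floor(N / 2)
  power <- Mod(spec[2:(nf + 1)])^2   # drop the DC bin
  df <- 1 / (N * dx)
  freq <- seq_len(nf) * df
  m <- which.max(power)
  med <- stats::median(power)
  ratio <- if (med > 0) power[m] / med else Inf
  significant <- is.finite(power[m]) && power[m] > 1e-18 &&
    (med == 0 || ratio >= k_sig)
  period <- NA_real_
  if (significant) {
    # parabolic refinement on log power; guard the spectrum edges
    delta <- 0
    if (m > 1 && m < nf && power[m - 1] > 0 && power[m + 1] > 0) {
      lp <- log(power[(m - 1):(m + 1)])
      denom <- lp[1] - 2 * lp[2] + lp[3]
      if (denom < 0) delta <- 0.5 * (lp[1] - lp[3]) / denom
    }
    f_peak <- (m + delta) * df
    period <- 1 / f_peak
    span <- diff(range(p$position))
    if (period > span / 2) period <- NA_real_
  }
  structure(list(period_nm = period,
                 peak_power_ratio = if (med > 0) ratio else Inf,
                 freq = freq, power = power, df = df,
                 n = n, dx = dx),
            class = "period_estimate")
}

#' @export
print.period_estimate <- function(x, ...) {
  if (is.na(x$period_nm))
    cat("period estimate: no significant period\n")
  else
    cat(sprintf("period estimate: %.2f nm (peak/median power %.1f)\n",
                x$period_nm, x$peak_power_ratio))
  invisible(x)
}

#' Aggregate per-fibril period estimates
#'
#' Sample mean and standard deviation (n - 1 denominator) over the
#' estimates that carry a period; estimates without a period are excluded
#' and counted.
#'
#' @param estimates list of [estimate_period()] results (or a numeric
#'   vector of periods).
#' @param breaks histogram breaks passed to [graphics::hist()].
#' @return list with `mean_nm`, `sd_nm` (`NA` for a single estimate),
#'   `n`, `n_absent` and `histogram` (a [graphics::hist()] object).
#' @export
aggregate_periods <- function(estimates, breaks = "Sturges") {
  periods <- if (is.numeric(estimates)) estimates
  else vapply(estimates, function(e) e$period_nm, numeric(1))
  n_absent <- sum(is.na(periods))
  periods <- periods[!is.na(periods)]
  if (!length(periods))
    stop("no estimate carries a period", call. = FALSE)
  list(
    mean_nm = mean(periods),
    sd_nm = if (length(periods) > 1) stats::sd(periods) else NA_real_,
    n = length(periods),
    n_absent = n_absent,
    histogram = graphics::hist(periods, breaks = breaks, plot = FALSE)
  )
}
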