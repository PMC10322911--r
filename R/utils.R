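# Internal numerical helpers shared by the simulator and both detectors.

abort_config <- function(msg) abort(msg, class = "swrloop_config_error")
abort_input <- function(msg) abort(msg, class = "swrloop_input_error")

assert_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    abort_config(sprintf("`%s` must be a %s finite number, got %s",
                         name, if (strict) "positive" else "non-negative",
                         paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

# Clamp a band edge to 0.95 x Nyquist: a filter edge at (or above) Nyquist is
# ill-defined, and the 150-250 Hz ripple band hits exactly Nyquist at the
# 500 Hz online rate.
clamp_band <- function(band, rate_hz) {
  nyq <- rate_hz / 2
  hi <- min(band[2], 0.95 * nyq)
  lo <- band[1]
  if (lo <= 0 || lo >= hi) {
    abort_config(sprintf("band (%g, %g) Hz is not realisable at %g Hz sampling",
                         band[1], band[2], rate_hz))
  }
  c(lo, hi)
}

# n-pole Butterworth band-pass (signal::butter doubles the order for "pass",
# so poles must be even).
bandpass_filter <- function(band, rate_hz, poles = 4L) {
  band <- clamp_band(band, rate_hz)
  signal::butter(poles / 2L, band / (rate_hz / 2), type = "pass")
}

# Causal (forward-only) IIR filtering, optionally continuing from carried
# state; returns list(y, state) so streaming chunks chain exactly.
causal_filter <- function(filt, x, state = NULL) {
  b <- filt$b
  a <- filt$a
  if (is.null(state)) {
    y <- as.numeric(signal::filter(filt, x))
  } else {
    y <- as.numeric(signal::filter(b, a, x,
                                   init.x = state$x, init.y = state$y))
  }
  keep <- max(length(b), length(a)) - 1L
  list(y = y,
       state = list(x = tail(x, keep), y = tail(y, keep)))
}

# Trailing (causal) root-mean-square over `width` samples; partial windows at
# the start use the samples available so far. `carry` holds the squared tail
# of the previous chunk for streaming use.
trailing_rms <- function(x, width, carry = NULL) {
  sq <- x^2
  if (!is.null(carry)) sq <- c(carry, sq)
  cs <- cumsum(sq)
  n <- seq_along(sq)
  lo <- pmax(n - width, 0L)
  out <- sqrt((cs - c(0, cs)[lo + 1L]) / (n - lo))
  if (!is.null(carry)) out <- out[-seq_along(carry)]
  out
}

# Centered moving average (odd or even width; even widths are centered on the
# sample and its predecessor). NAs at the edges are filled with the overall
# mean so z-scoring downstream stays well defined.
centered_mean <- function(x, width) {
  if (width <= 1L) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
  y[is.na(y)] <- mean(x)
  y
}

# Centered Gaussian smoothing (kernel truncated at +/- 4 SD, renormalised);
# edge NAs filled with the overall mean. Unlike a boxcar, the Gaussian makes
# the supra-threshold span of a smoothed bump grow with its height, which is
# what lets a duration floor separate strong events from brief noise bumps.
gaussian_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  h <- ceiling(4 * sd_samples)
  kern <- stats::dnorm(seq(-h, h), 0, sd_samples)
  kern <- kern / sum(kern)
  y <- as.numeric(stats::filter(x, kern, sides = 2))
  y[is.na(y)] <- mean(x)
  y
}

# Gaussian 1/f^alpha noise of unit standard deviation, via FFT spectral
# shaping of white noise.
one_over_f_noise <- function(n, alpha = 1) {
  wh <- rnorm(n)
  if (alpha == 0) return(wh)
  X <- fft(wh)
  f <- c(1e-9, seq_len(n - 1L))
  f <- pmin(f, n - f)  # mirrored (negative) frequencies
  X <- X / f^(alpha / 2)
  X[1L] <- 0          # no DC component
  x <- Re(fft(X, inverse = TRUE)) / n
  x / sd(x)
}

# Rising edges of a logical vector, with optional carried last value from the
# previous chunk.
rising_edges <- function(above, prev = FALSE) {
  which(above & !c(prev, above[-length(above)]))
}

# Zero-phase filtering with odd-reflection end padding, so constants and
# edge samples come through without the start-up transients of plain
# forward-backward filtering. Padding is generous (50 filter lengths) to
# cover the long settle of low-cutoff anti-alias designs.
zero_phase <- function(filt, x) {
  n <- length(x)
  p <- min(50L * max(length(filt$b), length(filt$a)), n - 1L)
  pre <- 2 * x[1L] - x[(p + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- as.numeric(signal::filtfilt(filt, c(pre, x, post)))
  y[(p + 1L):(p + n)]
}
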