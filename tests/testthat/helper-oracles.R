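# Independent oracles. These deliberately avoid the package's code paths:
# filtering goes through stats::filter (convolution + recursive), RMS through
# cumulative sums, and state machines through separate vectorised logic.

# Causal IIR filtering via stats::filter: MA part as a one-sided convolution,
# AR part as a recursive filter (assumes a[1] == 1, as signal::butter emits).
oracle_iir <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  ma <- stats::filter(xp, b, method = "convolution", sides = 1)
  ma <- as.numeric(ma)[nb:length(xp)]
  as.numeric(stats::filter(ma, -a[-1], method = "recursive"))
}

# Trailing RMS via cumulative sums (partial windows at the start).
oracle_trailing_rms <- function(x, w) {
  cs <- cumsum(x^2)
  n <- seq_along(x)
  lo <- pmax(n - w, 0)
  sqrt((cs - c(0, cs)[lo + 1]) / (n - lo))
}

# Whole-vector (batch) replica of the online trigger state machine.
# Returns 1-based sample indices of crossings with their dispositions.
oracle_batch_detect <- function(lfp, thresholds, config) {
  fs <- config$online_rate_hz
  nyq <- fs / 2
  clamp <- function(band) c(band[1], min(band[2], 0.95 * nyq))
  br <- signal::butter(config$filter_poles / 2, clamp(config$ripple_band) / nyq,
                       type = "pass")
  bn <- signal::butter(config$filter_poles / 2, clamp(config$noise_band) / nyq,
                       type = "pass")
  w <- round(config$rms_window_s * fs)
  rr <- oracle_trailing_rms(oracle_iir(br$b, br$a, lfp[, "ripple"]), w)
  rn <- oracle_trailing_rms(oracle_iir(bn$b, bn$a, lfp[, "noise"]), w)
  th_r <- thresholds$threshold[thresholds$channel == "ripple"]
  th_n <- thresholds$threshold[thresholds$channel == "noise"]
  above <- rr > th_r
  cross <- which(above & !c(FALSE, above[-length(above)]))
  disp <- character(length(cross))
  last <- -Inf
  for (j in seq_along(cross)) {
    i <- cross[j]
    t_cross <- (i - 1) / fs
    if (rn[i] > th_n) {
      disp[j] <- "VETOED"
    } else if (t_cross - last < config$lockout_s) {
      disp[j] <- "LOCKED_OUT"
    } else {
      disp[j] <- "FIRED"
      last <- t_cross
    }
  }
  list(index = cross, disposition = disp)
}

# Band power of a segment via raw periodogram ordinates.
oracle_band_power <- function(x, fs, band = c(150, 250)) {
  n <- length(x)
  sp <- abs(fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs >= band[1] & freqs <= min(band[2], fs / 2)
  sum(sp[sel])
}

# Amplitude of a known-frequency tone by projection onto its quadratures.
oracle_tone_amplitude <- function(x, f_hz, fs) {
  tt <- (seq_along(x) - 1) / fs
  2 * sqrt(mean(x * sin(2 * pi * f_hz * tt))^2 +
             mean(x * cos(2 * pi * f_hz * tt))^2)
}

# Brute-force renewal simulation of the three-state dwell process,
# accumulating NREM occupancy (independent of generate_state_sequence).
oracle_nrem_fraction <- function(duration_s, means, n_rep = 1000,
                                 seed = 99) {
  set.seed(seed)
  total_nrem <- 0
  for (r in seq_len(n_rep)) {
    t0 <- 0
    st <- "NREM"
    while (t0 < duration_s) {
      d <- rexp(1, 1 / means[[st]])
      if (st == "NREM") total_nrem <- total_nrem + min(d, duration_s - t0)
      t0 <- t0 + d
      st <- switch(st,
        NREM = sample(c("REM", "WAKE"), 1),
        REM  = sample(c("WAKE", "NREM"), 1, prob = c(0.7, 0.3)),
        WAKE = "NREM")
    }
  }
  total_nrem / (n_rep * duration_s)
}

# Expected ripple count under the generator's definition (Poisson arrivals
# thinned by the refractory gap and end margin), by direct simulation.
oracle_thinned_count <- function(duration_s, rate, min_gap, n_rep = 200,
                                 seed = 7) {
  set.seed(seed)
  counts <- replicate(n_rep, {
    k <- rpois(1, rate * duration_s)
    o <- sort(runif(k, 0, max(0, duration_s - 0.15)))
    sum(c(TRUE, diff(o) > min_gap))
  })
  list(mean = mean(counts), sd = sd(counts))
}
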