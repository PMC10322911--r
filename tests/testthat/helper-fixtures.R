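# Shared fixture builders: everything is generated in code at test time.

# A short NREM-only session config (cheap to simulate).
short_config <- function(duration_s = 300, ripple_rate_hz = 0.35, ...) {
  session_config(duration_s = duration_s,
                 ripple_rate_hz = ripple_rate_hz,
                 states = state_config(mean_nrem_s = 1e9,
                                       initial_state = "NREM"),
                 ...)
}

# White Gaussian two-channel baseline matrix at the online rate.
white_baseline <- function(duration_s = 120, sd_uv = 10, fs = 500,
                           seed = 42) {
  set.seed(seed)
  n <- duration_s * fs
  cbind(ripple = rnorm(n, 0, sd_uv), noise = rnorm(n, 0, sd_uv))
}

# Hanning-windowed ripple burst (carrier f_hz, peak amplitude amp) as a
# vector of length round(dur_s * fs).
ripple_burst <- function(dur_s, amp, f_hz = 200, fs = 500) {
  tt <- seq(0, dur_s, by = 1 / fs)
  amp * sin(pi * tt / dur_s)^2 * sin(2 * pi * f_hz * tt)
}

# Inject a waveform into a channel of a matrix at time t0_s.
inject <- function(mat, channel, wave, t0_s, fs = 500) {
  idx <- floor(t0_s * fs) + seq_along(wave)
  mat[idx, channel] <- mat[idx, channel] + wave
  mat
}

# Wrap a bare matrix as a minimal session (no states -> calibration uses the
# recording start).
as_session <- function(mat, fs = 500) {
  structure(list(lfp = mat, sampling_rate_hz = fs,
                 duration_s = nrow(mat) / fs,
                 channel_roles = c(ripple = "ripple", noise = "noise"),
                 truth = NULL, artifacts = NULL, states = NULL,
                 band_sd_uv = NA_real_, seed = NA_integer_, config = NULL),
            class = "swr_session")
}

# SD of the causally band-pass-filtered ripple-band content of a vector
# (the amplitude unit used by the simulator).
band_sd_of <- function(x, fs = 500) {
  filt <- signal::butter(2, c(150, 0.95 * fs / 2) / (fs / 2), type = "pass")
  sd(as.numeric(signal::filter(filt, x)))
}
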