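#' Synthesize a two-channel LFP session with ground-truthed ripples
#'
#' Builds a ripple channel and a noise-reference channel of Gaussian
#' 1/f^alpha background (per-state SD scaling), embeds sharp-wave-ripple
#' events at Poisson times within NREM epochs on the ripple channel only,
#' and adds brief broadband artifact transients to both channels. Each
#' ripple is a Hanning-windowed sinusoid (carrier drawn per event) riding
#' on a negative raised-cosine sharp-wave deflection of the same extent.
#'
#' Amplitudes are specified in units of the baseline ripple-band RMS: the
#' standard deviation of the causally band-pass-filtered, ripple-free
#' background over the first two minutes of the session. An event of
#' `amplitude_z = 5` therefore peaks at five times the baseline ripple-band
#' SD, which is what makes `mean + k * SD` threshold calibration comparable
#' across seeds.
#'
#' @param config A [session_config()] (see [benchmark_config()] for the
#'   pinned evaluation fixture).
#' @param seed Integer seed; the whole session is reproducible from it.
#' @return An object of class `swr_session`: list with elements
#'   `lfp` (numeric matrix, samples x 2, microvolts, columns `ripple` and
#'   `noise`), `sampling_rate_hz`, `duration_s`, `channel_roles`,
#'   `truth` (tibble of ground-truth ripples: `onset_s`, `peak_s`,
#'   `offset_s`, `amplitude_z`, `center_freq_hz`, `duration_s`),
#'   `artifacts` (tibble `start_s`, `end_s`), `states` (epoch tibble),
#'   `band_sd_uv`, `seed` and `config`.
#' @examples
#' s <- synthesize_recording(session_config(duration_s = 60), seed = 1)
#' nrow(s$truth)
#' @export
synthesize_recording <- function(config = session_config(), seed = 1L) {
  if (!inherits(config, "swr_session_config")) {
    abort_config("`config` must be a `session_config()`")
  }
  set.seed(seed)
  fs <- config$sampling_rate_hz
  dur <- config$duration_s
  n <- round(dur * fs)

  states <- draw_state_sequence(dur, config$states)
  scal <- rep(1, n)
  for (i in seq_len(nrow(states))) {
    sc <- config$state_scaling[[states$state[i]]]
    i1 <- floor(states$start_s[i] * fs) + 1L
    i2 <- min(floor(states$end_s[i] * fs), n)
    if (i2 >= i1) scal[i1:i2] <- sc
  }

  bg_ripple <- one_over_f_noise(n, config$one_over_f_alpha) *
    config$noise_sd_uv * scal
  bg_noise <- one_over_f_noise(n, config$one_over_f_alpha) *
    config$noise_sd_uv * scal

  # Baseline ripple-band RMS: the amplitude unit for ripples and artifacts.
  ref_filt <- bandpass_filter(c(150, 250), fs)
  ref_n <- min(n, round(120 * fs))
  band_sd <- sd(causal_filter(ref_filt, bg_ripple[seq_len(ref_n)])$y)

  truth <- draw_ripple_truth(states, config)
  x_ripple <- bg_ripple
  if (nrow(truth) > 0L) {
    amp_uv <- truth$amplitude_z * band_sd
    for (i in seq_len(nrow(truth))) {
      idx <- floor(truth$onset_s[i] * fs):floor(truth$offset_s[i] * fs)
      idx <- idx[idx >= 0L & idx < n]
      tt <- (idx - truth$onset_s[i] * fs) / fs
      env <- sin(pi * tt / truth$duration_s[i])^2
      wave <- amp_uv[i] * env *
        (sin(2 * pi * truth$center_freq_hz[i] * tt) - 1)
      x_ripple[idx + 1L] <- x_ripple[idx + 1L] + wave
    }
  }

  n_art <- rpois(1L, config$artifact_rate_hz * dur)
  art_start <- sort(runif(n_art, 0, max(0, dur - config$artifact_duration_s)))
  artifacts <- tibble::tibble(start_s = art_start,
                              end_s = art_start + config$artifact_duration_s)
  x_noise <- bg_noise
  for (a in artifacts$start_s) {
    idx <- floor(a * fs):floor((a + config$artifact_duration_s) * fs)
    idx <- idx[idx >= 0L & idx < n]
    tt <- (idx - a * fs) / fs
    wave <- rnorm(length(idx)) *
      sin(pi * tt / config$artifact_duration_s)^2 *
      config$artifact_amplitude_sd * band_sd
    x_ripple[idx + 1L] <- x_ripple[idx + 1L] + wave
    x_noise[idx + 1L] <- x_noise[idx + 1L] + wave
  }

  lfp <- cbind(ripple = x_ripple, noise = x_noise)
  structure(list(lfp = lfp,
                 sampling_rate_hz = fs,
                 duration_s = dur,
                 channel_roles = c(ripple = "ripple", noise = "noise"),
                 truth = truth,
                 artifacts = artifacts,
                 states = states,
                 band_sd_uv = band_sd,
                 seed = seed,
                 config = config),
            class = "swr_session")
}

# State sequence without re-seeding (synthesize_recording owns the seed).
draw_state_sequence <- function(duration_s, config) {
  means <- config$mean_dwell_s
  state <- config$initial_state
  t0 <- 0
  start <- end <- numeric(0)
  lab <- character(0)
  while (t0 < duration_s) {
    dwell <- rexp(1L, rate = 1 / means[[state]])
    start <- c(start, t0)
    end <- c(end, min(t0 + dwell, duration_s))
    lab <- c(lab, state)
    t0 <- t0 + dwell
    state <- switch(state,
      NREM = sample(c("REM", "WAKE"), 1L),
      REM  = sample(c("WAKE", "NREM"), 1L, prob = c(0.7, 0.3)),
      WAKE = "NREM")
  }
  tibble::tibble(start_s = start, end_s = end, state = lab)
}

# Ground-truth ripple table: Poisson onsets within NREM, refractory gap,
# log-normal durations (clipped) and amplitudes (right-truncated), events
# kept only if fully inside their NREM epoch.
draw_ripple_truth <- function(states, config) {
  nrem <- state_intervals(states, "NREM")
  onsets <- numeric(0)
  epoch_end <- numeric(0)
  for (i in seq_len(nrow(nrem))) {
    len <- nrem[i, 2] - nrem[i, 1]
    k <- rpois(1L, config$ripple_rate_hz * len)
    if (k > 0L) {
      o <- sort(runif(k, nrem[i, 1], max(nrem[i, 1], nrem[i, 2] - 0.15)))
      onsets <- c(onsets, o)
      epoch_end <- c(epoch_end, rep(nrem[i, 2], k))
    }
  }
  if (length(onsets) == 0L) {
    return(tibble::tibble(onset_s = numeric(0), peak_s = numeric(0),
                          offset_s = numeric(0), amplitude_z = numeric(0),
                          center_freq_hz = numeric(0),
                          duration_s = numeric(0)))
  }
  ord <- order(onsets)
  onsets <- onsets[ord]
  epoch_end <- epoch_end[ord]
  keep <- c(TRUE, diff(onsets) > config$min_gap_s)
  onsets <- onsets[keep]
  epoch_end <- epoch_end[keep]
  m <- length(onsets)
  durs <- pmin(pmax(rlnorm(m, config$ripple_duration_meanlog,
                           config$ripple_duration_sdlog),
                    config$ripple_duration_bounds_s[1]),
               config$ripple_duration_bounds_s[2])
  amps <- pmin(rlnorm(m, config$ripple_amplitude_meanlog,
                      config$ripple_amplitude_sdlog),
               config$ripple_amplitude_max)
  cf <- runif(m, config$ripple_freq_range_hz[1], config$ripple_freq_range_hz[2])
  inside <- onsets + durs <= epoch_end
  tibble::tibble(onset_s = onsets,
                 peak_s = onsets + durs / 2,
                 offset_s = onsets + durs,
                 amplitude_z = amps,
                 center_freq_hz = cf,
                 duration_s = durs)[inside, ]
}

#' @export
print.swr_session <- function(x, ...) {
  cat(sprintf(
    "<swr_session> %.0f s at %g Hz, %d ripples, %d artifacts, %d epochs (seed %d)\n",
    x$duration_s, x$sampling_rate_hz, nrow(x$truth), nrow(x$artifacts),
    nrow(x$states), x$seed))
  invisible(x)
}
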