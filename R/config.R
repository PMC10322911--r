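#' Sleep-state sequence configuration
#'
#' Parameters of the alternating-renewal (semi-Markov) model that generates
#' WAKE/NREM/REM epoch sequences: exponential dwell times with per-state
#' means, and a fixed embedded transition chain
#' (NREM -> REM or WAKE equally; REM -> WAKE 0.7 / NREM 0.3; WAKE -> NREM).
#'
#' @param mean_nrem_s,mean_rem_s,mean_wake_s Mean epoch durations in seconds.
#' @param initial_state State the sequence starts in.
#' @return A list of class `swr_state_config`.
#' @export
state_config <- function(mean_nrem_s = 300, mean_rem_s = 60, mean_wake_s = 120,
                         initial_state = c("NREM", "REM", "WAKE")) {
  assert_scalar_pos(mean_nrem_s, "mean_nrem_s")
  assert_scalar_pos(mean_rem_s, "mean_rem_s")
  assert_scalar_pos(mean_wake_s, "mean_wake_s")
  initial_state <- match.arg(initial_state)
  structure(list(mean_dwell_s = c(NREM = mean_nrem_s, REM = mean_rem_s,
                                  WAKE = mean_wake_s),
                 initial_state = initial_state),
            class = "swr_state_config")
}

#' LFP session configuration
#'
#' Describes one simulated recording: background noise, sleep-state
#' structure, the ripple process embedded in NREM, and shared broadband
#' artifacts. Ripple amplitudes are expressed in units of the baseline
#' ripple-band RMS (the standard deviation of the band-pass-filtered,
#' ripple-free background), so detector thresholds calibrated as
#' mean + k SD are commensurable across seeds.
#'
#' @param duration_s Session length in seconds.
#' @param sampling_rate_hz 500 (online path) or 20000 (raw acquisition).
#' @param noise_sd_uv Broadband background SD in microvolts (NREM scale).
#' @param one_over_f_alpha Spectral exponent of the 1/f^alpha background.
#' @param state_scaling Per-state multiplicative SD scaling.
#' @param states A [state_config()].
#' @param ripple_rate_hz Poisson ripple rate per second of NREM.
#' @param ripple_duration_meanlog,ripple_duration_sdlog Log-normal parameters
#'   of ripple duration in seconds.
#' @param ripple_duration_bounds_s Durations are clipped to this range.
#' @param ripple_amplitude_meanlog,ripple_amplitude_sdlog Log-normal
#'   parameters of the envelope peak, in baseline ripple-band SD units.
#' @param ripple_amplitude_max Amplitude ceiling (SD units); the log-normal is
#'   right-truncated here, mimicking the bounded dynamic range of real
#'   recordings.
#' @param ripple_freq_range_hz Per-event carrier frequency range.
#' @param min_gap_s Minimum gap between consecutive ripple onsets
#'   (ripple-process refractoriness).
#' @param artifact_rate_hz Poisson rate of shared broadband artifacts.
#' @param artifact_amplitude_sd Artifact amplitude, in baseline ripple-band
#'   SD units.
#' @param artifact_duration_s Artifact transient width in seconds.
#' @return A list of class `swr_session_config`.
#' @export
session_config <- function(duration_s = 1800,
                           sampling_rate_hz = 500,
                           noise_sd_uv = 50,
                           one_over_f_alpha = 1,
                           state_scaling = c(NREM = 1.0, REM = 0.8, WAKE = 1.2),
                           states = state_config(),
                           ripple_rate_hz = 0.35,
                           ripple_duration_meanlog = log(0.100),
                           ripple_duration_sdlog = 0.12,
                           ripple_duration_bounds_s = c(0.060, 0.118),
                           ripple_amplitude_meanlog = log(5),
                           ripple_amplitude_sdlog = log(5 / 3) / qnorm(0.9),
                           ripple_amplitude_max = 8,
                           ripple_freq_range_hz = c(160, 230),
                           min_gap_s = 0.35,
                           artifact_rate_hz = 0.05,
                           artifact_amplitude_sd = 8,
                           artifact_duration_s = 0.008) {
  assert_scalar_pos(duration_s, "duration_s")
  if (!sampling_rate_hz %in% c(500, 20000)) {
    abort_config("`sampling_rate_hz` must be 500 or 20000")
  }
  assert_scalar_pos(noise_sd_uv, "noise_sd_uv")
  assert_scalar_pos(ripple_rate_hz, "ripple_rate_hz", strict = FALSE)
  assert_scalar_pos(artifact_rate_hz, "artifact_rate_hz", strict = FALSE)
  stopifnot(inherits(states, "swr_state_config"))
  if (any(ripple_duration_bounds_s < 0.020) ||
      any(ripple_duration_bounds_s > 0.120)) {
    abort_config("ripple durations must lie within [0.020, 0.120] s")
  }
  structure(as.list(environment()), class = "swr_session_config")
}

#' Reference-regime benchmark session configuration
#'
#' The version-pinned fixture used throughout the acceptance surface:
#' a 30-minute, 500 Hz, NREM-dominated sleep session with 0.35 ripples per
#' NREM second (log-normal amplitudes, median 5 SD, 10% below 3 SD, ceiling
#' 8 SD) and shared broadband artifacts at 0.05/s and 8 SD. Run with seeds
#' 1-10. Do not edit these values: downstream detection-rate and latency
#' regimes are calibrated against them.
#'
#' @return A `swr_session_config`.
#' @export
benchmark_config <- function() {
  session_config(
    duration_s = 1800,
    sampling_rate_hz = 500,
    states = state_config(mean_nrem_s = 900, mean_rem_s = 60, mean_wake_s = 30,
                          initial_state = "NREM")
  )
}

#' Online (closed-loop) detector configuration
#'
#' The streaming detector band-passes the ripple channel (150-250 Hz) and the
#' noise-reference channel (80-500 Hz), tracks a trailing RMS on both, and
#' fires on ripple-RMS threshold crossings when the noise channel is below its
#' own threshold. Band edges above 0.95 x Nyquist are clamped at filter-design
#' time (the 250 and 500 Hz edges are not realisable at the 500 Hz online
#' rate).
#'
#' @param ripple_band,noise_band Pass bands in Hz.
#' @param online_rate_hz Sampling rate of the online path.
#' @param rms_window_s Trailing RMS window length, seconds.
#' @param threshold_k_ripple,threshold_k_noise Threshold SD multipliers.
#' @param lockout_s Refractory period after a fired trigger; must cover the
#'   stimulation train span.
#' @param processing_latency_s Fixed detection-to-trigger delay of the
#'   processing chain, seconds.
#' @param filter_poles Number of poles of the Butterworth band-pass (even).
#' @return A list of class `swr_detection_config`.
#' @export
detection_config <- function(ripple_band = c(150, 250),
                             noise_band = c(80, 500),
                             online_rate_hz = 500,
                             rms_window_s = 0.010,
                             threshold_k_ripple = 4,
                             threshold_k_noise = 4,
                             lockout_s = 0.250,
                             processing_latency_s = 0.010,
                             filter_poles = 4L) {
  assert_scalar_pos(online_rate_hz, "online_rate_hz")
  assert_scalar_pos(rms_window_s, "rms_window_s")
  assert_scalar_pos(lockout_s, "lockout_s")
  assert_scalar_pos(processing_latency_s, "processing_latency_s",
                    strict = FALSE)
  if (filter_poles %% 2L != 0L || filter_poles < 2L) {
    abort_config("`filter_poles` must be a positive even integer")
  }
  clamp_band(ripple_band, online_rate_hz)  # validates realisability
  clamp_band(noise_band, online_rate_hz)
  structure(as.list(environment()), class = "swr_detection_config")
}

#' Offline (post hoc) detector configuration
#'
#' @param target_rate_hz Working rate; raw 20 kHz signals are decimated here.
#' @param ripple_band Pass band in Hz (upper edge clamped as online).
#' @param boundary_z,peak_z Normalized-power cutoffs: event boundaries are the
#'   nearest samples below `boundary_z` around a local maximum exceeding
#'   `peak_z`.
#' @param search_window_s Maximum outward search from a peak for its
#'   boundaries.
#' @param duration_bounds_s Inclusive event-duration limits, seconds.
#' @param blank_s Half-width of the blanking window around each stimulation
#'   pulse; blanked samples are excluded from z-scoring and cannot belong to
#'   events.
#' @param smooth_sd_s SD (seconds) of the centred Gaussian kernel that turns
#'   the squared band-pass signal into an instantaneous power estimate before
#'   z-scoring (roughly one ripple cycle). A Gaussian (rather than boxcar)
#'   kernel makes a bump's supra-boundary span grow with its height, so the
#'   duration floor can reject brief noise transients.
#' @param filter_poles Butterworth poles (even).
#' @return A list of class `swr_offline_config`.
#' @export
offline_config <- function(target_rate_hz = 500,
                           ripple_band = c(150, 250),
                           boundary_z = 2,
                           peak_z = 3,
                           search_window_s = 0.150,
                           duration_bounds_s = c(0.020, 0.200),
                           blank_s = 0.010,
                           smooth_sd_s = 0.007,
                           filter_poles = 4L) {
  assert_scalar_pos(target_rate_hz, "target_rate_hz")
  if (!(boundary_z < peak_z)) {
    abort_config("`boundary_z` must be smaller than `peak_z`")
  }
  if (any(duration_bounds_s <= 0) ||
      duration_bounds_s[1] >= duration_bounds_s[2]) {
    abort_config("`duration_bounds_s` must be positive and ordered")
  }
  assert_scalar_pos(search_window_s, "search_window_s")
  assert_scalar_pos(smooth_sd_s, "smooth_sd_s", strict = FALSE)
  clamp_band(ripple_band, target_rate_hz)
  structure(as.list(environment()), class = "swr_offline_config")
}

#' Stimulation protocols
#'
#' `MFB_TRAIN` is the rewarding medial-forebrain-bundle protocol: fourteen
#' 1-ms, 100 uA square pulses at 140 Hz (nominal 100 ms train).
#' `VHC_PULSE` is the ripple-disrupting ventral-hippocampal-commissure
#' protocol: a single 0.5-ms voltage pulse (5-15 V).
#'
#' @param kind Protocol name.
#' @param amplitude Pulse amplitude; uA for `MFB_TRAIN` (default 100),
#'   volts for `VHC_PULSE` (default 10, range 5-15).
#' @return A list of class `swr_stim_protocol`.
#' @export
stim_protocol <- function(kind = c("MFB_TRAIN", "VHC_PULSE"),
                          amplitude = NULL) {
  kind <- match.arg(kind)
  proto <- switch(kind,
    MFB_TRAIN = list(kind = kind, n_pulses = 14L, pulse_width_s = 0.001,
                     pulse_rate_hz = 140, amplitude = amplitude %||% 100,
                     amplitude_unit = "uA"),
    VHC_PULSE = list(kind = kind, n_pulses = 1L, pulse_width_s = 0.0005,
                     pulse_rate_hz = NA_real_, amplitude = amplitude %||% 10,
                     amplitude_unit = "V")
  )
  if (kind == "VHC_PULSE" && (proto$amplitude < 5 || proto$amplitude > 15)) {
    abort_config("VHC_PULSE amplitude must lie in 5-15 V")
  }
  structure(proto, class = "swr_stim_protocol")
}

#' Behavioural dataset configuration
#'
#' Per-group exponential decay of block freezing across extinction sessions,
#' truncated-Gaussian per-tone noise, and fear-recovery increments for the
#' renewal / remote / reinstatement probes. The closed-loop (CL) group decays
#' twice as fast as the non-stimulated (NS) and open-loop (OL) groups and
#' shows no recovery.
#'
#' @param n_per_group Animals per group (NS, OL, CL).
#' @param decay_rates Per-session decay rate of first-block freezing,
#'   by group.
#' @param tone_noise_sd Per-tone truncated-Gaussian noise SD
#'   (percentage points).
#' @param test_mean,test_sd,test_range Distribution of post-training test
#'   CS+ freezing (percent).
#' @param n_sessions Extinction sessions generated (max 7).
#' @param tones_per_session CS+ presentations per session.
#' @param recovery Named increments (percentage points) added at the
#'   renewal / remote / reinstatement probes for NS and OL animals; CL gets
#'   none.
#' @return A list of class `swr_behavior_config`.
#' @export
behavior_config <- function(n_per_group = c(NS = 9, OL = 9, CL = 9),
                            decay_rates = c(NS = 0.36, OL = 0.36, CL = 0.72),
                            tone_noise_sd = 5,
                            test_mean = 75, test_sd = 10,
                            test_range = c(40, 95),
                            n_sessions = 7,
                            tones_per_session = 20,
                            recovery = c(renewal = 30, remote = 25,
                                         reinstatement = 20)) {
  if (any(decay_rates < 0)) abort_config("decay rates must be non-negative")
  assert_scalar_pos(tone_noise_sd, "tone_noise_sd", strict = FALSE)
  if (n_sessions < 1 || n_sessions > 7) {
    abort_config("`n_sessions` must lie in 1-7")
  }
  structure(as.list(environment()), class = "swr_behavior_config")
}
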