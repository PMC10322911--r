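#' Calibrate per-animal detection thresholds
#'
#' Runs the causal online filter chain (band-pass then trailing RMS) over a
#' baseline segment of both channels and sets each channel's threshold at
#' `mean + k * SD` of its RMS trace, mirroring the per-animal threshold
#' adjustment performed before conditioning.
#'
#' The baseline segment emulates the supervised choice of a quiet sleep
#' baseline: when the input carries state labels, the first `baseline_s`
#' seconds of the first NREM epoch at least `baseline_s` long are used
#' (falling back, with a warning, to the start of the recording when no such
#' epoch exists); a bare matrix is used from its start.
#'
#' @param baseline A `swr_session`, or a numeric matrix (samples x 2, columns
#'   `ripple` then `noise`) at the online rate.
#' @param config A [detection_config()].
#' @param baseline_s Length of baseline used, seconds.
#' @param allow_degenerate If `TRUE`, a constant baseline (zero RMS variance)
#'   yields a threshold equal to the RMS mean instead of an error.
#' @return A tibble of class `swr_thresholds` with one row per channel:
#'   `channel`, `baseline_mean`, `baseline_sd`, `threshold` (all in
#'   microvolts of RMS).
#' @export
calibrate_thresholds <- function(baseline, config = detection_config(),
                                 baseline_s = 60, allow_degenerate = FALSE) {
  stopifnot(inherits(config, "swr_detection_config"))
  lfp <- session_lfp(baseline, config$online_rate_hz)
  fs <- config$online_rate_hz
  n_base <- round(baseline_s * fs)
  if (baseline_s < 60) {
    abort_input("baseline must be at least 60 s long")
  }
  if (nrow(lfp) < n_base) {
    abort_input(sprintf("baseline segment needs %d samples, recording has %d",
                        n_base, nrow(lfp)))
  }
  from <- 1L
  if (inherits(baseline, "swr_session") && !is.null(baseline$states)) {
    nrem <- baseline$states[baseline$states$state == "NREM" &
                              (baseline$states$end_s -
                                 baseline$states$start_s) >= baseline_s, ,
                            drop = FALSE]
    if (nrow(nrem) > 0L) {
      from <- floor(nrem$start_s[1L] * fs) + 1L
    } else {
      warn("no NREM epoch long enough for calibration; using recording start")
    }
  }
  lfp <- lfp[seq(from, length.out = n_base), , drop = FALSE]
  w <- max(1L, round(config$rms_window_s * fs))
  filts <- list(ripple = bandpass_filter(config$ripple_band, fs,
                                         config$filter_poles),
                noise = bandpass_filter(config$noise_band, fs,
                                        config$filter_poles))
  ks <- c(ripple = config$threshold_k_ripple, noise = config$threshold_k_noise)
  rows <- purrr::map(c("ripple", "noise"), function(ch) {
    rms <- trailing_rms(causal_filter(filts[[ch]], lfp[, ch])$y, w)
    m <- mean(rms)
    s <- sd(rms)
    if (s == 0 && !allow_degenerate) {
      abort_input(sprintf(
        "degenerate baseline on %s channel: RMS trace has zero variance", ch))
    }
    tibble::tibble(channel = ch, baseline_mean = m, baseline_sd = s,
                   threshold = m + ks[[ch]] * s)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("swr_thresholds", class(out))
  attr(out, "config") <- config
  out
}

# Extract the samples x 2 LFP matrix (ripple, noise) from a session or a
# bare matrix, checking channel-role metadata and the sampling rate.
session_lfp <- function(x, expect_rate = NULL) {
  if (inherits(x, "swr_session")) {
    roles <- x$channel_roles
    if (is.null(roles) || !all(c("ripple", "noise") %in% names(roles))) {
      abort_config("session lacks ripple/noise channel-role metadata")
    }
    if (!is.null(expect_rate) && x$sampling_rate_hz != expect_rate) {
      abort_input(sprintf(
        "recording is at %g Hz; decimate to %g Hz first (see decimate_raw())",
        x$sampling_rate_hz, expect_rate))
    }
    m <- x$lfp[, c(roles[["ripple"]], roles[["noise"]]), drop = FALSE]
    colnames(m) <- c("ripple", "noise")
    return(m)
  }
  if (is.matrix(x) && ncol(x) >= 2L) {
    m <- x[, 1:2, drop = FALSE]
    colnames(m) <- c("ripple", "noise")
    return(m)
  }
  abort_config("expected a `swr_session` or a samples x 2 matrix")
}

#' Streaming closed-loop ripple detection
#'
#' Processes the recording strictly causally, in chunks with carried filter,
#' RMS and trigger state: at each sample where the ripple-channel trailing
#' RMS first crosses its threshold (a rising edge), the detector emits one
#' log entry — `FIRED` if the noise channel is concurrently below its own
#' threshold and the previous fired trigger is at least one lockout period
#' old, `VETOED` if the noise channel is supra-threshold at that sample, and
#' `LOCKED_OUT` otherwise. Triggers are timestamped
#' `crossing + processing_latency`. Truncating the input at any sample never
#' changes triggers emitted before it.
#'
#' @param session A `swr_session` (or samples x 2 matrix) at the online rate.
#' @param thresholds A [calibrate_thresholds()] result.
#' @param config The [detection_config()] used for calibration.
#' @param chunk_s Chunk length used for streaming, seconds (does not affect
#'   the result).
#' @return A tibble of class `swr_triggers`: `crossing_s`, `trigger_s`,
#'   `disposition`.
#' @export
stream_detect <- function(session, thresholds, config = detection_config(),
                          chunk_s = 10) {
  stopifnot(inherits(config, "swr_detection_config"),
            inherits(thresholds, "swr_thresholds"))
  lfp <- session_lfp(session, config$online_rate_hz)
  fs <- config$online_rate_hz
  w <- max(1L, round(config$rms_window_s * fs))
  th_r <- thresholds$threshold[thresholds$channel == "ripple"]
  th_n <- thresholds$threshold[thresholds$channel == "noise"]
  filt_r <- bandpass_filter(config$ripple_band, fs, config$filter_poles)
  filt_n <- bandpass_filter(config$noise_band, fs, config$filter_poles)

  n <- nrow(lfp)
  chunk <- max(w + 1L, round(chunk_s * fs))
  starts <- seq(1L, n, by = chunk)
  st_r <- st_n <- NULL
  carry_r <- carry_n <- NULL
  prev_above <- FALSE
  last_fired <- -Inf
  cross_t <- numeric(0)
  disp <- character(0)

  for (s0 in starts) {
    idx <- s0:min(n, s0 + chunk - 1L)
    fr <- causal_filter(filt_r, lfp[idx, "ripple"], st_r)
    fn <- causal_filter(filt_n, lfp[idx, "noise"], st_n)
    st_r <- fr$state
    st_n <- fn$state
    rms_r <- trailing_rms(fr$y, w, carry_r)
    rms_n <- trailing_rms(fn$y, w, carry_n)
    carry_r <- tail(fr$y, w - 1L)^2
    carry_n <- tail(fn$y, w - 1L)^2
    above <- rms_r > th_r
    edges <- rising_edges(above, prev_above)
    prev_above <- above[length(above)]
    for (e in edges) {
      t_cross <- (idx[e] - 1L) / fs
      d <- if (rms_n[e] > th_n) {
        "VETOED"
      } else if (t_cross - last_fired < config$lockout_s) {
        "LOCKED_OUT"
      } else {
        last_fired <- t_cross
        "FIRED"
      }
      cross_t <- c(cross_t, t_cross)
      disp <- c(disp, d)
    }
  }

  out <- tibble::tibble(crossing_s = cross_t,
                        trigger_s = cross_t + config$processing_latency_s,
                        disposition = disp)
  class(out) <- c("swr_triggers", class(out))
  attr(out, "config") <- config
  out
}

#' Schedule stimulation trains from fired triggers
#'
#' One train per `FIRED` trigger, starting at the trigger time: the MFB
#' protocol lays out 14 pulse onsets at 1/140 s intervals (last onset
#' 13/140 s after the first; nominal train span 100 ms), the VHC protocol a
#' single 0.5 ms pulse.
#'
#' @param triggers A [stream_detect()] log (or any tibble with `trigger_s`
#'   and `disposition`).
#' @param protocol A [stim_protocol()].
#' @return A tibble of class `swr_stim_trains`: `train_id`, `train_start_s`,
#'   `pulse`, `onset_s`, `width_s`, `amplitude`.
#' @export
schedule_stimulation <- function(triggers, protocol = stim_protocol()) {
  if (!inherits(protocol, "swr_stim_protocol")) {
    abort_config("unknown stimulation protocol")
  }
  fired <- triggers$trigger_s[triggers$disposition == "FIRED"]
  offsets <- if (protocol$n_pulses > 1L) {
    (seq_len(protocol$n_pulses) - 1L) / protocol$pulse_rate_hz
  } else {
    0
  }
  out <- purrr::map2(fired, seq_along(fired), function(t0, id) {
    tibble::tibble(train_id = id, train_start_s = t0,
                   pulse = seq_len(protocol$n_pulses),
                   onset_s = t0 + offsets,
                   width_s = protocol$pulse_width_s,
                   amplitude = protocol$amplitude)
  }) |> dplyr::bind_rows()
  if (nrow(out) == 0L) {
    out <- tibble::tibble(train_id = integer(0), train_start_s = numeric(0),
                          pulse = integer(0), onset_s = numeric(0),
                          width_s = numeric(0), amplitude = numeric(0))
  }
  class(out) <- c("swr_stim_trains", class(out))
  attr(out, "protocol") <- protocol
  out
}

#' Add stimulation artifacts to a recording
#'
#' Superimposes a saturating square transient on both channels for the
#' duration of every stimulation pulse, so that offline detection can be
#' exercised under realistic stimulation contamination. With
#' `artifact_gain_uv = 0` the recording is returned unchanged.
#'
#' @param session A `swr_session`.
#' @param trains A [schedule_stimulation()] table.
#' @param artifact_gain_uv Amplitude of the square transient, microvolts.
#' @return The session with contaminated `lfp` and the trains recorded in
#'   `$stim_trains`.
#' @export
render_stimulus_artifact <- function(session, trains, artifact_gain_uv = 2000) {
  stopifnot(inherits(session, "swr_session"))
  fs <- session$sampling_rate_hz
  n <- nrow(session$lfp)
  if (nrow(trains) > 0L && artifact_gain_uv != 0) {
    if (any(trains$onset_s < 0 | trains$onset_s + trains$width_s >
            session$duration_s)) {
      abort_input("stimulation pulses extend beyond the recording span")
    }
    for (i in seq_len(nrow(trains))) {
      idx <- floor(trains$onset_s[i] * fs):ceiling(
        (trains$onset_s[i] + trains$width_s[i]) * fs)
      idx <- idx[idx >= 0L & idx < n] + 1L
      session$lfp[idx, ] <- session$lfp[idx, ] + artifact_gain_uv
    }
  }
  session$stim_trains <- trains
  session
}
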