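#' Decimate a raw recording to the working rate
#'
#' Zero-phase Butterworth anti-alias low-pass filtering (cut at 0.8 x the
#' stage's output Nyquist) followed by sample picking, applied in stages of
#' at most factor 10 for numerical stability, reducing e.g. 20 kHz
#' acquisition to the 500 Hz analysis rate. The input rate must be an
#' integer multiple of the target.
#'
#' @param x Numeric vector or samples x channels matrix, or a `swr_session`.
#' @param from_rate_hz Input sampling rate (taken from the session if given).
#' @param target_rate_hz Output rate.
#' @return Decimated vector/matrix of length `ceiling(n / ratio)`, or the
#'   session with `lfp` and `sampling_rate_hz` replaced.
#' @export
decimate_raw <- function(x, from_rate_hz = NULL, target_rate_hz = 500) {
  if (inherits(x, "swr_session")) {
    from_rate_hz <- x$sampling_rate_hz
    if (from_rate_hz == target_rate_hz) return(x)
    x$lfp <- decimate_raw(x$lfp, from_rate_hz, target_rate_hz)
    x$sampling_rate_hz <- target_rate_hz
    return(x)
  }
  if (is.null(from_rate_hz)) abort_config("`from_rate_hz` is required")
  q <- from_rate_hz / target_rate_hz
  if (abs(q - round(q)) > 1e-9 || q < 1) {
    abort_config(sprintf("input rate %g is not an integer multiple of %g",
                         from_rate_hz, target_rate_hz))
  }
  q <- as.integer(round(q))
  if (q == 1L) return(x)
  if (is.matrix(x)) {
    out <- apply(x, 2L, decimate_raw, from_rate_hz = from_rate_hz,
                 target_rate_hz = target_rate_hz)
    colnames(out) <- colnames(x)
    return(out)
  }
  for (qf in decimation_stages(q)) {
    lp <- signal::butter(6, 0.8 / qf, type = "low")
    x <- zero_phase(lp, x)[seq(1, length(x), by = qf)]
  }
  x
}

# Factor a decimation ratio into stages of at most 10 (large single-stage
# IIR designs at very low normalised cutoffs are numerically fragile).
decimation_stages <- function(q) {
  stages <- integer(0)
  for (p in c(7L, 5L, 3L, 2L)) {
    while (q %% p == 0L) {
      stages <- c(stages, p)
      q <- q %/% p
    }
  }
  if (q > 1L) stages <- c(stages, q)
  # merge small factors up to 10 (e.g. 2,2 -> 4) to keep stage count low
  stages <- sort(stages, decreasing = TRUE)
  out <- integer(0)
  while (length(stages) > 0L) {
    f <- stages[1L]
    stages <- stages[-1L]
    j <- which(f * stages <= 10L)[1L]
    if (!is.na(j)) {
      f <- f * stages[j]
      stages <- stages[-j]
    }
    out <- c(out, f)
  }
  out
}

#' Normalized squared signal
#'
#' Squares a band-pass-filtered trace, estimates instantaneous power with a
#' short centred Gaussian kernel, and z-scores the result over the whole
#' (non-blanked) trace, so event thresholds can be expressed in SDs of
#' normalized power. Blanked samples are excluded from the moments and
#' returned as `NA`.
#'
#' @param x Filtered signal (finite, length > 1).
#' @param smooth_sd Gaussian kernel SD in samples (0 = raw squared signal).
#' @param blank Optional logical vector marking samples to exclude.
#' @return Numeric z-trace; non-blanked values have mean 0 and SD 1.
#' @export
normalized_squared <- function(x, smooth_sd = 0, blank = NULL) {
  if (length(x) < 2L || !all(is.finite(x))) {
    abort_input("signal must be finite with length > 1")
  }
  p <- gaussian_smooth(x^2, smooth_sd)
  keep <- if (is.null(blank)) rep(TRUE, length(p)) else !blank
  m <- mean(p[keep])
  s <- sd(p[keep])
  if (!is.finite(s) || s == 0) {
    abort_input("degenerate signal: normalized power has zero variance")
  }
  z <- (p - m) / s
  z[!keep] <- NA_real_
  z
}

#' Offline (post hoc) ripple detection
#'
#' The gold-standard detector: zero-phase 150-250 Hz band-pass of the ripple
#' channel (upper edge clamped below Nyquist), normalized squared power,
#' candidate events where power exceeds `peak_z` SDs with boundaries walked
#' outward to the nearest sub-`boundary_z` samples (at most `search_window_s`
#' from the peak), overlapping candidates merged, and events kept only if
#' their duration lies within `duration_bounds_s` (inclusive). When
#' stimulation trains are supplied, samples within `blank_s` of any pulse are
#' blanked: excluded from z-scoring and unable to belong to events.
#'
#' @param x A `swr_session` (decimated automatically if at 20 kHz) or a
#'   numeric vector at `target_rate_hz` (the ripple channel).
#' @param config An [offline_config()].
#' @param stim_trains Optional [schedule_stimulation()] table for blanking.
#' @return A tibble of class `swr_events`, sorted and non-overlapping:
#'   `onset_s`, `peak_s`, `offset_s`, `peak_z`, `duration_s`.
#' @export
detect_offline <- function(x, config = offline_config(), stim_trains = NULL) {
  stopifnot(inherits(config, "swr_offline_config"))
  fs <- config$target_rate_hz
  if (inherits(x, "swr_session")) {
    x <- decimate_raw(x, target_rate_hz = fs)
    sig <- session_lfp(x)[, "ripple"]
  } else {
    sig <- as.numeric(x)
  }
  n <- length(sig)
  blank <- rep(FALSE, n)
  if (!is.null(stim_trains) && nrow(stim_trains) > 0L) {
    for (i in seq_len(nrow(stim_trains))) {
      i1 <- floor((stim_trains$onset_s[i] - config$blank_s) * fs) + 1L
      i2 <- ceiling((stim_trains$onset_s[i] + stim_trains$width_s[i] +
                       config$blank_s) * fs) + 1L
      blank[max(1L, i1):min(n, i2)] <- TRUE
    }
  }
  filt <- bandpass_filter(config$ripple_band, fs, config$filter_poles)
  filtered <- zero_phase(filt, sig)
  smooth_sd <- config$smooth_sd_s * fs
  z <- normalized_squared(filtered, smooth_sd, blank)

  events <- find_power_events(z, fs, config, smooth_sd)
  class(events) <- c("swr_events", class(events))
  attr(events, "config") <- config
  events
}

# Candidate extraction from a z-trace: supra-boundary runs, local maxima
# above peak_z (maxima within one smoothing-kernel width are one peak),
# boundary walk capped at the search window, overlap merge, duration filter.
find_power_events <- function(z, fs, config, smooth_sd) {
  empty <- tibble::tibble(onset_s = numeric(0), peak_s = numeric(0),
                          offset_s = numeric(0), peak_z = numeric(0),
                          duration_s = numeric(0))
  above <- !is.na(z) & z >= config$boundary_z
  if (!any(above)) return(empty)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  starts <- starts[keep]
  ends <- ends[keep]
  win <- round(config$search_window_s * fs)

  out <- list()
  for (r in seq_along(starts)) {
    i1 <- starts[r]
    i2 <- ends[r]
    seg <- z[i1:i2]
    peaks <- which(seg >= config$peak_z)
    if (length(peaks) == 0L) next
    # thin peaks: keep segment argmax within each cluster separated by less
    # than one smoothing window
    cl <- cumsum(c(1L, diff(peaks) > max(1, 4 * smooth_sd)))
    reps <- vapply(split(peaks, cl), function(ii) ii[which.max(seg[ii])], 1L)
    spans <- lapply(reps, function(pk) {
      c(max(i1, i1 + pk - 1L - win), min(i2, i1 + pk - 1L + win),
        i1 + pk - 1L)
    })
    # merge overlapping spans within the run (single event, max peak z)
    spans <- spans[order(vapply(spans, `[`, 1, 1))]
    cur <- spans[[1L]]
    for (sp in spans[-1L]) {
      if (sp[1] <= cur[2]) {
        cur[2] <- max(cur[2], sp[2])
        if (z[sp[3]] > z[cur[3]]) cur[3] <- sp[3]
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- sp
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  if (length(out) == 0L) return(empty)
  m <- do.call(rbind, out)
  ev <- tibble::tibble(onset_s = (m[, 1] - 1) / fs,
                       peak_s = (m[, 3] - 1) / fs,
                       offset_s = m[, 2] / fs,
                       peak_z = z[m[, 3]],
                       # integer sample count, so the inclusive duration
                       # bounds are exact at the boundaries
                       duration_s = (m[, 2] - m[, 1] + 1) / fs) |>
    dplyr::filter(.data$duration_s >= config$duration_bounds_s[1],
                  .data$duration_s <= config$duration_bounds_s[2]) |>
    dplyr::arrange(.data$onset_s)
  ev
}
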