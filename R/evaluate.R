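#' Match online triggers to reference ripple events
#'
#' One-to-one greedy matching: each `FIRED` trigger (in time order) is
#' assigned the unmatched reference event whose window
#' `[onset, offset + tolerance]` contains the trigger time and whose onset is
#' nearest (ties broken toward the earlier event). Unmatched triggers are
#' false-positive detections (FPD), unmatched reference events missed
#' detections (MD).
#'
#' @param triggers A [stream_detect()] log (only `FIRED` rows are scored).
#' @param events A reference event table — [detect_offline()] output or a
#'   ground-truth table with `onset_s` and `offset_s`.
#' @param tolerance_s Post-offset tolerance, seconds: an online trigger fires
#'   after event onset plus processing latency and may legitimately land just
#'   beyond the reference offset.
#' @return An object of class `swr_matches`: list with `pairs` (tibble
#'   `trigger_id`, `trigger_s`, `event_id`, `onset_s`, `latency_s`),
#'   `n_triggers`, `n_events`, `tolerance_s`.
#' @export
match_triggers <- function(triggers, events, tolerance_s = 0.050) {
  if (tolerance_s < 0) abort_config("`tolerance_s` must be non-negative")
  fired <- triggers$trigger_s[triggers$disposition == "FIRED"]
  if (is.unsorted(fired) || is.unsorted(events$onset_s)) {
    abort_input("triggers and events must be sorted in time")
  }
  n_ev <- nrow(events)
  used <- rep(FALSE, n_ev)
  pair_tr <- pair_ev <- integer(0)
  for (j in seq_along(fired)) {
    cand <- which(!used & events$onset_s <= fired[j] &
                    fired[j] <= events$offset_s + tolerance_s)
    if (length(cand) > 0L) {
      d <- abs(fired[j] - events$onset_s[cand])
      best <- cand[which.min(d)]  # which.min takes the first = earlier onset
      used[best] <- TRUE
      pair_tr <- c(pair_tr, j)
      pair_ev <- c(pair_ev, best)
    }
  }
  pairs <- tibble::tibble(trigger_id = pair_tr,
                          trigger_s = fired[pair_tr],
                          event_id = pair_ev,
                          onset_s = events$onset_s[pair_ev],
                          latency_s = fired[pair_tr] -
                            events$onset_s[pair_ev])
  structure(list(pairs = pairs,
                 n_triggers = length(fired),
                 n_events = n_ev,
                 tolerance_s = tolerance_s),
            class = "swr_matches")
}

#' @export
print.swr_matches <- function(x, ...) {
  cat(sprintf("<swr_matches> %d/%d triggers matched to %d events (tol %g s)\n",
              nrow(x$pairs), x$n_triggers, x$n_events, x$tolerance_s))
  invisible(x)
}

#' Positive / false-positive / missed detection rates
#'
#' The three-way partition of the union of online triggers and reference
#' events: positive detections (matched pairs), false positives (unmatched
#' triggers) and misses (unmatched events), each as a percentage of
#' `n_pd + n_fpd + n_md`, so the three rates sum to 100 by construction.
#'
#' @param matches A [match_triggers()] result.
#' @return A one-row tibble of class `swr_rates`: counts `n_pd`, `n_fpd`,
#'   `n_md` and percentages `pd_pct`, `fpd_pct`, `md_pct`.
#' @export
detection_rates <- function(matches) {
  stopifnot(inherits(matches, "swr_matches"))
  n_pd <- nrow(matches$pairs)
  n_fpd <- matches$n_triggers - n_pd
  n_md <- matches$n_events - n_pd
  total <- n_pd + n_fpd + n_md
  if (total == 0L) {
    abort_input("no triggers and no events: detection rates are undefined")
  }
  out <- tibble::tibble(n_pd = n_pd, n_fpd = n_fpd, n_md = n_md,
                        pd_pct = 100 * n_pd / total,
                        fpd_pct = 100 * n_fpd / total,
                        md_pct = 100 * n_md / total)
  class(out) <- c("swr_rates", class(out))
  out
}

#' Trigger-latency summary
#'
#' Latency of each positive detection — trigger time minus reference event
#' onset — with a 1-ms-bin histogram (covering at least 0-50 ms, extended so
#' every matched pair is counted) and its modal bin. Negative latencies are
#' kept and flagged rather than dropped.
#'
#' @param matches A [match_triggers()] result.
#' @return An object of class `swr_latency`: `latencies_s`, `histogram`
#'   (tibble `bin_ms` left edge, `count`), `min_s`, `max_s`, `modal_bin_ms`,
#'   `n_negative`, `empty` flag.
#' @export
trigger_latencies <- function(matches) {
  stopifnot(inherits(matches, "swr_matches"))
  lat <- matches$pairs$latency_s
  if (length(lat) == 0L) {
    warn("no positive detections: latency summary is empty")
    return(structure(list(latencies_s = numeric(0),
                          histogram = tibble::tibble(bin_ms = 0:49,
                                                     count = rep(0L, 50)),
                          min_s = NA_real_, max_s = NA_real_,
                          modal_bin_ms = NA_real_, n_negative = 0L,
                          empty = TRUE),
                     class = "swr_latency"))
  }
  ms <- lat * 1000
  lo <- min(0, floor(min(ms)))
  hi <- max(50, ceiling(max(ms)) + 1)
  edges <- seq(lo, hi, by = 1)
  counts <- tabulate(findInterval(ms, edges), nbins = length(edges) - 1L)
  hist <- tibble::tibble(bin_ms = edges[-length(edges)], count = counts)
  structure(list(latencies_s = lat,
                 histogram = hist,
                 min_s = min(lat), max_s = max(lat),
                 modal_bin_ms = hist$bin_ms[which.max(hist$count)],
                 n_negative = sum(lat < 0),
                 empty = FALSE),
            class = "swr_latency")
}

#' @export
print.swr_latency <- function(x, ...) {
  if (x$empty) {
    cat("<swr_latency> empty (no positive detections)\n")
  } else {
    cat(sprintf(
      "<swr_latency> n=%d, min %.1f ms, modal bin %g ms, max %.1f ms\n",
      length(x$latencies_s), 1000 * x$min_s, x$modal_bin_ms, 1000 * x$max_s))
  }
  invisible(x)
}
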