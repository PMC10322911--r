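#' Tidy a trigger-event match table
#'
#' @param x A [match_triggers()] result.
#' @param ... Unused.
#' @return The matched pairs as a tibble (`trigger_id`, `trigger_s`,
#'   `event_id`, `onset_s`, `latency_s`).
#' @method tidy swr_matches
#' @export
tidy.swr_matches <- function(x, ...) x$pairs

#' One-row summary of a match table
#'
#' @param x A [match_triggers()] result.
#' @param ... Unused.
#' @return The [detection_rates()] tibble.
#' @method glance swr_matches
#' @export
glance.swr_matches <- function(x, ...) detection_rates(x)

#' Tidy a latency summary
#'
#' @param x A [trigger_latencies()] result.
#' @param ... Unused.
#' @return The 1-ms-bin histogram tibble (`bin_ms`, `count`).
#' @method tidy swr_latency
#' @export
tidy.swr_latency <- function(x, ...) x$histogram

#' One-row summary of trigger latencies
#'
#' @param x A [trigger_latencies()] result.
#' @param ... Unused.
#' @return Tibble with `n`, `min_ms`, `modal_bin_ms`, `max_ms`, `n_negative`.
#' @method glance swr_latency
#' @export
glance.swr_latency <- function(x, ...) {
  tibble::tibble(n = length(x$latencies_s),
                 min_ms = 1000 * x$min_s,
                 modal_bin_ms = x$modal_bin_ms,
                 max_ms = 1000 * x$max_s,
                 n_negative = x$n_negative)
}

#' Tidy a freezing dataset
#'
#' @param x A [generate_freezing_dataset()] result.
#' @param ... Unused.
#' @return The tone-level tibble (`animal`, `group`, `session`, `tone`,
#'   `freezing_pct`).
#' @method tidy swr_freezing_dataset
#' @export
tidy.swr_freezing_dataset <- function(x, ...) x$tones

#' Group-level summary of a freezing dataset
#'
#' @param x A [generate_freezing_dataset()] result.
#' @param ... Passed to [summarize_extinction()].
#' @return One row per group: median sessions to remission, fraction
#'   remitted, median delta freezing at the remote probe.
#' @method glance swr_freezing_dataset
#' @export
glance.swr_freezing_dataset <- function(x, ...) {
  summarize_extinction(x, ...) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_sessions_to_remission = median(.data$sessions_to_remission),
      fraction_remitted = mean(.data$remitted),
      median_delta_remote = median(.data$delta_remote),
      .groups = "drop")
}
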