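#' Plot a session segment with ground-truth ripples
#'
#' Both channels over a time window, with ground-truth ripple extents shaded
#' and artifacts marked.
#'
#' @param object A `swr_session`.
#' @param from_s,to_s Window to draw, seconds.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot swr_session
#' @export
autoplot.swr_session <- function(object, from_s = 0,
                                 to_s = min(10, object$duration_s), ...) {
  fs <- object$sampling_rate_hz
  idx <- seq(max(1L, floor(from_s * fs) + 1L), min(nrow(object$lfp),
                                                   ceiling(to_s * fs)))
  df <- tibble::tibble(time_s = (idx - 1) / fs,
                       ripple = object$lfp[idx, "ripple"],
                       noise = object$lfp[idx, "noise"]) |>
    tidyr::pivot_longer(-"time_s", names_to = "channel",
                        values_to = "uv")
  truth <- dplyr::filter(object$truth, .data$offset_s >= from_s,
                         .data$onset_s <= to_s)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$uv)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "LFP (µV)") +
    ggplot2::theme_minimal()
  if (nrow(truth) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = truth,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue")
  }
  p
}

#' Plot a trigger-latency histogram
#'
#' The 1-ms-bin histogram of delays between reference event onsets and
#' stimulation triggers.
#'
#' @param object A [trigger_latencies()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot swr_latency
#' @export
autoplot.swr_latency <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(.data$bin_ms, .data$count)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::labs(x = "trigger latency from event onset (ms)",
                  y = "stimulations") +
    ggplot2::theme_minimal()
}

#' Plot extinction trajectories by group
#'
#' Per-session first-block freezing relative to the post-training test, per
#' animal, coloured by group.
#'
#' @param object A [generate_freezing_dataset()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot swr_freezing_dataset
#' @export
autoplot.swr_freezing_dataset <- function(object, ...) {
  df <- object$tones |>
    dplyr::group_by(.data$animal, .data$group, .data$session) |>
    dplyr::summarise(first_block = block_average(.data$freezing_pct)[1L],
                     .groups = "drop") |>
    dplyr::left_join(object$animals[, c("animal", "test_cs_freezing")],
                     by = "animal") |>
    dplyr::mutate(reduction = freezing_reduction(.data$first_block,
                                                 .data$test_cs_freezing))
  ggplot2::ggplot(df, ggplot2::aes(.data$session, .data$reduction,
                                   group = .data$animal,
                                   colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 20, linetype = "dashed") +
    ggplot2::labs(x = "extinction session",
                  y = "freezing (% of post-training test)") +
    ggplot2::theme_minimal()
}
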