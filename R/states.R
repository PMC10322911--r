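#' Generate a sleep-state epoch sequence
#'
#' Draws an alternating-renewal sequence of WAKE/NREM/REM epochs covering
#' `[0, duration_s)`: exponential dwell times with the configured per-state
#' means, chained by a fixed embedded transition matrix
#' (NREM -> REM/WAKE equally, REM -> WAKE 0.7 / NREM 0.3, WAKE -> NREM).
#' The result is deterministic under a fixed seed.
#'
#' @param duration_s Total duration in seconds.
#' @param config A [state_config()].
#' @param seed Integer seed.
#' @return A tibble with columns `start_s`, `end_s`, `state`; epochs are
#'   sorted, non-overlapping and contiguous over `[0, duration_s)`.
#' @examples
#' generate_state_sequence(3600, state_config(), seed = 1)
#' @export
generate_state_sequence <- function(duration_s, config = state_config(),
                                    seed = 1L) {
  assert_scalar_pos(duration_s, "duration_s")
  stopifnot(inherits(config, "swr_state_config"))
  set.seed(seed)
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

# Intervals of one state, as a two-column matrix (used by the simulator).
state_intervals <- function(states, label) {
  sel <- states[states$state == label, , drop = FALSE]
  cbind(sel$start_s, sel$end_s)
}

#' Time spent in each sleep state
#'
#' Fraction of total recording time per state label, the summary underlying
#' sleep-architecture comparisons.
#'
#' @param states A state-sequence tibble from [generate_state_sequence()].
#' @return A tibble with `state`, `seconds`, `fraction` (fractions sum to 1).
#' @export
sleep_architecture <- function(states) {
  if (!is.data.frame(states) || nrow(states) == 0L) {
    abort_input("`states` must be a non-empty state-sequence data frame")
  }
  states |>
    dplyr::mutate(dur = .data$end_s - .data$start_s) |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(seconds = sum(.data$dur), .groups = "drop") |>
    dplyr::mutate(fraction = .data$seconds / sum(.data$seconds)) |>
    dplyr::arrange(dplyr::desc(.data$seconds))
}
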