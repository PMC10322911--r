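#' Block-average tone freezing
#'
#' Means over consecutive non-overlapping blocks of tones (the 20 daily CS+
#' presentations fall into four blocks of five).
#'
#' @param tone_freezing Numeric vector of per-tone freezing percentages.
#' @param block_size Tones per block; must divide the vector length.
#' @return Numeric vector of block means.
#' @examples
#' block_average(c(rep(100, 5), rep(0, 15)))
#' @export
block_average <- function(tone_freezing, block_size = 5L) {
  if (length(tone_freezing) %% block_size != 0L) {
    abort_input(sprintf("length %d is not divisible by block size %d",
                        length(tone_freezing), block_size))
  }
  as.numeric(colMeans(matrix(tone_freezing, nrow = block_size)))
}

#' Freezing reduction relative to the post-training test
#'
#' `first_block * 100 / test_cs_freezing` — extinction-session freezing as a
#' percentage of the initial (post-training CS+ test) freezing. Values above
#' 100 are possible when freezing exceeds the test level.
#'
#' @param first_block_freezing First-block freezing, percent (vectorised).
#' @param test_cs_freezing Post-training test CS+ freezing, percent (> 0).
#' @return Reduction percentage(s).
#' @examples
#' freezing_reduction(30, 60)  # 50
#' @export
freezing_reduction <- function(first_block_freezing, test_cs_freezing) {
  if (!is.numeric(test_cs_freezing) || any(test_cs_freezing <= 0)) {
    abort_input("`test_cs_freezing` must be positive (undefined baseline)")
  }
  first_block_freezing * 100 / test_cs_freezing
}

#' First extinction day reaching fear remission
#'
#' Remission is achieved on the first day whose first-block freezing falls
#' strictly below `threshold_pct` percent of the initial test freezing;
#' animals not reaching it within `max_days` are reported as not achieved
#' (`NA`).
#'
#' @param daily_first_block First-block freezing per extinction day, percent
#'   (1 to `max_days` values).
#' @param test_cs_freezing Post-training test CS+ freezing, percent (> 0).
#' @param threshold_pct Remission threshold, percent of initial freezing.
#' @param max_days Maximum number of extinction days considered.
#' @return Integer day, or `NA_integer_` if remission is not achieved.
#' @examples
#' remission_day(c(90, 50, 15), 100)  # 3
#' @export
remission_day <- function(daily_first_block, test_cs_freezing,
                          threshold_pct = 20, max_days = 7L) {
  if (threshold_pct <= 0 || threshold_pct >= 100) {
    abort_config("`threshold_pct` must lie in (0, 100)")
  }
  daily <- head(daily_first_block, max_days)
  red <- freezing_reduction(daily, test_cs_freezing)
  hit <- which(red < threshold_pct)  # strict: exactly threshold is no remission
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Delta freezing
#'
#' Signed difference between a probe-session freezing value (e.g. the remote
#' test) and the post-training test CS+ freezing, in percentage points.
#'
#' @param probe_freezing,test_cs_freezing Freezing percentages in [0, 100]
#'   (vectorised).
#' @return `probe_freezing - test_cs_freezing`.
#' @examples
#' delta_freezing(10, 80)  # -70
#' @export
delta_freezing <- function(probe_freezing, test_cs_freezing) {
  rng <- range(c(probe_freezing, test_cs_freezing))
  if (rng[1] < 0 || rng[2] > 100) {
    abort_input("freezing values must lie in [0, 100]")
  }
  probe_freezing - test_cs_freezing
}

#' Per-animal extinction summary
#'
#' Applies the remission criterion to a freezing dataset: per animal, the
#' first-block freezing and reduction for each extinction session, the
#' remission day (censored at `max_days` for animals that never remit,
#' matching the experimental stop rule), and delta freezing at the remote
#' probe.
#'
#' @param dataset A [generate_freezing_dataset()] result, or a tones tibble
#'   (`animal`, `group`, `session`, `tone`, `freezing_pct`) plus an `animals`
#'   tibble via the `animals` argument.
#' @param animals Per-animal table when `dataset` is a plain tones tibble.
#' @param threshold_pct,block_size,max_days Remission criterion parameters.
#' @return A tibble with one row per animal: `animal`, `group`,
#'   `test_cs_freezing`, `reduction_pct` (list-column, per session),
#'   `remission_day` (`NA` = not achieved), `sessions_to_remission`
#'   (censored at `max_days`), `remitted`, `delta_remote`, and the probe
#'   percentages.
#' @export
summarize_extinction <- function(dataset, animals = NULL, threshold_pct = 20,
                                 block_size = 5L, max_days = 7L) {
  if (inherits(dataset, "swr_freezing_dataset")) {
    tones <- dataset$tones
    animals <- dataset$animals
  } else {
    tones <- dataset
    if (is.null(animals)) abort_input("`animals` table is required")
  }
  first_blocks <- tones |>
    dplyr::group_by(.data$animal, .data$session) |>
    dplyr::summarise(
      first_block = block_average(.data$freezing_pct, block_size)[1L],
      .groups = "drop")

  animals |>
    dplyr::rowwise() |>
    dplyr::mutate(
      daily = list(first_blocks$first_block[
        first_blocks$animal == .data$animal][
          order(first_blocks$session[first_blocks$animal == .data$animal])]),
      reduction_pct = list(freezing_reduction(.data$daily,
                                              .data$test_cs_freezing)),
      remission_day = remission_day(.data$daily, .data$test_cs_freezing,
                                    threshold_pct, max_days),
      sessions_to_remission = ifelse(is.na(.data$remission_day), max_days,
                                     .data$remission_day),
      remitted = !is.na(.data$remission_day),
      delta_remote = delta_freezing(.data$remote_pct,
                                    .data$test_cs_freezing)) |>
    dplyr::ungroup() |>
    dplyr::select(-"daily")
}
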