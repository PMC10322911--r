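#' Generate a synthetic fear-extinction freezing dataset
#'
#' Per-animal freezing trajectories for three groups — non-stimulated (NS),
#' open-loop (OL) and closed-loop (CL): tone-level freezing during extinction
#' decays exponentially across sessions from the animal's post-training test
#' CS+ level, with truncated-Gaussian per-tone noise and clipping to
#' [0, 100] %. The CL group decays twice as fast by default and shows no
#' fear recovery at the renewal / remote / reinstatement probes, mimicking
#' accelerated extinction under ripple-triggered reward stimulation.
#'
#' @param config A [behavior_config()].
#' @param seed Integer seed.
#' @return An object of class `swr_freezing_dataset`: list with `animals`
#'   (tibble `animal`, `group`, `test_cs_freezing`, `renewal_pct`,
#'   `remote_pct`, `reinstatement_pct`) and `tones` (tibble `animal`,
#'   `group`, `session`, `tone`, `freezing_pct`).
#' @export
generate_freezing_dataset <- function(config = behavior_config(), seed = 1L) {
  stopifnot(inherits(config, "swr_behavior_config"))
  set.seed(seed)
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n_animal <- length(groups)
  ids <- sprintf("%s%02d", groups, stats::ave(seq_len(n_animal), groups,
                                              FUN = seq_along))
  clip01 <- function(x) pmin(pmax(x, 0), 100)
  noise <- function(n) {
    if (config$tone_noise_sd == 0) rep(0, n) else
      rnorm(n, 0, config$tone_noise_sd)
  }
  test <- clip01(pmin(pmax(rnorm(n_animal, config$test_mean, config$test_sd),
                           config$test_range[1]), config$test_range[2]))

  tones <- purrr::map(seq_len(n_animal), function(i) {
    rate <- config$decay_rates[[groups[i]]]
    purrr::map(seq_len(config$n_sessions), function(s) {
      level <- test[i] * exp(-rate * (s - 1))
      tibble::tibble(animal = ids[i], group = groups[i], session = s,
                     tone = seq_len(config$tones_per_session),
                     freezing_pct = clip01(level +
                                             noise(config$tones_per_session)))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  final <- test * exp(-purrr::map_dbl(groups, ~config$decay_rates[[.x]]) *
                        (config$n_sessions - 1))
  probe <- function(which) {
    inc <- ifelse(groups == "CL", 0, config$recovery[[which]])
    clip01(final + inc + noise(n_animal))
  }
  animals <- tibble::tibble(animal = ids, group = groups,
                            test_cs_freezing = test,
                            renewal_pct = probe("renewal"),
                            remote_pct = probe("remote"),
                            reinstatement_pct = probe("reinstatement"))
  structure(list(animals = animals, tones = tones, seed = seed,
                 config = config),
            class = "swr_freezing_dataset")
}

#' @export
print.swr_freezing_dataset <- function(x, ...) {
  cat(sprintf("<swr_freezing_dataset> %d animals (%s), %d sessions x %d tones\n",
              nrow(x$animals),
              paste(names(table(x$animals$group)), collapse = "/"),
              max(x$tones$session), max(x$tones$tone)))
  invisible(x)
}
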