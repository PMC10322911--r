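#' Write a recording bundle to disk
#'
#' Serialises a session as a flat channel-interleaved little-endian int16
#' binary (`lfp.dat`) with a JSON sidecar (`metadata.json`: channels, rate,
#' microvolts per bit) plus delimited truth / state / artifact tables —
#' everything needed to reload the session losslessly at int16 resolution.
#'
#' @param session A `swr_session`.
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_recording <- function(session, path) {
  stopifnot(inherits(session, "swr_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  peak <- max(abs(session$lfp), 1e-12)
  uv_per_bit <- peak / 32000
  counts <- round(t(session$lfp) / uv_per_bit)  # channel-interleaved
  writeBin(as.integer(counts), file.path(path, "lfp.dat"),
           size = 2L, endian = "little")
  meta <- list(n_channels = ncol(session$lfp),
               n_samples = nrow(session$lfp),
               sampling_rate_hz = session$sampling_rate_hz,
               duration_s = session$duration_s,
               uv_per_bit = uv_per_bit,
               channel_names = colnames(session$lfp),
               channel_roles = as.list(session$channel_roles),
               band_sd_uv = session$band_sd_uv,
               seed = session$seed)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(session$truth, file.path(path, "truth.csv"), row.names = FALSE)
  write.csv(session$states, file.path(path, "states.csv"), row.names = FALSE)
  write.csv(session$artifacts, file.path(path, "artifacts.csv"),
            row.names = FALSE)
  invisible(path)
}

#' Read a recording bundle
#'
#' Validates the sidecar against the binary payload (channel count x sample
#' count x 2 bytes must equal the file size) and reconstructs the session in
#' microvolts.
#'
#' @param path Directory written by [write_recording()].
#' @return A `swr_session` (without the generating `config`).
#' @export
read_recording <- function(path) {
  meta_file <- file.path(path, "metadata.json")
  dat_file <- file.path(path, "lfp.dat")
  if (!file.exists(meta_file) || !file.exists(dat_file)) {
    abort_input("corrupt bundle: metadata.json or lfp.dat missing")
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  expect_bytes <- meta$n_channels * meta$n_samples * 2
  if (file.size(dat_file) != expect_bytes) {
    abort_input(sprintf(
      "corrupt bundle: lfp.dat has %d bytes, metadata implies %d",
      file.size(dat_file), expect_bytes))
  }
  counts <- readBin(dat_file, "integer", n = meta$n_channels * meta$n_samples,
                    size = 2L, signed = TRUE, endian = "little")
  lfp <- t(matrix(counts, nrow = meta$n_channels)) * meta$uv_per_bit
  colnames(lfp) <- meta$channel_names
  read_tbl <- function(f) {
    fp <- file.path(path, f)
    if (file.exists(fp)) tibble::as_tibble(read.csv(fp)) else NULL
  }
  structure(list(lfp = lfp,
                 sampling_rate_hz = meta$sampling_rate_hz,
                 duration_s = meta$duration_s,
                 channel_roles = unlist(meta$channel_roles),
                 truth = read_tbl("truth.csv"),
                 artifacts = read_tbl("artifacts.csv"),
                 states = read_tbl("states.csv"),
                 band_sd_uv = meta$band_sd_uv,
                 seed = meta$seed,
                 config = NULL),
            class = "swr_session")
}

#' Run the full closed-loop pipeline on one simulated session
#'
#' simulate -> calibrate -> stream detection -> stimulation scheduling ->
#' stimulus-artifact rendering -> offline detection (with blanking) ->
#' trigger/event matching and rates/latencies -> sleep architecture ->
#' behavioural summary. Deterministic under fixed seed; the report embeds
#' the configuration hash and seed.
#'
#' @param config A [session_config()].
#' @param seed Integer seed (drives the LFP session; the behaviour dataset
#'   uses `seed + 1`).
#' @param detection,offline,behavior Module configurations.
#' @param protocol A [stim_protocol()].
#' @param out_dir Optional directory for intermediate files (recording
#'   bundle, triggers, trains, events, report.json).
#' @return A list report: `seed`, `config_hash`, `rates`, `latency`,
#'   `sleep`, `behavior`, `n_truth`, `n_triggers`, `n_events` (clean
#'   recording) and `n_events_stimulated` (blanked detection on the
#'   contaminated recording).
#' @export
run_pipeline <- function(config = benchmark_config(), seed = 1L,
                         detection = detection_config(),
                         offline = offline_config(),
                         behavior = behavior_config(),
                         protocol = stim_protocol("MFB_TRAIN"),
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
  }
  session <- stage("simulate", synthesize_recording(config, seed))
  thresholds <- stage("calibrate", calibrate_thresholds(session, detection))
  triggers <- stage("stream_detect",
                    stream_detect(session, thresholds, detection))
  trains <- stage("schedule_stimulation",
                  schedule_stimulation(triggers, protocol))
  stimulated <- stage("render_stimulus_artifact",
                      render_stimulus_artifact(session, trains))
  # events under stimulation contamination (with pulse blanking) are
  # reported, but accuracy is scored against the uncontaminated recording:
  # blanking removes the very events the triggers responded to, so the
  # contaminated event set cannot serve as the reference
  events_stim <- stage("detect_offline",
                       detect_offline(stimulated, offline,
                                      stim_trains = trains))
  events <- stage("detect_offline", detect_offline(session, offline))
  matches <- stage("evaluate", match_triggers(triggers, events))
  rates <- detection_rates(matches)
  latency <- trigger_latencies(matches)
  sleep <- sleep_architecture(session$states)
  freezing <- stage("behavior", generate_freezing_dataset(behavior, seed + 1L))
  behav <- glance(freezing)

  report <- list(seed = seed,
                 config_hash = rlang::hash(list(config, detection, offline,
                                                behavior, protocol)),
                 n_truth = nrow(session$truth),
                 n_triggers = sum(triggers$disposition == "FIRED"),
                 n_events = nrow(events),
                 n_events_stimulated = nrow(events_stim),
                 rates = rates,
                 latency = glance(latency),
                 latency_histogram = tidy(latency),
                 sleep = sleep,
                 behavior = behav)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_recording(stimulated, file.path(out_dir, "recording"))
    write.csv(triggers, file.path(out_dir, "triggers.csv"), row.names = FALSE)
    write.csv(trains, file.path(out_dir, "trains.csv"), row.names = FALSE)
    write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
    jsonlite::write_json(purrr::map(report, function(x) {
      if (inherits(x, "data.frame")) as.data.frame(x) else x
    }), file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}
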