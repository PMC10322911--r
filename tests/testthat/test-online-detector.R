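test_that("a constant baseline is rejected unless degenerate thresholds are allowed", {
  zeros <- as_session(cbind(ripple = rep(0, 500 * 70),
                            noise = rep(0, 500 * 70)))
  expect_error(calibrate_thresholds(zeros), class = "swrloop_input_error")
  th <- calibrate_thresholds(zeros, allow_degenerate = TRUE)
  expect_equal(th$threshold, c(0, 0))
})

test_that("a pure in-band sinusoid calibrates to its RMS amplitude", {
  fs <- 500
  tt <- (0:(120 * fs - 1)) / fs
  amp <- 50
  tone <- amp * sin(2 * pi * 200 * tt)
  th <- calibrate_thresholds(as_session(cbind(ripple = tone, noise = tone)),
                             baseline_s = 120)
  # long steady tone: RMS trace ~ A/sqrt(2) everywhere, SD ~ 0, so the
  # threshold sits at the tone's RMS (within filter gain/settling effects)
  expect_lt(abs(th$threshold[th$channel == "ripple"] - amp / sqrt(2)),
            0.05 * amp)
})

test_that("calibration equals an independent batch mean+kSD oracle", {
  base <- white_baseline(120)
  cfg <- detection_config()
  th <- calibrate_thresholds(as_session(base), cfg)
  w <- round(cfg$rms_window_s * cfg$online_rate_hz)
  nyq <- cfg$online_rate_hz / 2
  for (ch in c("ripple", "noise")) {
    band <- if (ch == "ripple") cfg$ripple_band else cfg$noise_band
    bf <- signal::butter(2, c(band[1], min(band[2], 0.95 * nyq)) / nyq, "pass")
    rms <- oracle_trailing_rms(oracle_iir(bf$b, bf$a, base[1:(60 * 500), ch]),
                               w)
    ref <- mean(rms) + 4 * sd(rms)
    expect_lt(abs(th$threshold[th$channel == ch] - ref) / ref, 0.01)
  }
})

test_that("an isolated strong ripple fires exactly one trigger inside the event", {
  base <- white_baseline(120, seed = 5)
  bsd <- band_sd_of(base[, "ripple"])
  mat <- inject(base, "ripple", ripple_burst(0.08, 12 * bsd), t0_s = 90)
  cfg <- detection_config(threshold_k_ripple = 6, threshold_k_noise = 6)
  th <- calibrate_thresholds(as_session(base), cfg)
  log <- stream_detect(as_session(mat), th, cfg)
  fired <- log[log$disposition == "FIRED", ]
  expect_equal(nrow(fired), 1L)
  expect_gte(fired$crossing_s, 90)
  expect_lte(fired$crossing_s, 90 + 0.08 + 0.02)
})

test_that("a concurrent broadband artifact on the noise channel vetoes the trigger", {
  base <- white_baseline(120, seed = 5)
  bsd <- band_sd_of(base[, "ripple"])
  set.seed(8)
  burst <- rnorm(0.1 * 500 + 1) * 12 * bsd
  mat <- inject(base, "ripple", ripple_burst(0.08, 12 * bsd), t0_s = 90)
  mat <- inject(mat, "noise", burst, t0_s = 89.99)
  cfg <- detection_config(threshold_k_ripple = 6, threshold_k_noise = 6)
  th <- calibrate_thresholds(as_session(base), cfg)
  log <- stream_detect(as_session(mat), th, cfg)
  expect_equal(sum(log$disposition == "FIRED"), 0L)
  expect_gte(sum(log$disposition == "VETOED"), 1L)
})

test_that("the lockout suppresses the second of two closely spaced ripples", {
  base <- white_baseline(120, seed = 5)
  bsd <- band_sd_of(base[, "ripple"])
  mat <- inject(base, "ripple", ripple_burst(0.05, 12 * bsd), t0_s = 90)
  mat <- inject(mat, "ripple", ripple_burst(0.05, 12 * bsd), t0_s = 90.1)
  cfg <- detection_config(threshold_k_ripple = 6, threshold_k_noise = 6,
                          lockout_s = 0.2)
  th <- calibrate_thresholds(as_session(base), cfg)
  log <- stream_detect(as_session(mat), th, cfg)
  expect_equal(sum(log$disposition == "FIRED"), 1L)
  expect_gte(sum(log$disposition == "LOCKED_OUT"), 1L)
})

test_that("streaming detection equals the whole-vector batch oracle", {
  s <- synthesize_recording(short_config(200), seed = 3)
  cfg <- detection_config()
  th <- calibrate_thresholds(s, cfg)
  log <- stream_detect(s, th, cfg, chunk_s = 7)  # deliberately odd chunking
  oracle <- oracle_batch_detect(s$lfp, th, cfg)
  expect_equal(round(log$crossing_s * 500) + 1, oracle$index)
  expect_equal(log$disposition, oracle$disposition)
})

test_that("truncating the input never changes earlier triggers (causality)", {
  s <- synthesize_recording(short_config(200), seed = 12)
  cfg <- detection_config()
  th <- calibrate_thresholds(s, cfg)
  full <- stream_detect(s, th, cfg)
  cut_s <- 101.3
  s_cut <- s
  s_cut$lfp <- s$lfp[1:round(cut_s * 500), ]
  part <- stream_detect(s_cut, th, cfg)
  expect_equal(part, full[full$crossing_s < cut_s, ])
})

test_that("processing latency shifts trigger times exactly, not crossings", {
  s <- synthesize_recording(short_config(150), seed = 13)
  th <- calibrate_thresholds(s)
  a <- stream_detect(s, th, detection_config(processing_latency_s = 0.010))
  b <- stream_detect(s, th, detection_config(processing_latency_s = 0.015))
  expect_equal(a$crossing_s, b$crossing_s)
  expect_equal(b$trigger_s - a$trigger_s,
               rep(0.005, nrow(a)))
})

test_that("fired triggers respect the lockout and the noise veto in any session", {
  s <- synthesize_recording(short_config(300, artifact_rate_hz = 0.1),
                            seed = 21)
  cfg <- detection_config()
  th <- calibrate_thresholds(s, cfg)
  log <- stream_detect(s, th, cfg)
  fired <- log$crossing_s[log$disposition == "FIRED"]
  if (length(fired) > 1) {
    expect_true(all(diff(fired) >= cfg$lockout_s))
  }
  expect_error(stream_detect(structure(list(lfp = s$lfp,
                                            sampling_rate_hz = 500),
                                       class = "swr_session"), th, cfg),
               class = "swrloop_config_error")
})

test_that("stimulation trains follow the configured protocol exactly", {
  trig <- tibble::tibble(crossing_s = c(1, 2, 3),
                         trigger_s = c(1.01, 2.01, 3.01),
                         disposition = c("FIRED", "VETOED", "FIRED"))
  mfb <- schedule_stimulation(trig, stim_protocol("MFB_TRAIN"))
  expect_equal(length(unique(mfb$train_id)), 2L)
  t1 <- mfb[mfb$train_id == 1, ]
  expect_equal(nrow(t1), 14L)
  expect_equal(max(t1$onset_s) - min(t1$onset_s), 13 / 140)
  expect_equal(t1$onset_s[1], 1.01)
  expect_equal(unique(t1$width_s), 0.001)
  expect_equal(unique(t1$amplitude), 100)
  # pulses do not overlap: inter-onset interval exceeds the pulse width
  expect_true(all(diff(t1$onset_s) > t1$width_s[1]))
  vhc <- schedule_stimulation(trig, stim_protocol("VHC_PULSE"))
  expect_equal(nrow(vhc[vhc$train_id == 1, ]), 1L)
  expect_equal(unique(vhc$width_s), 0.0005)
  empty <- schedule_stimulation(trig[trig$disposition == "VETOED", ],
                                stim_protocol("MFB_TRAIN"))
  expect_equal(nrow(empty), 0L)
  expect_error(stim_protocol("VHC_PULSE", amplitude = 20),
               class = "swrloop_config_error")
})

test_that("stimulus-artifact rendering is local and vanishes at zero gain", {
  s <- synthesize_recording(short_config(120), seed = 2)
  trig <- tibble::tibble(crossing_s = 60, trigger_s = 60.01,
                         disposition = "FIRED")
  trains <- schedule_stimulation(trig, stim_protocol("MFB_TRAIN"))
  same <- render_stimulus_artifact(s, trains, artifact_gain_uv = 0)
  expect_identical(same$lfp, s$lfp)
  mod <- render_stimulus_artifact(s, trains, artifact_gain_uv = 2000)
  fs <- s$sampling_rate_hz
  changed <- which(mod$lfp[, "ripple"] != s$lfp[, "ripple"])
  expect_gt(length(changed), 0L)
  span <- range(trains$onset_s) + c(0, max(trains$width_s))
  expect_true(all(changed / fs >= span[1] - 0.005 &
                    changed / fs <= span[2] + 0.005))
})
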