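Package: swrloop
Title: Closed-Loop Sharp-Wave-Ripple Detection, Evaluation and Fear-Extinction Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates hippocampal local field potential recordings with
    ground-truthed sharp-wave ripples (SWRs), sleep-state structure and shared
    broadband artifacts; runs a causal, streaming two-channel ripple detector
    (band-pass + sliding RMS threshold with noise veto, lockout and
    stimulation scheduling) next to a zero-phase offline detector
    (normalized squared power, 2/3 SD boundary and peak criteria, 20-200 ms
    duration bounds); scores online triggers against reference events as
    positive, false-positive and missed detections with trigger-latency
    histograms; and computes fear-extinction metrics (freezing reduction,
    remission day, delta freezing) from per-tone freezing tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
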