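Package: earvitals
Title: Physiological Monitoring from In-Ear Audio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates heart rate, respiratory rate and breathing-phase structure
    from in-ear microphone recordings. Periodic audio segments are selected with
    short-time energy / zero-crossing endpoint detection and autocorrelation
    periodicity gating, breathing and heartbeat sounds are separated from
    bone-conducted and ambient noise with a template-constrained semi-supervised
    non-negative matrix factorization (KL divergence, multiplicative updates,
    soft spectrogram masks), and breathing phases (inhale, exhale, pause) are
    labeled with a two-state Viterbi decoder, a small convolutional
    breath-extraction gate and an attention-augmented bidirectional LSTM.
    Includes a seeded synthetic-data generator with convolutive FIR mixing and
    ground truth, plus SDR/SIR/SI-SDR separation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
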