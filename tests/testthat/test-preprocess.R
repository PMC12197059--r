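test_that("band-pass filter attenuates the stop band and passes the band", {
  fs <- 44100
  t <- seq(0, 2, by = 1 / fs)
  tone <- function(f) audio_signal(sin(2 * pi * f * t), fs)
  gain_db <- function(f) {
    y <- bandpass_filter(tone(f))
    10 * log10(sum(y$samples^2) / sum(tone(f)$samples^2))
  }
  expect_lt(gain_db(100), -30)          # stop band
  expect_lt(abs(gain_db(2000)), 1)      # pass band within 1 dB of unity
  # designed response agrees with the measured tone energies
  expect_lt(abs(gain_db(2000) - 20 * log10(bandpass_response(2000, fs))), 0.3)
})

test_that("band-pass filter maps zero to zero, preserves length, is linear", {
  fs <- 8000
  z <- suppressWarnings(bandpass_filter(audio_signal(numeric(4000), fs)))
  expect_equal(z$samples, numeric(4000))
  set.seed(5)
  x <- stats::rnorm(4000); y <- stats::rnorm(4000)
  f <- function(v) suppressWarnings(bandpass_filter(audio_signal(v, fs)))$samples
  lhs <- f(2 * x - 3 * y)
  rhs <- 2 * f(x) - 3 * f(y)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
  expect_length(f(x), 4000)
})

test_that("band edges at or above Nyquist shrink with a warning or error", {
  x <- audio_signal(stats::rnorm(2000), 8000)
  expect_warning(bandpass_filter(x, 500, 8000), "shrunk")
  expect_error(bandpass_filter(x, 500, 8000, auto_shrink = FALSE), "Nyquist")
  expect_error(bandpass_filter(x, 0, 1000), "low_hz")
})

test_that("short-time energy matches direct summation", {
  x <- audio_signal(rep(0.5, 1600), 16000)   # 160-sample frames
  e <- short_term_energy(x)
  expect_equal(e$values, rep(40, 10))
  expect_equal(short_term_energy(audio_signal(numeric(800), 8000))$values,
               rep(0, 10))
  set.seed(3)
  r <- stats::rnorm(240)
  e2 <- short_term_energy(audio_signal(r, 8000))  # 80-sample frames
  expect_equal(e2$values, c(sum(r[1:80]^2), sum(r[81:160]^2),
                            sum(r[161:240]^2)))
  expect_error(short_term_energy(audio_signal(1:5 / 10, 8000)), "shorter")
})

test_that("zero-crossing rate counts sign changes with zero-inheritance", {
  fs <- 8000  # 80-sample frames
  alt <- audio_signal(rep(c(1, -1), 80), fs)
  expect_equal(zero_crossing_rate(alt)$values, c(1, 1))
  expect_equal(zero_crossing_rate(audio_signal(rep(1, 160), fs))$values,
               c(0, 0))
  # zeros inherit the previous sign: 1,0,1 has no crossing
  z <- audio_signal(rep(c(1, 0), 80), fs)
  expect_equal(zero_crossing_rate(z)$values, c(0, 0))
  # sine with k full cycles per frame crosses about 2k times
  k <- 5
  t <- (0:(fs - 1)) / fs
  s <- audio_signal(sin(2 * pi * (k * 100) * t), fs)  # k cycles per 10 ms
  zc <- zero_crossing_rate(s)$values
  expect_true(all(abs(zc - 2 * k / 79) <= 2 / 79))
})

test_that("dual-threshold detector finds fixed-length segments", {
  fs <- 8000
  set.seed(9)
  noise <- function(n) stats::runif(n, -0.5, 0.5)
  thr <- detector_thresholds(energy_high = 1, energy_low = 0.1,
                             zcr_min = 0.05)
  # silence
  expect_equal(nrow(detect_segments(audio_signal(numeric(fs * 20), fs), thr)),
               0)
  # one 20 s burst starting at t = 2 -> one segment [2, 17)
  x <- c(numeric(2 * fs), noise(20 * fs))
  seg <- detect_segments(audio_signal(x, fs), thr)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_s, 2, tolerance = 0.02)
  expect_equal(seg$end_s - seg$start_s, 15)
  # two bursts -> two disjoint 15 s segments
  x2 <- c(numeric(2 * fs), noise(16 * fs), numeric(4 * fs), noise(16 * fs))
  seg2 <- detect_segments(audio_signal(x2, fs), thr)
  expect_equal(nrow(seg2), 2)
  expect_true(all(seg2$end_s - seg2$start_s == 15))
  expect_lte(seg2$end_s[1], seg2$start_s[2])
  # truncated tail discarded: burst too close to the end
  x3 <- c(numeric(2 * fs), noise(10 * fs))
  expect_equal(nrow(detect_segments(audio_signal(x3, fs), thr)), 0)
})

test_that("dual-end mode closes a segment when energy falls below the low threshold", {
  fs <- 8000
  set.seed(10)
  x <- c(numeric(fs), stats::runif(2 * fs, -0.5, 0.5), numeric(2 * fs))
  thr <- detector_thresholds(energy_high = 1, energy_low = 0.1,
                             zcr_min = 0.05)
  seg <- detect_segments(audio_signal(x, fs), thr, mode = "dual")
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_s, 1, tolerance = 0.02)
  expect_equal(seg$end_s, 3, tolerance = 0.05)
})

test_that("Hilbert envelope tracks an AM tone and decimates", {
  fs <- 8000
  t <- seq(0, 5, by = 1 / fs)
  am <- (1 + 0.5 * sin(2 * pi * 1 * t)) * sin(2 * pi * 1000 * t)
  env <- extract_envelope(audio_signal(am, fs), downsample_factor = 1)
  truth <- 1 + 0.5 * sin(2 * pi * 1 * t)
  interior <- seq(round(0.25 * fs), length(t) - round(0.25 * fs))
  expect_lt(max(abs(env$samples[interior] - truth[interior])), 0.05)
  # factor-1 is the plain analytic magnitude; larger factors change the rate
  env100 <- extract_envelope(audio_signal(am, fs), 100)
  expect_equal(env100$sample_rate, 80)
  expect_equal(length(env100$samples), ceiling(length(t) / 100))
  # zeros map to zeros
  expect_equal(extract_envelope(audio_signal(numeric(1000), fs), 10)$samples,
               numeric(100))
})

test_that("autocorrelation period estimation recovers known periods", {
  # bursts spaced exactly 1 s apart at 100 Hz envelope rate
  fs <- 100
  t <- seq(0, 8, by = 1 / fs)
  env <- audio_signal(exp(-((t %% 1) - 0.2)^2 / 0.005), fs)
  expect_equal(as.numeric(estimate_period(env)), 1.0, tolerance = 1 / fs + 1e-9)
  # sinusoidal envelope, 2 Hz at 50 Hz rate
  fs2 <- 50
  t2 <- seq(0, 10, by = 1 / fs2)
  env2 <- audio_signal(1 + sin(2 * pi * 2 * t2), fs2)
  expect_equal(as.numeric(estimate_period(env2)), 0.5, tolerance = 0.02)
})

test_that("period estimation is scale invariant and rejects aperiodic input", {
  fs <- 50
  t <- seq(0, 10, by = 1 / fs)
  env <- audio_signal(1 + sin(2 * pi * 2 * t), fs)
  for (c0 in c(0.01, 1, 250)) {
    scaled <- audio_signal(c0 * env$samples, fs)
    expect_equal(as.numeric(estimate_period(scaled)),
                 as.numeric(estimate_period(env)))
  }
  expect_true(is.na(estimate_period(audio_signal(rep(1, 500), fs))))
  set.seed(2)
  wn <- estimate_period(audio_signal(stats::rnorm(500), fs))
  expect_true(is.na(wn) || attr(wn, "spacing_cv") > 0.5)
})

test_that("strictly periodic envelopes are recovered within one sample spacing", {
  fs <- 40
  for (T0 in c(0.5, 1, 2, 3)) {
    t <- seq(0, 4 * T0 + 2, by = 1 / fs)
    env <- audio_signal(1 + cos(2 * pi * t / T0), fs)
    expect_lte(abs(as.numeric(estimate_period(env)) - T0), 1 / fs + 1e-9)
  }
})

test_that("segment acceptance uses closed period bounds", {
  expect_true(accept_segment(1.0, 0, 3))
  expect_false(accept_segment(3.5, 0, 3))
  expect_true(accept_segment(3, 0, 3))     # upper bound inclusive
  expect_true(accept_segment(0.3, 0.3, 3)) # lower bound inclusive
  expect_false(accept_segment(NA_real_, 0, 3))
  expect_error(accept_segment(1, 3, 0), "d1 <= d2")
})
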