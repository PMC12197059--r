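test_that("breath generator produces exact onsets and phase structure", {
  g <- gen_breath(60, br_bpm = 12, seed = 90)
  lab <- g$phases$labels
  onsets <- sum(lab == "INHALE" & c(TRUE, lab[-length(lab)] != "INHALE"))
  expect_equal(onsets, 12)
  expect_equal(length(g$audio$samples), 60 * 8000)
  # zero depth gives silence but a valid phase track
  g0 <- gen_breath(10, br_bpm = 12, depth = 0, seed = 91)
  expect_equal(g0$audio$samples, numeric(10 * 8000))
  expect_true(any(g0$phases$labels == "INHALE"))
  expect_error(gen_breath(10, br_bpm = 100), "br_bpm")
  expect_error(gen_breath(10, inhale_frac = 0.5, exhale_frac = 0.5,
                          pause_frac = 0.5), "sum to 1")
})

test_that("pauses are quiet relative to inhalation bursts", {
  g <- gen_breath(30, br_bpm = 12, seed = 92)
  fs <- g$audio$sample_rate
  centers <- (seq_along(g$phases$labels) - 0.5) * g$phases$step_s
  idx_of <- function(phase) {
    keep <- g$phases$labels == phase
    unlist(lapply(which(keep), function(i) {
      i0 <- floor((centers[i] - 0.005) * fs) + 1
      i0:(i0 + round(0.01 * fs) - 1)
    }))
  }
  rms <- function(ix) sqrt(mean(g$audio$samples[ix]^2))
  expect_lt(rms(idx_of("PAUSE")), 0.05 * rms(idx_of("INHALE")))
})

test_that("heartbeat generator is exact in count and timing", {
  h <- gen_heartbeat(60, hr_bpm = 72, seed = 93)
  expect_length(h$beat_times, 72)
  ibi <- diff(h$beat_times)
  expect_lt(abs(mean(ibi) - 60 / 72) / (60 / 72), 0.02)
  expect_error(gen_heartbeat(10, hr_bpm = 300), "hr_bpm")
})

test_that("heart energy sits low in the analysis band and survives the band-pass", {
  h <- gen_heartbeat(60, hr_bpm = 72, seed = 94)
  P <- Mod(stats::fft(h$audio$samples))^2
  f <- (seq_along(P) - 1) * 8000 / length(P)
  half <- f <= 4000
  expect_gte(sum(P[half & f < 1200]) / sum(P[half]), 0.80)
  bp <- suppressWarnings(bandpass_filter(h$audio))
  expect_gte(sum(bp$samples^2) / sum(h$audio$samples^2), 0.70)
  b <- gen_breath(30, br_bpm = 15, seed = 95)
  bb <- suppressWarnings(bandpass_filter(b$audio))
  expect_gte(sum(bb$samples^2) / sum(b$audio$samples^2), 0.70)
})

test_that("noise generators are deterministic with kind-specific structure", {
  expect_length(gen_noise(0, "room")$samples, 0)
  n1 <- gen_noise(10, "footsteps", seed = 96)
  n2 <- gen_noise(10, "footsteps", seed = 96)
  expect_identical(n1$samples, n2$samples)
  n3 <- gen_noise(10, "footsteps", seed = 97)
  expect_false(identical(n1$samples, n3$samples))
  # footsteps: at least one transient per second above 5x median amplitude
  thr <- 5 * stats::median(abs(n1$samples))
  sec <- floor((seq_along(n1$samples) - 1) / 8000)
  hits <- tapply(abs(n1$samples) > thr, sec, any)
  expect_true(all(hits))
})

test_that("convolutive mixing equals a direct FIR convolution", {
  set.seed(98)
  b <- gen_breath(5, br_bpm = 15, seed = 1)$audio
  h <- gen_heartbeat(5, hr_bpm = 80, seed = 2)$audio
  nz <- gen_noise(5, "room", seed = 3)
  # unit-impulse filters give a plain sum
  sp_id <- mixture_spec(4)
  sp_id$a_breath <- sp_id$a_heart <- sp_id$a_noise <- c(1, 0, 0, 0)
  mix_id <- mix_convolutive(b, h, nz, sp_id)
  expect_equal(mix_id$samples, b$samples + h$samples + nz$samples,
               tolerance = 1e-12)
  # zero noise filter removes the noise
  sp0 <- mixture_spec(5)
  sp0$a_noise <- c(0, 0, 0, 0)
  mix0 <- mix_convolutive(b, h, nz, sp0)
  mix0_ref <- mix_convolutive(b, h, NULL, sp0)
  expect_equal(mix0$samples, mix0_ref$samples, tolerance = 1e-12)
  # random filters against a naive O(N * 4) loop
  sp <- mixture_spec(6)
  naive <- function(x, a) {
    y <- numeric(length(x))
    for (k in 0:3) {
      shifted <- c(numeric(k), x[seq_len(length(x) - k)])
      y <- y + a[k + 1] * shifted
    }
    y
  }
  got <- mix_convolutive(b, h, nz, sp)$samples
  want <- naive(b$samples, sp$a_breath) + naive(h$samples, sp$a_heart) +
    naive(nz$samples, sp$a_noise)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("mixture specs have length-4 filters with the largest tap first", {
  for (s in 1:5) {
    sp <- mixture_spec(s)
    for (a in list(sp$a_breath, sp$a_heart, sp$a_noise)) {
      expect_length(a, 4)
      expect_true(all(a >= 0.2 & a <= 1))
      expect_equal(which.max(a), 1)
    }
  }
})

test_that("corpora are reproducible with exact ground truth", {
  expect_length(make_corpus(0), 0)
  c1 <- make_corpus(2, corpus_config(duration_s = 4), seed = 5)
  c2 <- make_corpus(2, corpus_config(duration_s = 4), seed = 5)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  cfg <- corpus_config(duration_s = 60, hr_bpm = 96, br_bpm = 12)
  it <- make_corpus(1, cfg, seed = 6)[[1]]
  expect_equal(length(it$truth$beat_times), 96)
  expect_equal(as.numeric(breath_cycle_rate(it$truth$phases)), 12)
  # images are the FIR-filtered sources and sum to the mixture
  s <- it$spec
  expect_equal(it$mixture$samples,
               it$truth$images$breath$samples + it$truth$images$heart$samples +
                 it$truth$images$noise$samples, tolerance = 1e-9)
})

test_that("corpus files are written as plain WAV/CSV/JSON", {
  out <- withr::local_tempdir()
  # mixture peaks can exceed full scale; the writer clamps with a warning
  suppressWarnings(make_corpus(1, corpus_config(duration_s = 3), seed = 7,
                               out_dir = out))
  expect_true(file.exists(file.path(out, "item001.wav")))
  expect_true(file.exists(file.path(out, "item001.breath.wav")))
  expect_true(file.exists(file.path(out, "item001.labels.csv")))
  truth <- jsonlite::read_json(file.path(out, "item001.truth.json"),
                               simplifyVector = TRUE)
  expect_length(truth$fir$a_breath, 4)
  back <- read_wav(file.path(out, "item001.wav"))
  expect_equal(back$sample_rate, 8000)
})

test_that("phase-sequence corpora have aligned labels and fixed shape", {
  corp <- make_phase_corpus(12, seq_len = 87, seed = 8)
  expect_length(corp$sequences, 12)
  expect_length(corp$labels, 12)
  expect_true(all(vapply(corp$sequences, nrow, 1L) == 87))
  expect_true(all(unlist(corp$labels) %in% PHASE_LEVELS))
  # every phase appears somewhere
  expect_setequal(unique(unlist(corp$labels)), PHASE_LEVELS)
  # determinism
  corp2 <- make_phase_corpus(12, seq_len = 87, seed = 8)
  expect_identical(corp$sequences[[3]], corp2$sequences[[3]])
})
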