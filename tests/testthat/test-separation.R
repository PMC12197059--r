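test_that("STFT places a tone in the nearest frequency bin and keeps energy", {
  fs <- 16000
  z <- stft(audio_signal(numeric(fs), fs))
  expect_true(all(z$V == 0))
  t <- (0:(fs - 1)) / fs
  sp <- stft(audio_signal(sin(2 * pi * 1000 * t), fs))
  target_bin <- which.min(abs(sp$f - 1000))
  interior <- 4:(ncol(sp$V) - 4)
  expect_true(all(apply(sp$V[, interior], 2, which.max) == target_bin))
  # per-frame Parseval: sum |S|^2 / n_fft equals the windowed frame energy
  set.seed(6)
  x <- stats::rnorm(4000)
  sp2 <- stft(audio_signal(x, 8000))
  p <- sp2$params
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(p$window_len - 1)) / p$window_len)
  s_pad <- c(numeric(p$pad), x, numeric(p$window_len))
  for (j in c(3, 7, 11)) {
    i0 <- (j - 1) * p$hop
    fr <- s_pad[(i0 + 1):(i0 + p$window_len)] * w
    lhs <- (sum(sp2$V[, j]^2) * 2 - sp2$V[1, j]^2 -
              sp2$V[nrow(sp2$V), j]^2) / p$n_fft
    expect_equal(lhs, sum(fr^2), tolerance = 1e-10)
  }
})

test_that("ISTFT inverts the STFT to floating-point accuracy", {
  for (s in 1:3) {
    set.seed(s)
    x <- stats::rnorm(6000)
    y <- istft(stft(audio_signal(x, 8000)))
    expect_lt(max(abs(y$samples - x)), 1e-6)
    expect_length(y$samples, 6000)
  }
  z <- stft(audio_signal(numeric(2000), 8000))
  expect_equal(istft(z)$samples, numeric(2000))
})

test_that("the KL objective evaluates its closed forms", {
  set.seed(4)
  W <- matrix(stats::runif(12, 0.1, 1), 4, 3)
  H <- matrix(stats::runif(9, 0.1, 1), 3, 3)
  expect_equal(kl_cost(W %*% H, W, H, mu = 0), 0, tolerance = 1e-9)
  # scalar case: v = 1, lambda = 2
  expect_equal(kl_cost(matrix(1), matrix(1), matrix(2), mu = 0),
               log(1 / 2) - 1 + 2, tolerance = 1e-12)
  # the L1 penalty is exactly linear in sum(H)
  H4 <- matrix(c(1, 1, 1, 1), 2, 2)  # sums to 4
  V <- matrix(stats::runif(4, 0.5, 2), 2, 2)
  W2 <- matrix(stats::runif(4, 0.1, 1), 2, 2)
  expect_equal(kl_cost(V, W2, H4, mu = 0.5) - kl_cost(V, W2, H4, mu = 0), 2)
})

test_that("the H update has the exact-fit fixed point and never increases cost", {
  set.seed(7)
  W <- matrix(stats::runif(32, 0.1, 1), 8, 4)
  H <- matrix(stats::runif(48, 0.1, 1), 4, 12)
  H2 <- nmf_update_h(W %*% H, W, H, mu = 0)
  expect_equal(H2, H, tolerance = 1e-12)
  V <- matrix(stats::runif(96, 0, 2), 8, 12)
  Hc <- H
  prev <- kl_cost(V, W, Hc, mu = 0)
  for (i in 1:5) {
    Hc <- nmf_update_h(V, W, Hc, mu = 0)
    cur <- kl_cost(V, W, Hc, mu = 0)
    expect_lte(cur, prev + 1e-9 * abs(prev))
    prev <- cur
  }
  # zero rows stay zero under the multiplicative form
  Hz <- H; Hz[2, ] <- 0
  expect_equal(nmf_update_h(V, W, Hz, mu = 0)[2, ], numeric(12))
})

test_that("the W update freezes template columns and renormalizes free ones", {
  set.seed(8)
  W <- matrix(stats::runif(40, 0.1, 1), 10, 4)
  H <- matrix(stats::runif(24, 0.1, 1), 4, 6)
  V <- matrix(stats::runif(60, 0, 2), 10, 6)
  expect_identical(nmf_update_w(V, W, H, integer(0))$W, W)
  upd <- nmf_update_w(V, W, H, 3:4)
  expect_equal(sqrt(colSums(upd$W[, 3:4]^2)), c(1, 1), tolerance = 1e-9)
  expect_identical(upd$W[, 1:2], W[, 1:2])
  # renormalization compensated in H: the product is what the raw rule gives
  expect_equal(kl_cost(V, upd$W, upd$H, 0),
               kl_cost(V, nmf_update_w(V, W, H, 3:4)$W,
                       nmf_update_w(V, W, H, 3:4)$H, 0))
})

test_that("a single free column recovers a rank-1 spectral profile", {
  set.seed(12)
  w_true <- stats::runif(20, 0.1, 1)
  h_true <- stats::runif(30, 0.5, 2)
  V <- outer(w_true, h_true)
  W <- matrix(stats::runif(20, 0.1, 1), 20, 1)
  W <- W / sqrt(sum(W^2))
  H <- matrix(stats::runif(30, 0.1, 1), 1, 30)
  for (i in 1:200) {
    H <- nmf_update_h(V, W, H, mu = 0)
    u <- nmf_update_w(V, W, H, 1L)
    W <- u$W; H <- u$H
  }
  cosine <- sum(W * w_true) / sqrt(sum(W^2) * sum(w_true^2))
  expect_gt(cosine, 0.95)
})

test_that("learned templates are unit-norm and capture source spectra", {
  fs <- 8000
  t <- (0:(10 * fs - 1)) / fs
  set.seed(13)
  tone <- audio_signal(sin(2 * pi * 800 * t) * (1 + 0.1 * stats::rnorm(length(t))),
                       fs)
  lo <- audio_signal(signal::filtfilt(signal::butter(4, c(500, 900) / (fs / 2),
                                                     "pass"),
                                      stats::rnorm(length(t))), fs)
  hi <- audio_signal(signal::filtfilt(signal::butter(4, c(2000, 3000) / (fs / 2),
                                                     "pass"),
                                      stats::rnorm(length(t))), fs)
  bank <- learn_templates(list(breath = lo, heart = tone, noise = hi),
                          k_per_source = c(breath = 2, heart = 1, noise = 2),
                          max_iter = 100, seed = 3)
  for (blk in list(bank$breath, bank$heart, bank$noise))
    expect_equal(sqrt(colSums(blk^2)), rep(1, ncol(blk)), tolerance = 1e-9)
  # rank-1 tone template matches the mean tone spectrum
  ref <- rowMeans(stft(tone)$V)
  cosine <- sum(bank$heart[, 1] * ref) / sqrt(sum(ref^2))
  expect_gt(cosine, 0.99)
  # disjoint-band sources yield templates with little cross-band energy
  band_lo <- bank$f >= 400 & bank$f <= 1000
  band_hi <- bank$f >= 1900 & bank$f <= 3100
  expect_gt(sum(bank$breath[band_lo, ]^2) / sum(bank$breath^2), 0.9)
  expect_gt(sum(bank$noise[band_hi, ]^2) / sum(bank$noise^2), 0.9)
  expect_error(learn_templates(list(breath = lo, heart = tone)), "noise")
})

test_that("masks partition unity and reconstructions conserve the segment", {
  it <- fixture_mixture(401, duration_s = 5)
  res <- separate(it$mixture, fixture_templates(),
                  sep_config(max_iter = 60, seed = 2))
  msum <- Reduce(`+`, res$masks)
  expect_lt(max(abs(msum - 1)), 1e-6)
  expect_true(all(vapply(res$masks, function(m) all(m >= 0 & m <= 1 + 1e-12),
                         TRUE)))
  # summed masked reconstructions reproduce the input segment
  recon <- Reduce(`+`, lapply(res$masks, function(m) {
    sp <- res$spec; sp$V <- res$spec$V * m; istft(sp)$samples
  }))
  expect_lt(max(abs(recon - it$mixture$samples)), 1e-6)
})

test_that("separation handles silence and is deterministic under a seed", {
  bank <- fixture_templates()
  z <- audio_signal(numeric(8000 * 2), 8000)
  expect_warning(res0 <- separate(z, bank, sep_config(max_iter = 5)),
                 "all-zero")
  expect_equal(res0$audio_breath$samples, numeric(16000))
  expect_equal(res0$audio_heart$samples, numeric(16000))

  it <- fixture_mixture(402, duration_s = 4)
  r1 <- separate(it$mixture, bank, sep_config(max_iter = 30, seed = 11))
  r2 <- separate(it$mixture, bank, sep_config(max_iter = 30, seed = 11))
  expect_identical(r1$cost, r2$cost)
  expect_identical(r1$model$H, r2$model$H)
})

test_that("a breath-only mixture is assigned mostly to the breath block", {
  b <- gen_breath(8, br_bpm = 15, seed = 31)
  res <- separate(b$audio, fixture_templates(),
                  sep_config(max_iter = 80, seed = 3))
  # most of the input survives into the breath estimate
  expect_gt(si_sdr(b$audio, res$audio_breath), 5)
  # and the breath mask dominates where the mixture has energy
  w <- res$spec$V > stats::quantile(res$spec$V, 0.9)
  expect_gt(mean(res$masks$breath[w]), 0.5)
})

test_that("disjoint-band stationary sources separate with little cross-band leakage", {
  fs <- 8000
  n <- 6 * fs
  set.seed(33)
  lo <- signal::filtfilt(signal::butter(4, c(500, 900) / (fs / 2), "pass"),
                         stats::rnorm(n))
  hi <- signal::filtfilt(signal::butter(4, c(2000, 3000) / (fs / 2), "pass"),
                         stats::rnorm(n))
  mix <- audio_signal(lo + hi, fs)
  bank <- learn_templates(
    list(breath = audio_signal(lo, fs), heart = audio_signal(hi, fs),
         noise = audio_signal(stats::rnorm(n) * 1e-3, fs)),
    k_per_source = c(breath = 4, heart = 4, noise = 2),
    max_iter = 80, seed = 4)
  res <- separate(mix, bank, sep_config(max_iter = 80, seed = 5))
  band_energy <- function(x, f1, f2) {
    P <- Mod(stats::fft(x))^2
    f <- (seq_along(P) - 1) * fs / length(P)
    sum(P[f >= f1 & f <= f2 & f <= fs / 2])
  }
  be <- res$audio_breath$samples
  he <- res$audio_heart$samples
  expect_lt(band_energy(be, 1800, 3200) / band_energy(be, 0, 4000), 0.05)
  expect_lt(band_energy(he, 400, 1000) / band_energy(he, 0, 4000), 0.05)
})

test_that("template banks round-trip through JSON", {
  bank <- fixture_templates()
  p <- withr::local_tempfile(fileext = ".json")
  write_template_bank(bank, p)
  back <- read_template_bank(p)
  expect_equal(back$breath, bank$breath, tolerance = 1e-12)
  expect_equal(back$params$n_fft, bank$params$n_fft)
})
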