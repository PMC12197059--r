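# Shared fixtures, built in code. The template bank is expensive to learn,
# so it is memoized for the whole test session.

.fixture_env <- new.env(parent = emptyenv())

fixture_templates <- function() {
  if (is.null(.fixture_env$bank)) {
    tb <- gen_breath(30, br_bpm = 14, seed = 900001)$audio
    th <- gen_heartbeat(30, hr_bpm = 80, seed = 900002)$audio
    tn <- gen_noise(30, "footsteps", seed = 900003)
    .fixture_env$bank <- learn_templates(
      list(breath = tb, heart = th, noise = tn), max_iter = 100, seed = 7)
  }
  .fixture_env$bank
}

fixture_mixture <- function(seed, duration_s = 15, hr_bpm = NULL,
                            br_bpm = NULL) {
  make_corpus(1, corpus_config(duration_s = duration_s, hr_bpm = hr_bpm,
                               br_bpm = br_bpm), seed = seed)[[1]]
}

# stereo PCM16 WAV written byte-by-byte (write_wav itself is mono)
write_stereo_wav <- function(left, right, rate, path) {
  stopifnot(length(left) == length(right))
  inter <- as.integer(round(rbind(left, right) * 32768))
  inter <- pmin(32767L, pmax(-32768L, inter))
  data_size <- length(inter) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(1L); w16(2L); w32(as.integer(rate)); w32(as.integer(rate) * 4L)
  w16(4L); w16(16L)
  writeChar("data", con, eos = NULL); w32(data_size)
  writeBin(as.vector(inter), con, size = 2, endian = "little")
  invisible(path)
}

# band-disjoint feature-sequence fixture for the phase model: each class
# activates its own group of feature dimensions, with additive noise and a
# soft onset/offset ramp at phase changes
make_disjoint_phase_sequences <- function(n_seq, seq_len = 40, n_feat = 12,
                                          noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  groups <- split(seq_len(n_feat), rep(1:3, each = n_feat / 3))
  seqs <- list(); labs <- list()
  for (i in seq_len(n_seq)) {
    lab <- integer(0)
    cls <- sample(1:3, 1)
    while (length(lab) < seq_len) {
      lab <- c(lab, rep(cls, sample(5:12, 1)))
      cls <- sample(setdiff(1:3, cls), 1)
    }
    lab <- lab[seq_len(seq_len)]
    X <- matrix(stats::rnorm(seq_len * n_feat, sd = noise_sd),
                seq_len, n_feat)
    for (t in seq_len(seq_len)) X[t, groups[[lab[t]]]] <-
        X[t, groups[[lab[t]]]] + 1.5
    seqs[[i]] <- X
    labs[[i]] <- PHASE_LEVELS[lab]
  }
  list(sequences = seqs, labels = labs)
}

# two-class spectro-temporal patches: breath-like patches put energy in the
# upper half of the patch, the others in the lower half
make_bem_patches <- function(n, h = 20, w = 20, seed = 1) {
  set.seed(seed)
  labels <- rep(c("BREATH", "NON_BREATH"), length.out = n)
  patches <- lapply(seq_len(n), function(i) {
    P <- matrix(abs(stats::rnorm(h * w, sd = 0.3)), h, w)
    rows <- if (labels[i] == "BREATH") 1:(h %/% 2) else (h %/% 2 + 1):h
    P[rows, ] <- P[rows, ] + 1.2
    P
  })
  list(patches = patches, labels = labels)
}

# exhaustive MAP path of the 2-state HMM (oracle for viterbi_segment)
brute_force_viterbi <- function(p, trans, prior = c(0.5, 0.5)) {
  n <- length(p)
  best <- NULL; best_lp <- -Inf
  for (mask in 0:(2^n - 1)) {
    states <- as.integer(intToBits(mask))[seq_len(n)]  # 1 = ACTIVE
    lp <- log(prior[ifelse(states[1] == 1L, 1L, 2L)]) +
      log(ifelse(states[1] == 1L, p[1], 1 - p[1]))
    if (n > 1) for (t in 2:n) {
      from <- ifelse(states[t - 1] == 1L, 1L, 2L)
      to <- ifelse(states[t] == 1L, 1L, 2L)
      lp <- lp + log(trans[from, to]) +
        log(ifelse(states[t] == 1L, p[t], 1 - p[t]))
    }
    if (lp > best_lp) { best_lp <- lp; best <- states }
  }
  best
}
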