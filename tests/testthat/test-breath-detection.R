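test_that("the logistic RMS mapping hits its closed-form values", {
  tau <- 0.001
  expect_equal(rms_to_prob(tau, tau), 0.5)
  expect_equal(rms_to_prob(tau + log(3), tau), 0.75, tolerance = 1e-12)
  expect_gte(rms_to_prob(tau + 10, tau), 0.999)
  r <- seq(0, 2, by = 0.1)
  expect_true(all(diff(rms_to_prob(r, tau)) > 0))
  expect_error(rms_to_prob(-0.1), "non-negative")
})

test_that("transition models are row-stochastic with the documented defaults", {
  m <- transition_model()
  expect_equal(rowSums(m), c(ACTIVE = 1, PAUSE = 1))
  expect_equal(m["ACTIVE", "ACTIVE"], 0.55)
  expect_equal(m["PAUSE", ], c(ACTIVE = 0.5, PAUSE = 0.5))
  expect_error(transition_model(1.2), "probabilities")
})

test_that("Viterbi decoding matches exhaustive enumeration for short sequences", {
  set.seed(40)
  for (rep in 1:50) {
    n <- sample(1:12, 1)
    p <- stats::runif(n, 0.05, 0.95)
    trans <- transition_model(stats::runif(1, 0.4, 0.9),
                              stats::runif(1, 0.3, 0.8))
    prior <- stats::runif(1, 0.2, 0.8)
    prior <- c(prior, 1 - prior)
    got <- viterbi_segment(p, trans, prior)
    expect_equal(got, brute_force_viterbi(p, trans, prior))
  }
})

test_that("Viterbi boundary behavior: saturation, ties, empty input", {
  expect_equal(viterbi_segment(rep(0.99, 20)), rep(1L, 20))
  # genuine tie (uniform transitions, uninformative emissions) -> PAUSE
  expect_equal(viterbi_segment(rep(0.5, 10), transition_model(0.5, 0.5)),
               rep(0L, 10))
  expect_equal(viterbi_segment(numeric(0)), integer(0))
  expect_error(viterbi_segment(c(0.5, 1)), "strictly")
})

test_that("active runs alternate INHALE/EXHALE and short runs are merged", {
  # 1.5 s active, 0.5 s pause, 1.5 s active at 0.1 s steps
  path <- c(rep(1, 15), rep(0, 5), rep(1, 15))
  tr <- states_to_phase_labels(path, 0.1)
  expect_equal(unique(tr$labels[1:15]), "INHALE")
  expect_equal(unique(tr$labels[16:20]), "PAUSE")
  expect_equal(unique(tr$labels[21:35]), "EXHALE")

  expect_equal(states_to_phase_labels(rep(0, 30), 0.1)$labels,
               rep("PAUSE", 30))
  # a 0.3 s blip inside a pause is below the 1 s minimum and removed
  blip <- c(rep(0, 20), rep(1, 3), rep(0, 20))
  expect_equal(unique(states_to_phase_labels(blip, 0.1)$labels), "PAUSE")
})

test_that("phase assignment conserves ACTIVE duration up to sub-minimum merges", {
  set.seed(41)
  for (rep in 1:10) {
    path <- inverse.rle(list(
      lengths = sample(3:25, 8, replace = TRUE),
      values = rep(c(0L, 1L), 4)))
    tr <- states_to_phase_labels(path, 0.1, min_phase_s = 1.0)
    kept <- sum(tr$labels != "PAUSE")
    r <- rle(path)
    expected <- sum(r$lengths[r$values == 1L & r$lengths >= 10])
    expect_equal(kept, expected)
  }
})

test_that("label_breath_phases recovers generator breathing on clean audio", {
  g <- gen_breath(30, br_bpm = 15, seed = 50)
  tr <- label_breath_phases(g$audio, min_phase_s = 0.35)
  expect_equal(as.numeric(breath_cycle_rate(tr)), 15, tolerance = 1)
})

test_that("BEM training separates a separable fixture and is reproducible", {
  fx <- make_bem_patches(120, seed = 60)
  idx <- seq_len(120)
  tr <- idx[1:90]; te <- idx[91:120]
  cfg <- bem_config(epochs = 15, batch = 30, seed = 2)
  m <- train_bem(fx$patches[tr], fx$labels[tr], cfg)
  expect_lt(m$loss[length(m$loss)], m$loss[1])
  pr <- bem_classify(m, fx$patches[te])
  acc <- mean(colnames(pr)[max.col(pr)] == fx$labels[te])
  expect_gte(acc, 0.95)
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-6)
  m2 <- train_bem(fx$patches[tr], fx$labels[tr], cfg)
  expect_identical(m$params, m2$params)
  expect_error(train_bem(fx$patches[1:5], rep("BREATH", 5), cfg),
               "two classes")
})

test_that("BEM scores shuffled labels at chance", {
  fx <- make_bem_patches(160, seed = 61)
  set.seed(62)
  shuffled <- sample(fx$labels)   # break the label-structure association
  m <- train_bem(fx$patches[1:120], shuffled[1:120],
                 bem_config(epochs = 10, batch = 30, seed = 2))
  pr <- bem_classify(m, fx$patches[121:160])
  # against the (independent) permuted labels accuracy must sit at chance
  acc <- mean(colnames(pr)[max.col(pr)] == shuffled[121:160])
  expect_gte(acc, 0.3)
  expect_lte(acc, 0.7)
  # degenerate input still yields a valid probability vector
  pz <- bem_classify(m, matrix(0, 20, 20))
  expect_false(any(is.na(pz)))
  expect_equal(sum(pz), 1, tolerance = 1e-6)
})

test_that("BEM backpropagation matches numerical gradients", {
  set.seed(63)
  k <- 4; nf <- 3
  patches <- lapply(1:3, function(i) matrix(stats::rnorm(36), 6, 6))
  cols <- lapply(patches, earvitals:::.im2col, k = k)
  params <- list(Wf = earvitals:::.nn_init_mat(k * k, nf),
                 bf = stats::rnorm(nf),
                 Wo = earvitals:::.nn_init_mat(9 * nf, 2),
                 bo = stats::rnorm(2))
  y <- c(1, 2, 1)
  loss_fn <- function(p) {
    s <- 0
    for (i in 1:3) {
      fwd <- earvitals:::.bem_forward(p, cols[[i]])
      pr <- earvitals:::.nn_softmax(matrix(fwd$logits, 1))
      s <- s - log(pr[y[i]])
    }
    s / 3
  }
  grads <- earvitals:::.zero_like(params)
  for (i in 1:3) {
    fwd <- earvitals:::.bem_forward(params, cols[[i]])
    pr <- as.numeric(earvitals:::.nn_softmax(matrix(fwd$logits, 1)))
    dl <- pr; dl[y[i]] <- dl[y[i]] - 1
    grads <- earvitals:::.bem_backward(params, cols[[i]], fwd, dl / 3, grads)
  }
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
      eps <- 1e-6
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      gn <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
      expect_lt(abs(gn - grads[[nm]][i]) /
                  max(1e-8, abs(gn) + abs(grads[[nm]][i])), 1e-5)
    }
  }
})

test_that("BPDM backpropagation matches numerical gradients", {
  set.seed(64)
  B <- 2; Tn <- 5; D <- 3; H <- 4; d <- 3; ncl <- 3
  X <- array(stats::rnorm(B * Tn * D), c(B, Tn, D))
  Y <- matrix(sample(1:ncl, B * Tn, TRUE), B, Tn)
  for (att in c(TRUE, FALSE)) {
    cfg <- bpdm_config(hidden = H, attn_dim = d, attention = att, seed = 9)
    set.seed(9)
    params <- earvitals:::.bpdm_init(D, H, d, ncl, att)
    res <- earvitals:::.bpdm_batch(params, X, Y, cfg, ncl)
    num_loss <- function(p)
      earvitals:::.bpdm_batch(p, X, Y, cfg, ncl, want_grads = FALSE)$loss
    for (nm in names(params)) {
      for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
        eps <- 1e-6
        p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
        gn <- (num_loss(p1) - num_loss(p2)) / (2 * eps)
        expect_lt(abs(gn - res$grads[[nm]][i]) /
                    max(1e-8, abs(gn) + abs(res$grads[[nm]][i])), 1e-4)
      }
    }
  }
})

test_that("BPDM learns a band-disjoint fixture with calibrated attention", {
  fx <- make_disjoint_phase_sequences(120, seed = 70)
  tr <- 1:90; te <- 91:120
  cfg <- bpdm_config(hidden = 8, attn_dim = 6, epochs = 15, batch = 30,
                     seed = 3)
  m <- train_bpdm(fx$sequences[tr], fx$labels[tr], cfg)
  expect_lt(m$loss[length(m$loss)], m$loss[1])

  correct <- list(INHALE = c(0, 0), EXHALE = c(0, 0), PAUSE = c(0, 0))
  boundary_err <- c()
  ok <- 0; tot <- 0
  for (i in te) {
    p <- bpdm_classify(m, fx$sequences[[i]])
    lab <- fx$labels[[i]]
    ok <- ok + sum(p$labels == lab); tot <- tot + length(lab)
    for (cl in PHASE_LEVELS) {
      correct[[cl]][1] <- correct[[cl]][1] + sum(p$labels == cl & lab == cl)
      correct[[cl]][2] <- correct[[cl]][2] + sum(lab == cl)
    }
    truth_chg <- which(lab[-1] != lab[-length(lab)])
    pred_chg <- which(p$labels[-1] != p$labels[-length(p$labels)])
    if (length(truth_chg) && length(pred_chg))
      boundary_err <- c(boundary_err,
                        sapply(truth_chg,
                               function(b) min(abs(b - pred_chg))))
  }
  expect_gte(ok / tot, 0.90)
  for (cl in PHASE_LEVELS)
    expect_gte(correct[[cl]][1] / correct[[cl]][2], 0.85)
  expect_lte(stats::median(boundary_err), 2)

  # attention weights form a distribution at every step
  p1 <- bpdm_classify(m, fx$sequences[[1]])
  att <- attr(p1, "attention")
  expect_equal(rowSums(att), rep(1, nrow(att)), tolerance = 1e-6)
  expect_equal(rowSums(p1$probs), rep(1, length(p1$labels)),
               tolerance = 1e-6)
  expect_length(p1$labels, nrow(fx$sequences[[1]]))

  # determinism and constant-input stability
  m2 <- train_bpdm(fx$sequences[tr], fx$labels[tr], cfg)
  expect_identical(m$params, m2$params)
  # constant input maps to a constant label away from the sequence edges
  # (the bidirectional states differ near the boundaries)
  const <- matrix(0.5, nrow(fx$sequences[[1]]), ncol(fx$sequences[[1]]))
  interior <- bpdm_classify(m, const)$labels[6:(nrow(const) - 5)]
  expect_length(unique(interior), 1)
})

test_that("model checkpoints round-trip through JSON", {
  fx <- make_disjoint_phase_sequences(20, seed = 71)
  m <- train_bpdm(fx$sequences, fx$labels,
                  bpdm_config(hidden = 4, attn_dim = 3, epochs = 2,
                              batch = 10, seed = 1))
  p <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(m, p)
  back <- read_checkpoint(p)
  expect_equal(back$params$Wx_f, m$params$Wx_f, tolerance = 1e-12)
  expect_equal(back$config$seed, m$config$seed)
  a <- bpdm_classify(m, fx$sequences[[1]])
  b <- bpdm_classify(back, fx$sequences[[1]])
  expect_equal(a$labels, b$labels)
})
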