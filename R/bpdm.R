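#' @title Breath phase detection module (attention BiLSTM)
#' @description Per-step classification of feature sequences into INHALE /
#'   EXHALE / PAUSE. A bidirectional LSTM encodes the sequence; an additive
#'   attention layer scores every pair of steps with a single-layer
#'   feedforward alignment (`score(t, i) = v' tanh(Wa h_i + Ua h_t)`),
#'   normalizes the scores per step with a softmax, and forms a context
#'   vector `c_t = sum_i alpha_{t,i} h_i`; the fully connected softmax layer
#'   reads `[h_t, c_t]`. Training uses Adam on mean per-step cross-entropy
#'   with hand-written backpropagation through time. The `attention = FALSE`
#'   ablation drops the context vector and classifies from `h_t` alone.
#' @name bpdm
NULL

#' BPDM training configuration
#'
#' @param hidden LSTM hidden units per direction (default 24).
#' @param attn_dim Width of the feedforward alignment layer (default 12).
#' @param lr Adam learning rate.
#' @param epochs Training epochs (default 30).
#' @param batch Minibatch size (sequences).
#' @param seed RNG seed.
#' @param attention `FALSE` gives the plain-BiLSTM ablation.
#' @return A `bpdm_config` list.
#' @export
bpdm_config <- function(hidden = 24, attn_dim = 12, lr = 1e-3, epochs = 30,
                        batch = 64, seed = 1, attention = TRUE) {
  structure(list(hidden = hidden, attn_dim = attn_dim, lr = lr,
                 epochs = epochs, batch = batch, seed = seed,
                 attention = attention), class = "bpdm_config")
}

.bpdm_init <- function(D, H, d, n_classes, attention) {
  p <- list(
    Wx_f = .nn_init_mat(D, 4 * H), Wh_f = .nn_init_mat(H, 4 * H),
    b_f = c(numeric(H), rep(1, H), numeric(2 * H)),   # forget bias +1
    Wx_b = .nn_init_mat(D, 4 * H), Wh_b = .nn_init_mat(H, 4 * H),
    b_b = c(numeric(H), rep(1, H), numeric(2 * H))
  )
  H2 <- 2 * H
  if (attention) {
    p$Wa <- .nn_init_mat(H2, d)
    p$Ua <- .nn_init_mat(H2, d)
    p$va <- as.numeric(.nn_init_mat(d, 1))
    p$Wo <- .nn_init_mat(2 * H2, n_classes)
  } else {
    p$Wo <- .nn_init_mat(H2, n_classes)
  }
  p$bo <- numeric(n_classes)
  p
}

# batched one-direction LSTM forward; X is (B, T, D)
.lstm_forward <- function(X, Wx, Wh, b, reverse = FALSE) {
  B <- dim(X)[1]; T <- dim(X)[2]; D <- dim(X)[3]
  H <- nrow(Wh)
  ord <- if (reverse) rev(seq_len(T)) else seq_len(T)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Hs <- array(0, c(B, T, H)); Gs <- array(0, c(B, T, 4 * H))
  TCs <- array(0, c(B, T, H)); Hprev <- array(0, c(B, T, H))
  Cprev <- array(0, c(B, T, H))
  i_ix <- seq_len(H); f_ix <- H + i_ix; o_ix <- 2 * H + i_ix
  g_ix <- 3 * H + i_ix
  for (t in ord) {
    Xt <- matrix(X[, t, ], B, D)
    Z <- Xt %*% Wx + h %*% Wh
    Z <- sweep(Z, 2, b, `+`)
    gi <- stats::plogis(Z[, i_ix, drop = FALSE])
    gf <- stats::plogis(Z[, f_ix, drop = FALSE])
    go <- stats::plogis(Z[, o_ix, drop = FALSE])
    gg <- tanh(Z[, g_ix, drop = FALSE])
    Hprev[, t, ] <- h; Cprev[, t, ] <- cc
    cc <- gf * cc + gi * gg
    tc <- tanh(cc)
    h <- go * tc
    Gs[, t, ] <- cbind(gi, gf, go, gg)
    TCs[, t, ] <- tc
    Hs[, t, ] <- h
  }
  list(H = Hs, G = Gs, TC = TCs, Hprev = Hprev, Cprev = Cprev, ord = ord)
}

# batched one-direction LSTM backward; dH_ext is (B, T, H)
.lstm_backward <- function(X, cache, Wx, Wh, dH_ext) {
  B <- dim(X)[1]; T <- dim(X)[2]; D <- dim(X)[3]
  H <- nrow(Wh)
  i_ix <- seq_len(H); f_ix <- H + i_ix; o_ix <- 2 * H + i_ix
  g_ix <- 3 * H + i_ix
  dWx <- Wx * 0; dWh <- Wh * 0; db <- numeric(4 * H)
  dh_carry <- matrix(0, B, H); dc_carry <- matrix(0, B, H)
  for (t in rev(cache$ord)) {
    G <- matrix(cache$G[, t, ], B, 4 * H)
    gi <- G[, i_ix, drop = FALSE]; gf <- G[, f_ix, drop = FALSE]
    go <- G[, o_ix, drop = FALSE]; gg <- G[, g_ix, drop = FALSE]
    tc <- matrix(cache$TC[, t, ], B, H)
    cprev <- matrix(cache$Cprev[, t, ], B, H)
    hprev <- matrix(cache$Hprev[, t, ], B, H)
    dh <- dh_carry + matrix(dH_ext[, t, ], B, H)
    do_ <- dh * tc
    dc <- dc_carry + dh * go * (1 - tc^2)
    di <- dc * gg; dg <- dc * gi; df <- dc * cprev
    dZ <- cbind(di * gi * (1 - gi), df * gf * (1 - gf),
                do_ * go * (1 - go), dg * (1 - gg^2))
    Xt <- matrix(X[, t, ], B, D)
    dWx <- dWx + crossprod(Xt, dZ)
    dWh <- dWh + crossprod(hprev, dZ)
    db <- db + colSums(dZ)
    dh_carry <- dZ %*% t(Wh)
    dc_carry <- dc * gf
  }
  list(dWx = dWx, dWh = dWh, db = db)
}

# forward + loss + gradients for one minibatch.
# X (B, T, D); Y (B, T) integer labels or NULL (prediction only).
.bpdm_batch <- function(params, X, Y, config, n_classes,
                        want_grads = !is.null(Y)) {
  B <- dim(X)[1]; T <- dim(X)[2]
  H <- nrow(params$Wh_f); H2 <- 2 * H
  att <- isTRUE(config$attention)
  fw <- .lstm_forward(X, params$Wx_f, params$Wh_f, params$b_f, reverse = FALSE)
  bw <- .lstm_forward(X, params$Wx_b, params$Wh_b, params$b_b, reverse = TRUE)

  t_idx <- rep(seq_len(T), times = T)
  i_idx <- rep(seq_len(T), each = T)
  probs <- array(0, c(B, T, n_classes))
  alphas <- if (att) vector("list", B) else NULL
  loss <- 0
  grads <- if (want_grads) .zero_like(params) else NULL
  dM_all <- if (want_grads) array(0, c(B, T, H2)) else NULL

  for (bi in seq_len(B)) {
    M <- cbind(matrix(fw$H[bi, , ], T, H), matrix(bw$H[bi, , ], T, H))
    if (att) {
      A <- M %*% params$Wa; Bm <- M %*% params$Ua
      E2 <- tanh(A[i_idx, , drop = FALSE] + Bm[t_idx, , drop = FALSE])
      S <- matrix(E2 %*% params$va, T, T)       # [t, i]
      alpha <- .nn_softmax(S)
      C <- alpha %*% M
      feats <- cbind(M, C)
    } else {
      feats <- M
    }
    logits <- sweep(feats %*% params$Wo, 2, params$bo, `+`)
    P <- .nn_softmax(logits)
    probs[bi, , ] <- P
    if (att) alphas[[bi]] <- alpha
    if (is.null(Y)) next
    y <- Y[bi, ]
    loss <- loss + sum(-log(pmax(P[cbind(seq_len(T), y)], 1e-12)))
    if (!want_grads) next

    dlogits <- P
    dlogits[cbind(seq_len(T), y)] <- dlogits[cbind(seq_len(T), y)] - 1
    dlogits <- dlogits / (B * T)
    grads$Wo <- grads$Wo + crossprod(feats, dlogits)
    grads$bo <- grads$bo + colSums(dlogits)
    dfeats <- dlogits %*% t(params$Wo)
    if (att) {
      dM <- dfeats[, seq_len(H2), drop = FALSE]
      dC <- dfeats[, H2 + seq_len(H2), drop = FALSE]
      dalpha <- dC %*% t(M)
      dM <- dM + crossprod(alpha, dC)
      dS <- alpha * (dalpha - rowSums(dalpha * alpha))
      dS_vec <- as.vector(dS)
      dE2 <- outer(dS_vec, params$va) * (1 - E2^2)
      grads$va <- grads$va + colSums(E2 * dS_vec)
      dA <- rowsum(dE2, i_idx)
      dBm <- rowsum(dE2, t_idx)
      grads$Wa <- grads$Wa + crossprod(M, dA)
      grads$Ua <- grads$Ua + crossprod(M, dBm)
      dM <- dM + dA %*% t(params$Wa) + dBm %*% t(params$Ua)
    } else {
      dM <- dfeats
    }
    dM_all[bi, , ] <- dM
  }
  loss <- loss / (B * T)

  if (want_grads) {
    dHf <- dM_all[, , seq_len(H), drop = FALSE]
    dHb <- dM_all[, , H + seq_len(H), drop = FALSE]
    gf <- .lstm_backward(X, fw, params$Wx_f, params$Wh_f, dHf)
    gb <- .lstm_backward(X, bw, params$Wx_b, params$Wh_b, dHb)
    grads$Wx_f <- gf$dWx; grads$Wh_f <- gf$dWh; grads$b_f <- gf$db
    grads$Wx_b <- gb$dWx; grads$Wh_b <- gb$dWh; grads$b_b <- gb$db
  }
  list(loss = loss, grads = grads, probs = probs, alphas = alphas)
}

#' Train the breathing-phase detection model
#'
#' @param sequences List of feature matrices (steps x coefficients), all of
#'   the same length, or a 3-D array `(n, steps, coefficients)`.
#' @param labels List of per-step label vectors over `PHASE_LEVELS` (or a
#'   matrix `(n, steps)`).
#' @param config A [bpdm_config()].
#' @param verbose Print per-epoch loss.
#' @return A `bpdm_model` with parameters, class levels, feature
#'   normalization statistics, config and loss trajectory.
#' @export
train_bpdm <- function(sequences, labels, config = bpdm_config(),
                       verbose = FALSE) {
  if (is.array(sequences) && length(dim(sequences)) == 3L) {
    X <- sequences
  } else {
    Ts <- vapply(sequences, nrow, 1L)
    if (length(unique(Ts)) != 1L)
      stop("all sequences must have the same number of steps", call. = FALSE)
    X <- array(0, c(length(sequences), Ts[1], ncol(sequences[[1]])))
    for (i in seq_along(sequences)) X[i, , ] <- sequences[[i]]
  }
  n <- dim(X)[1]; T <- dim(X)[2]; D <- dim(X)[3]
  if (is.matrix(labels)) labels <- lapply(seq_len(nrow(labels)),
                                          function(i) labels[i, ])
  classes <- PHASE_LEVELS[PHASE_LEVELS %in%
                            unique(unlist(lapply(labels, as.character)))]
  if (!length(classes))
    classes <- sort(unique(unlist(lapply(labels, as.character))))
  Y <- t(vapply(labels, function(l) match(as.character(l), classes),
                integer(T)))
  if (any(is.na(Y))) stop("labels outside the class set", call. = FALSE)

  # feature standardization (stored with the model)
  mu <- apply(X, 3, mean)
  sdv <- pmax(apply(X, 3, stats::sd), 1e-6)
  for (j in seq_len(D)) X[, , j] <- (X[, , j] - mu[j]) / sdv[j]

  set.seed(config$seed)
  params <- .bpdm_init(D, config$hidden, config$attn_dim, length(classes),
                       config$attention)
  opt <- .adam_new(params)
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b0 in seq(1L, n, by = config$batch)) {
      ids <- ord[b0:min(n, b0 + config$batch - 1L)]
      res <- .bpdm_batch(params, X[ids, , , drop = FALSE],
                         Y[ids, , drop = FALSE], config, length(classes))
      step <- .adam_step(params, res$grads, opt, config$lr)
      params <- step$params; opt <- step$state
      ep_loss <- ep_loss + res$loss * length(ids) / n
    }
    losses[ep] <- ep_loss
    if (verbose) message(sprintf("bpdm epoch %d loss %.4f", ep, ep_loss))
  }
  structure(list(params = params, classes = classes, config = config,
                 norm = list(mu = mu, sd = sdv), input_dim = c(T, D),
                 loss = losses), class = "bpdm_model")
}

#' Classify a feature sequence into breathing phases
#'
#' @param model A [train_bpdm()] model.
#' @param feature_seq Feature matrix (steps x coefficients) -- typically a
#'   [featurize()] output -- or a 3-D array of several sequences.
#' @param step_s Seconds per step for the returned track; defaults to the
#'   feature hop when `feature_seq` carries layout metadata, else 0.044.
#' @return A [label_track()] with per-step class probabilities; the
#'   attention weight matrix (rows = steps, normalized) is attached as
#'   attribute `"attention"` for a single sequence.
#' @export
bpdm_classify <- function(model, feature_seq, step_s = NULL) {
  stopifnot(inherits(model, "bpdm_model"))
  ly <- attr(feature_seq, "layout")
  if (is.null(step_s))
    step_s <- if (!is.null(ly)) ly$hop_ms / 1000 else 0.044
  X <- if (is.matrix(feature_seq) || inherits(feature_seq, "feature_matrix")) {
    array(as.matrix(feature_seq),
          c(1, nrow(feature_seq), ncol(feature_seq)))
  } else feature_seq
  D <- dim(X)[3]
  for (j in seq_len(D))
    X[, , j] <- (X[, , j] - model$norm$mu[j]) / model$norm$sd[j]
  res <- .bpdm_batch(model$params, X, NULL, model$config,
                     length(model$classes), want_grads = FALSE)
  P <- matrix(res$probs[1, , ], dim(X)[2], length(model$classes))
  colnames(P) <- model$classes
  lab <- model$classes[max.col(P, ties.method = "first")]
  out <- label_track(lab, step_s, probs = P)
  if (!is.null(res$alphas)) attr(out, "attention") <- res$alphas[[1]]
  out
}

#' @export
print.bpdm_model <- function(x, ...) {
  cat(sprintf("<bpdm_model: %d steps x %d features, hidden %d/dir, attention=%s, classes %s>\n",
              x$input_dim[1], x$input_dim[2], x$config$hidden,
              x$config$attention, paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Save / load a BPDM or BEM checkpoint as JSON
#'
#' The checkpoint embeds the full configuration (including the seed), so any
#' reported metric can be reproduced.
#'
#' @param model A `bpdm_model` or `bem_model`.
#' @param path Output path.
#' @return `path` invisibly (`write_checkpoint`); the model
#'   (`read_checkpoint`).
#' @export
write_checkpoint <- function(model, path) {
  kind <- class(model)[1]
  obj <- list(kind = kind,
              params = model$params,
              classes = model$classes,
              config = unclass(model$config),
              norm = model$norm,
              input_dim = model$input_dim,
              loss = model$loss)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfgclass <- if (obj$kind == "bpdm_model") "bpdm_config" else "bem_config"
  model <- list(params = lapply(obj$params, function(p)
    if (is.matrix(p)) p else as.numeric(p)),
    classes = obj$classes,
    config = structure(as.list(obj$config), class = cfgclass),
    norm = obj$norm, input_dim = obj$input_dim, loss = obj$loss)
  class(model) <- obj$kind
  model
}
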