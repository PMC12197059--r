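#' @title Template-constrained semi-supervised NMF separation
#' @description Separates breathing and heartbeat sound from noise by
#'   factorizing the mixture magnitude spectrogram `V ~ W H` under the
#'   generalized Kullback-Leibler divergence with an L1 sparsity penalty on
#'   the activations. The basis `W = [Wb, Wh, Wn, Wun]` concatenates
#'   template blocks learned from clean breathing, heartbeat and
#'   bone-conducted-noise recordings (frozen by default) with a small
#'   unsupervised block that absorbs unmodeled noise. Soft masks built from
#'   the block reconstructions are applied to the mixture magnitude and
#'   inverted with the original phase.
#' @name separation
NULL

.EPS_NMF <- 1e-10

#' Construct a template bank
#' @param Wb,Wh,Wn Non-negative basis blocks (frequency x components) for
#'   breath, heart and noise; columns are normalized to unit Euclidean norm.
#' @param f Frequency axis the templates were learned on.
#' @param params STFT parameters used during learning.
#' @return A `template_bank` object.
#' @export
template_bank <- function(Wb, Wh, Wn, f = NULL, params = NULL) {
  blocks <- list(breath = as.matrix(Wb), heart = as.matrix(Wh),
                 noise = as.matrix(Wn))
  for (nm in names(blocks)) {
    B <- blocks[[nm]]
    if (any(B < 0)) stop("template entries must be non-negative", call. = FALSE)
    nrm <- sqrt(colSums(B^2))
    if (any(nrm == 0)) stop("zero template column in ", nm, call. = FALSE)
    blocks[[nm]] <- sweep(B, 2, nrm, "/")
  }
  structure(c(blocks, list(f = f, params = params)), class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("<template_bank: %d bins; breath %d, heart %d, noise %d components>\n",
              nrow(x$breath), ncol(x$breath), ncol(x$heart), ncol(x$noise)))
  invisible(x)
}

#' Generalized KL NMF objective with L1 activation penalty
#'
#' `D(V | WH) + mu * sum(H)` where `D` is the generalized Kullback-Leibler
#' divergence `sum(v * log(v / l) - v + l)` with `l = WH`, both floored at
#' `eps` inside the logarithm.
#'
#' @param V Non-negative data matrix.
#' @param W,H Non-negative factors.
#' @param mu L1 penalty weight on `H` (default 0).
#' @param eps Numerical floor (default 1e-10).
#' @return Scalar cost (non-negative when `mu >= 0`).
#' @export
kl_cost <- function(V, W, H, mu = 0, eps = .EPS_NMF) {
  L <- W %*% H
  Vf <- pmax(V, eps); Lf <- pmax(L, eps)
  # terms with v == 0 contribute just +l (v log v -> 0)
  d <- sum(ifelse(V > 0, Vf * (log(Vf) - log(Lf)), 0)) - sum(V) + sum(L)
  d + mu * sum(H)
}

#' Multiplicative update of the activation matrix
#'
#' KL multiplicative rule `H <- H * (W' (V / WH)) / (W' 1 + mu)`. Zeros in
#' `H` stay zero; with `W` fixed the update never increases [kl_cost()].
#'
#' @inheritParams kl_cost
#' @return Updated `H`.
#' @export
nmf_update_h <- function(V, W, H, mu = 0, eps = .EPS_NMF) {
  L <- pmax(W %*% H, eps)
  num <- crossprod(W, V / L)
  den <- matrix(colSums(W), nrow(H), ncol(H)) + mu
  H * num / pmax(den, eps)
}

#' Multiplicative update of selected basis columns
#'
#' Canonical KL rule `W <- W * ((V / WH) H') / (1 H')` applied to the columns
#' in `free_cols` only (template columns stay frozen). Updated columns are
#' re-normalized to unit Euclidean norm with the corresponding rows of `H`
#' rescaled inversely, so the product `W H` -- and hence the objective -- is
#' unchanged by the normalization.
#'
#' @inheritParams kl_cost
#' @param free_cols Integer indices of the columns to update.
#' @return List with updated `W` and `H`.
#' @export
nmf_update_w <- function(V, W, H, free_cols, eps = .EPS_NMF) {
  if (!length(free_cols)) return(list(W = W, H = H))
  L <- pmax(W %*% H, eps)
  R <- V / L
  num <- R %*% t(H[free_cols, , drop = FALSE])
  den <- matrix(rowSums(H[free_cols, , drop = FALSE]), nrow(W),
                length(free_cols), byrow = TRUE)
  Wf <- W[, free_cols, drop = FALSE] * num / pmax(den, eps)
  nrm <- sqrt(colSums(Wf^2))
  nrm[nrm < eps] <- 1
  W[, free_cols] <- sweep(Wf, 2, nrm, "/")
  H[free_cols, ] <- H[free_cols, , drop = FALSE] * nrm
  list(W = W, H = H)
}

#' Unsupervised KL-NMF (used for template learning)
#'
#' Plain alternating multiplicative KL updates with column normalization,
#' seeded initialization.
#'
#' @param V Non-negative matrix (frequency x time).
#' @param k Number of components.
#' @param max_iter Iterations (default 200).
#' @param seed RNG seed for the initialization.
#' @param eps Numerical floor.
#' @return List with `W` (unit-norm columns), `H`, and the cost trajectory.
#' @export
nmf_kl <- function(V, k, max_iter = 200, seed = 1, eps = .EPS_NMF) {
  set.seed(seed)
  F <- nrow(V); T <- ncol(V)
  W <- matrix(stats::runif(F * k, 0.1, 1), F, k)
  H <- matrix(stats::runif(k * T, 0.1, 1), k, T)
  cost <- numeric(max_iter)
  for (it in seq_len(max_iter)) {
    H <- nmf_update_h(V, W, H, mu = 0, eps = eps)
    upd <- nmf_update_w(V, W, H, seq_len(k), eps = eps)
    W <- upd$W; H <- upd$H
    cost[it] <- kl_cost(V, W, H, mu = 0, eps = eps)
  }
  list(W = W, H = H, cost = cost)
}

#' Learn spectral templates from clean reference recordings
#'
#' Runs an unsupervised KL-NMF per source on the concatenated magnitude
#' spectrograms of that source's clean recordings and returns the unit-norm
#' basis columns as a [template_bank()].
#'
#' @param reference Named list with elements `breath`, `heart`, `noise`, each
#'   a list of clean [audio_signal()] recordings (one signal may be passed
#'   directly).
#' @param k_per_source Named integer vector of components per source
#'   (defaults `c(breath = 10, heart = 10, noise = 10)`).
#' @param window_len_s,hop_frac,n_fft STFT parameters (see [stft()]).
#' @param max_iter NMF iterations per source.
#' @param seed RNG seed.
#' @return A [template_bank()].
#' @export
learn_templates <- function(reference,
                            k_per_source = c(breath = 10, heart = 10,
                                             noise = 10),
                            window_len_s = 0.046, hop_frac = 0.5,
                            n_fft = NULL, max_iter = 200, seed = 1) {
  need <- c("breath", "heart", "noise")
  if (!all(need %in% names(reference)))
    stop("`reference` must name breath, heart and noise recordings",
         call. = FALSE)
  Ws <- list(); f_axis <- NULL; params <- NULL
  for (src in need) {
    recs <- reference[[src]]
    if (inherits(recs, "audio_signal")) recs <- list(recs)
    if (!length(recs))
      stop("no reference recordings for source: ", src, call. = FALSE)
    Vs <- lapply(recs, function(a) {
      sp <- stft(a, window_len_s, hop_frac, n_fft)
      f_axis <<- sp$f; params <<- sp$params
      sp$V
    })
    V <- do.call(cbind, Vs)
    k <- k_per_source[[src]]
    fit <- nmf_kl(V, k, max_iter = max_iter,
                  seed = seed + match(src, need))
    Ws[[src]] <- fit$W
  }
  template_bank(Ws$breath, Ws$heart, Ws$noise, f = f_axis, params = params)
}

#' Separation configuration
#'
#' @param k_unsupervised Components in the free (unsupervised) block.
#' @param mu L1 activation penalty weight on the template blocks.
#' @param mu_unsup L1 penalty on the unsupervised block's activations; the
#'   stronger default keeps the free block from absorbing energy the
#'   templates already explain.
#' @param lambda_h,lambda_l,lambda_n Weights of the auxiliary template
#'   data-fit terms (heart, breath, noise).
#' @param beta Divergence exponent; only `beta = 1` (KL) is supported.
#' @param max_iter Maximum multiplicative iterations.
#' @param tol Relative cost-change convergence tolerance.
#' @param eps_floor Numerical floor.
#' @param seed RNG seed for the activation initialization.
#' @param finetune_templates If `TRUE` the template blocks are also updated
#'   (pulled toward both the mixture and their template spectrograms);
#'   default `FALSE` keeps them frozen.
#' @return A `sep_config` list.
#' @export
sep_config <- function(k_unsupervised = 5, mu = 0.3, mu_unsup = 2,
                       lambda_h = 1, lambda_l = 1, lambda_n = 1, beta = 1,
                       max_iter = 200, tol = 1e-6, eps_floor = .EPS_NMF,
                       seed = 1, finetune_templates = FALSE) {
  if (beta != 1) stop("only beta = 1 (KL divergence) is supported", call. = FALSE)
  structure(list(k_unsupervised = k_unsupervised, mu = mu,
                 mu_unsup = mu_unsup, lambda_h = lambda_h,
                 lambda_l = lambda_l, lambda_n = lambda_n, beta = beta,
                 max_iter = max_iter, tol = tol, eps_floor = eps_floor,
                 seed = seed, finetune_templates = finetune_templates),
            class = "sep_config")
}

#' Separate breathing and heartbeat audio from a mixture segment
#'
#' Runs the semi-supervised NMF on the segment's magnitude spectrogram with
#' frozen template blocks plus a free unsupervised block, forms soft masks
#' `mask_src = (W_src H_src) / (W H)`, applies them to the mixture magnitude,
#' and reconstructs breath and heart audio with the mixture phase.
#'
#' @param segment An accepted [audio_signal()] segment.
#' @param templates A [template_bank()].
#' @param config A [sep_config()].
#' @param template_audio Optional named list (`breath`, `heart`, `noise`) of
#'   clean template recordings; when supplied (and always when
#'   `finetune_templates = TRUE`) auxiliary KL data-fit terms on the template
#'   spectrograms are included in the objective, weighted by the lambda
#'   hyperparameters.
#' @return A `separation_result`: `audio_breath`, `audio_heart`, the four
#'   masks, the fitted model (`W`, `H`, block map), the cost trajectory and a
#'   convergence flag.
#' @export
separate <- function(segment, templates, config = sep_config(),
                     template_audio = NULL) {
  stopifnot(inherits(segment, "audio_signal"),
            inherits(templates, "template_bank"))
  p <- templates$params
  sp <- stft(segment,
             window_len_s = if (is.null(p)) 0.046 else
               p$window_len / p$sample_rate,
             hop_frac = if (is.null(p)) 0.5 else p$hop / p$window_len,
             n_fft = if (is.null(p)) NULL else p$n_fft)
  V <- sp$V
  eps <- config$eps_floor
  Fb <- nrow(V)
  if (nrow(templates$breath) != Fb)
    stop("template frequency axis does not match the segment STFT",
         call. = FALSE)

  blocks <- list(breath = templates$breath, heart = templates$heart,
                 noise = templates$noise)
  set.seed(config$seed)
  ku <- config$k_unsupervised
  Wun <- matrix(stats::runif(Fb * ku, 0.1, 1), Fb, ku)
  Wun <- sweep(Wun, 2, sqrt(colSums(Wun^2)), "/")
  W <- cbind(blocks$breath, blocks$heart, blocks$noise, Wun)
  ks <- c(breath = ncol(blocks$breath), heart = ncol(blocks$heart),
          noise = ncol(blocks$noise), unsup = ku)
  idx <- split(seq_len(sum(ks)), rep(names(ks), ks))[names(ks)]
  K <- sum(ks); Tn <- ncol(V)
  H <- matrix(stats::runif(K * Tn, 0.1, 1), K, Tn)
  # per-row L1 weights: template blocks get mu, the free block mu_unsup
  mu_row <- rep(config$mu, K)
  mu_row[idx$unsup] <- config$mu_unsup

  if (all(V == 0)) {
    warning("all-zero segment; returning zero outputs", call. = FALSE)
    zero <- audio_signal(numeric(length(segment$samples)),
                         segment$sample_rate)
    mask0 <- matrix(0, Fb, Tn)
    return(structure(list(audio_breath = zero, audio_heart = zero,
                          masks = list(breath = mask0, heart = mask0,
                                       noise = mask0, unsup = mask0),
                          model = list(W = W, H = H, blocks = idx,
                                       config = config),
                          cost = numeric(0), converged = TRUE,
                          spec = sp), class = "separation_result"))
  }

  # auxiliary template fits (Eq.-6-style constraints on the template blocks)
  aux <- NULL
  finetune <- isTRUE(config$finetune_templates)
  if (!is.null(template_audio) || finetune) {
    if (is.null(template_audio))
      stop("finetune_templates = TRUE requires `template_audio`", call. = FALSE)
    lam <- c(breath = config$lambda_l, heart = config$lambda_h,
             noise = config$lambda_n)
    aux <- lapply(names(template_audio), function(src) {
      Va <- stft(template_audio[[src]],
                 window_len_s = sp$params$window_len / sp$params$sample_rate,
                 hop_frac = sp$params$hop / sp$params$window_len,
                 n_fft = sp$params$n_fft)$V
      Ha <- matrix(stats::runif(ks[[src]] * ncol(Va), 0.1, 1),
                   ks[[src]], ncol(Va))
      list(src = src, V = Va, H = Ha, lambda = lam[[src]])
    })
  }

  cost_fn <- function(W, H, aux) {
    cst <- kl_cost(V, W, H, mu = 0, eps = eps) + sum(mu_row * rowSums(H))
    if (!is.null(aux))
      for (a in aux)
        cst <- cst + a$lambda *
          kl_cost(a$V, W[, idx[[a$src]], drop = FALSE], a$H, 0, eps)
    cst
  }

  cost <- numeric(config$max_iter)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    L <- pmax(W %*% H, eps)
    H <- H * crossprod(W, V / L) /
      pmax(matrix(colSums(W), K, Tn) + mu_row, eps)
    if (!is.null(aux)) {
      for (j in seq_along(aux)) {
        a <- aux[[j]]
        aux[[j]]$H <- nmf_update_h(a$V, W[, idx[[a$src]], drop = FALSE],
                                   a$H, mu = 0, eps = eps)
      }
    }
    free <- idx$unsup
    if (finetune) {
      # template blocks move under the combined main + auxiliary gradient
      for (a in aux) {
        cols <- idx[[a$src]]
        L <- pmax(W %*% H, eps)
        La <- pmax(W[, cols, drop = FALSE] %*% a$H, eps)
        num <- (V / L) %*% t(H[cols, , drop = FALSE]) +
          a$lambda * (a$V / La) %*% t(a$H)
        den <- matrix(rowSums(H[cols, , drop = FALSE]), Fb, length(cols),
                      byrow = TRUE) +
          a$lambda * matrix(rowSums(a$H), Fb, length(cols), byrow = TRUE)
        Wc <- W[, cols, drop = FALSE] * num / pmax(den, eps)
        nrm <- sqrt(colSums(Wc^2)); nrm[nrm < eps] <- 1
        W[, cols] <- sweep(Wc, 2, nrm, "/")
        H[cols, ] <- H[cols, , drop = FALSE] * nrm
        for (j in seq_along(aux))
          if (aux[[j]]$src == a$src) aux[[j]]$H <- aux[[j]]$H * nrm
      }
    }
    upd <- nmf_update_w(V, W, H, free, eps = eps)
    W <- upd$W; H <- upd$H
    cost[it] <- cost_fn(W, H, aux)
    if (it > 1 && abs(cost[it - 1] - cost[it]) <=
        config$tol * max(abs(cost[it - 1]), eps)) {
      cost <- cost[seq_len(it)]
      converged <- TRUE
      break
    }
  }
  if (!converged && config$max_iter > 0)
    cost <- cost[seq_len(config$max_iter)]

  L <- W %*% H
  Lf <- pmax(L, eps)
  masks <- lapply(idx, function(cols)
    (W[, cols, drop = FALSE] %*% H[cols, , drop = FALSE]) / Lf)

  recon <- function(mask) {
    sp2 <- sp
    sp2$V <- V * mask
    istft(sp2)
  }
  structure(list(audio_breath = recon(masks$breath),
                 audio_heart = recon(masks$heart),
                 masks = masks,
                 model = list(W = W, H = H, blocks = idx, config = config),
                 cost = cost, converged = converged, spec = sp),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("<separation_result: %d iterations, converged=%s, final cost %.4g>\n",
              length(x$cost), x$converged,
              if (length(x$cost)) x$cost[length(x$cost)] else NA))
  invisible(x)
}

#' Write a template bank to JSON
#' @param bank A [template_bank()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_template_bank <- function(bank, path) {
  stopifnot(inherits(bank, "template_bank"))
  obj <- list(breath = bank$breath, heart = bank$heart, noise = bank$noise,
              f = bank$f, params = bank$params)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a template bank from JSON
#' @param path JSON file written by [write_template_bank()].
#' @return A [template_bank()].
#' @export
read_template_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  template_bank(obj$breath, obj$heart, obj$noise, f = obj$f,
                params = as.list(obj$params))
}
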