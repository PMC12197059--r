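#' @title Breath extraction module (CNN gate)
#' @description A single-layer convolutional classifier that decides whether
#'   a spectro-temporal feature patch contains breath sound: 10 filters of
#'   size 12 x 12, ReLU, then one fully connected layer with softmax over
#'   the two classes (BREATH / NON_BREATH). Trained with Adam on softmax
#'   cross-entropy; backpropagation is written out by hand.
#' @name bem
NULL

#' BEM training configuration
#'
#' @param n_filters Number of convolution filters (default 10).
#' @param kernel Square kernel size (default 12).
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch Minibatch size.
#' @param seed RNG seed (initialization and shuffling).
#' @return A `bem_config` list.
#' @export
bem_config <- function(n_filters = 10, kernel = 12, lr = 1e-3, epochs = 30,
                       batch = 32, seed = 1) {
  structure(list(n_filters = n_filters, kernel = kernel, lr = lr,
                 epochs = epochs, batch = batch, seed = seed),
            class = "bem_config")
}

# patch (h x w) -> (n_positions x kernel^2) matrix of valid-window columns
.im2col <- function(P, k) {
  h <- nrow(P); w <- ncol(P)
  oh <- h - k + 1L; ow <- w - k + 1L
  # index of top-left corners, column-major over (oh, ow)
  corners <- as.vector(outer(seq_len(oh), (seq_len(ow) - 1L) * h, `+`))
  offs <- as.vector(outer(seq_len(k) - 1L, (seq_len(k) - 1L) * h, `+`))
  idx <- outer(corners, offs, `+`)
  matrix(P[idx], nrow = oh * ow)
}

.bem_forward <- function(params, cols) {
  A <- sweep(cols %*% params$Wf, 2, params$bf, `+`)   # positions x filters
  R <- pmax(A, 0)
  flat <- as.numeric(R)
  logits <- as.numeric(crossprod(params$Wo, flat)) + params$bo
  list(A = A, R = R, flat = flat, logits = logits)
}

# accumulate gradients for one patch; dlogits is length-2
.bem_backward <- function(params, cols, fwd, dlogits, grads) {
  grads$Wo <- grads$Wo + outer(fwd$flat, dlogits)
  grads$bo <- grads$bo + dlogits
  dflat <- as.numeric(params$Wo %*% dlogits)
  dR <- matrix(dflat, nrow(fwd$A), ncol(fwd$A))
  dA <- dR * (fwd$A > 0)
  grads$Wf <- grads$Wf + crossprod(cols, dA)
  grads$bf <- grads$bf + colSums(dA)
  grads
}

#' Train the breath-extraction CNN
#'
#' @param patches List of equal-size numeric matrices (feature patches), or
#'   a 3-D array `(n, h, w)`.
#' @param labels Factor/character/integer vector of two classes, one per
#'   patch.
#' @param config A [bem_config()].
#' @param verbose Print the per-epoch loss.
#' @return A `bem_model` holding the parameters, class levels, config and
#'   the training-loss trajectory.
#' @export
train_bem <- function(patches, labels, config = bem_config(),
                      verbose = FALSE) {
  if (is.array(patches) && length(dim(patches)) == 3L)
    patches <- lapply(seq_len(dim(patches)[1]),
                      function(i) patches[i, , ])
  n <- length(patches)
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2L)
    stop("training data must contain two classes", call. = FALSE)
  y <- match(as.character(labels), classes)
  k <- config$kernel
  h <- nrow(patches[[1]]); w <- ncol(patches[[1]])
  if (h < k || w < k)
    stop("patches smaller than the convolution kernel", call. = FALSE)
  npos <- (h - k + 1L) * (w - k + 1L)
  nf <- config$n_filters

  set.seed(config$seed)
  params <- list(Wf = .nn_init_mat(k * k, nf), bf = numeric(nf),
                 Wo = .nn_init_mat(npos * nf, 2L), bo = numeric(2L))
  cols_all <- lapply(patches, .im2col, k = k)
  opt <- .adam_new(params)
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b0 in seq(1L, n, by = config$batch)) {
      ids <- ord[b0:min(n, b0 + config$batch - 1L)]
      grads <- .zero_like(params)
      bl <- 0
      for (i in ids) {
        fwd <- .bem_forward(params, cols_all[[i]])
        p <- .nn_softmax(matrix(fwd$logits, 1))
        bl <- bl + .nn_xent(p, y[i])
        dlogits <- as.numeric(p)
        dlogits[y[i]] <- dlogits[y[i]] - 1
        grads <- .bem_backward(params, cols_all[[i]], fwd,
                               dlogits / length(ids), grads)
      }
      step <- .adam_step(params, grads, opt, config$lr)
      params <- step$params; opt <- step$state
      ep_loss <- ep_loss + bl / length(ids) * length(ids) / n
    }
    losses[ep] <- ep_loss
    if (verbose) message(sprintf("bem epoch %d loss %.4f", ep, ep_loss))
  }
  structure(list(params = params, classes = classes, config = config,
                 input_dim = c(h, w), loss = losses), class = "bem_model")
}

#' Classify feature patches with a trained BEM
#'
#' @param model A [train_bem()] model.
#' @param patches List of matrices or a 3-D array, sized like the training
#'   patches.
#' @return Matrix of class probabilities (rows sum to 1), columns named by
#'   class.
#' @export
bem_classify <- function(model, patches) {
  stopifnot(inherits(model, "bem_model"))
  if (is.matrix(patches)) patches <- list(patches)
  if (is.array(patches) && length(dim(patches)) == 3L)
    patches <- lapply(seq_len(dim(patches)[1]), function(i) patches[i, , ])
  k <- model$config$kernel
  out <- t(vapply(patches, function(P) {
    fwd <- .bem_forward(model$params, .im2col(P, k))
    as.numeric(.nn_softmax(matrix(fwd$logits, 1)))
  }, numeric(2L)))
  colnames(out) <- model$classes
  out
}

#' @export
print.bem_model <- function(x, ...) {
  cat(sprintf("<bem_model: %dx%d input, %d filters %dx%d, classes %s>\n",
              x$input_dim[1], x$input_dim[2], x$config$n_filters,
              x$config$kernel, x$config$kernel,
              paste(x$classes, collapse = "/")))
  invisible(x)
}
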