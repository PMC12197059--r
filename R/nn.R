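#' @title Minimal neural-network primitives
#' @description Shared pieces for the breath-extraction CNN and the
#'   attention-BiLSTM phase model: seeded initialization, softmax
#'   cross-entropy and an Adam optimizer. Written in plain matrix algebra
#'   with manual backpropagation; gradient correctness is verified against
#'   numerical differentiation in the test suite.
#' @name nn
#' @keywords internal
NULL

.nn_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# mean cross-entropy of row-stochastic P against integer labels
.nn_xent <- function(P, y) -mean(log(pmax(P[cbind(seq_along(y), y)], 1e-12)))

.nn_init_mat <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

.adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.zero_like <- function(params) lapply(params, function(p) p * 0)
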