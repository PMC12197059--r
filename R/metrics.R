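#' @title Separation and classification metrics
#' @description BSS-eval-style decomposition of a separated estimate into
#'   target, interference, noise and artifact components by least-squares
#'   projection, the SDR / SIR / SI-SDR ratios in dB, and the confusion-count
#'   classification metrics (accuracy, recall), mean absolute error and
#'   error CDFs.
#' @name metrics
NULL

.DB_CAP <- 100

.db_ratio <- function(num, den, eps = 1e-12) {
  if (num <= eps && den <= eps) return(0)
  if (den <= eps) return(.DB_CAP)
  if (num <= eps) return(-.DB_CAP)
  min(.DB_CAP, max(-.DB_CAP, 10 * log10(num / den)))
}

.proj_span <- function(y, X) {
  # least-squares projection of y onto the column span of X
  X <- as.matrix(X)
  keep <- colSums(X^2) > 0
  if (!any(keep)) return(numeric(length(y)))
  fit <- stats::lm.fit(X[, keep, drop = FALSE], y)
  as.numeric(X[, keep, drop = FALSE] %*% fit$coefficients)
}

#' Decompose a separation estimate into BSS-eval components
#'
#' Orthogonal least-squares projections: `s_target` is the projection of the
#' estimate onto the span of the target reference; `e_inter` the additional
#' part explained by the other sources; `e_noise` the additional part
#' explained by the noise reference; `e_artif` the remainder. The four
#' components sum to the estimate exactly.
#'
#' @param estimate Separated signal (numeric vector or [audio_signal()]).
#' @param target Clean reference of the target source.
#' @param interferers List (possibly empty) of the other clean sources.
#' @param noise_ref Optional noise reference signal.
#' @return A `bss_decomposition` with components `s_target`, `e_inter`,
#'   `e_noise`, `e_artif`.
#' @export
bss_decompose <- function(estimate, target, interferers = list(),
                          noise_ref = NULL) {
  g <- function(v) if (inherits(v, "audio_signal")) v$samples else as.numeric(v)
  y <- g(estimate); s <- g(target)
  ints <- lapply(interferers, g)
  nref <- if (is.null(noise_ref)) NULL else g(noise_ref)
  lens <- c(length(y), length(s), vapply(ints, length, 1L),
            if (!is.null(nref)) length(nref))
  if (length(unique(lens)) != 1L)
    stop("all signals must have equal length", call. = FALSE)

  s_target <- .proj_span(y, cbind(s))
  p1 <- s_target
  X2 <- cbind(s, do.call(cbind, c(ints, list(NULL))))
  p2 <- if (length(ints)) .proj_span(y, X2) else p1
  e_inter <- p2 - p1
  p3 <- if (!is.null(nref)) .proj_span(y, cbind(X2, nref)) else p2
  e_noise <- p3 - p2
  e_artif <- y - p3
  structure(list(s_target = s_target, e_inter = e_inter, e_noise = e_noise,
                 e_artif = e_artif), class = "bss_decomposition")
}

#' Signal-to-distortion ratio in dB
#'
#' `10 log10(||s_target||^2 / ||e_inter + e_noise + e_artif||^2)`, capped at
#' +/- 100 dB so reports stay finite.
#'
#' @param d A [bss_decompose()] result.
#' @return SDR in dB.
#' @export
sdr <- function(d) {
  stopifnot(inherits(d, "bss_decomposition"))
  err <- d$e_inter + d$e_noise + d$e_artif
  .db_ratio(sum(d$s_target^2), sum(err^2))
}

#' Signal-to-interference ratio in dB
#'
#' `10 log10(||s_target||^2 / ||e_inter||^2)`, capped at +/- 100 dB.
#'
#' @inheritParams sdr
#' @return SIR in dB.
#' @export
sir <- function(d) {
  stopifnot(inherits(d, "bss_decomposition"))
  .db_ratio(sum(d$s_target^2), sum(d$e_inter^2))
}

#' Scale-invariant signal-to-distortion ratio in dB
#'
#' With optimal scale `alpha = <s_hat, s> / ||s||^2`:
#' `10 log10(||alpha s||^2 / ||alpha s - s_hat||^2)`, capped at +/- 100 dB.
#' Invariant to positive rescaling of the estimate.
#'
#' @param s Clean reference signal.
#' @param s_hat Separated estimate.
#' @return SI-SDR in dB.
#' @export
si_sdr <- function(s, s_hat) {
  g <- function(v) if (inherits(v, "audio_signal")) v$samples else as.numeric(v)
  s <- g(s); s_hat <- g(s_hat)
  if (length(s) != length(s_hat))
    stop("signals must have equal length", call. = FALSE)
  if (sum(s^2) == 0) stop("reference signal is zero", call. = FALSE)
  alpha <- sum(s_hat * s) / sum(s^2)
  .db_ratio(sum((alpha * s)^2), sum((alpha * s - s_hat)^2))
}

#' @rdname si_sdr
#' @export
si_sir <- si_sdr

#' Confusion counts
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(as.list(v), class = "confusion_counts")
}

#' Classification accuracy `(TP + TN) / (TP + TN + FP + FN)`
#' @param c A [confusion_counts()] object.
#' @return Fraction in \[0, 1\]; `NA` when the total is zero.
#' @export
accuracy <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tot <- c$TP + c$TN + c$FP + c$FN
  if (tot == 0) return(NA_real_)
  (c$TP + c$TN) / tot
}

#' Recall (true positive rate) `TP / (TP + FN)`
#' @inheritParams accuracy
#' @return Fraction in \[0, 1\]; `NA` (undefined) when `TP + FN = 0`.
#' @export
recall <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$TP + c$FN == 0) return(NA_real_)
  c$TP / (c$TP + c$FN)
}

#' Mean absolute error between predictions and truth
#' @param predicted,truth Equal-length non-empty numeric vectors.
#' @return `(1/n) * sum(|predicted - truth|)`.
#' @export
mae <- function(predicted, truth) {
  if (!length(predicted) || length(predicted) != length(truth))
    stop("need equal non-zero lengths", call. = FALSE)
  mean(abs(predicted - truth))
}

#' Empirical error CDF
#'
#' @param errors Numeric vector of (absolute) errors.
#' @return A data frame with columns `error` (sorted unique values) and
#'   `cum_fraction`, plus the step function itself as attribute `"fun"`.
#' @export
error_cdf <- function(errors) {
  if (!length(errors)) stop("empty error vector", call. = FALSE)
  fn <- stats::ecdf(errors)
  xs <- sort(unique(errors))
  out <- data.frame(error = xs, cum_fraction = fn(xs))
  attr(out, "fun") <- fn
  out
}
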