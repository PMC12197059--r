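#' @title MFCC and logMel feature extraction
#' @description Frame-level features for breath modeling: mel-frequency
#'   cepstral coefficients (orthonormal DCT-II of log mel-filterbank
#'   energies) and dB-scaled mel energies (logMel), computed from the
#'   Hamming-windowed power spectrum. logMel stands in for delta/acceleration
#'   coefficients.
#' @name features
NULL

.EPS_FEAT <- 1e-10

#' Hz to mel conversion
#'
#' `mel(f) = 2595 * log10(1 + f / 700)`: strictly increasing, 0 at 0 Hz,
#' compressive at high frequency to mimic auditory sensitivity.
#'
#' @param f Frequency in Hz (non-negative).
#' @return Mel value(s).
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) stop("frequencies must be non-negative", call. = FALSE)
  2595 * log10(1 + f / 700)
}

#' Mel to Hz conversion (inverse of [hz_to_mel()])
#' @param m Mel value(s).
#' @return Frequency in Hz.
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' @param n_mels Number of triangular filters (default 26).
#' @param n_fft FFT size the filters act on.
#' @param sample_rate Sample rate in Hz.
#' @param f_min,f_max Band edges; default 0 to Nyquist.
#' @return A `mel_filterbank`: list with `weights` (n_mels x (n_fft/2+1)) and
#'   the mel band edges `f_edges` in Hz.
#' @export
mel_filterbank <- function(n_mels = 26, n_fft, sample_rate, f_min = 0,
                           f_max = sample_rate / 2) {
  nb <- n_fft %/% 2L + 1L
  freqs <- (seq_len(nb) - 1L) * sample_rate / n_fft
  edges_mel <- seq(hz_to_mel(f_min), hz_to_mel(f_max), length.out = n_mels + 2L)
  edges <- mel_to_hz(edges_mel)
  W <- matrix(0, n_mels, nb)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (freqs - lo) / max(ce - lo, 1e-12)
    dn <- (hi - freqs) / max(hi - ce, 1e-12)
    W[m, ] <- pmax(0, pmin(up, dn))
  }
  structure(list(weights = W, f_edges = edges, n_fft = n_fft,
                 sample_rate = sample_rate), class = "mel_filterbank")
}

#' Hamming-windowed power spectrum of one frame
#'
#' `P = |FFT(s * w)|^2` over the one-sided spectrum, `w` the Hamming window.
#'
#' @param frame Numeric sample vector (non-empty).
#' @param n_fft FFT size; `NULL` uses the next power of two.
#' @param window `"hamming"` (default) or `"none"`.
#' @return Power values of length `n_fft/2 + 1`.
#' @export
power_spectrum <- function(frame, n_fft = NULL, window = c("hamming", "none")) {
  window <- match.arg(window)
  n <- length(frame)
  if (!n) stop("empty frame", call. = FALSE)
  if (is.null(n_fft)) n_fft <- stats::nextn(n, 2)
  w <- if (window == "hamming")
    0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1)) else rep(1, n)
  sw <- frame * w
  S <- stats::fft(c(sw, numeric(n_fft - n)))
  Mod(S[seq_len(n_fft %/% 2L + 1L)])^2
}

# orthonormal DCT-II matrix (n_out x n_in)
.dct_matrix <- function(n_out, n_in) {
  i <- 0:(n_out - 1)
  m <- 0:(n_in - 1)
  M <- sqrt(2 / n_in) * cos(pi * outer(i, (2 * m + 1), `*`) / (2 * n_in))
  M[1, ] <- M[1, ] / sqrt(2)
  M
}

#' Mel-frequency cepstral coefficients of one power spectrum
#'
#' Filter energies are floored at `eps` before the logarithm; the DCT-II is
#' orthonormal, so a constant log-energy vector maps to
#' `C0 = c * sqrt(n_mels)` with all higher coefficients zero.
#'
#' @param P One-sided power spectrum (non-negative).
#' @param filterbank A [mel_filterbank()].
#' @param n_coeffs Number of cepstral coefficients (default 13).
#' @param eps Energy floor.
#' @return Numeric vector of `n_coeffs` coefficients.
#' @export
mfcc <- function(P, filterbank, n_coeffs = 13, eps = .EPS_FEAT) {
  stopifnot(inherits(filterbank, "mel_filterbank"))
  E <- as.numeric(filterbank$weights %*% P)
  logE <- log(pmax(E, eps))
  as.numeric(.dct_matrix(n_coeffs, length(logE)) %*% logE)
}

#' dB-scaled mel energies (logMel) of one power spectrum
#'
#' `10 * log10(max(mel_energy, eps))`; the floor keeps the logarithm finite
#' for silent frames.
#'
#' @inheritParams mfcc
#' @return Numeric vector of `n_mels` dB values.
#' @export
log_mel <- function(P, filterbank, eps = .EPS_FEAT) {
  stopifnot(inherits(filterbank, "mel_filterbank"))
  E <- as.numeric(filterbank$weights %*% P)
  10 * log10(pmax(E, eps))
}

#' Frame-level feature matrix for breath modeling
#'
#' Frames the signal, computes the Hamming-windowed power spectrum per frame
#' and concatenates `[MFCC | logMel]` per row. The default hop is derived so
#' that one second of signal yields 87 feature steps with a 44 ms frame
#' (the sequence-length convention of the phase-detection model):
#' `hop_ms = (1000 - frame_ms) / 86`.
#'
#' @param x An [audio_signal()].
#' @param frame_ms Frame length in milliseconds (default 44).
#' @param hop_ms Hop in milliseconds; `NULL` (default) derives the 87-steps-
#'   per-second convention.
#' @param n_mels,n_mfcc Filterbank size and cepstral order.
#' @param include Character subset of `c("mfcc", "logmel")`.
#' @return A `feature_matrix`: matrix (frames x coefficients) with layout
#'   metadata attributes.
#' @export
featurize <- function(x, frame_ms = 44, hop_ms = NULL, n_mels = 26,
                      n_mfcc = 13, include = c("mfcc", "logmel")) {
  stopifnot(inherits(x, "audio_signal"))
  include <- match.arg(include, several.ok = TRUE)
  fs <- x$sample_rate
  frame_len <- max(2L, round(frame_ms / 1000 * fs))
  if (is.null(hop_ms)) {
    # 87 steps per second: hop chosen so one second yields exactly 87 frames
    hop <- max(1L, floor((fs - frame_len) / 86))
    hop_ms <- hop / fs * 1000
  } else {
    hop <- max(1L, round(hop_ms / 1000 * fs))
  }
  starts <- .frame_starts(length(x$samples), frame_len, hop)
  if (!length(starts)) stop("signal shorter than one frame", call. = FALSE)
  n_fft <- stats::nextn(frame_len, 2)
  fb <- mel_filterbank(n_mels, n_fft, fs)
  dct <- .dct_matrix(n_mfcc, n_mels)
  ncol_out <- ("mfcc" %in% include) * n_mfcc +
    ("logmel" %in% include) * n_mels
  out <- matrix(0, length(starts), ncol_out)
  for (j in seq_along(starts)) {
    fr <- x$samples[starts[j]:(starts[j] + frame_len - 1L)]
    P <- power_spectrum(fr, n_fft)
    E <- as.numeric(fb$weights %*% P)
    row <- numeric(0)
    if ("mfcc" %in% include)
      row <- c(row, as.numeric(dct %*% log(pmax(E, .EPS_FEAT))))
    if ("logmel" %in% include)
      row <- c(row, 10 * log10(pmax(E, .EPS_FEAT)))
    out[j, ] <- row
  }
  structure(out, class = c("feature_matrix", "matrix", "array"),
            layout = list(n_mfcc = if ("mfcc" %in% include) n_mfcc else 0L,
                          n_logmel = if ("logmel" %in% include) n_mels else 0L,
                          frame_ms = frame_ms, hop_ms = hop_ms,
                          sample_rate = fs))
}

#' @export
print.feature_matrix <- function(x, ...) {
  ly <- attr(x, "layout")
  cat(sprintf("<feature_matrix: %d steps x %d coefs (%d mfcc + %d logmel), %g ms frame / %.3f ms hop>\n",
              nrow(x), ncol(x), ly$n_mfcc, ly$n_logmel, ly$frame_ms, ly$hop_ms))
  invisible(x)
}
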