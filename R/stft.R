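#' @title Short-time Fourier analysis
#' @description STFT with a periodic Hann window and an exact weighted
#'   overlap-add inverse. The default 46 ms window with 50% hop satisfies the
#'   constant-overlap-add condition, so `istft(stft(x))` reproduces `x` to
#'   floating-point accuracy away from the very edges.
#' @name stft_analysis
NULL

.hann_periodic <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Construct a spectrogram object
#' @param V Non-negative magnitude matrix (frequency x time).
#' @param phase Phase matrix in radians, same dimensions as `V`.
#' @param f Frequency axis in Hz (length `nrow(V)`).
#' @param t Frame-center time axis in seconds (length `ncol(V)`).
#' @param params List of analysis parameters (window, hop, n_fft, length).
#' @return A `spectrogram` object.
#' @export
spectrogram <- function(V, phase, f, t, params) {
  V <- as.matrix(V); phase <- as.matrix(phase)
  if (!all(dim(V) == dim(phase)))
    stop("V and phase dimensions differ", call. = FALSE)
  if (any(V < 0)) stop("magnitudes must be non-negative", call. = FALSE)
  if (length(f) != nrow(V) || length(t) != ncol(V))
    stop("axis lengths must match V", call. = FALSE)
  structure(list(V = V, phase = phase, f = f, t = t, params = params),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d bins x %d frames, %g-%g Hz, n_fft %d>\n",
              nrow(x$V), ncol(x$V), min(x$f), max(x$f), x$params$n_fft))
  invisible(x)
}

#' Short-time Fourier transform
#'
#' @param x An [audio_signal()].
#' @param window_len_s Window length in seconds (default 0.046).
#' @param hop_frac Hop as a fraction of the window (default 0.5; must divide
#'   the window so overlap-add reconstruction is exact).
#' @param n_fft FFT size; `NULL` (default) uses the next power of two at or
#'   above the window length.
#' @return A [spectrogram()] holding one-sided magnitude and phase.
#' @export
stft <- function(x, window_len_s = 0.046, hop_frac = 0.5, n_fft = NULL) {
  stopifnot(inherits(x, "audio_signal"))
  fs <- x$sample_rate
  wl <- max(4L, round(window_len_s * fs))
  if (wl %% 2L == 1L) wl <- wl + 1L
  hop <- round(wl * hop_frac)
  if (hop > wl) stop("hop must not exceed the window length", call. = FALSE)
  if (is.null(n_fft)) n_fft <- stats::nextn(wl, 2)
  if (n_fft < wl) stop("n_fft must be at least the window length", call. = FALSE)
  w <- .hann_periodic(wl)
  s <- x$samples
  # pad so edges are analysed and the frame grid covers the full signal
  pad <- wl - hop
  s_pad <- c(numeric(pad), s, numeric(wl))
  starts <- seq(1L, length(s_pad) - wl + 1L, by = hop)
  nb <- n_fft %/% 2L + 1L
  S <- matrix(0 + 0i, nb, length(starts))
  for (j in seq_along(starts)) {
    fr <- s_pad[starts[j]:(starts[j] + wl - 1L)] * w
    S[, j] <- stats::fft(c(fr, numeric(n_fft - wl)))[seq_len(nb)]
  }
  f <- (seq_len(nb) - 1L) * fs / n_fft
  t <- (starts - 1L - pad + wl / 2) / fs
  spectrogram(Mod(S), Arg(S), f, t,
              params = list(window_len = wl, hop = hop, n_fft = n_fft,
                            pad = pad, n_samples = length(s), sample_rate = fs))
}

#' Inverse short-time Fourier transform
#'
#' Weighted overlap-add reconstruction from one-sided magnitude and phase.
#' For an unmodified spectrogram this inverts [stft()] exactly (interior
#' samples within 1e-6 for float64).
#'
#' @param spec A [spectrogram()].
#' @return An [audio_signal()] of the original analysed length.
#' @export
istft <- function(spec) {
  stopifnot(inherits(spec, "spectrogram"))
  p <- spec$params
  wl <- p$window_len; hop <- p$hop; n_fft <- p$n_fft
  w <- .hann_periodic(wl)
  nb <- nrow(spec$V)
  S <- spec$V * exp(1i * spec$phase)
  nt <- ncol(S)
  out_len <- p$pad + p$n_samples + wl
  y <- numeric(out_len)
  wsum <- numeric(out_len)
  for (j in seq_len(nt)) {
    full <- c(S[, j], Conj(S[seq(nb - 1L, 2L), j]))
    fr <- Re(stats::fft(full, inverse = TRUE)) / n_fft
    fr <- fr[seq_len(wl)]
    i0 <- (j - 1L) * hop
    idx <- (i0 + 1L):(i0 + wl)
    y[idx] <- y[idx] + fr * w
    wsum[idx] <- wsum[idx] + w^2
  }
  keep <- (p$pad + 1L):(p$pad + p$n_samples)
  wsum[wsum < 1e-12] <- 1
  audio_signal((y / wsum)[keep], p$sample_rate)
}
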