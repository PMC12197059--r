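#' @title Endpoint detection and periodicity gating
#' @description Band-pass filtering, frame-level short-time energy and
#'   zero-crossing rate, dual-threshold segment detection, Hilbert-envelope
#'   extraction and autocorrelation period estimation. Together these select
#'   the quasi-periodic 15-second audio segments that the separation stage
#'   consumes.
#' @name preprocess
NULL

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an `order`-pole Butterworth band-pass forward and backward
#' (zero-phase), so detected segment timestamps are not delayed. The default
#' band 500--8000 Hz targets the range where in-ear physiological sound is
#' strongest; ambient noise above 8 kHz is rejected.
#'
#' @param x An [audio_signal()].
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Overall filter order (even; default 4).
#' @param auto_shrink If `TRUE` (default) a `high_hz` at or above Nyquist is
#'   shrunk to 0.45 * sample rate with a warning instead of erroring.
#' @return Filtered [audio_signal()] of the same length.
#' @export
bandpass_filter <- function(x, low_hz = 500, high_hz = 8000, order = 4,
                            auto_shrink = TRUE) {
  stopifnot(inherits(x, "audio_signal"))
  nyq <- x$sample_rate / 2
  if (order %% 2 != 0) stop("`order` must be even for a band-pass", call. = FALSE)
  if (low_hz <= 0 || low_hz >= high_hz)
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  if (high_hz >= nyq) {
    if (!auto_shrink)
      stop("high_hz must be below the Nyquist frequency", call. = FALSE)
    high_hz <- 0.45 * x$sample_rate
    warning(sprintf("band edge shrunk to %.0f Hz (below Nyquist)", high_hz),
            call. = FALSE)
    if (low_hz >= high_hz) stop("band collapsed after shrinking", call. = FALSE)
  }
  if (!length(x$samples)) return(x)
  bf <- signal::butter(order / 2, c(low_hz, high_hz) / nyq, type = "pass")
  y <- signal::filtfilt(bf, x$samples)
  audio_signal(y, x$sample_rate)
}

#' Zero-phase amplitude response of the band-pass filter
#'
#' Evaluates the amplitude gain of the filter that [bandpass_filter()]
#' applies. Forward-backward filtering applies the Butterworth twice, so the
#' zero-phase amplitude gain is the squared one-pass magnitude `|H(w)|^2`
#' (and the energy retention of a narrowband signal is its square,
#' `|H(w)|^4`). Used to verify stop-band attenuation and pass-band flatness.
#'
#' @param freqs_hz Frequencies to evaluate (Hz).
#' @param sample_rate Sample rate in Hz.
#' @inheritParams bandpass_filter
#' @return Linear zero-phase amplitude gain at each frequency.
#' @export
bandpass_response <- function(freqs_hz, sample_rate, low_hz = 500,
                              high_hz = 8000, order = 4) {
  nyq <- sample_rate / 2
  bf <- signal::butter(order / 2, c(low_hz, high_hz) / nyq, type = "pass")
  w <- pi * freqs_hz / nyq
  ej <- exp(-1i * w)
  horner <- function(cf) {
    v <- rep(0 + 0i, length(w))
    for (c0 in rev(cf)) v <- v * ej + c0  # b0 + b1 z^-1 + ...
    v
  }
  h <- horner(bf$b) / horner(bf$a)
  Mod(h)^2
}

#' Construct a frame series
#' @param values Per-frame scalar values (finite, non-negative).
#' @param frame_ms,hop_ms Frame and hop lengths in milliseconds.
#' @param start_s Time of the first frame's left edge (seconds).
#' @return A `frame_series` object.
#' @export
frame_series <- function(values, frame_ms, hop_ms, start_s = 0) {
  values <- as.numeric(values)
  if (frame_ms < hop_ms || hop_ms <= 0)
    stop("need frame_ms >= hop_ms > 0", call. = FALSE)
  if (length(values) && (!all(is.finite(values)) || any(values < 0)))
    stop("frame values must be finite and non-negative", call. = FALSE)
  structure(list(values = values, frame_ms = frame_ms, hop_ms = hop_ms,
                 start_s = start_s), class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series: %d frames, %g ms frame / %g ms hop>\n",
              length(x$values), x$frame_ms, x$hop_ms))
  invisible(x)
}

.frame_starts <- function(n, frame_len, hop) {
  if (n < frame_len) integer(0) else seq(1L, n - frame_len + 1L, by = hop)
}

#' Short-time energy
#'
#' Per-frame energy `E = sum(s^2)` over non-overlapping (by default) 10 ms
#' frames.
#'
#' @param x An [audio_signal()].
#' @param frame_ms,hop_ms Frame/hop length in milliseconds.
#' @return A [frame_series()].
#' @export
short_term_energy <- function(x, frame_ms = 10, hop_ms = 10) {
  stopifnot(inherits(x, "audio_signal"))
  frame_len <- max(1L, round(frame_ms / 1000 * x$sample_rate))
  hop <- max(1L, round(hop_ms / 1000 * x$sample_rate))
  starts <- .frame_starts(length(x$samples), frame_len, hop)
  if (!length(starts))
    stop("signal shorter than one frame", call. = FALSE)
  idx <- outer(starts, 0:(frame_len - 1L), `+`)
  vals <- rowSums(matrix(x$samples[idx]^2, nrow = length(starts)))
  frame_series(vals, frame_ms, hop_ms)
}

#' Short-time zero-crossing rate
#'
#' Per-frame fraction of sign changes, `(# sign changes)/(frame_len - 1)`.
#' `sign(0)` inherits the previous sign so runs of exact zeros do not count
#' as crossings.
#'
#' @inheritParams short_term_energy
#' @return A [frame_series()].
#' @export
zero_crossing_rate <- function(x, frame_ms = 10, hop_ms = 10) {
  stopifnot(inherits(x, "audio_signal"))
  frame_len <- max(2L, round(frame_ms / 1000 * x$sample_rate))
  hop <- max(1L, round(hop_ms / 1000 * x$sample_rate))
  n <- length(x$samples)
  starts <- .frame_starts(n, frame_len, hop)
  if (!length(starts))
    stop("signal shorter than one frame", call. = FALSE)
  s <- sign(x$samples)
  # zeros inherit the previous sign (leading zeros inherit the first sign seen)
  nz <- which(s != 0)
  if (!length(nz)) {
    s <- rep(1, n)
  } else if (length(nz) < n) {
    idx <- cummax(ifelse(s != 0, seq_len(n), 0L))
    idx[idx == 0L] <- nz[1]
    s <- s[idx]
  }
  chg <- c(0, as.numeric(s[-1] != s[-n]))
  cs <- c(0, cumsum(chg))
  # crossings strictly inside the frame: positions start+1 .. start+len-1
  vals <- (cs[starts + frame_len] - cs[starts + 1L]) / (frame_len - 1L)
  frame_series(vals, frame_ms, hop_ms)
}

#' Detector thresholds for dual-threshold endpoint detection
#'
#' @param energy_high,energy_low High/low frame-energy thresholds (the high
#'   threshold opens a segment, the low one closes it in `"dual"` mode).
#' @param zcr_min Minimum zero-crossing rate for a frame to count as active.
#' @param min_consecutive_frames Frames that must jointly exceed the high
#'   energy and ZCR thresholds before a segment opens (default 5).
#' @param segment_len_s Fixed candidate-segment length in seconds (default 15).
#' @return A `detector_thresholds` object.
#' @export
detector_thresholds <- function(energy_high, energy_low = 0, zcr_min = 0,
                                min_consecutive_frames = 5,
                                segment_len_s = 15) {
  if (energy_high < energy_low || energy_low < 0)
    stop("need energy_high >= energy_low >= 0", call. = FALSE)
  if (min_consecutive_frames < 1)
    stop("min_consecutive_frames must be >= 1", call. = FALSE)
  structure(list(energy_high = energy_high, energy_low = energy_low,
                 zcr_min = zcr_min,
                 min_consecutive_frames = as.integer(min_consecutive_frames),
                 segment_len_s = segment_len_s),
            class = "detector_thresholds")
}

#' Derive detector thresholds from template recordings
#'
#' The detector sets its thresholds from a reference signal template: the
#' high energy threshold is the 90th percentile of the
#' template frame energies, the low threshold the 50th, and the ZCR floor the
#' 10th percentile of template frame ZCRs.
#'
#' @param template An [audio_signal()] of clean reference sound.
#' @param frame_ms Frame length used for the statistics.
#' @param ... Passed to [detector_thresholds()].
#' @return A [detector_thresholds()] object.
#' @export
thresholds_from_template <- function(template, frame_ms = 10, ...) {
  e <- short_term_energy(template, frame_ms, frame_ms)$values
  z <- zero_crossing_rate(template, frame_ms, frame_ms)$values
  detector_thresholds(
    energy_high = stats::quantile(e, 0.9, names = FALSE),
    energy_low  = stats::quantile(e, 0.5, names = FALSE),
    zcr_min     = stats::quantile(z, 0.1, names = FALSE),
    ...
  )
}

#' Detect candidate segments with the dual-threshold rule
#'
#' A segment opens at the first frame of the first run of at least
#' `min_consecutive_frames` frames whose energy exceeds `energy_high` and
#' whose ZCR exceeds `zcr_min`. In `"fixed"` mode (default) the segment spans
#' `segment_len_s` seconds and scanning resumes after its end; truncated tail
#' segments are discarded. In `"dual"` mode the segment instead closes at the
#' first frame whose energy falls below `energy_low`.
#'
#' @param x A (band-pass filtered) [audio_signal()].
#' @param thresholds A [detector_thresholds()].
#' @param frame_ms,hop_ms Framing for the detection features.
#' @param mode `"fixed"` (15 s segments) or `"dual"` (energy-low end rule).
#' @return A data frame with columns `start_s`, `end_s`.
#' @export
detect_segments <- function(x, thresholds, frame_ms = 10, hop_ms = 10,
                            mode = c("fixed", "dual")) {
  stopifnot(inherits(x, "audio_signal"),
            inherits(thresholds, "detector_thresholds"))
  mode <- match.arg(mode)
  out <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (length(x$samples) < round(frame_ms / 1000 * x$sample_rate)) return(out)
  e <- short_term_energy(x, frame_ms, hop_ms)$values
  z <- zero_crossing_rate(x, frame_ms, hop_ms)$values
  n <- min(length(e), length(z))
  active <- e[seq_len(n)] > thresholds$energy_high &
    z[seq_len(n)] > thresholds$zcr_min
  hop_s <- hop_ms / 1000
  total_s <- length(x$samples) / x$sample_rate
  k <- thresholds$min_consecutive_frames
  i <- 1L
  while (i <= n - k + 1L) {
    if (all(active[i:(i + k - 1L)])) {
      start_s <- (i - 1L) * hop_s
      if (mode == "fixed") {
        end_s <- start_s + thresholds$segment_len_s
        if (end_s <= total_s + 1e-9) {
          out <- rbind(out, data.frame(start_s = start_s, end_s = end_s))
        } else {
          break  # truncated tail discarded; nothing further can fit
        }
        i <- as.integer(ceiling(end_s / hop_s)) + 1L
      } else {
        j <- i + k - 1L
        while (j < n && e[j + 1L] >= thresholds$energy_low) j <- j + 1L
        end_s <- min(total_s, j * hop_s)
        out <- rbind(out, data.frame(start_s = start_s, end_s = end_s))
        i <- j + 2L
      }
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Hilbert envelope with decimation
#'
#' Magnitude of the analytic signal (computed via FFT), optionally low-pass
#' filtered and decimated by an integer factor to reduce downstream
#' autocorrelation cost while keeping the slow periodicity information.
#'
#' @param x An [audio_signal()].
#' @param downsample_factor Integer decimation factor (default 100).
#' @return An [audio_signal()] at rate `sample_rate / downsample_factor`.
#' @export
extract_envelope <- function(x, downsample_factor = 100) {
  stopifnot(inherits(x, "audio_signal"))
  f <- as.integer(downsample_factor)
  if (f < 1) stop("downsample_factor must be >= 1", call. = FALSE)
  n <- length(x$samples)
  if (!n) return(audio_signal(numeric(0), x$sample_rate / f))
  env <- Mod(.analytic_signal(x$samples))
  if (f == 1L) return(audio_signal(env, x$sample_rate))
  # anti-alias before picking every f-th sample
  bf <- signal::butter(4, 0.8 / f, type = "low")
  env_f <- signal::filtfilt(bf, env)
  audio_signal(env_f[seq(1L, n, by = f)], x$sample_rate / f)
}

.analytic_signal <- function(s) {
  n <- length(s)
  S <- stats::fft(s)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(S * h, inverse = TRUE) / n
}

#' Estimate the dominant envelope period by autocorrelation
#'
#' Computes the biased autocorrelation of the mean-removed envelope, finds
#' peaks with topographic prominence above `peak_min_prominence` (default
#' `0.25 * acf(0)`), and returns the mean spacing of successive peak lags
#' divided by the envelope sample rate. Returns `NA` (undefined) when fewer
#' than two peaks qualify -- distinct from a period of zero.
#'
#' @param envelope An [audio_signal()] envelope (typically decimated).
#' @param peak_min_prominence Absolute prominence threshold; `NULL` (default)
#'   uses `0.25 * acf(0)`; the relatively high default keeps envelope
#'   jitter out of the mean peak spacing.
#' @return Estimated period in seconds, or `NA_real_`; the spacing coefficient
#'   of variation is attached as attribute `"spacing_cv"` when defined.
#' @export
estimate_period <- function(envelope, peak_min_prominence = NULL) {
  stopifnot(inherits(envelope, "audio_signal"))
  v <- envelope$samples - mean(envelope$samples)
  n <- length(v)
  if (n < 4L || sum(v^2) == 0) return(NA_real_)
  # biased autocorrelation via FFT; the linear lag taper (n - k)/n of the
  # biased estimator shifts peak maxima toward zero lag, so it is divided
  # out before peak finding (lags beyond 0.85 n, where the correction
  # amplifies noise, are not searched)
  nfft <- stats::nextn(2L * n, 2)
  V <- stats::fft(c(v, numeric(nfft - n)))
  r <- Re(stats::fft(V * Conj(V), inverse = TRUE))[seq_len(n)] / nfft
  r <- r / n  # biased normalization
  kmax <- floor(0.85 * n)
  lags <- seq_len(kmax)
  r_u <- r[lags + 1L] * n / (n - lags)
  if (is.null(peak_min_prominence)) peak_min_prominence <- 0.25 * r[1]
  peaks <- .prominent_peaks(r_u, peak_min_prominence)
  if (length(peaks) < 2L) return(NA_real_)
  d <- diff(peaks)
  t_hat <- mean(d) / envelope$sample_rate
  attr(t_hat, "spacing_cv") <- if (mean(d) > 0) stats::sd(d) / mean(d) else NA
  t_hat
}

# local maxima with topographic prominence >= min_prom; returns lag indices
# (1-based positions within the supplied vector)
.prominent_peaks <- function(r, min_prom) {
  n <- length(r)
  if (n < 3L) return(integer(0))
  is_peak <- which(r[2:(n - 1)] > r[1:(n - 2)] & r[2:(n - 1)] >= r[3:n]) + 1L
  keep <- logical(length(is_peak))
  for (k in seq_along(is_peak)) {
    p <- is_peak[k]; h <- r[p]
    i <- p; lmin <- h
    while (i > 1L && r[i] <= h) { i <- i - 1L; lmin <- min(lmin, r[i]) }
    left_base <- if (r[i] > h) lmin else min(lmin, r[seq_len(p)])
    i <- p; rmin <- h
    while (i < n && r[i] <= h) { i <- i + 1L; rmin <- min(rmin, r[i]) }
    right_base <- if (r[i] > h) rmin else min(rmin, r[p:n])
    keep[k] <- (h - max(left_base, right_base)) >= min_prom
  }
  is_peak[keep]
}

#' Accept or reject a candidate segment by its period
#'
#' Accepts when the estimated period is defined and lies in the closed
#' interval `[d1, d2]`, default `[0.3, 3]` s; the lower bound excludes the
#' degenerate near-zero lag.
#'
#' @param period_s Estimated period in seconds (may be `NA`).
#' @param d1,d2 Closed acceptance bounds in seconds.
#' @return Logical flag.
#' @export
accept_segment <- function(period_s, d1 = 0.3, d2 = 3.0) {
  if (d1 > d2) stop("need d1 <= d2", call. = FALSE)
  !is.na(period_s) && period_s >= d1 && period_s <= d2
}

#' Extract a time slice from an audio signal
#' @param x An [audio_signal()].
#' @param start_s,end_s Half-open interval `[start_s, end_s)` in seconds.
#' @return The sliced [audio_signal()].
#' @export
slice_audio <- function(x, start_s, end_s) {
  stopifnot(inherits(x, "audio_signal"), end_s > start_s)
  i0 <- floor(start_s * x$sample_rate) + 1L
  i1 <- min(length(x$samples), floor(end_s * x$sample_rate))
  audio_signal(x$samples[i0:i1], x$sample_rate)
}
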