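#' @title Audio and label carriers
#' @description Core S3 types shared by every stage of the pipeline:
#'   `audio_signal` (a mono waveform with its sample rate) and `label_track`
#'   (a fixed-step sequence of breathing-phase labels).
#' @name signal_io
NULL

#' Breathing-phase label levels
#'
#' The three phases the phase detector distinguishes. A complete breathing
#' cycle contains inhalation, exhalation and (possibly zero-length) pauses;
#' inhalation-pause and exhalation-pause are not distinguished.
#' @export
PHASE_LEVELS <- c("INHALE", "EXHALE", "PAUSE")

#' Construct a mono audio signal
#'
#' @param samples Numeric vector of amplitudes, nominal range \[-1, 1\].
#' @param sample_rate Sampling rate in Hz (positive scalar).
#' @return An `audio_signal` object (list with `samples`, `sample_rate`).
#' @export
audio_signal <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (length(sample_rate) != 1L || !is.finite(sample_rate) || sample_rate <= 0)
    stop("`sample_rate` must be a positive finite scalar", call. = FALSE)
  if (length(samples) && !all(is.finite(samples)))
    stop("all samples must be finite", call. = FALSE)
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s), rms %.4g>\n",
              length(x$samples), x$sample_rate, duration_s(x),
              if (length(x$samples)) sqrt(mean(x$samples^2)) else 0))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param x An `audio_signal`.
#' @return Length of `x` divided by its sample rate.
#' @export
duration_s <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  length(x$samples) / x$sample_rate
}

#' Construct a phase label track
#'
#' @param labels Character vector over `PHASE_LEVELS` (or a binary
#'   BREATH/NON_BREATH variant for the breath-extraction gate).
#' @param step_s Seconds per label step (positive scalar).
#' @param probs Optional per-step class-probability matrix (rows sum to 1).
#' @return A `label_track` object.
#' @export
label_track <- function(labels, step_s, probs = NULL) {
  labels <- as.character(labels)
  if (length(step_s) != 1L || !is.finite(step_s) || step_s <= 0)
    stop("`step_s` must be a positive scalar", call. = FALSE)
  if (!length(labels)) stop("`labels` must be non-empty", call. = FALSE)
  if (!is.null(probs)) {
    probs <- as.matrix(probs)
    if (nrow(probs) != length(labels))
      stop("`probs` must have one row per label", call. = FALSE)
    if (any(abs(rowSums(probs) - 1) > 1e-6))
      stop("`probs` rows must sum to 1", call. = FALSE)
  }
  structure(list(labels = labels, step_s = as.numeric(step_s), probs = probs),
            class = "label_track")
}

#' @export
print.label_track <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<label_track: %d steps x %g s (%s)>\n", length(x$labels),
              x$step_s, paste(names(tab), as.integer(tab), sep = ":",
                              collapse = " ")))
  invisible(x)
}

## ---- WAV container (RIFF PCM16/24 and IEEE float32) ------------------------

.wav_fmt_codes <- c(pcm = 1L, float = 3L)

#' Read a WAV file
#'
#' Reads RIFF/WAVE files containing PCM16, PCM24 or IEEE float32 payloads with
#' one or two channels. Stereo is downmixed to mono by channel mean; integer
#' samples are scaled to \[-1, 1\] by the symmetric `1/2^(bits-1)` convention.
#'
#' @param path Path to an existing `.wav` file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        code     = sum(as.integer(fmt_raw[1:2]) * c(1L, 256L)),
        channels = sum(as.integer(fmt_raw[3:4]) * c(1L, 256L)),
        rate     = sum(as.integer(fmt_raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits     = sum(as.integer(fmt_raw[15:16]) * c(1L, 256L))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("missing fmt chunk in ", path, call. = FALSE)
  if (is.null(data_raw) || length(data_raw) == 0L)
    stop("empty audio payload in ", path, call. = FALSE)
  if (!fmt$channels %in% 1:2)
    stop("unsupported channel count: ", fmt$channels, call. = FALSE)

  if (fmt$code == 1L && fmt$bits == 16L) {
    n <- length(data_raw) %/% 2L
    x <- readBin(data_raw, "integer", n, size = 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$code == 1L && fmt$bits == 24L) {
    n <- length(data_raw) %/% 3L
    b <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else if (fmt$code == 3L && fmt$bits == 32L) {
    n <- length(data_raw) %/% 4L
    x <- readBin(data_raw, "double", n, size = 4, endian = "little")
  } else {
    stop(sprintf("unsupported WAV codec (format %d, %d bit)", fmt$code,
                 fmt$bits), call. = FALSE)
  }
  if (fmt$channels == 2L) {
    n2 <- (length(x) %/% 2L) * 2L
    x <- (x[seq(1, n2, by = 2)] + x[seq(2, n2, by = 2)]) / 2
  }
  audio_signal(x, fmt$rate)
}

#' Write a WAV file
#'
#' Samples outside \[-1, 1\] are clamped with a warning. `read_wav(write_wav(x))`
#' is exact for `"float32"` and within one quantization step for the integer
#' depths.
#'
#' @param x An [audio_signal()].
#' @param path Output path.
#' @param bit_depth One of `"float32"` (default), `"pcm16"`, `"pcm24"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, bit_depth = c("float32", "pcm16", "pcm24")) {
  stopifnot(inherits(x, "audio_signal"))
  bit_depth <- match.arg(bit_depth)
  s <- x$samples
  if (length(s) && (max(s) > 1 || min(s) < -1)) {
    warning("samples outside [-1, 1] clamped before writing", call. = FALSE)
    s <- pmin(1, pmax(-1, s))
  }
  bits <- switch(bit_depth, float32 = 32L, pcm16 = 16L, pcm24 = 24L)
  code <- if (bit_depth == "float32") 3L else 1L
  bytes_per <- bits %/% 8L
  data_size <- length(s) * bytes_per

  con <- file(path, "wb")
  on.exit(close(con))
  w_u32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w_u32(36L + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_u32(16L)
  w_u16(code); w_u16(1L); w_u32(as.integer(x$sample_rate))
  w_u32(as.integer(x$sample_rate) * bytes_per)   # byte rate
  w_u16(bytes_per); w_u16(bits)
  writeChar("data", con, eos = NULL); w_u32(data_size)
  if (bit_depth == "float32") {
    writeBin(s, con, size = 4, endian = "little")
  } else if (bit_depth == "pcm16") {
    q <- as.integer(pmin(32767, pmax(-32768, round(s * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    q <- round(s * 8388608)
    q <- pmin(8388607, pmax(-8388608, q))
    q <- ifelse(q < 0, q + 16777216, q)
    b <- rbind(q %% 256, (q %/% 256) %% 256, (q %/% 65536) %% 256)
    writeBin(as.raw(as.integer(b)), con)
  }
  if (data_size %% 2L == 1L) writeBin(as.raw(0L), con)
  invisible(path)
}

## ---- Label CSV (start_s,end_s,label) ---------------------------------------

#' Read interval phase labels from CSV and rasterize to a step grid
#'
#' The CSV must have columns `start_s,end_s,label` with half-open intervals
#' `[start_s, end_s)`. Gaps between intervals are filled with `PAUSE`.
#'
#' @param path CSV file path.
#' @param step_s Step of the output grid in seconds.
#' @param duration_s Optional total duration; defaults to the largest `end_s`.
#' @return A [label_track()].
#' @export
read_labels <- function(path, step_s, duration_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) data.frame(start_s = numeric(),
                                                end_s = numeric(),
                                                label = character()))
  if (nrow(df) == 0L) {
    if (is.null(duration_s))
      stop("empty label file needs an explicit `duration_s`", call. = FALSE)
    n <- max(1L, floor(duration_s / step_s))
    return(label_track(rep("PAUSE", n), step_s))
  }
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(df)))
    stop("label CSV must have columns start_s,end_s,label", call. = FALSE)
  if (any(df$end_s < df$start_s))
    stop("label interval with end_s < start_s", call. = FALSE)
  ord <- order(df$start_s)
  df <- df[ord, ]
  if (nrow(df) > 1L && any(df$start_s[-1] < df$end_s[-nrow(df)] - 1e-9))
    stop("overlapping label intervals", call. = FALSE)
  if (is.null(duration_s)) duration_s <- max(df$end_s)
  n <- max(1L, floor(round(duration_s / step_s, 9)))
  labels <- rep("PAUSE", n)
  centers <- (seq_len(n) - 0.5) * step_s
  for (i in seq_len(nrow(df))) {
    hit <- centers >= df$start_s[i] & centers < df$end_s[i]
    labels[hit] <- df$label[i]
  }
  label_track(labels, step_s)
}

#' Write interval phase labels as CSV
#'
#' Collapses a [label_track()] back to `start_s,end_s,label` run intervals
#' (PAUSE runs included, so the file round-trips).
#'
#' @param track A [label_track()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(track, path) {
  stopifnot(inherits(track, "label_track"))
  r <- rle(track$labels)
  ends <- cumsum(r$lengths) * track$step_s
  starts <- c(0, ends[-length(ends)])
  utils::write.csv(data.frame(start_s = starts, end_s = ends,
                              label = r$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
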