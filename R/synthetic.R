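#' @title Seeded synthetic physiological audio with ground truth
#' @description Generators for quasi-periodic breath noise (inhale / exhale /
#'   pause envelope structure), periodic S1+S2 heartbeat pulses, and
#'   environment noise, plus the convolutive mixing model (length-4 FIR
#'   filters per source). Every generator is deterministic under a fixed
#'   seed and returns exact ground truth (phase track, beat times,
#'   configured rates), standing in for private in-ear recordings.
#' @name synthetic
NULL

.bandlimited_noise <- function(n, fs, low_hz, high_hz, order = 2) {
  x <- stats::rnorm(n)
  nyq <- fs / 2
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  signal::filtfilt(bf, x)
}

#' Generate quasi-periodic breath noise with exact phase ground truth
#'
#' Each breathing cycle is inhale, half the pause, exhale, half the pause.
#' Inhale and exhale are band-limited noise bursts under a raised-cosine
#' envelope; the two phases sound similar -- their turbulence bands overlap
#' broadly, inhalation being somewhat brighter (900--3200 Hz) than
#' exhalation (550--2200 Hz) -- so telling them apart requires sequence
#' context, not just a per-frame spectral cue. Pauses are silent. The
#' returned phase track is constructed from the same boundaries, so it is
#' exact.
#'
#' @param duration_s Total duration in seconds.
#' @param br_bpm Breathing rate in breaths/min (6--60).
#' @param inhale_frac,exhale_frac,pause_frac Cycle fractions (must sum to 1).
#' @param depth RMS amplitude of the active phases (0 gives silence).
#' @param sample_rate Sample rate in Hz (default 8000).
#' @param step_s Ground-truth label step (default 0.01 s).
#' @param seed RNG seed.
#' @return List with `audio` ([audio_signal()]) and `phases`
#'   ([label_track()]).
#' @export
gen_breath <- function(duration_s, br_bpm = 15, inhale_frac = 0.4,
                       exhale_frac = 0.4, pause_frac = 0.2, depth = 0.1,
                       sample_rate = 8000, step_s = 0.01, seed = 1) {
  if (abs(inhale_frac + exhale_frac + pause_frac - 1) > 1e-9)
    stop("phase fractions must sum to 1", call. = FALSE)
  if (br_bpm < 6 || br_bpm > 60)
    stop("br_bpm must lie in [6, 60]", call. = FALSE)
  set.seed(seed)
  fs <- sample_rate
  n <- round(duration_s * fs)
  cyc <- 60 / br_bpm
  x <- numeric(n)
  n_steps <- max(1L, floor(round(duration_s / step_s, 9)))
  labels <- rep("PAUSE", n_steps)
  centers <- (seq_len(n_steps) - 0.5) * step_s

  burst <- function(t0, t1, low_hz, high_hz) {
    i0 <- floor(t0 * fs) + 1L; i1 <- min(n, floor(t1 * fs))
    if (i1 <= i0) return()
    m <- i1 - i0 + 1L
    env <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = m))
    noise <- .bandlimited_noise(m, fs, low_hz, min(high_hz, 0.45 * fs))
    seg <- env * noise
    r <- sqrt(mean(seg^2))
    if (r > 0 && depth > 0) seg <- seg * depth / r
    x[i0:i1] <<- x[i0:i1] + seg
  }

  t0 <- 0
  while (t0 < duration_s - 1e-9) {
    ti1 <- t0 + inhale_frac * cyc
    tp1 <- ti1 + pause_frac * cyc / 2
    te1 <- tp1 + exhale_frac * cyc
    if (depth > 0) {
      burst(t0, min(ti1, duration_s), 900, 3200)
      if (tp1 < duration_s) burst(tp1, min(te1, duration_s), 550, 2200)
    }
    labels[centers >= t0 & centers < min(ti1, duration_s)] <- "INHALE"
    labels[centers >= tp1 & centers < min(te1, duration_s)] <- "EXHALE"
    t0 <- t0 + cyc
  }
  list(audio = audio_signal(x, fs), phases = label_track(labels, step_s))
}

#' Generate periodic S1+S2 heartbeat pulses with exact beat times
#'
#' Beats occur at the configured rate with +/-2% timing jitter; each beat is
#' an S1 pulse (Hann-windowed 760 Hz tone burst, 0.12 s) followed 0.2 s
#' later by a weaker, brighter S2 pulse (1050 Hz, 0.06 s) -- the
#' exercise-shortened systolic interval that lets a 0.25 s refractory rule
#' merge the pair into one counted beat. The pulses sit at the low end of
#' the 500--8000 Hz analysis band: energy is concentrated below 1200 Hz yet
#' most of it survives the zero-phase band-pass whose low edge is 500 Hz.
#'
#' @param duration_s Duration in seconds.
#' @param hr_bpm Heart rate in beats/min (40--200).
#' @param amplitude Peak amplitude scale (default 0.15).
#' @param sample_rate Sample rate in Hz (default 8000).
#' @param seed RNG seed.
#' @return List with `audio` ([audio_signal()]) and `beat_times` (S1 onset
#'   times in seconds).
#' @export
gen_heartbeat <- function(duration_s, hr_bpm = 72, amplitude = 0.15,
                          sample_rate = 8000, seed = 1) {
  if (hr_bpm < 40 || hr_bpm > 200)
    stop("hr_bpm must lie in [40, 200]", call. = FALSE)
  set.seed(seed)
  fs <- sample_rate
  n <- round(duration_s * fs)
  ibi <- 60 / hr_bpm
  # beat count fixed by the nominal grid; jitter perturbs timing only
  k <- seq(0, duration_s - 1e-9, by = ibi)
  beat_times <- k + stats::runif(length(k), -0.02, 0.02) * ibi
  beat_times <- pmin(pmax(beat_times, 0), duration_s - 1e-9)

  pulse <- function(f0, dur, amp) {
    m <- round(dur * fs)
    t <- (0:(m - 1)) / fs
    env <- 0.5 - 0.5 * cos(2 * pi * (0:(m - 1)) / (m - 1))
    amp * env * sin(2 * pi * f0 * t)
  }
  s1 <- pulse(800, 0.12, 1)
  s2 <- pulse(1100, 0.06, 0.72)
  x <- numeric(n)
  add_at <- function(t0, p) {
    i0 <- floor(t0 * fs) + 1L
    i1 <- min(n, i0 + length(p) - 1L)
    if (i1 >= i0) x[i0:i1] <<- x[i0:i1] + p[seq_len(i1 - i0 + 1L)]
  }
  for (tb in beat_times) {
    add_at(tb, s1)
    if (tb + 0.2 < duration_s) add_at(tb + 0.2, s2)
  }
  if (any(x != 0)) x <- x * amplitude / max(abs(x))
  list(audio = audio_signal(x, fs), beat_times = beat_times)
}

#' Generate environment noise
#'
#' `room`: low-level pink noise. `footsteps`: a transient train (about two
#' impacts per second, walking cadence) over a faint pink floor. `gym` /
#' `playground`: broadband noise plus sparse transients at increasing level.
#' Deterministic per seed.
#'
#' @param duration_s Duration in seconds.
#' @param kind One of `"room"`, `"gym"`, `"playground"`, `"footsteps"`.
#' @param level RMS scale of the dominant component (default 0.08).
#' @param sample_rate Sample rate in Hz.
#' @param seed RNG seed.
#' @return An [audio_signal()].
#' @export
gen_noise <- function(duration_s, kind = c("room", "gym", "playground",
                                           "footsteps"),
                      level = 0.08, sample_rate = 8000, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  fs <- sample_rate
  n <- round(duration_s * fs)
  if (n == 0L) return(audio_signal(numeric(0), fs))

  pink <- function(m) {
    # FFT spectral shaping ~ 1/sqrt(f)
    w <- stats::rnorm(m)
    Wf <- stats::fft(w)
    f <- c(1, seq_len(m - 1))
    f <- pmin(f, m - f + 1)
    Wf <- Wf / sqrt(f)
    Re(stats::fft(Wf, inverse = TRUE)) / m
  }
  scale_rms <- function(v, target) {
    r <- sqrt(mean(v^2)); if (r > 0) v * target / r else v
  }
  transients <- function(rate_hz, amp, f_lo, f_hi) {
    x <- numeric(n)
    t0 <- stats::runif(1, 0, 1 / rate_hz)
    while (t0 < duration_s) {
      m <- round(0.06 * fs)
      tt <- (0:(m - 1)) / fs
      burst <- exp(-tt / 0.012) *
        .bandlimited_noise(m, fs, f_lo, min(f_hi, 0.45 * fs), order = 4)
      burst <- amp * burst / max(abs(burst))
      i0 <- floor(t0 * fs) + 1L
      i1 <- min(n, i0 + m - 1L)
      if (i1 >= i0) x[i0:i1] <- x[i0:i1] + burst[seq_len(i1 - i0 + 1L)]
      t0 <- t0 + 1 / rate_hz * stats::runif(1, 0.85, 1.15)
    }
    x
  }

  x <- switch(kind,
    room = scale_rms(pink(n), 0.35 * level),
    # bone-conducted footsteps: low-band impact thumps at walking cadence
    footsteps = scale_rms(transients(2, 1, 500, 640), level) +
      scale_rms(pink(n), 0.1 * level),
    gym = scale_rms(pink(n), 0.7 * level) +
      scale_rms(transients(0.7, 1, 500, 700), 0.7 * level),
    playground = scale_rms(.bandlimited_noise(n, fs, 300, 3500), level) +
      scale_rms(transients(0.4, 1, 500, 700), 0.5 * level)
  )
  audio_signal(x, fs)
}

#' Build a labeled feature-sequence corpus for phase-model training
#'
#' Generates clean breath audio with varied breathing rates and depths,
#' extracts `[MFCC | logMel]` features on the 87-steps-per-second grid, and
#' chops them into fixed-length sequences with exact per-step phase labels
#' from the generator's ground truth. Inhalation and exhalation occupy
#' different turbulence bands, so the corpus is band-separable at the
#' feature level, with phase-edge steps left ambiguous by the amplitude
#' envelope.
#'
#' @param n_seq Number of sequences to return.
#' @param seq_len Steps per sequence (default 87, i.e. about 1 s).
#' @param br_range Breathing-rate range sampled per source signal.
#' @param leak Residual-interference level as a fraction of the breath
#'   depth (default 0.5): footstep noise mixed into the breath audio,
#'   emulating what leaks through an imperfect separation mask. Set 0 for
#'   clean sequences.
#' @param sample_rate Sample rate in Hz.
#' @param seed RNG seed.
#' @return List with `sequences` (list of `seq_len x D` matrices) and
#'   `labels` (list of per-step label vectors).
#' @export
make_phase_corpus <- function(n_seq = 600, seq_len = 87,
                              br_range = c(10, 30), leak = 0.5,
                              sample_rate = 8000, seed = 1) {
  seqs <- list(); labs <- list()
  src <- 0L
  while (length(seqs) < n_seq) {
    src <- src + 1L
    s_seed <- (seed * 131L + src) %% .Machine$integer.max
    set.seed(s_seed)
    br <- stats::runif(1, br_range[1], br_range[2])
    depth <- stats::runif(1, 0.05, 0.15)
    g <- gen_breath(60, br_bpm = br, depth = depth,
                    sample_rate = sample_rate, seed = s_seed + 1)
    audio <- g$audio
    if (leak > 0) {
      nz <- gen_noise(60, "footsteps", level = leak * depth,
                      sample_rate = sample_rate, seed = s_seed + 2)
      audio <- audio_signal(audio$samples + nz$samples, sample_rate)
    }
    f <- featurize(audio)
    hop_s <- attr(f, "layout")$hop_ms / 1000
    centers <- (seq_len(nrow(f)) - 1) * hop_s +
      attr(f, "layout")$frame_ms / 2000
    li <- pmin(length(g$phases$labels),
               pmax(1L, floor(centers / g$phases$step_s) + 1L))
    step_labels <- g$phases$labels[li]
    for (s0 in seq(1L, nrow(f) - seq_len + 1L, by = seq_len)) {
      if (length(seqs) >= n_seq) break
      seqs[[length(seqs) + 1L]] <- f[s0:(s0 + seq_len - 1L), , drop = FALSE]
      labs[[length(labs) + 1L]] <- step_labels[s0:(s0 + seq_len - 1L)]
    }
  }
  list(sequences = seqs, labels = labs)
}

#' Random length-4 FIR mixing filters
#'
#' Coefficients drawn uniform(0.2, 1) with the largest tap moved to the
#' front (causal, mildly reverberant).
#'
#' @param seed RNG seed.
#' @return A `mixture_spec`: list of length-4 vectors `a_breath`, `a_heart`,
#'   `a_noise`.
#' @export
mixture_spec <- function(seed = 1) {
  set.seed(seed)
  draw <- function() {
    a <- stats::runif(4, 0.2, 1)
    i <- which.max(a)
    c(a[i], a[-i])
  }
  structure(list(a_breath = draw(), a_heart = draw(), a_noise = draw(),
                 seed = seed), class = "mixture_spec")
}

.fir <- function(x, a) as.numeric(signal::filter(a, 1, x))

#' Convolutive mixture of breath, heart and noise sources
#'
#' `mixture(t) = sum_k a_breath(k) breath(t-k) + a_heart(k) heart(t-k)
#' + a_noise(k) noise(t-k)` with length-4 FIR filters, truncated to the
#' source length.
#'
#' @param breath,heart,noise Equal-length [audio_signal()] sources (noise
#'   may be `NULL`).
#' @param spec A [mixture_spec()].
#' @return The mixture [audio_signal()].
#' @export
mix_convolutive <- function(breath, heart, noise = NULL, spec = mixture_spec()) {
  stopifnot(inherits(spec, "mixture_spec"))
  fs <- breath$sample_rate
  if (heart$sample_rate != fs ||
      (!is.null(noise) && noise$sample_rate != fs))
    stop("sources must share a sample rate", call. = FALSE)
  lens <- c(length(breath$samples), length(heart$samples),
            if (!is.null(noise)) length(noise$samples))
  if (length(unique(lens)) != 1L)
    stop("sources must share a length", call. = FALSE)
  m <- .fir(breath$samples, spec$a_breath) + .fir(heart$samples, spec$a_heart)
  if (!is.null(noise)) m <- m + .fir(noise$samples, spec$a_noise)
  audio_signal(m, fs)
}

#' Corpus generation configuration
#'
#' @param duration_s Item duration in seconds (default 15).
#' @param hr_bpm,br_bpm Configured rates; either scalars (used for every
#'   item) or `NULL` to draw per item from `hr_range` / `br_range`.
#' @param hr_range,br_range Sampling ranges used when the rates are `NULL`.
#' @param noise_kind Environment noise type.
#' @param breath_depth,heart_amplitude,noise_level Source levels.
#' @param sample_rate Sample rate in Hz.
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(duration_s = 15, hr_bpm = NULL, br_bpm = NULL,
                          hr_range = c(60, 150), br_range = c(10, 30),
                          noise_kind = "footsteps", breath_depth = 0.1,
                          heart_amplitude = 0.15, noise_level = 0.08,
                          sample_rate = 8000) {
  structure(list(duration_s = duration_s, hr_bpm = hr_bpm, br_bpm = br_bpm,
                 hr_range = hr_range, br_range = br_range,
                 noise_kind = noise_kind, breath_depth = breath_depth,
                 heart_amplitude = heart_amplitude,
                 noise_level = noise_level, sample_rate = sample_rate),
            class = "corpus_config")
}

#' Generate a corpus of convolutive mixtures with ground truth
#'
#' Each item holds the mixture, the clean sources, the exact phase track and
#' beat times, the configured rates and the FIR mixing spec. With `out_dir`
#' set, per-item WAV files, a phase-label CSV and a ground-truth JSON are
#' written (`{id}.wav`, `{id}.breath.wav`, `{id}.heart.wav`,
#' `{id}.labels.csv`, `{id}.truth.json`).
#'
#' @param n_items Number of items (0 gives an empty corpus).
#' @param config A [corpus_config()].
#' @param seed Base RNG seed; item `i` uses sub-seeds derived from it.
#' @param out_dir Optional output directory.
#' @return List of items, each a list with `mixture`, `truth` (clean
#'   sources + labels + rates) and `spec`.
#' @export
make_corpus <- function(n_items, config = corpus_config(), seed = 1,
                        out_dir = NULL) {
  items <- vector("list", n_items)
  if (!is.null(out_dir) && n_items > 0)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_items)) {
    base <- (seed * 1000L + i) %% .Machine$integer.max
    set.seed(base)
    hr <- if (is.null(config$hr_bpm))
      stats::runif(1, config$hr_range[1], config$hr_range[2]) else config$hr_bpm
    br <- if (is.null(config$br_bpm))
      stats::runif(1, config$br_range[1], config$br_range[2]) else config$br_bpm
    b <- gen_breath(config$duration_s, br_bpm = br,
                    depth = config$breath_depth,
                    sample_rate = config$sample_rate, seed = base + 1)
    h <- gen_heartbeat(config$duration_s, hr_bpm = hr,
                       amplitude = config$heart_amplitude,
                       sample_rate = config$sample_rate, seed = base + 2)
    nz <- gen_noise(config$duration_s, kind = config$noise_kind,
                    level = config$noise_level,
                    sample_rate = config$sample_rate, seed = base + 3)
    spec <- mixture_spec(seed = base + 4)
    mix <- mix_convolutive(b$audio, h$audio, nz, spec)
    fs <- config$sample_rate
    images <- list(
      breath = audio_signal(.fir(b$audio$samples, spec$a_breath), fs),
      heart = audio_signal(.fir(h$audio$samples, spec$a_heart), fs),
      noise = audio_signal(.fir(nz$samples, spec$a_noise), fs))
    truth <- list(breath = b$audio, heart = h$audio, noise = nz,
                  images = images,
                  phases = b$phases, beat_times = h$beat_times,
                  hr_bpm = hr, br_bpm = br)
    items[[i]] <- list(id = sprintf("item%03d", i), mixture = mix,
                       truth = truth, spec = spec)
    if (!is.null(out_dir)) {
      id <- items[[i]]$id
      write_wav(mix, file.path(out_dir, paste0(id, ".wav")))
      write_wav(b$audio, file.path(out_dir, paste0(id, ".breath.wav")))
      write_wav(h$audio, file.path(out_dir, paste0(id, ".heart.wav")))
      write_labels(b$phases, file.path(out_dir, paste0(id, ".labels.csv")))
      jsonlite::write_json(
        list(hr_bpm = hr, br_bpm = br, beat_times = h$beat_times,
             fir = list(a_breath = spec$a_breath, a_heart = spec$a_heart,
                        a_noise = spec$a_noise)),
        file.path(out_dir, paste0(id, ".truth.json")),
        digits = NA, auto_unbox = TRUE)
    }
  }
  items
}
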