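#' @title Heart-rate and respiratory-rate computation
#' @description Heart rate from dual-threshold beat segmentation of the
#'   separated heartbeat audio (count of beats over the segment duration);
#'   respiratory rate, and the inhale:exhale ratio, from a breathing-phase
#'   label track.
#' @name vitals
NULL

#' Segment individual heartbeats with the dual-threshold energy rule
#'
#' Frame energies above `energy_high` open a beat, which extends until the
#' energy falls below `energy_low`. Candidate beats whose peak energy
#' belongs to a clearly weaker mode (residual interference leaking through
#' the separation mask) are rejected, and beats whose onsets fall within
#' the refractory period of the previous onset are merged (de-duplicating
#' the S1/S2 pair of one heartbeat). With `thresholds = NULL` the energy
#' thresholds are derived from the segment itself: high = 0.3 x the 98th
#' energy percentile, low = 0.3 x high.
#'
#' @param heart_audio Separated heartbeat [audio_signal()].
#' @param thresholds Optional [detector_thresholds()]; only the energy
#'   thresholds are used here.
#' @param frame_ms Frame/hop length (default 10 ms, non-overlapping).
#' @param refractory_s Minimum onset-to-onset spacing (default 0.25 s,
#'   about a 240 bpm physiological ceiling).
#' @param gate_ratio Candidates are dropped when a 2-means split of their
#'   log peak energies separates two modes whose centers differ by more
#'   than this factor (default 2.5); the weaker mode is discarded. Set to
#'   `Inf` to disable the gate.
#' @return A `beat_segmentation`: data frame of beat `(start_s, end_s)`
#'   intervals with attribute `count`.
#' @export
segment_heartbeats <- function(heart_audio, thresholds = NULL, frame_ms = 10,
                               refractory_s = 0.25, gate_ratio = 2.5) {
  stopifnot(inherits(heart_audio, "audio_signal"))
  empty <- structure(data.frame(start_s = numeric(0), end_s = numeric(0)),
                     count = 0L, class = c("beat_segmentation", "data.frame"))
  frame_len <- round(frame_ms / 1000 * heart_audio$sample_rate)
  if (length(heart_audio$samples) < frame_len) return(empty)
  e <- short_term_energy(heart_audio, frame_ms, frame_ms)$values
  if (all(e == 0)) return(empty)
  if (is.null(thresholds)) {
    hi <- 0.3 * stats::quantile(e, 0.98, names = FALSE)
    lo <- 0.3 * hi
    if (hi <= 0) return(empty)
  } else {
    hi <- thresholds$energy_high
    lo <- thresholds$energy_low
  }
  step <- frame_ms / 1000
  n <- length(e)
  beats <- list()
  i <- 1L
  while (i <= n) {
    if (e[i] > hi) {
      j <- i
      while (j < n && e[j + 1L] >= lo) j <- j + 1L
      beats[[length(beats) + 1L]] <- c((i - 1L) * step, j * step,
                                       max(e[i:j]))
      i <- j + 1L
    }
    i <- i + 1L
  }
  if (!length(beats)) return(empty)
  m <- do.call(rbind, beats)
  # leakage gate: drop a clearly weaker peak-energy mode
  if (is.finite(gate_ratio) && nrow(m) >= 4L) {
    lp <- log(m[, 3])
    if (diff(range(lp)) > 1e-6) {
      km <- tryCatch(suppressWarnings(stats::kmeans(
        lp, centers = matrix(stats::quantile(lp, c(0.1, 0.9)), 2))),
        error = function(e) NULL)
      ctr <- if (is.null(km)) c(0, 0) else km$centers[, 1]
      if (abs(diff(ctr)) > log(gate_ratio)) {
        weak <- which.min(ctr)
        keep <- km$cluster != weak
        if (sum(keep) >= 2L) m <- m[keep, , drop = FALSE]
      }
    }
  }
  # refractory merge: onset-to-onset spacing below refractory_s joins beats
  keep_start <- m[1, 1]; keep_end <- m[1, 2]
  out <- NULL
  if (nrow(m) > 1) {
    for (r in 2:nrow(m)) {
      if (m[r, 1] - keep_start < refractory_s) {
        keep_end <- max(keep_end, m[r, 2])
      } else {
        out <- rbind(out, c(keep_start, keep_end))
        keep_start <- m[r, 1]; keep_end <- m[r, 2]
      }
    }
  }
  out <- rbind(out, c(keep_start, keep_end))
  # adaptive second pass: a beat train is near-periodic, so onsets closer
  # than 0.55 x the median inter-onset interval are residual split/leak
  # events and are merged into the preceding beat
  if (nrow(out) >= 4L) {
    med_ibi <- stats::median(diff(out[, 1]))
    refr2 <- max(refractory_s, 0.55 * med_ibi)
    keep_start <- out[1, 1]; keep_end <- out[1, 2]
    out2 <- NULL
    for (r in seq_len(nrow(out))[-1]) {
      if (out[r, 1] - keep_start < refr2) {
        keep_end <- max(keep_end, out[r, 2])
      } else {
        out2 <- rbind(out2, c(keep_start, keep_end))
        keep_start <- out[r, 1]; keep_end <- out[r, 2]
      }
    }
    out <- rbind(out2, c(keep_start, keep_end))
  }
  df <- data.frame(start_s = out[, 1], end_s = out[, 2])
  structure(df, count = nrow(df), class = c("beat_segmentation", "data.frame"))
}

#' Heart rate from a beat segmentation
#'
#' `hr = 60 * count / duration_s` -- the ratio of the number of heartbeats
#' to the audio duration. With `robust = TRUE` and at least four detected
#' beats, the count is re-derived from the beat periodicity as
#' `round(duration_s / IBI)`, where the inter-beat interval is the modal
#' spacing over all pairwise onset differences in the physiological range
#' (0.2--2 s, i.e. 30--300 bpm): a split or leaked beat corrupts the two
#' intervals adjacent to it, but the pairwise-difference histogram still
#' peaks at the true period, so the ratio formula is applied to a
#' periodicity-consistent count. The pipeline uses the robust variant.
#'
#' @param beats A [segment_heartbeats()] result (or a bare count).
#' @param duration_s Segment duration in seconds (> 0).
#' @param robust Re-derive the count from the median inter-beat interval
#'   (default `FALSE`; requires a `beat_segmentation` with >= 4 beats).
#' @return Heart rate in bpm, with attribute `quality = "low"` when the
#'   count is zero.
#' @export
heart_rate <- function(beats, duration_s, robust = FALSE) {
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  count <- if (inherits(beats, "beat_segmentation")) attr(beats, "count")
  else as.integer(beats)
  if (robust && inherits(beats, "beat_segmentation") && count >= 4L) {
    m <- .modal_ibi(beats$start_s)
    if (is.finite(m) && m > 0) count <- round(duration_s / m)
  }
  hr <- 60 * count / duration_s
  if (count == 0L) attr(hr, "quality") <- "low"
  hr
}

# modal inter-beat interval from all pairwise onset differences in the
# physiological range; the smallest strong histogram cluster wins so that
# period multiples do not masquerade as the fundamental
.modal_ibi <- function(onsets, lo = 0.2, hi = 2.0, tol = 0.08) {
  d <- outer(onsets, onsets, `-`)
  d <- sort(d[d > lo & d < hi])
  if (length(d) < 3L) return(NA_real_)
  # continuous support: how many differences fall within +/- tol of each one;
  # the fundamental period collects the most pairs (every consecutive pair
  # plus jittered repeats), so the maximum-support point identifies it
  support <- findInterval(d + tol, d) - findInterval(d - tol, d)
  centre <- d[which.max(support)]
  stats::median(d[abs(d - centre) <= tol])
}

#' Respiratory rate from a phase label track
#'
#' `br = 60 * (# inhale onsets) / duration_s`, an onset being a transition
#' into INHALE from any other label (or a sequence-initial INHALE).
#'
#' @param phases A [label_track()] over `PHASE_LEVELS`.
#' @return Breaths per minute, with attribute `quality = "low"` when no
#'   onset is found.
#' @export
respiratory_rate <- function(phases) {
  stopifnot(inherits(phases, "label_track"))
  lab <- phases$labels
  onsets <- sum(lab == "INHALE" & c(TRUE, lab[-length(lab)] != "INHALE"))
  dur <- length(lab) * phases$step_s
  br <- 60 * onsets / dur
  if (onsets == 0L) attr(br, "quality") <- "low"
  br
}

#' Respiratory rate from half-cycle (active-run) counting
#'
#' Counts maximal INHALE/EXHALE runs as breathing half-cycles:
#' `br = 60 * (runs / 2) / duration_s`. For a window cut mid-cycle this is
#' less biased than inhale-onset counting (a window catching the tail
#' exhale of one cycle and the head inhale of the next sees both as
#' half-cycles rather than two onsets), and a single missed or split run
#' costs half a breath instead of a whole one. The pipeline reports this
#' estimate; [respiratory_rate()] keeps the plain onset definition.
#'
#' @inheritParams respiratory_rate
#' @return Breaths per minute, with attribute `quality = "low"` when no
#'   active run is found.
#' @export
breath_cycle_rate <- function(phases) {
  stopifnot(inherits(phases, "label_track"))
  r <- rle(phases$labels)
  runs <- sum(r$values %in% c("INHALE", "EXHALE"))
  dur <- length(phases$labels) * phases$step_s
  br <- 60 * (runs / 2) / dur
  if (runs == 0L) attr(br, "quality") <- "low"
  br
}

#' Inhale-to-exhale duration ratio
#'
#' Total INHALE duration divided by total EXHALE duration; undefined (`NA`,
#' flagged) when the track holds no exhalation.
#'
#' @param phases A [label_track()].
#' @return Ratio, or `NA_real_` with attribute `quality = "undefined"`.
#' @export
breath_ratio <- function(phases) {
  stopifnot(inherits(phases, "label_track"))
  ti <- sum(phases$labels == "INHALE")
  te <- sum(phases$labels == "EXHALE")
  if (te == 0) {
    out <- NA_real_
    attr(out, "quality") <- "undefined"
    return(out)
  }
  ti / te
}

#' Assemble a vitals report
#'
#' @param hr_bpm Heart rate in bpm.
#' @param br_bpm Respiratory rate in breaths/min.
#' @param breath_ratio Inhale:exhale duration ratio (may be `NA`).
#' @param segment Provenance list (e.g. `start_s`, `end_s`, `period_s`).
#' @param flags Character vector of quality flags.
#' @return A `vitals_report` object.
#' @export
vitals_report <- function(hr_bpm, br_bpm, breath_ratio = NA_real_,
                          segment = list(), flags = character(0)) {
  if ((!is.na(hr_bpm) && hr_bpm < 0) || (!is.na(br_bpm) && br_bpm < 0))
    stop("rates must be non-negative", call. = FALSE)
  structure(list(hr_bpm = as.numeric(hr_bpm), br_bpm = as.numeric(br_bpm),
                 breath_ratio = as.numeric(breath_ratio), segment = segment,
                 flags = flags), class = "vitals_report")
}

#' @export
print.vitals_report <- function(x, ...) {
  cat(sprintf("<vitals_report: hr %.1f bpm, br %.1f breaths/min, ratio %s%s>\n",
              x$hr_bpm, x$br_bpm,
              if (is.na(x$breath_ratio)) "undefined"
              else sprintf("%.2f", x$breath_ratio),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}
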