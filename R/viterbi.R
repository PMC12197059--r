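#' @title Two-state Viterbi breath-activity labeling
#' @description Auto-labels breath activity from the frame-level RMS
#'   envelope: a logistic map turns RMS into the probability of the ACTIVE
#'   (inhale/exhale) state, a two-state HMM with a mild self-transition
#'   preference is decoded with the Viterbi algorithm, and maximal ACTIVE
#'   runs are assigned alternating INHALE/EXHALE labels starting with
#'   inhalation.
#' @name breath_labeling
NULL

#' Logistic mapping from frame RMS to breath-activity probability
#'
#' `p(S = 1 | RMS) = exp(RMS - tau) / (1 + exp(RMS - tau))`: equals 0.5 at
#' the decision threshold `tau` and increases monotonically with RMS. The
#' default `tau = 0.001` suits faint in-ear recordings; it is not universal
#' and should be calibrated per signal (see [auto_tau()]).
#'
#' @param rms Non-negative RMS value(s).
#' @param tau Decision threshold (default 0.001).
#' @return Probability value(s) in (0, 1).
#' @export
rms_to_prob <- function(rms, tau = 0.001) {
  if (any(rms < 0)) stop("RMS must be non-negative", call. = FALSE)
  stats::plogis(rms - tau)
}

#' Calibrate the RMS decision threshold from the signal
#'
#' Places the threshold at the 30% point between the 10th and 90th
#' percentiles of the frame RMS distribution: a scale-free default between
#' the quiet (pause) and loud (breath-burst) modes. The point sits below
#' the halfway mark because the two breath phases recover with unequal
#' amplitude after separation -- the exhalation band overlaps the heartbeat
#' and footstep bands more than the inhalation band does -- and a midpoint
#' threshold loses the weaker phase entirely.
#'
#' @param rms Vector of frame RMS values.
#' @param frac Interpolation point between the two percentiles (default 0.3).
#' @return Calibrated threshold.
#' @export
auto_tau <- function(rms, frac = 0.3) {
  q <- stats::quantile(rms, c(0.1, 0.9), names = FALSE)
  q[1] + frac * (q[2] - q[1])
}

#' Frame-level RMS envelope
#' @param x An [audio_signal()].
#' @param frame_ms,hop_ms Frame/hop length in milliseconds.
#' @return A [frame_series()] of RMS values.
#' @export
frame_rms <- function(x, frame_ms = 10, hop_ms = 10) {
  e <- short_term_energy(x, frame_ms, hop_ms)
  frame_len <- max(1L, round(frame_ms / 1000 * x$sample_rate))
  frame_series(sqrt(e$values / frame_len), frame_ms, hop_ms)
}

#' Two-state transition model for breath activity
#'
#' Row-stochastic 2x2 matrix over states ACTIVE (inhale/exhale) and PAUSE.
#' Activity tends to persist (`p_stay_active`, default 0.55, the midpoint of
#' the 0.5--0.6 range); the pause row is uniform, giving the pause equal
#' chances of persisting or transitioning.
#'
#' @param p_stay_active Self-transition probability of the ACTIVE state.
#' @param p_stay_pause Self-transition probability of PAUSE (default 0.5).
#' @return A 2x2 matrix with rows/cols `c("ACTIVE", "PAUSE")`.
#' @export
transition_model <- function(p_stay_active = 0.55, p_stay_pause = 0.5) {
  if (p_stay_active < 0 || p_stay_active > 1 ||
      p_stay_pause < 0 || p_stay_pause > 1)
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  m <- matrix(c(p_stay_active, 1 - p_stay_active,
                1 - p_stay_pause, p_stay_pause),
              2, 2, byrow = TRUE,
              dimnames = list(c("ACTIVE", "PAUSE"), c("ACTIVE", "PAUSE")))
  m
}

#' Most probable breath-activity state path (Viterbi decoding)
#'
#' Decodes the MAP path of the two-state HMM with emission probabilities
#' `p(obs | ACTIVE) = p` and `p(obs | PAUSE) = 1 - p`, in the log domain.
#' Ties are broken toward PAUSE (both in the per-step maximization and in
#' the final backtrack start).
#'
#' @param prob_seq Per-step ACTIVE probabilities in (0, 1).
#' @param transition A [transition_model()] matrix.
#' @param prior Initial state distribution `c(ACTIVE, PAUSE)` (default
#'   uniform).
#' @return Integer vector of the same length: 1 = ACTIVE, 0 = PAUSE. Empty
#'   input gives an empty path.
#' @export
viterbi_segment <- function(prob_seq, transition = transition_model(),
                            prior = c(0.5, 0.5)) {
  n <- length(prob_seq)
  if (!n) return(integer(0))
  if (any(prob_seq <= 0 | prob_seq >= 1))
    stop("probabilities must lie strictly in (0, 1)", call. = FALSE)
  lt <- log(transition)          # rows: from; cols: to (ACTIVE, PAUSE)
  lp <- log(prior)
  # state 1 = ACTIVE, state 2 = PAUSE
  emit <- rbind(log(prob_seq), log(1 - prob_seq))
  delta <- matrix(-Inf, 2, n)
  psi <- matrix(1L, 2, n)
  delta[, 1] <- lp + emit[, 1]
  for (t in 2:max(2, n)) {
    if (t > n) break
    for (s in 1:2) {
      cand <- delta[, t - 1] + lt[, s]
      # tie toward PAUSE: prefer predecessor 2 on equality
      best <- if (cand[2] >= cand[1]) 2L else 1L
      psi[s, t] <- best
      delta[s, t] <- cand[best] + emit[s, t]
    }
  }
  path <- integer(n)
  path[n] <- if (delta[2, n] >= delta[1, n]) 2L else 1L
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[path[t + 1], t + 1]
  as.integer(path == 1L)
}

#' Convert a binary activity path to alternating phase labels
#'
#' Maximal ACTIVE runs shorter than `min_phase_s` are first merged into
#' their (PAUSE) neighbors -- the longer neighbor absorbs the run, a leading
#' tie going to the previous one -- then the surviving ACTIVE runs are
#' labeled INHALE, EXHALE, INHALE, ... in order, starting with inhalation
#' (the first cut point marks the start of inspiration). PAUSE runs stay
#' PAUSE.
#'
#' @param state_path Integer/logical vector (1 = ACTIVE, 0 = PAUSE).
#' @param step_s Seconds per step.
#' @param min_phase_s Minimum duration of a complete breathing phase
#'   (default 1 s).
#' @param start_phase First label assigned to an ACTIVE run (default
#'   `"INHALE"`).
#' @return A [label_track()] over `PHASE_LEVELS`.
#' @export
states_to_phase_labels <- function(state_path, step_s, min_phase_s = 1.0,
                                   start_phase = c("INHALE", "EXHALE")) {
  start_phase <- match.arg(start_phase)
  n <- length(state_path)
  if (!n) stop("empty state path", call. = FALSE)
  st <- as.integer(state_path != 0)
  min_steps <- ceiling(min_phase_s / step_s - 1e-9)
  r <- rle(st)
  nrun <- length(r$values)
  if (nrun > 1L) {
    # short ACTIVE runs become PAUSE (their neighbors are PAUSE runs)
    short <- which(r$values == 1L & r$lengths < min_steps)
    if (length(short)) {
      r$values[short] <- 0L
      r <- rle(inverse.rle(r))
    }
  }
  labels <- rep("PAUSE", n)
  pos <- cumsum(c(0L, r$lengths))
  order_cycle <- if (start_phase == "INHALE") c("INHALE", "EXHALE")
  else c("EXHALE", "INHALE")
  a <- 0L
  for (k in seq_along(r$values)) {
    if (r$values[k] == 1L) {
      lab <- order_cycle[(a %% 2L) + 1L]
      labels[(pos[k] + 1L):pos[k + 1L]] <- lab
      a <- a + 1L
    }
  }
  label_track(labels, step_s)
}

#' Label breathing phases of separated breath audio
#'
#' Convenience wrapper: frame RMS, logistic activity probability (with
#' per-signal threshold calibration by default), Viterbi decoding, and
#' alternating phase assignment.
#'
#' @param x Separated breath [audio_signal()].
#' @param tau RMS decision threshold; `NULL` (default) calibrates with
#'   [auto_tau()].
#' @param transition A [transition_model()].
#' @param frame_ms RMS frame length (default 10 ms, non-overlapping).
#' @param min_phase_s Minimum phase duration passed to
#'   [states_to_phase_labels()].
#' @param min_pause_s PAUSE runs shorter than this are bridged (treated as
#'   ACTIVE) before phase assignment, so a brief sub-threshold dip inside
#'   one breath phase does not fragment it (default 0.15 s; 0 disables).
#' @param normalize Divide the frame RMS by its maximum before the logistic
#'   mapping (default `TRUE`). Raw audio RMS is much smaller than 1, which
#'   leaves the logistic's log-odds (`RMS - tau`) too weak against the
#'   transition preferences; normalization makes the labeling
#'   scale-invariant, matching the requirement that the decision threshold
#'   be adjusted per signal.
#' @return A [label_track()] of phases at `frame_ms / 1000` step.
#' @export
label_breath_phases <- function(x, tau = NULL,
                                transition = transition_model(),
                                frame_ms = 10, min_phase_s = 1.0,
                                min_pause_s = 0.15, normalize = TRUE) {
  r <- frame_rms(x, frame_ms, frame_ms)
  if (normalize && max(r$values) > 0)
    r$values <- r$values / max(r$values)
  if (is.null(tau)) tau <- auto_tau(r$values)
  p <- rms_to_prob(r$values, tau)
  p <- pmin(1 - 1e-12, pmax(1e-12, p))
  path <- viterbi_segment(p, transition)
  step_s <- frame_ms / 1000
  if (min_pause_s > 0 && length(path) > 2L) {
    r0 <- rle(path)
    inner <- seq_along(r0$values)[-c(1, length(r0$values))]
    short_pause <- inner[r0$values[inner] == 0L &
                           r0$lengths[inner] < min_pause_s / step_s]
    if (length(short_pause)) {
      r0$values[short_pause] <- 1L
      path <- inverse.rle(r0)
    }
  }
  states_to_phase_labels(path, step_s = step_s, min_phase_s = min_phase_s)
}
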