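#' @title End-to-end monitoring pipeline
#' @description Wires the stages together: band-pass filtering, dual-
#'   threshold segment detection, envelope periodicity gating, NMF
#'   separation, breathing-phase labeling (Viterbi auto-labeler, or the
#'   trained BEM gate + BPDM classifier when models are supplied) and
#'   vitals computation, with deterministic seeding and JSON reports that
#'   embed the effective configuration.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Namespaced parameters for every stage; unknown keys are rejected.
#'
#' @param seed Global RNG seed.
#' @param preprocess List: `low_hz`, `high_hz`, `order`, `frame_ms`,
#'   `min_consecutive_frames`, `segment_len_s`, `downsample_factor`,
#'   `d1`, `d2` (periodicity acceptance bounds, seconds).
#' @param separation List: [sep_config()] arguments.
#' @param labeling List: `tau` (`NULL` = auto-calibrated), `p_stay_active`,
#'   `frame_ms`, `min_phase_s`, `min_pause_s`. The default
#'   `min_phase_s = 0.35` accepts the burst cores the Viterbi decoder
#'   detects for exercise breathing up to about 35 breaths/min (detected
#'   run length is roughly half the nominal phase duration); raise it
#'   toward 1 s for resting subjects.
#' @param vitals List: `refractory_s`, `beat_frame_ms`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            preprocess = list(),
                            separation = list(),
                            labeling = list(),
                            vitals = list()) {
  def <- list(
    seed = seed,
    preprocess = list(low_hz = 500, high_hz = 8000, order = 4,
                      frame_ms = 10, min_consecutive_frames = 5,
                      segment_len_s = 15, downsample_factor = 100,
                      d1 = 0.3, d2 = 3.0),
    separation = list(k_unsupervised = 5, mu = 0.1, lambda_h = 1,
                      lambda_l = 1, lambda_n = 1, max_iter = 200,
                      tol = 1e-6, finetune_templates = FALSE),
    labeling = list(tau = NULL, p_stay_active = 0.55, frame_ms = 10,
                    min_phase_s = 0.35, min_pause_s = 0.15),
    vitals = list(refractory_s = 0.25, beat_frame_ms = 10)
  )
  merge_ns <- function(base, user, ns) {
    unknown <- setdiff(names(user), names(base))
    if (length(unknown))
      stop("unknown config key(s) in ", ns, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    base[names(user)] <- user
    base
  }
  def$preprocess <- merge_ns(def$preprocess, preprocess, "preprocess")
  def$separation <- merge_ns(def$separation, separation, "separation")
  def$labeling <- merge_ns(def$labeling, labeling, "labeling")
  def$vitals <- merge_ns(def$vitals, vitals, "vitals")
  structure(def, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  known <- c("seed", "preprocess", "separation", "labeling", "vitals")
  unknown <- setdiff(names(obj), known)
  if (length(unknown))
    stop("unknown top-level config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, obj)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full monitoring pipeline on one recording
#'
#' Preprocesses the recording (band-pass, dual-threshold detection,
#' envelope periodicity gate), separates each accepted segment with the
#' template-constrained NMF, labels breathing phases (with the supplied
#' BEM/BPDM models, else the Viterbi auto-labeler) and computes per-segment
#' vitals.
#'
#' @param input An [audio_signal()] or a WAV path.
#' @param templates A [template_bank()] (or path to a JSON bank).
#' @param models Optional list with elements `bem` and/or `bpdm`.
#' @param config A [pipeline_config()].
#' @param template_audio Optional clean template recordings passed to
#'   [separate()] when fine-tuning is enabled.
#' @return A `pipeline_result`: list with `status` (`"ok"` or
#'   `"no-signal"`), `reports` (one [vitals_report()] per accepted
#'   segment), `segments` (detection/acceptance table), `config_hash` and
#'   `version`.
#' @export
run_pipeline <- function(input, templates, models = NULL,
                         config = pipeline_config(), template_audio = NULL) {
  x <- if (is.character(input)) read_wav(input) else input
  stopifnot(inherits(x, "audio_signal"))
  if (is.character(templates)) templates <- read_template_bank(templates)
  pp <- config$preprocess
  set.seed(config$seed)

  filtered <- suppressWarnings(
    bandpass_filter(x, pp$low_hz, pp$high_hz, pp$order))
  thr <- if (!is.null(template_audio)) {
    # template-derived percentiles (breath + heart reference sound)
    tpl <- audio_signal(c(template_audio$breath$samples,
                          template_audio$heart$samples),
                        x$sample_rate)
    thresholds_from_template(tpl, pp$frame_ms,
                             min_consecutive_frames =
                               pp$min_consecutive_frames,
                             segment_len_s = pp$segment_len_s)
  } else {
    # fall back to a low percentile of the recording's own frame energies
    detector_thresholds(
      energy_high = stats::quantile(
        short_term_energy(filtered, pp$frame_ms, pp$frame_ms)$values,
        0.2, names = FALSE),
      energy_low = 0, zcr_min = 0,
      min_consecutive_frames = pp$min_consecutive_frames,
      segment_len_s = pp$segment_len_s)
  }
  segs <- detect_segments(filtered, thr, pp$frame_ms, pp$frame_ms)

  seg_table <- NULL
  reports <- list()
  for (i in seq_len(nrow(segs))) {
    seg <- slice_audio(filtered, segs$start_s[i], segs$end_s[i])
    env <- extract_envelope(seg, pp$downsample_factor)
    per <- estimate_period(env)
    acc <- accept_segment(as.numeric(per), pp$d1, pp$d2)
    seg_table <- rbind(seg_table,
                       data.frame(start_s = segs$start_s[i],
                                  end_s = segs$end_s[i],
                                  period_s = as.numeric(per),
                                  accepted = acc))
    if (!acc) next

    scfg <- do.call(sep_config, c(config$separation,
                                  list(seed = config$seed + i)))
    sep <- separate(seg, templates, scfg, template_audio = template_audio)

    lb <- config$labeling
    phases <- if (!is.null(models$bpdm)) {
      .pipeline_phases_nn(sep$audio_breath, models, lb)
    } else {
      label_breath_phases(sep$audio_breath, tau = lb$tau,
                          transition = transition_model(lb$p_stay_active),
                          frame_ms = lb$frame_ms,
                          min_phase_s = lb$min_phase_s,
                          min_pause_s = lb$min_pause_s)
    }

    beats <- segment_heartbeats(sep$audio_heart,
                                frame_ms = config$vitals$beat_frame_ms,
                                refractory_s = config$vitals$refractory_s)
    dur <- duration_s(seg)
    hr <- heart_rate(beats, dur, robust = TRUE)
    br <- breath_cycle_rate(phases)
    flags <- c(attr(hr, "quality"), attr(br, "quality"),
               if (!sep$converged) "nmf-not-converged")
    reports[[length(reports) + 1L]] <- vitals_report(
      hr_bpm = as.numeric(hr), br_bpm = as.numeric(br),
      breath_ratio = as.numeric(breath_ratio(phases)),
      segment = list(start_s = segs$start_s[i], end_s = segs$end_s[i],
                     midpoint_s = (segs$start_s[i] + segs$end_s[i]) / 2,
                     period_s = as.numeric(per)),
      flags = if (is.null(flags)) character(0) else flags)
  }
  structure(list(
    status = if (length(reports)) "ok" else "no-signal",
    reports = reports,
    segments = if (is.null(seg_table))
      data.frame(start_s = numeric(0), end_s = numeric(0),
                 period_s = numeric(0), accepted = logical(0)) else seg_table,
    config_hash = .config_hash(config),
    version = as.character(utils::packageVersion("earvitals"))),
    class = "pipeline_result")
}

# phase labeling through the trained models: BEM gates 1-s feature windows,
# BPDM labels the gated sequence per step
.pipeline_phases_nn <- function(breath_audio, models, lb) {
  feats <- featurize(breath_audio)
  ly <- attr(feats, "layout")
  T_model <- models$bpdm$input_dim[1]
  n <- nrow(feats)
  labels <- rep("PAUSE", n)
  for (s0 in seq(1L, n - T_model + 1L, by = T_model)) {
    chunk <- feats[s0:(s0 + T_model - 1L), , drop = FALSE]
    use <- TRUE
    if (!is.null(models$bem)) {
      pr <- bem_classify(models$bem, t(chunk))
      use <- colnames(pr)[which.max(pr[1, ])] != "NON_BREATH"
    }
    if (use) {
      tr <- bpdm_classify(models$bpdm, chunk, step_s = ly$hop_ms / 1000)
      labels[s0:(s0 + T_model - 1L)] <- tr$labels
    }
  }
  label_track(labels, ly$hop_ms / 1000)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %s, %d/%d segments accepted>\n", x$status,
              sum(x$segments$accepted), nrow(x$segments)))
  for (r in x$reports) print(r)
  invisible(x)
}

#' Write a pipeline result as a JSON report
#'
#' The report embeds the configuration hash and the package version for
#' provenance.
#'
#' @param result A [run_pipeline()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  obj <- list(status = result$status,
              reports = lapply(result$reports, unclass),
              segments = result$segments,
              config_hash = result$config_hash,
              version = result$version)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}
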