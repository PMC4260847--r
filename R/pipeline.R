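# End-to-end orchestration: files in, scored events and metrics out.

#' Run the full PLM detection pipeline on input files
#'
#' Reads the EDF, hypnogram and (optional) respiratory annotations, runs
#' the two-pass leg-movement detector, applies respiratory exclusion,
#' classifies PLM runs and computes subject metrics, then writes
#' `lm_events.csv`, `metrics.json`, `config.json` and `run_log.json` into
#' `out_dir`. On any stage error, partial outputs are removed and the error
#' is re-thrown.
#'
#' @param edf path to the EDF recording.
#' @param hypnogram path to the hypnogram CSV (`epoch_index,stage`).
#' @param resp_events optional path to the respiratory CSV
#'   (`onset_s,offset_s,type`).
#' @param out_dir output directory.
#' @param config a [plmad_config()] or path to a YAML/JSON config file.
#' @param leg_channels,ecg_channel EDF channel labels; auto-detected when
#'   `NULL`.
#' @return Invisibly, a list with `events`, `metrics`, `runs`, `log`.
#' @export
run_detection <- function(edf, hypnogram, resp_events = NULL,
                          out_dir = ".", config = plmad_config(),
                          leg_channels = NULL, ecg_channel = NULL) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cleanup <- function() {
    unlink(file.path(out_dir, c("lm_events.csv", "metrics.json",
                                "config.json", "run_log.json")))
  }
  tryCatch({
    cmap <- NULL
    if (!is.null(leg_channels)) {
      cmap <- stats::setNames(leg_channels,
                              paste0("leg_", seq_along(leg_channels)))
      if (!is.null(ecg_channel)) cmap <- c(cmap, ecg = ecg_channel)
    }
    rec <- read_recording(edf, channel_map = cmap)
    hyp <- read_hypnogram(hypnogram)
    resp <- if (is.null(resp_events)) NULL else read_resp_events(resp_events)

    det <- detect_lm(rec, hyp, config,
                     leg_channels = if (is.null(cmap)) NULL else
                       names(cmap)[startsWith(names(cmap), "leg_")],
                     ecg_channel = if (is.null(cmap)) NULL else
                       intersect("ecg", names(cmap)))
    events <- det$events
    if (!is.null(resp) && config$respiratory$mode != "off") {
      w <- config$respiratory$window
      events <- respiratory_exclude(
        events, resp,
        win = exclusion_windows(w[1], w[2], w[3], w[4]),
        mode = config$respiratory$mode,
        semantics = config$respiratory$semantics)
    }
    r_peaks <- NULL
    ch <- find_channels(rec,
                        ecg_channel = if (is.null(cmap)) NULL else
                          intersect("ecg", names(cmap)))
    if (length(ch$ecg) == 1L && !is.na(ch$ecg))
      r_peaks <- detect_r_peaks(rec$traces[[ch$ecg]])
    metrics <- compute_subject_metrics(events, hyp, rec$duration_s,
                                       r_peaks = r_peaks, config = config)
    events <- attr(metrics, "events")

    log <- c(det$log,
             list(n_resp_excluded = sum(has_flag(events$flags, "resp_excluded")),
                  n_retained_final = sum(events$retained),
                  n_plm_runs = length(attr(metrics, "runs"))))
    # stage-count conservation: every final row is retained or carries a
    # rejection flag
    rej <- has_flag(events$flags, "too_short") |
      has_flag(events$flags, "too_long") |
      has_flag(events$flags, "auc_rejected") |
      has_flag(events$flags, "resp_excluded")
    stopifnot(all(events$retained | rej))

    write_results(events, metrics, out_dir)
    write_config(config, file.path(out_dir, "config.json"))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(events = events, metrics = metrics,
                   runs = attr(metrics, "runs"), log = log))
  }, error = function(e) {
    cleanup()
    stop("run_detection failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Compute and write the respiratory-locked EMG profile
#'
#' @param edf,hypnogram,resp_events input paths as in [run_detection()].
#' @param out path of the output `profile.csv`.
#' @param anchor `"onset"` or `"offset"`.
#' @param leg_channels optional EDF channel labels for the leg EMG.
#' @return The profile data.frame, invisibly.
#' @export
run_resp_profile <- function(edf, hypnogram, resp_events,
                             out = "profile.csv", anchor = "offset",
                             leg_channels = NULL) {
  cmap <- if (is.null(leg_channels)) NULL else
    stats::setNames(leg_channels, paste0("leg_", seq_along(leg_channels)))
  rec <- read_recording(edf, channel_map = cmap)
  hyp <- read_hypnogram(hypnogram)
  resp <- read_resp_events(resp_events)
  ch <- find_channels(rec)
  legs <- rec$traces[ch$legs]
  leg <- if (length(legs) == 2L) merge_leg_channels(legs[[1]], legs[[2]])
  else legs[[1]]
  prof <- timelocked_emg_profile(leg, resp, hyp, anchor = anchor)
  utils::write.csv(prof, out, row.names = FALSE)
  invisible(prof)
}

#' Simulate a synthetic PSG to disk
#'
#' @param out_dir output directory.
#' @param spec a [synth_spec()], or path to a YAML/JSON file of
#'   `synth_spec` arguments.
#' @param seed overrides `spec$seed` when not `NULL`.
#' @return Paths written, invisibly.
#' @export
run_simulate <- function(out_dir, spec = synth_spec(), seed = NULL) {
  if (is.character(spec)) {
    ext <- tolower(tools::file_ext(spec))
    raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(spec)
    else jsonlite::read_json(spec, simplifyVector = TRUE)
    for (f in c("bursts", "trains", "resp_events", "baseline_uv"))
      if (!is.null(raw[[f]]) && !is.data.frame(raw[[f]]))
        raw[[f]] <- as.data.frame(raw[[f]])
    spec <- do.call(synth_spec, raw)
  }
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  write_synth_psg(synth_psg(spec), out_dir)
}
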