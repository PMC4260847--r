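#' Pipeline configuration with published defaults
#'
#' Every default equals the published scoring constant: thresholds 8/2 µV
#' with a 20-s noise window and 50-µV shutoff; detector timing rules
#' 0.15/0.05/0.1/0.75/2.0/10.0 s with a 0.5 AUC factor; respiratory
#' boundary windows 5.0/0.5/0.5/5.0 s; PLM rules IMI 5-90 s and run
#' length 4 or more; periodicity bounds 10-90 s with sequences of 3 or
#' more; heart-rate window
#' 10 cycles per side. Override any subset via `...` as nested lists, e.g.
#' `plmad_config(snr_plus = list(enabled = TRUE))`.
#'
#' @param ... named overrides merged over the defaults (one level deep).
#' @return A nested list of class `plmad_config`.
#' @export
plmad_config <- function(...) {
  cfg <- list(
    channels = list(merge_rule = "mean"),
    adaptive = list(mode = "ecg", n_weights = 5L, forgetting = 0.999,
                    init_delta = 100, self_ref_advance = 5L,
                    self_fallback = TRUE),
    thresholds = list(U_uv = 8, L_uv = 2, noise_window_s = 20,
                      shutoff_uv = 50, form = "log"),
    snr_plus = list(enabled = FALSE, gate_uv = 2),
    detector = list(rms_window_s = 0.15, fall_time_s = 0.05, bridge_s = 0.1,
                    min_dur_s = 0.75, merge_s = 2.0, max_dur_s = 10.0,
                    auc_factor = 0.5, auc_mode = "normalized"),
    respiratory = list(mode = "splmad",
                       window = c(5.0, 0.5, 0.5, 5.0),
                       semantics = "overlap"),
    plm = list(imi_min_s = 5, imi_max_s = 90, min_run = 4L,
               short_imi = "break"),
    periodicity = list(imi_min_s = 10, imi_max_s = 90, min_seq = 3L),
    hr = list(n_cycles = 10L)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("plmad_config: unknown section(s): ",
                        paste(bad, collapse = ", "))
  for (s in names(over)) {
    bad_keys <- setdiff(names(over[[s]]), names(cfg[[s]]))
    if (length(bad_keys)) stop("plmad_config: unknown key(s) in ", s, ": ",
                               paste(bad_keys, collapse = ", "))
    cfg[[s]] <- utils::modifyList(cfg[[s]], over[[s]])
  }
  structure(cfg, class = "plmad_config")
}

#' Load a configuration file
#'
#' YAML (if the `yaml` package is available) or JSON; keys are validated
#' against [plmad_config()] and merged over the defaults.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return A `plmad_config` list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("read_config: YAML config requires the 'yaml' package; use JSON")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(plmad_config, raw)
}

#' Write the effective configuration next to results
#'
#' @param config a `plmad_config`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
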