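# CSV readers/writers for hypnogram, respiratory events, and results.

#' Read a hypnogram CSV
#'
#' Expected columns: `epoch_index,stage` (0-based epoch index; any extra
#' columns are ignored). Rows are sorted by epoch index.
#'
#' @param path CSV file path.
#' @param epoch_len_s epoch length in seconds (default 30).
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_len_s = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(df)))
    stop("hypnogram CSV must have columns epoch_index,stage")
  df <- df[order(df$epoch_index), , drop = FALSE]
  hypnogram(df$stage, epoch_len_s = epoch_len_s)
}

#' Read a respiratory-event CSV
#'
#' Expected columns: `onset_s,offset_s,type`.
#'
#' @param path CSV file path.
#' @return A [resp_events()] table.
#' @export
read_resp_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "offset_s") %in% names(df)))
    stop("respiratory CSV must have columns onset_s,offset_s[,type]")
  if (is.null(df$type)) df$type <- "other"
  resp_events(df$onset_s, df$offset_s, df$type)
}

#' Write detection results
#'
#' Emits `lm_events.csv` (onset_s, offset_s, duration_s, state, flags,
#' run_id, retained) and `metrics.json` (keys exactly the
#' [subject_metrics()] fields). Output is bit-stable for fixed inputs.
#'
#' @param events an `lm_events` table.
#' @param metrics a [subject_metrics()] object (or `NULL` to skip).
#' @param out_dir output directory, created if needed.
#' @return Named character vector of files written, invisibly.
#' @export
write_results <- function(events, metrics, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ev_path <- file.path(out_dir, "lm_events.csv")
  cols <- c("onset_s", "offset_s", "duration_s", "peak_rms_uv",
            "auc_norm_uv", "state", "flags", "retained", "run_id")
  utils::write.csv(as.data.frame(events)[, cols], ev_path, row.names = FALSE)
  out <- c(lm_events = ev_path)
  if (!is.null(metrics)) {
    m_path <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(unclass(metrics), m_path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null",
                         pretty = TRUE)
    out <- c(out, metrics = m_path)
  }
  invisible(out)
}

#' Read back an `lm_events.csv` written by [write_results()]
#'
#' @param path CSV file path.
#' @return An `lm_events` table.
#' @export
read_lm_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(flags = "character",
                                       state = "character"))
  df$flags[is.na(df$flags)] <- ""
  lm_events(df$onset_s, df$offset_s, peak_rms_uv = df$peak_rms_uv,
            auc_norm_uv = df$auc_norm_uv, state = df$state,
            flags = df$flags, retained = df$retained, run_id = df$run_id)
}
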