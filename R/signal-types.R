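#' Construct a signal trace
#'
#' A `signal_trace` is a single sampled channel: amplitudes in microvolts
#' plus the sampling rate, a channel label, and the channel's offset from
#' recording start. All time coordinates in the package are seconds from
#' recording start, sample indexing is 0-based, and every event interval is
#' half-open `[onset, offset)`.
#'
#' @param samples numeric vector of amplitudes (µV); must be finite.
#' @param fs sampling rate in Hz, > 0.
#' @param label channel name.
#' @param start_time seconds offset from recording start (default 0).
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(samples, fs, label = "EMG", start_time = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal_trace: need at least one sample")
  if (!all(is.finite(samples))) stop("signal_trace: amplitudes must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("signal_trace: fs must be a single positive number")
  structure(
    list(samples = samples, fs = fs, label = as.character(label),
         start_time = as.numeric(start_time)),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %s: %d samples @ %g Hz (%.1f s)\n",
              x$label, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$samples)

trace_duration <- function(x) length(x$samples) / x$fs

#' Construct a recording
#'
#' A named collection of [signal_trace()] channels covering a common span.
#' Traces whose length differs by at most one sample from the nominal
#' duration are accepted (EDF records are written in whole seconds).
#'
#' @param traces named list of `signal_trace` objects.
#' @param duration_s total recording duration in seconds; defaults to the
#'   longest trace duration.
#' @param meta free-form named list of metadata.
#' @return An object of class `recording`.
#' @export
recording <- function(traces, duration_s = NULL, meta = list()) {
  if (!is.list(traces) || length(traces) == 0L || is.null(names(traces)) ||
      any(!nzchar(names(traces))))
    stop("recording: traces must be a non-empty named list")
  ok <- vapply(traces, inherits, logical(1), "signal_trace")
  if (!all(ok)) stop("recording: every trace must be a signal_trace")
  durs <- vapply(traces, trace_duration, numeric(1))
  if (is.null(duration_s)) duration_s <- max(durs)
  if (duration_s <= 0) stop("recording: duration_s must be > 0")
  structure(list(traces = traces, duration_s = duration_s, meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %.1f s, %d channel(s): %s\n", x$duration_s,
              length(x$traces), paste(names(x$traces), collapse = ", ")))
  invisible(x)
}

# Internal stage vocabulary. R&K S1-S4 plus REM and wake; AASM N1-N3 map
# onto S1-S3 (N3 -> S3).
.stage_levels <- c("W", "S1", "S2", "S3", "S4", "R", "UNSCORED")

normalize_stage <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  map <- c("W" = "W", "WAKE" = "W", "0" = "W",
           "S1" = "S1", "N1" = "S1", "1" = "S1",
           "S2" = "S2", "N2" = "S2", "2" = "S2",
           "S3" = "S3", "N3" = "S3", "3" = "S3",
           "S4" = "S4", "4" = "S4",
           "R" = "R", "REM" = "R", "5" = "R",
           "UNSCORED" = "UNSCORED", "U" = "UNSCORED", "?" = "UNSCORED")
  out <- unname(map[s])
  if (any(is.na(out)))
    stop("unknown sleep stage token(s): ",
         paste(unique(s[is.na(out)]), collapse = ", "))
  out
}

#' Construct a hypnogram
#'
#' @param stages character vector of stage tokens, one per epoch. R&K
#'   (`S1`..`S4`) and AASM (`N1`..`N3`) vocabularies are both accepted and
#'   mapped to the internal set `W, S1, S2, S3, S4, R, UNSCORED`.
#' @param epoch_len_s epoch length in seconds (default 30).
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_len_s = 30) {
  if (epoch_len_s <= 0) stop("hypnogram: epoch_len_s must be > 0")
  stages <- normalize_stage(stages)
  structure(list(epoch_len_s = as.numeric(epoch_len_s), stages = stages),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %g s (%.2f h); stages: %s\n",
              length(x$stages), x$epoch_len_s,
              length(x$stages) * x$epoch_len_s / 3600,
              paste(names(table(x$stages)), collapse = ", ")))
  invisible(x)
}

hypnogram_span_s <- function(h) length(h$stages) * h$epoch_len_s

#' Sleep stage at a set of time points
#'
#' @param h a [hypnogram()].
#' @param t_s numeric vector of times (seconds from recording start).
#' @return character vector of stages; times beyond the scored span return
#'   `"UNSCORED"`.
#' @export
stage_at <- function(h, t_s) {
  idx <- floor(t_s / h$epoch_len_s) + 1L
  out <- rep("UNSCORED", length(t_s))
  ok <- idx >= 1L & idx <= length(h$stages)
  out[ok] <- h$stages[idx[ok]]
  out
}

is_sleep_stage <- function(stage) stage %in% c("S1", "S2", "S3", "S4", "R")

#' Construct a respiratory event table
#'
#' @param onset_s,offset_s event boundaries in seconds (`onset < offset`).
#' @param type event types; one of `apnea`, `hypopnea`, `other`.
#' @return A `data.frame` with class `resp_events`.
#' @export
resp_events <- function(onset_s = numeric(), offset_s = numeric(),
                        type = rep("other", length(onset_s))) {
  onset_s <- as.numeric(onset_s); offset_s <- as.numeric(offset_s)
  if (length(onset_s) != length(offset_s))
    stop("resp_events: onset/offset length mismatch")
  if (any(onset_s < 0) || any(onset_s >= offset_s))
    stop("resp_events: require 0 <= onset_s < offset_s")
  type <- as.character(type)
  bad <- setdiff(unique(type), c("apnea", "hypopnea", "other"))
  if (length(bad)) stop("resp_events: unknown type(s): ",
                        paste(bad, collapse = ", "))
  df <- data.frame(onset_s = onset_s, offset_s = offset_s, type = type,
                   stringsAsFactors = FALSE)
  df <- df[order(df$onset_s, df$offset_s), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1L && any(df$onset_s[-1L] < df$offset_s[-nrow(df)]))
    warning("resp_events: overlapping respiratory events kept as-is")
  class(df) <- c("resp_events", "data.frame")
  df
}

# Canonical empty LM-event table. Events are rows; `flags` is a
# semicolon-joined string over {bridged, merged, too_short, too_long,
# auc_rejected, resp_excluded, detector_off}; `retained` marks events that
# survived every screen.
lm_events <- function(onset_s = numeric(), offset_s = numeric(),
                      peak_rms_uv = rep(NA_real_, length(onset_s)),
                      auc_norm_uv = rep(NA_real_, length(onset_s)),
                      state = rep(NA_character_, length(onset_s)),
                      flags = rep("", length(onset_s)),
                      retained = rep(TRUE, length(onset_s)),
                      run_id = rep(NA_integer_, length(onset_s))) {
  if (any(onset_s >= offset_s)) stop("lm_events: require onset_s < offset_s")
  df <- data.frame(onset_s = as.numeric(onset_s),
                   offset_s = as.numeric(offset_s),
                   duration_s = as.numeric(offset_s) - as.numeric(onset_s),
                   peak_rms_uv = as.numeric(peak_rms_uv),
                   auc_norm_uv = as.numeric(auc_norm_uv),
                   state = as.character(state),
                   flags = as.character(flags),
                   retained = as.logical(retained),
                   run_id = as.integer(run_id),
                   stringsAsFactors = FALSE)
  class(df) <- c("lm_events", "data.frame")
  df
}

add_flag <- function(flags, flag, where = TRUE) {
  ifelse(where & nzchar(flags), paste(flags, flag, sep = ";"),
         ifelse(where, flag, flags))
}

has_flag <- function(flags, flag) {
  vapply(strsplit(flags, ";", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}

#' Subject-level PLM metrics container
#'
#' Undefined quantities (e.g. a night ratio when one half of the night has
#' zero events, or heart-rate measures without ECG) are `NA`, never 0.
#'
#' @param ... named metric values; see field list below.
#' @return An object of class `subject_metrics`: a named list with fields
#'   `plms_per_h`, `plmw_per_h`, `lm_count`, `plm_count`,
#'   `periodicity_sleep`, `periodicity_wake`, `night_ratio_plm`,
#'   `night_ratio_lm`, `hr_delta_mean`, `hr_slope_mean`, `hours_sleep`,
#'   `hours_wake`, `reliable`.
#' @export
subject_metrics <- function(...) {
  fields <- c("plms_per_h", "plmw_per_h", "lm_count", "plm_count",
              "periodicity_sleep", "periodicity_wake",
              "night_ratio_plm", "night_ratio_lm",
              "hr_delta_mean", "hr_slope_mean",
              "hours_sleep", "hours_wake", "reliable")
  x <- list(...)
  bad <- setdiff(names(x), fields)
  if (length(bad)) stop("subject_metrics: unknown field(s): ",
                        paste(bad, collapse = ", "))
  out <- stats::setNames(vector("list", length(fields)), fields)
  out[fields] <- NA
  out[names(x)] <- x
  for (f in c("lm_count", "plm_count"))
    if (!is.na(out[[f]]) && out[[f]] < 0) stop("subject_metrics: negative count")
  structure(out, class = "subject_metrics")
}

#' @export
print.subject_metrics <- function(x, ...) {
  cat("<subject_metrics>\n")
  for (f in names(x)) cat(sprintf("  %-18s %s\n", f, format(x[[f]])))
  invisible(x)
}
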