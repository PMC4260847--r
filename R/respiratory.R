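# Respiratory-event exclusion windows and the time-locked EMG profile that
# motivates them. Leg activity clusters around respiratory event boundaries
# (several seconds before onset and after offset), so movements there are
# respiratory phenomena, not periodic leg movements; movements deep inside
# an event are kept.

#' Respiratory exclusion windows
#'
#' Defaults: exclude LMs from 5.0 s before until 0.5 s after a respiratory
#' event's onset, and from 0.5 s before until 5.0 s after its offset. The
#' AASM-2007-style rule (entire event ± 0.5 s) is available via
#' [aasm2007_windows()] / `respiratory.mode = "aasm2007"`.
#'
#' @param pre_onset_s,post_onset_s,pre_offset_s,post_offset_s window widths
#'   in seconds (all >= 0).
#' @return An object of class `exclusion_windows`.
#' @export
exclusion_windows <- function(pre_onset_s = 5.0, post_onset_s = 0.5,
                              pre_offset_s = 0.5, post_offset_s = 5.0) {
  v <- c(pre_onset_s, post_onset_s, pre_offset_s, post_offset_s)
  if (any(v < 0)) stop("exclusion_windows: widths must be >= 0")
  structure(list(pre_onset_s = pre_onset_s, post_onset_s = post_onset_s,
                 pre_offset_s = pre_offset_s, post_offset_s = post_offset_s),
            class = "exclusion_windows")
}

#' @rdname exclusion_windows
#' @export
aasm2007_windows <- function() {
  exclusion_windows(0.5, 0.5, 0.5, 0.5)
}

#' Flag leg movements inside respiratory exclusion windows
#'
#' An LM is flagged `resp_excluded` (and `retained` set `FALSE`) iff its
#' half-open interval overlaps `[onset - pre_onset, onset + post_onset)` or
#' `[offset - pre_offset, offset + post_offset)` of any respiratory event.
#' Under the AASM-2007-style windows the whole event span ± 0.5 s excludes;
#' under the default windows, LMs strictly inside an event but away from
#' its boundaries are kept. With `semantics = "onset"` only the LM onset
#' (not any overlap) must fall inside a window.
#'
#' @param lms an `lm_events` table (sorted by onset).
#' @param resp a [resp_events()] table.
#' @param win an [exclusion_windows()].
#' @param mode `"splmad"` (boundary windows, default), `"aasm2007"` (whole
#'   event ± 0.5 s), or `"off"`.
#' @param semantics `"overlap"` (default) or `"onset"`.
#' @return `lms` with `resp_excluded` flags applied.
#' @export
respiratory_exclude <- function(lms, resp, win = exclusion_windows(),
                                mode = c("splmad", "aasm2007", "off"),
                                semantics = c("overlap", "onset")) {
  mode <- match.arg(mode)
  semantics <- match.arg(semantics)
  if (mode == "off" || is.null(resp) || nrow(resp) == 0L || nrow(lms) == 0L)
    return(lms)
  if (mode == "aasm2007") win <- aasm2007_windows()
  windows <- if (mode == "aasm2007") {
    # one window spanning the whole event plus the margins
    cbind(resp$onset_s - win$pre_onset_s, resp$offset_s + win$post_offset_s)
  } else {
    rbind(cbind(resp$onset_s - win$pre_onset_s,
                resp$onset_s + win$post_onset_s),
          cbind(resp$offset_s - win$pre_offset_s,
                resp$offset_s + win$post_offset_s))
  }
  excl <- vapply(seq_len(nrow(lms)), function(i) {
    if (semantics == "overlap") {
      any(lms$onset_s[i] < windows[, 2] & lms$offset_s[i] > windows[, 1])
    } else {
      any(lms$onset_s[i] >= windows[, 1] & lms$onset_s[i] < windows[, 2])
    }
  }, logical(1))
  lms$flags <- add_flag(lms$flags, "resp_excluded", where = excl)
  lms$retained <- lms$retained & !excl
  lms
}

#' Time-locked leg-EMG profile around respiratory events
#'
#' For each qualifying respiratory event, the rectified leg EMG is averaged
#' in 0.5-s bins spanning 30 s before to 30 s after the chosen anchor
#' (onset or offset): 120 bins. Events are dropped when they end in (or are
#' immediately followed by) wake, last under 15 s, or lie within 30 s of
#' another respiratory event. The profile aggregates per-event bin means
#' with mean and median across events, which keeps events with noisy EMG
#' from dominating the pooled estimate.
#'
#' @param x leg-EMG [signal_trace()] (rectified internally).
#' @param resp a [resp_events()] table.
#' @param hyp a [hypnogram()]; used for the wake filter.
#' @param anchor `"onset"` or `"offset"`.
#' @param span_s half-width of the profile (default 30 s).
#' @param bin_s bin width (default 0.5 s).
#' @param min_event_s minimum event duration (default 15 s).
#' @param isolation_s minimum distance to another event (default 30 s).
#' @return data.frame with `bin_center_s`, `mean_uv`, `median_uv`,
#'   `n_events` (constant column); zero qualifying events give a 0-row
#'   frame with `n_events = 0` attribute.
#' @export
timelocked_emg_profile <- function(x, resp, hyp,
                                   anchor = c("onset", "offset"),
                                   span_s = 30, bin_s = 0.5,
                                   min_event_s = 15, isolation_s = 30) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(x, "signal_trace"), inherits(hyp, "hypnogram"))
  r <- abs(x$samples); fs <- x$fs; n <- length(r)
  n_bins <- as.integer(round(2 * span_s / bin_s))

  keep <- rep(TRUE, nrow(resp))
  dur <- resp$offset_s - resp$onset_s
  keep[dur < min_event_s] <- FALSE
  # isolation: distance between event spans, both directions
  if (nrow(resp) > 1L) {
    for (i in seq_len(nrow(resp))) {
      others <- setdiff(seq_len(nrow(resp)), i)
      gap <- pmax(resp$onset_s[i] - resp$offset_s[others],
                  resp$onset_s[others] - resp$offset_s[i])
      if (any(gap < isolation_s)) keep[i] <- FALSE
    }
  }
  # ends in / immediately followed by wake: the epoch containing the event
  # offset, or the next epoch, is stage W
  off_ep <- stage_at(hyp, resp$offset_s)
  next_ep <- stage_at(hyp, resp$offset_s + hyp$epoch_len_s)
  keep[off_ep == "W" | next_ep == "W"] <- FALSE

  qual <- which(keep)
  centers <- seq(-span_s + bin_s / 2, span_s - bin_s / 2, by = bin_s)
  if (length(qual) == 0L) {
    out <- data.frame(bin_center_s = centers, mean_uv = NA_real_,
                      median_uv = NA_real_, n_events = 0L)
    return(out)
  }
  per_event <- matrix(NA_real_, nrow = length(qual), ncol = n_bins)
  for (k in seq_along(qual)) {
    a <- if (anchor == "onset") resp$onset_s[qual[k]] else resp$offset_s[qual[k]]
    for (b in seq_len(n_bins)) {
      t0 <- a - span_s + (b - 1L) * bin_s
      idx <- interval_sample_range(t0, t0 + bin_s, fs, n)
      if (length(idx)) per_event[k, b] <- mean(r[idx])
    }
  }
  data.frame(bin_center_s = centers,
             mean_uv = colMeans(per_event, na.rm = TRUE),
             median_uv = apply(per_event, 2, stats::median, na.rm = TRUE),
             n_events = length(qual))
}
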