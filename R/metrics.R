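# PLM run classification and subject-level indices.

#' Group leg movements into periodic (PLM) runs
#'
#' A PLM run is a maximal sequence of four or more consecutive retained LMs
#' whose successive onset-to-onset inter-movement intervals (IMIs) all lie
#' in `[imi_min, imi_max]` seconds. Runs may span sleep-wake transitions.
#' In the default `short_imi = "break"` mode an out-of-range IMI terminates
#' the run at the offending movement (which may anchor a new run); with
#' `"ignore"`, a movement arriving less than `imi_min` after the previous
#' counted movement is skipped and does not break the run.
#'
#' @param lms an `lm_events` table, sorted by onset; only `retained` rows
#'   are considered (respiratory-excluded events are already off).
#' @param imi_min_s,imi_max_s IMI bounds in seconds (defaults 5 and 90).
#' @param min_run minimum run length (default 4).
#' @param short_imi `"break"` or `"ignore"`.
#' @return List of runs; each run is a list with `lm_idx` (row indices into
#'   `lms`), `onsets_s`, and `imis_s`.
#' @export
find_plm_runs <- function(lms, imi_min_s = 5, imi_max_s = 90, min_run = 4L,
                          short_imi = c("break", "ignore")) {
  short_imi <- match.arg(short_imi)
  idx <- which(if (is.null(lms$retained)) rep(TRUE, nrow(lms)) else lms$retained)
  onsets <- lms$onset_s[idx]
  runs <- list()
  if (length(onsets) == 0L) return(runs)
  cur <- 1L  # positions into `idx`
  flush <- function(cur) {
    if (length(cur) >= min_run) {
      runs[[length(runs) + 1L]] <<- list(
        lm_idx = idx[cur], onsets_s = onsets[cur],
        imis_s = diff(onsets[cur]))
    }
  }
  for (j in seq_along(onsets)[-1L]) {
    imi <- onsets[j] - onsets[cur[length(cur)]]
    if (imi >= imi_min_s && imi <= imi_max_s) {
      cur <- c(cur, j)
    } else if (imi < imi_min_s && short_imi == "ignore") {
      next  # intervening movement ignored; run continues
    } else {
      flush(cur)
      cur <- j
    }
  }
  flush(cur)
  runs
}

#' Assign run ids back onto the event table
#'
#' @param lms an `lm_events` table.
#' @param runs output of [find_plm_runs()].
#' @return `lms` with `run_id` filled for run members.
#' @export
assign_run_ids <- function(lms, runs) {
  lms$run_id <- NA_integer_
  for (k in seq_along(runs)) lms$run_id[runs[[k]]$lm_idx] <- k
  lms
}

#' PLM and LM indices per hour of sleep and wake
#'
#' PLMS/h is the number of run-member movements whose onset epoch is a
#' sleep stage, divided by total sleep time in hours; PLMW/h likewise for
#' wake. `lm_count` counts all retained movements (periodic or not) after
#' respiratory exclusion; `plm_count` counts run members.
#'
#' @param runs output of [find_plm_runs()].
#' @param lms the `lm_events` table the runs index into.
#' @param hyp a [hypnogram()].
#' @return List with `plms_per_h`, `plmw_per_h`, `lm_count`, `plm_count`,
#'   `hours_sleep`, `hours_wake`. Indices are `NA` when the corresponding
#'   denominator is zero.
#' @export
plm_indices <- function(runs, lms, hyp) {
  hrs <- hyp$epoch_len_s / 3600
  hours_sleep <- sum(is_sleep_stage(hyp$stages)) * hrs
  hours_wake <- sum(hyp$stages == "W") * hrs
  member <- unique(unlist(lapply(runs, `[[`, "lm_idx")))
  member_state <- stage_at(hyp, lms$onset_s[member])
  n_s <- sum(is_sleep_stage(member_state))
  n_w <- sum(member_state == "W")
  list(plms_per_h = if (hours_sleep > 0) n_s / hours_sleep else NA_real_,
       plmw_per_h = if (hours_wake > 0) n_w / hours_wake else NA_real_,
       lm_count = if (is.null(lms$retained)) nrow(lms) else sum(lms$retained),
       plm_count = length(member),
       hours_sleep = hours_sleep, hours_wake = hours_wake)
}

#' Periodicity index
#'
#' The fraction of inter-movement intervals that (a) lie in
#' `[imi_min, imi_max)` seconds and (b) belong to a sequence of at least
#' `min_seq` consecutive such intervals, over the total number of IMIs.
#' Distinguishes periodic movement (index near 1) from scattered movement
#' (index near 0). Undefined (`NA`) with fewer than two movements.
#'
#' @param lms an `lm_events` table (retained rows are used).
#' @param hyp optional [hypnogram()]; with `state_filter` restricts the
#'   movements by the stage at their onset before forming IMIs.
#' @param state_filter `"all"`, `"sleep"` or `"wake"`.
#' @param imi_min_s,imi_max_s qualifying IMI bounds (defaults 10 and 90 s;
#'   the interval is closed-open).
#' @param min_seq minimum length of a qualifying sequence (default 3).
#' @return A value in `[0, 1]`, or `NA`.
#' @export
periodicity_index <- function(lms, hyp = NULL,
                              state_filter = c("all", "sleep", "wake"),
                              imi_min_s = 10, imi_max_s = 90, min_seq = 3L) {
  state_filter <- match.arg(state_filter)
  keep <- if (is.null(lms$retained)) rep(TRUE, nrow(lms)) else lms$retained
  onsets <- lms$onset_s[keep]
  if (state_filter != "all") {
    if (is.null(hyp)) stop("periodicity_index: hypnogram needed for state filter")
    st <- stage_at(hyp, onsets)
    onsets <- onsets[if (state_filter == "sleep") is_sleep_stage(st) else st == "W"]
  }
  if (length(onsets) < 2L) return(NA_real_)
  imis <- diff(sort(onsets))
  qual <- imis >= imi_min_s & imis < imi_max_s
  r <- rle(qual)
  good <- sum(r$lengths[r$values & r$lengths >= min_seq])
  good / length(imis)
}

#' Night ratio of event counts
#'
#' Number of events with onset in the first half of the study divided by
#' the number in the second half. Undefined (`NA`, not 0 or Inf) when
#' either half has zero events.
#'
#' @param onsets_s event onset times (seconds from study start).
#' @param study_span_s total study span in seconds.
#' @return A positive ratio or `NA`.
#' @export
night_ratio <- function(onsets_s, study_span_s) {
  if (study_span_s <= 0) stop("night_ratio: study_span_s must be > 0")
  mid <- study_span_s / 2
  n1 <- sum(onsets_s < mid)
  n2 <- sum(onsets_s >= mid)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  n1 / n2
}

#' Compute the full subject-level metric set
#'
#' @param lms an `lm_events` table after respiratory exclusion.
#' @param hyp a [hypnogram()].
#' @param study_span_s total study span (seconds).
#' @param r_peaks optional R-peak times from [detect_r_peaks()] for the
#'   PLM-locked heart-rate measures.
#' @param config a [plmad_config()].
#' @return A [subject_metrics()] object, plus runs as attribute `"runs"`.
#' @export
compute_subject_metrics <- function(lms, hyp, study_span_s, r_peaks = NULL,
                                    config = plmad_config()) {
  pc <- config$plm
  runs <- find_plm_runs(lms, pc$imi_min_s, pc$imi_max_s, pc$min_run,
                        pc$short_imi)
  lms <- assign_run_ids(lms, runs)
  idx <- plm_indices(runs, lms, hyp)
  member <- which(!is.na(lms$run_id))
  plm_onsets <- lms$onset_s[member]
  retained_onsets <- lms$onset_s[lms$retained]

  hr_delta <- hr_slope <- NA_real_
  if (!is.null(r_peaks) && length(r_peaks) > 1L && length(plm_onsets)) {
    resp <- lapply(plm_onsets, function(t0)
      hr_response(r_peaks, t0, n_cycles = config$hr$n_cycles))
    ok <- !vapply(resp, is.null, logical(1))
    if (any(ok)) {
      hr_delta <- mean(vapply(resp[ok], `[[`, numeric(1), "delta"))
      hr_slope <- mean(vapply(resp[ok], `[[`, numeric(1), "slope"))
    }
  }
  m <- subject_metrics(
    plms_per_h = idx$plms_per_h, plmw_per_h = idx$plmw_per_h,
    lm_count = idx$lm_count, plm_count = idx$plm_count,
    periodicity_sleep = periodicity_index(lms, hyp, "sleep",
      config$periodicity$imi_min_s, config$periodicity$imi_max_s,
      config$periodicity$min_seq),
    periodicity_wake = periodicity_index(lms, hyp, "wake",
      config$periodicity$imi_min_s, config$periodicity$imi_max_s,
      config$periodicity$min_seq),
    night_ratio_plm = night_ratio(plm_onsets, study_span_s),
    night_ratio_lm = night_ratio(retained_onsets, study_span_s),
    hr_delta_mean = hr_delta, hr_slope_mean = hr_slope,
    hours_sleep = idx$hours_sleep, hours_wake = idx$hours_wake,
    reliable = study_span_s >= 2 * 3600)
  attr(m, "runs") <- runs
  attr(m, "events") <- lms
  m
}
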