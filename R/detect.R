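# Candidate leg-movement detection: RMS envelope -> three-threshold state
# machine -> bridging/duration/merge rules -> AUC screen, run as a two-pass
# pipeline (the first pass only feeds the noise-floor substitution).

# 1-based sample indices covered by the half-open interval [onset, offset)
# seconds at sampling rate fs, clamped to 1..n.
interval_sample_range <- function(onset_s, offset_s, fs, n) {
  i0 <- as.integer(ceiling(onset_s * fs - 1e-9)) + 1L
  i1 <- as.integer(ceiling(offset_s * fs - 1e-9))
  i0 <- max(1L, i0); i1 <- min(n, i1)
  if (i1 < i0) integer() else i0:i1
}

#' Detector timing and screening rules
#'
#' Defaults are the published scoring constants: a 0.15-s RMS smoothing
#' window; a 0.05-s fall time below the lower threshold to close a
#' candidate; gaps of at most 0.1 s bridged; candidates shorter than 0.75 s
#' rejected (0.5-s AASM minimum plus 0.25 s of filter stretching); surviving
#' movements within 2.0 s merged; movements longer than 10.0 s rejected;
#' and candidates whose time-normalized AUC falls below half the upper
#' threshold rejected as fragmentary myoclonus.
#'
#' @param rms_window_s,fall_time_s,bridge_s,min_dur_s,merge_s,max_dur_s,auc_factor
#'   rule values in seconds (and a unitless AUC factor); see description.
#' @return An object of class `detector_rules`.
#' @export
detector_rules <- function(rms_window_s = 0.15, fall_time_s = 0.05,
                           bridge_s = 0.1, min_dur_s = 0.75, merge_s = 2.0,
                           max_dur_s = 10.0, auc_factor = 0.5) {
  vals <- c(rms_window_s, fall_time_s, bridge_s, min_dur_s, merge_s,
            max_dur_s, auc_factor)
  if (any(vals <= 0)) stop("detector_rules: all rule values must be positive")
  if (min_dur_s >= max_dur_s) stop("detector_rules: min_dur_s < max_dur_s required")
  structure(list(rms_window_s = rms_window_s, fall_time_s = fall_time_s,
                 bridge_s = bridge_s, min_dur_s = min_dur_s,
                 merge_s = merge_s, max_dur_s = max_dur_s,
                 auc_factor = auc_factor),
            class = "detector_rules")
}

#' Moving RMS envelope
#'
#' y(n) = sqrt of the centered moving mean of x² over a `window_s` window
#' (same shrinking-edge convention as [noise_floor()]).
#'
#' @param x a [signal_trace()] or numeric vector.
#' @param window_s RMS window in seconds (default 0.15).
#' @param fs sampling rate, required for bare vectors.
#' @return Numeric vector of per-sample RMS values (µV, >= 0).
#' @export
rms_envelope <- function(x, window_s = 0.15, fs = NULL) {
  if (inherits(x, "signal_trace")) { fs <- x$fs; x <- x$samples }
  if (is.null(fs)) stop("rms_envelope: fs required for bare vectors")
  w <- max(1L, round(window_s * fs))
  sqrt(pmax(moving_mean(x^2, w), 0))
}

#' Detect candidate leg movements with the three-threshold state machine
#'
#' A candidate opens at the first sample where the envelope strictly
#' exceeds α(n) while the detector is enabled, and closes once the envelope
#' has stayed strictly below β(n) for `fall_time_s`; its offset is one
#' sample past the last point at or above the falloff threshold ψ(n) before
#' that drop. Candidates still open at end of signal or at a noise shutoff
#' are closed at their last ψ-crossing and flagged.
#'
#' @param y per-sample RMS envelope (µV).
#' @param profile a [vat_thresholds()] profile of the same length.
#' @param rules a [detector_rules()].
#' @param fs sampling rate (Hz).
#' @return data.frame with `onset_s`, `offset_s`, `flags` (half-open
#'   intervals in seconds, sorted, non-overlapping).
#' @export
detect_candidates <- function(y, profile, rules = detector_rules(), fs) {
  stopifnot(inherits(profile, "vat_profile"))
  fall <- max(1L, round(rules$fall_time_s * fs))
  m <- detect_candidates_core(y, profile$alpha, profile$beta, profile$psi,
                              profile$enabled, fall)
  flags <- c("", "open_ended", "detector_off")[m[, "flag"] + 1L]
  data.frame(onset_s = m[, "onset"] / fs, offset_s = m[, "offset"] / fs,
             flags = flags, stringsAsFactors = FALSE)
}

# Merge sorted half-open intervals whose gap is <= gap_s; joined rows get
# `flag` appended. df needs onset_s/offset_s/flags.
merge_gaps <- function(df, gap_s, flag) {
  if (nrow(df) <= 1L) return(df)
  out <- df[1L, , drop = FALSE]
  for (i in 2L:nrow(df)) {
    j <- nrow(out)
    if (df$onset_s[i] - out$offset_s[j] <= gap_s) {
      out$offset_s[j] <- max(out$offset_s[j], df$offset_s[i])
      joined <- unique(unlist(strsplit(c(out$flags[j], df$flags[i], flag),
                                       ";", fixed = TRUE)))
      out$flags[j] <- paste(joined[nzchar(joined)], collapse = ";")
    } else {
      out <- rbind(out, df[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Bridge, duration-filter and merge candidate intervals
#'
#' Applies, in exactly this order: (1) bridge gaps <= `bridge_s`;
#' (2) reject durations < `min_dur_s` (flag `too_short`); (3) merge
#' surviving movements with gaps <= `merge_s`; (4) reject durations
#' above `max_dur_s` (flag `too_long`). Rejected intervals are retained as
#' audit rows with `retained = FALSE`.
#'
#' @param intervals data.frame with `onset_s`, `offset_s` and optional
#'   `flags`, sorted and non-overlapping.
#' @param rules a [detector_rules()].
#' @return data.frame with `onset_s`, `offset_s`, `flags`, `retained`,
#'   sorted by onset.
#' @export
bridge_and_filter <- function(intervals, rules = detector_rules()) {
  df <- as.data.frame(intervals)
  if (is.null(df$flags)) df$flags <- rep("", nrow(df))
  df <- df[order(df$onset_s), c("onset_s", "offset_s", "flags"), drop = FALSE]
  # (1) bridge
  df <- merge_gaps(df, rules$bridge_s, "bridged")
  # (2) minimum duration
  dur <- df$offset_s - df$onset_s
  short <- dur < rules$min_dur_s
  rejected <- df[short, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$flags <- add_flag(rejected$flags, "too_short")
    rejected$retained <- FALSE
  }
  kept <- df[!short, , drop = FALSE]
  # (3) merge
  kept <- merge_gaps(kept, rules$merge_s, "merged")
  # (4) maximum duration
  if (nrow(kept)) {
    kept$retained <- TRUE
    long <- (kept$offset_s - kept$onset_s) > rules$max_dur_s
    kept$flags[long] <- add_flag(kept$flags[long], "too_long")
    kept$retained[long] <- FALSE
  }
  out <- rbind(kept, rejected)
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' AUC screen against fragmentary myoclonus
#'
#' True leg movements hold their amplitude near the detection threshold for
#' their whole duration; sub-200-ms myoclonic spikes do not. Each candidate
#' is scored by the trapezoidal integral of the rectified cleaned signal
#' over its interval, time-normalized to a mean amplitude in µV, and kept
#' iff that is at least `auc_factor` times the mean upper threshold α over
#' the interval. With `mode = "invert"` the rejected (myoclonus) candidates
#' are returned as the kept set instead. `mode = "raw"` compares the raw
#' area in µV·s instead of the normalized mean.
#'
#' @param x_clean cleaned leg-EMG [signal_trace()].
#' @param intervals data.frame with `onset_s`, `offset_s`, optional `flags`
#'   and `retained` (only retained rows are screened).
#' @param profile second-pass [vat_thresholds()] profile.
#' @param rules a [detector_rules()].
#' @param mode `"normalized"` (default), `"raw"`, or `"invert"`.
#' @return `intervals` with `auc_norm_uv` filled and failing rows flagged
#'   `auc_rejected` / `retained = FALSE`.
#' @export
auc_screen <- function(x_clean, intervals, profile, rules = detector_rules(),
                       mode = c("normalized", "raw", "invert")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x_clean, "signal_trace"))
  df <- as.data.frame(intervals)
  if (is.null(df$flags)) df$flags <- rep("", nrow(df))
  if (is.null(df$retained)) df$retained <- rep(TRUE, nrow(df))
  df$auc_norm_uv <- rep(NA_real_, nrow(df))
  if (nrow(df) == 0L) return(df)
  r <- abs(x_clean$samples); fs <- x_clean$fs; n <- length(r)
  for (i in seq_len(nrow(df))) {
    if (!df$retained[i]) next
    idx <- interval_sample_range(df$onset_s[i], df$offset_s[i], fs, n)
    if (length(idx) < 2L)
      stop("auc_screen: zero-length interval at ", df$onset_s[i], " s")
    seg <- r[idx]
    area <- sum((seg[-1] + seg[-length(seg)]) / 2) / fs    # µV·s
    dur <- (length(idx) - 1L) / fs
    norm <- area / dur
    df$auc_norm_uv[i] <- norm
    thr <- rules$auc_factor * mean(profile$alpha[idx])
    stat <- if (mode == "raw") area else norm
    pass <- stat >= thr
    if (mode == "invert") pass <- !pass
    if (!pass) {
      df$flags[i] <- add_flag(df$flags[i], "auc_rejected")
      df$retained[i] <- FALSE
    }
  }
  df
}

# Resolve leg / ECG channel names in a recording.
find_channels <- function(rec, leg_channels = NULL, ecg_channel = NULL) {
  nm <- names(rec$traces)
  if (is.null(leg_channels)) {
    leg_channels <- nm[grepl("^(leg|lat|rat|tib)", nm, ignore.case = TRUE)]
    if (length(leg_channels) == 0L)
      stop("detect_lm: no leg channel found among: ",
           paste(nm, collapse = ", "))
    leg_channels <- leg_channels[seq_len(min(2L, length(leg_channels)))]
  }
  if (is.null(ecg_channel) || length(ecg_channel) == 0L) {
    hit <- nm[grepl("^(ecg|ekg)", nm, ignore.case = TRUE)]
    ecg_channel <- if (is.null(ecg_channel) && length(hit)) hit[1L]
    else NA_character_
  }
  list(legs = leg_channels, ecg = ecg_channel)
}

#' Run the full two-pass leg-movement detector
#'
#' Orchestration: merge leg channels, adaptively cancel cardiac
#' interference (ECG-reference when an ECG channel is present, optional
#' self-reference otherwise), first-pass noise floor and thresholds,
#' optional SNR+ boost, RMS envelope, first-pass candidates and
#' bridge/duration rules, β/2 substitution, second-pass noise floor and
#' thresholds, second-pass candidates, bridge/duration rules, AUC screen,
#' and hypnogram stage labelling. Deterministic for fixed input and config.
#'
#' @param rec a [recording()] holding one or two leg-EMG channels and
#'   optionally an ECG channel.
#' @param hyp a [hypnogram()] covering the recording.
#' @param config a [plmad_config()] list.
#' @param leg_channels,ecg_channel trace names; auto-detected by prefix
#'   (`leg`/`lat`/`rat`, `ecg`) when `NULL`.
#' @return A list of class `lm_detection`: `events` (an `lm_events` table
#'   including rejected audit rows), `clean` (cleaned trace), `envelope`,
#'   `profile` (second-pass `vat_profile`), `log` (per-stage counts).
#' @export
detect_lm <- function(rec, hyp, config = plmad_config(),
                      leg_channels = NULL, ecg_channel = NULL) {
  stopifnot(inherits(rec, "recording"), inherits(hyp, "hypnogram"))
  rules <- do.call(detector_rules, config$detector[names(config$detector) %in%
                     names(formals(detector_rules))])
  ch <- find_channels(rec, leg_channels, ecg_channel)
  if (rec$duration_s < 2 * 3600)
    warning("recording shorter than 2 h; subject metrics will be flagged unreliable")

  # 1. merge legs
  legs <- rec$traces[ch$legs]
  leg <- if (length(legs) == 2L) {
    merge_leg_channels(legs[[1L]], legs[[2L]], rule = config$channels$merge_rule)
  } else legs[[1L]]
  fs <- leg$fs

  # 2. adaptive cancellation
  mode <- config$adaptive$mode
  cfg <- rls_config(config$adaptive$n_weights, config$adaptive$forgetting,
                    config$adaptive$init_delta, config$adaptive$self_ref_advance)
  clean <- if (mode == "off") {
    leg
  } else if (mode == "ecg" && !is.na(ch$ecg)) {
    ref <- rec$traces[[ch$ecg]]
    if (ref$fs != fs) ref <- resample_trace(ref, fs)
    if (length(ref$samples) != length(leg$samples)) {
      nmin <- min(length(ref$samples), length(leg$samples))
      ref$samples <- ref$samples[seq_len(nmin)]
      leg$samples <- leg$samples[seq_len(nmin)]
    }
    rls_cancel(leg, ref, cfg)
  } else if (mode == "self" ||
             (mode == "ecg" && is.na(ch$ecg) && config$adaptive$self_fallback)) {
    self_reference_cancel(leg, cfg)
  } else leg

  # 3. first-pass noise floor + thresholds
  thr <- config$thresholds
  eta1 <- noise_floor(clean, window_s = thr$noise_window_s)
  prof1 <- vat_thresholds(eta1, U = thr$U_uv, L = thr$L_uv,
                          shutoff_uv = thr$shutoff_uv)

  # 4. optional SNR+ (gated on the first-pass noise floor)
  boosted <- if (isTRUE(config$snr_plus$enabled)) {
    apply_snr_plus(clean, eta1, gate_uv = config$snr_plus$gate_uv)
  } else clean

  # 5. RMS envelope
  y <- rms_envelope(boosted, window_s = rules$rms_window_s)

  # 6-7. first pass: candidates through duration rules, then substitution
  cand1 <- detect_candidates(y, prof1, rules, fs)
  pass1 <- bridge_and_filter(cand1, rules)
  pass1_kept <- pass1[pass1$retained, , drop = FALSE]
  sub <- second_pass_signal(clean, pass1_kept, prof1)
  eta2 <- noise_floor(sub, window_s = thr$noise_window_s)
  prof2 <- vat_thresholds(eta2, U = thr$U_uv, L = thr$L_uv,
                          shutoff_uv = thr$shutoff_uv)

  # 8. second pass: candidates, duration rules, AUC screen
  cand2 <- detect_candidates(y, prof2, rules, fs)
  pass2 <- bridge_and_filter(cand2, rules)
  # the screen sees the same signal the thresholds saw (boosted when SNR+ on)
  screened <- auc_screen(boosted, pass2, prof2, rules,
                         mode = config$detector$auc_mode)

  n <- length(y)
  peak <- vapply(seq_len(nrow(screened)), function(i) {
    idx <- interval_sample_range(screened$onset_s[i], screened$offset_s[i], fs, n)
    if (length(idx)) max(y[idx]) else NA_real_
  }, numeric(1))
  events <- lm_events(screened$onset_s, screened$offset_s,
                      peak_rms_uv = peak,
                      auc_norm_uv = screened$auc_norm_uv,
                      state = stage_at(hyp, screened$onset_s),
                      flags = screened$flags,
                      retained = screened$retained)
  log <- list(n_candidates_pass1 = nrow(cand1),
              n_pass1_kept = nrow(pass1_kept),
              n_candidates_pass2 = nrow(cand2),
              n_too_short = sum(has_flag(events$flags, "too_short")),
              n_too_long = sum(has_flag(events$flags, "too_long")),
              n_auc_rejected = sum(has_flag(events$flags, "auc_rejected")),
              n_retained = sum(events$retained))
  structure(list(events = events, clean = clean, envelope = y,
                 profile = prof2, log = log, fs = fs),
            class = "lm_detection")
}
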