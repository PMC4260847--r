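# Seeded synthetic polysomnogram generator. Produces leg EMG (baseline
# noise with slow drift, leg-movement bursts with periodic structure,
# fragmentary-myoclonus spikes, ECG leakage), an ECG channel, a plausible
# hypnogram, respiratory events with time-locked leg activity, and exact
# ground-truth labels for every planted structure. The generator targets
# detector mechanics, not physiological realism.

#' Specification for a synthetic polysomnogram
#'
#' @param duration_h recording length in hours (default 8, a full night).
#' @param fs_hz leg-EMG/ECG sampling rate (default 100 Hz).
#' @param baseline_uv baseline noise sigma in µV: a scalar, or a data.frame
#'   `time_s,sigma_uv` stepping the sigma schedule (default 2 µV, a clean
#'   surface-EMG baseline).
#' @param drift_frac,drift_period_s slow sinusoidal modulation of the noise
#'   sigma (default ±10% over 30 min), emulating electrode drift.
#' @param bursts data.frame `onset_s,duration_s,amplitude_uv` of isolated
#'   leg-movement bursts (amplitude = target RMS of the burst core).
#' @param trains data.frame `start_s,count,imi_s,duration_s,amplitude_uv,
#'   jitter_s` of periodic movement trains (onset-to-onset interval
#'   `imi_s`, uniform jitter ±`jitter_s`).
#' @param myoclonus_rate_per_h rate of fragmentary-myoclonus spikes
#'   (< 200 ms transients, default 0).
#' @param myoclonus_amp_uv spike amplitude (default 30 µV).
#' @param ecg list `hr_bpm`, `amplitude_uv` (R-peak height in the ECG
#'   channel), `leak` (fraction of the ECG channel added to the leg EMG),
#'   `rr_jitter_s`; `NULL` for no ECG channel.
#' @param resp_events data.frame `onset_s,offset_s,type`, or `NULL`.
#' @param resp_coupling list `lag_s,duration_s,amplitude_uv`: a leg burst
#'   planted at every respiratory offset + `lag_s`; `NULL` to disable.
#' @param burst_band_hz frequency band of burst noise (default 20-45 Hz,
#'   straddling the SNR+ crossover).
#' @param hypnogram_stages explicit stage vector, or `NULL` for a plausible
#'   generated night (wake onset, 90-min NREM/REM cycles, brief arousals).
#' @param seed integer seed fixing every random draw.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(duration_h = 8, fs_hz = 100, baseline_uv = 2,
                       drift_frac = 0.1, drift_period_s = 1800,
                       bursts = NULL, trains = NULL,
                       myoclonus_rate_per_h = 0, myoclonus_amp_uv = 30,
                       ecg = list(hr_bpm = 60, amplitude_uv = 30,
                                  leak = 0.5, rr_jitter_s = 0.01),
                       resp_events = NULL, resp_coupling = NULL,
                       burst_band_hz = c(20, 45),
                       hypnogram_stages = NULL, seed = 1L) {
  if (duration_h <= 0 || fs_hz <= 0) stop("synth_spec: positive sizes required")
  structure(as.list(environment()), class = "synth_spec")
}

# band-limited unit-RMS noise of length n (uses the current RNG stream)
.band_noise <- function(n, fs, band) {
  if (n < 4L) return(stats::rnorm(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  X[f < band[1] | f > band[2]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- sqrt(mean(y^2))
  if (s == 0) y else y / s
}

# trapezoidal (Tukey-like) envelope with 10% ramps
.burst_envelope <- function(n) {
  ramp <- max(1L, round(0.1 * n))
  e <- rep(1, n)
  up <- seq_len(ramp) / ramp
  e[seq_len(ramp)] <- up
  e[(n - ramp + 1L):n] <- rev(up)
  e
}

.qrs_template <- function(fs) {
  t <- seq(-0.3, 0.45, by = 1 / fs)
  g <- function(a, mu, s) a * exp(-(t - mu)^2 / (2 * s^2))
  w <- g(0.1, -0.18, 0.03) + g(-0.15, -0.03, 0.01) + g(1, 0, 0.012) +
    g(-0.2, 0.035, 0.012) + g(0.25, 0.25, 0.05)
  list(t = t, w = w / max(w))
}

.default_hypnogram <- function(n_epochs) {
  # 20 min wake, then 90-min cycles: S1 S2 S3 S2 R with short wake breaks
  cyc <- c(rep("S1", 4), rep("S2", 40), rep("S3", 40), rep("S2", 40),
           rep("R", 30), rep("W", 6), rep("S2", 20))
  stages <- c(rep("W", 40), rep(cyc, length.out = max(0, n_epochs - 40)))
  stages[seq_len(n_epochs)]
}

#' Generate a synthetic polysomnogram with ground truth
#'
#' Deterministic for a fixed `spec$seed`: the RNG state is saved, seeded,
#' and restored. Planted bursts that overlap are merged in the ground
#' truth (with a warning).
#'
#' @param spec a [synth_spec()].
#' @return A list of class `synth_psg`: `recording` (leg EMG + optional
#'   ECG), `hypnogram`, `resp` ([resp_events()]), and `truth` -- a list
#'   with `lm_intervals` (data.frame `onset_s,offset_s,amplitude_uv,source,
#'   train_id`), `myoclonus_times_s`, `r_peak_times_s`, `sigma_uv`
#'   (per-sample noise sigma), and `spec`.
#' @export
synth_psg <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)

  fs <- spec$fs_hz
  dur_s <- round(spec$duration_h * 3600)
  n <- as.integer(dur_s * fs)
  t <- (seq_len(n) - 1) / fs

  # --- baseline noise with slow drift
  sigma <- if (is.data.frame(spec$baseline_uv)) {
    sf <- stats::stepfun(spec$baseline_uv$time_s[-1L],
                         spec$baseline_uv$sigma_uv)
    sf(t)
  } else rep(spec$baseline_uv, n)
  if (spec$drift_frac > 0)
    sigma <- sigma * (1 + spec$drift_frac *
                        sin(2 * pi * t / spec$drift_period_s))
  emg <- stats::rnorm(n) * sigma

  # --- leg-movement bursts (isolated + periodic trains)
  events <- data.frame(onset_s = numeric(), duration_s = numeric(),
                       amplitude_uv = numeric(), source = character(),
                       train_id = integer())
  if (!is.null(spec$bursts) && nrow(spec$bursts)) {
    b <- spec$bursts
    events <- rbind(events, data.frame(
      onset_s = b$onset_s, duration_s = b$duration_s,
      amplitude_uv = b$amplitude_uv, source = "burst",
      train_id = NA_integer_))
  }
  if (!is.null(spec$trains) && nrow(spec$trains)) {
    for (k in seq_len(nrow(spec$trains))) {
      tr <- spec$trains[k, ]
      jit <- if (is.null(tr$jitter_s) || is.na(tr$jitter_s)) 0 else tr$jitter_s
      onsets <- tr$start_s + (seq_len(tr$count) - 1) * tr$imi_s +
        stats::runif(tr$count, -jit, jit)
      events <- rbind(events, data.frame(
        onset_s = onsets, duration_s = tr$duration_s,
        amplitude_uv = tr$amplitude_uv, source = "train", train_id = k))
    }
  }
  resp <- if (is.null(spec$resp_events)) {
    resp_events()
  } else {
    resp_events(spec$resp_events$onset_s, spec$resp_events$offset_s,
                if (is.null(spec$resp_events$type)) "apnea"
                else spec$resp_events$type)
  }
  if (!is.null(spec$resp_coupling) && nrow(resp)) {
    rc <- spec$resp_coupling
    events <- rbind(events, data.frame(
      onset_s = resp$offset_s + rc$lag_s, duration_s = rc$duration_s,
      amplitude_uv = rc$amplitude_uv, source = "resp_coupled",
      train_id = NA_integer_))
  }
  if (nrow(events)) {
    events <- events[order(events$onset_s), , drop = FALSE]
    events <- events[events$onset_s >= 0 &
                       events$onset_s + events$duration_s <= dur_s, ,
                     drop = FALSE]
    rownames(events) <- NULL
    off <- events$onset_s + events$duration_s
    if (nrow(events) > 1L && any(events$onset_s[-1L] < off[-length(off)]))
      warning("synth_psg: overlapping planted bursts; ground truth merges them")
    for (i in seq_len(nrow(events))) {
      idx <- interval_sample_range(events$onset_s[i], off[i], fs, n)
      m <- length(idx)
      if (m < 4L) next
      emg[idx] <- emg[idx] + events$amplitude_uv[i] *
        .band_noise(m, fs, spec$burst_band_hz) * .burst_envelope(m)
    }
  }

  # --- fragmentary myoclonus: < 200 ms transients
  myo_times <- numeric()
  if (spec$myoclonus_rate_per_h > 0) {
    n_myo <- stats::rpois(1, spec$myoclonus_rate_per_h * spec$duration_h)
    myo_times <- sort(stats::runif(n_myo, 1, dur_s - 1))
    for (tm in myo_times) {
      w <- stats::runif(1, 0.05, 0.15)
      idx <- interval_sample_range(tm, tm + w, fs, n)
      m <- length(idx)
      if (m < 2L) next
      emg[idx] <- emg[idx] + spec$myoclonus_amp_uv *
        .band_noise(m, fs, c(25, 49)) * sin(pi * seq_len(m) / (m + 1))
    }
  }

  # --- ECG channel and leakage into the EMG
  traces <- list()
  r_peaks <- numeric()
  if (!is.null(spec$ecg)) {
    e <- spec$ecg
    rr <- 60 / e$hr_bpm
    n_beats <- ceiling(dur_s / rr) + 1L
    jit <- if (is.null(e$rr_jitter_s)) 0 else e$rr_jitter_s
    beat_t <- cumsum(c(0.5, rr + stats::rnorm(n_beats - 1L, 0, jit)))
    beat_t <- beat_t[beat_t < dur_s - 0.5]
    tmpl <- .qrs_template(fs)
    ecg_sig <- numeric(n)
    half <- length(tmpl$w)
    for (bt in beat_t) {
      i0 <- as.integer(round((bt + tmpl$t[1]) * fs)) + 1L
      sel <- i0:(i0 + half - 1L)
      ok <- sel >= 1L & sel <= n
      ecg_sig[sel[ok]] <- ecg_sig[sel[ok]] + e$amplitude_uv * tmpl$w[ok]
    }
    r_peaks <- beat_t
    emg <- emg + e$leak * ecg_sig
    traces$ecg <- signal_trace(ecg_sig, fs = fs, label = "ECG")
  }
  traces <- c(list(leg = signal_trace(emg, fs = fs, label = "LEG")), traces)
  rec <- recording(traces, duration_s = dur_s,
                   meta = list(synthetic = TRUE, seed = spec$seed))

  stages <- if (is.null(spec$hypnogram_stages)) {
    .default_hypnogram(as.integer(ceiling(dur_s / 30)))
  } else spec$hypnogram_stages
  hyp <- hypnogram(stages)

  truth <- list(
    lm_intervals = if (nrow(events)) {
      data.frame(onset_s = events$onset_s,
                 offset_s = events$onset_s + events$duration_s,
                 amplitude_uv = events$amplitude_uv,
                 source = events$source, train_id = events$train_id)
    } else data.frame(onset_s = numeric(), offset_s = numeric(),
                      amplitude_uv = numeric(), source = character(),
                      train_id = integer()),
    myoclonus_times_s = myo_times,
    r_peak_times_s = r_peaks,
    sigma_uv = sigma,
    spec = spec)
  structure(list(recording = rec, hypnogram = hyp, resp = resp,
                 truth = truth),
            class = "synth_psg")
}

#' Write a synthetic PSG to disk
#'
#' Emits `psg.edf`, `hypnogram.csv`, `resp_events.csv` and
#' `ground_truth.json` into `out_dir`.
#'
#' @param psg a [synth_psg()] result.
#' @param out_dir output directory (created if needed).
#' @return Named vector of paths, invisibly.
#' @export
write_synth_psg <- function(psg, out_dir) {
  stopifnot(inherits(psg, "synth_psg"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  edf <- file.path(out_dir, "psg.edf")
  write_edf(psg$recording, edf)
  hyp_path <- file.path(out_dir, "hypnogram.csv")
  utils::write.csv(data.frame(
    epoch_index = seq_along(psg$hypnogram$stages) - 1L,
    stage = psg$hypnogram$stages), hyp_path, row.names = FALSE)
  resp_path <- file.path(out_dir, "resp_events.csv")
  utils::write.csv(as.data.frame(psg$resp)[, c("onset_s", "offset_s", "type")],
                   resp_path, row.names = FALSE)
  gt_path <- file.path(out_dir, "ground_truth.json")
  gt <- psg$truth
  gt$sigma_uv <- NULL                       # per-sample; too large for JSON
  gt$spec <- gt$spec[setdiff(names(gt$spec),
                             c("bursts", "trains", "resp_events",
                               "hypnogram_stages", "baseline_uv"))]
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(c(edf = edf, hypnogram = hyp_path, resp = resp_path,
              ground_truth = gt_path))
}
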