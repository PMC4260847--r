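# Independent oracles and fixture builders used across the test files.

# Brute-force windowed mean: O(N*W), same centered/shrinking convention as
# the production moving average but computed sample-by-sample.
oracle_moving_mean <- function(x, w) {
  n <- length(x)
  h1 <- w %/% 2L
  h2 <- as.integer(ceiling(w / 2)) - 1L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h1); hi <- min(n, i + h2)
    mean(x[lo:hi])
  }, numeric(1))
}

# Per-onset rescanning simulator of the three-threshold state machine.
# Finds candidate onsets by direct search, then walks forward sample by
# sample tracking the last psi-crossing and the run below beta. Returns a
# matrix of 1-based (onset, last_psi, flag) rows.
oracle_candidates <- function(y, alpha, beta, psi, enabled, fall) {
  n <- length(y)
  onset_ok <- which(enabled & y > alpha)
  out <- matrix(integer(), ncol = 3)
  t <- 1L
  repeat {
    cand <- onset_ok[onset_ok >= t]
    if (length(cand) == 0L) break
    onset <- cand[1L]
    last_psi <- onset; below <- 0L; closed <- FALSE
    j <- onset + 1L
    while (j <= n) {
      if (!enabled[j]) { out <- rbind(out, c(onset, last_psi, 2L)); closed <- TRUE; break }
      if (y[j] >= psi[j]) last_psi <- j
      if (y[j] < beta[j]) {
        below <- below + 1L
        if (below >= fall) { out <- rbind(out, c(onset, last_psi, 0L)); closed <- TRUE; break }
      } else below <- 0L
      j <- j + 1L
    }
    if (!closed) { out <- rbind(out, c(onset, last_psi, 1L)); break }
    t <- j + 1L
  }
  out
}

# Exhaustive maximal-window search for PLM runs: for every start index the
# longest stretch of consecutive qualifying IMIs is taken; windows that are
# not left-maximal are discarded. Equivalent to enumerating all windows.
oracle_plm_runs <- function(onsets, imi_min = 5, imi_max = 90, min_run = 4L) {
  n <- length(onsets)
  if (n < min_run) return(list())
  ok <- diff(onsets) >= imi_min & diff(onsets) <= imi_max
  len <- integer(n - 1L)
  if (n >= 2L) {
    len[n - 1L] <- as.integer(ok[n - 1L])
    if (n >= 3L) for (i in (n - 2L):1L)
      len[i] <- if (ok[i]) len[i + 1L] + 1L else 0L
  }
  runs <- list()
  for (i in seq_len(n - 1L)) {
    if (len[i] == 0L) next
    if (i > 1L && ok[i - 1L]) next        # not left-maximal
    members <- i:(i + len[i])
    if (length(members) >= min_run)
      runs[[length(runs) + 1L]] <- members
  }
  runs
}

# Random envelope with burst-like structure: smoothed positive noise plus
# occasional rectangular elevations, exercising onsets, psi-dips and
# fall-time runs.
random_envelope <- function(n, fs = 100) {
  base <- abs(stats::filter(rnorm(n, sd = 2), rep(1 / 5, 5), sides = 2))
  base[is.na(base)] <- 0
  n_bursts <- rpois(1, n / fs / 20)
  if (n_bursts > 0) {
    for (k in seq_len(n_bursts)) {
      w <- sample(round(c(0.2, 0.5, 1, 2, 4) * fs), 1)
      i0 <- sample(n - w, 1)
      base[i0:(i0 + w - 1L)] <- base[i0:(i0 + w - 1L)] + runif(1, 5, 30)
    }
  }
  base
}

# QRS-like smooth wavelet train (amplitude 1) for self-reference tests.
spike_train <- function(n, fs, period_s = 1, width_s = 0.08) {
  t <- (seq_len(n) - 1) / fs
  phase <- (t %% period_s)
  d <- pmin(phase, period_s - phase)
  exp(-d^2 / (2 * (width_s / 2.355)^2))
}

# Standard quiet-night fixture: periodic trains plus isolated bursts on a
# 2 µV baseline with ECG leakage; ground truth from the generator.
quiet_fixture <- function(duration_h = 0.5, seed = 42, amplitude_uv = 30,
                          with_ecg = TRUE, snr_bursts = FALSE) {
  dur_s <- duration_h * 3600
  trains <- data.frame(start_s = 300, count = 8, imi_s = 30,
                       duration_s = 1.5, amplitude_uv = amplitude_uv,
                       jitter_s = 1)
  bursts <- data.frame(onset_s = c(120, dur_s - 200), duration_s = 2,
                       amplitude_uv = amplitude_uv)
  synth_psg(synth_spec(
    duration_h = duration_h, seed = seed, trains = trains, bursts = bursts,
    ecg = if (with_ecg) list(hr_bpm = 60, amplitude_uv = 30, leak = 0.5,
                             rr_jitter_s = 0.01) else NULL))
}
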