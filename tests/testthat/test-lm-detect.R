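fs <- 100

static_profile <- function(n, alpha = 8) {
  p <- vat_thresholds(rep(0, n))
  stopifnot(p$alpha[1] == alpha)
  p
}

test_that("RMS envelope of constants and sinusoids", {
  expect_equal(rms_envelope(signal_trace(rep(-3, 1000), fs)), rep(3, 1000))
  expect_equal(rms_envelope(signal_trace(rep(0, 1000), fs)), rep(0, 1000))
  t <- (0:9999) / fs
  y <- rms_envelope(signal_trace(sin(2 * pi * 20 * t), fs))
  mid <- 1000:9000
  expect_equal(mean(y[mid]), 1 / sqrt(2), tolerance = 0.01)
})

test_that("candidate state machine on hand-traced envelopes", {
  n <- fs * 10
  # never exceeds alpha
  y <- rep(4, n)
  expect_equal(nrow(detect_candidates(y, static_profile(n), fs = fs)), 0)
  # 12 µV plateau on [5, 7) s with alpha=8, beta=2, psi=5
  y <- numeric(n); y[501:700] <- 12
  cand <- detect_candidates(y, static_profile(n), fs = fs)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$onset_s, 5.00)
  expect_equal(cand$offset_s, 7.00)
  expect_equal(cand$flags, "")
  # exceeds alpha but never falls below beta: closed at end, flagged
  y <- rep(12, n)
  cand <- detect_candidates(y, static_profile(n), fs = fs)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$onset_s, 0)
  expect_equal(cand$offset_s, n / fs)
  expect_equal(cand$flags, "open_ended")
  # dips below beta for less than the 0.05 s fall time do not close
  y <- numeric(n); y[101:300] <- 12; y[301:303] <- 0; y[304:500] <- 12
  cand <- detect_candidates(y, static_profile(n), fs = fs)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$offset_s, 5.00)
})

test_that("state machine equals the brute-force simulator on random envelopes", {
  set.seed(20)
  for (rep_i in 1:20) {
    n <- 10000
    y <- random_envelope(n, fs)
    eta <- noise_floor(y, fs = fs)
    prof <- vat_thresholds(eta)
    got <- detect_candidates(y, prof, fs = fs)
    want <- oracle_candidates(y, prof$alpha, prof$beta, prof$psi,
                              prof$enabled, fall = 5L)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$onset_s, (want[, 1] - 1) / fs)
      expect_equal(got$offset_s, want[, 2] / fs)
    }
  }
})

test_that("bridge/reject/merge/reject applies in exactly that order", {
  rules <- detector_rules()
  # bridged within 0.1 s, combined duration acceptable
  out <- bridge_and_filter(data.frame(onset_s = c(0, 0.68),
                                      offset_s = c(0.6, 1.3)), rules)
  expect_equal(nrow(out), 1)
  expect_equal(out$onset_s, 0)
  expect_equal(out$offset_s, 1.3)
  expect_true(out$retained)
  expect_true(has_flag(out$flags, "bridged"))
  # isolated short candidate rejected
  out <- bridge_and_filter(data.frame(onset_s = 0, offset_s = 0.5), rules)
  expect_false(out$retained)
  expect_true(has_flag(out$flags, "too_short"))
  # merge-then-reject: [0,6) + [7.5,13) merges (gap 1.5) then dies (>10 s)
  out <- bridge_and_filter(data.frame(onset_s = c(0, 7.5),
                                      offset_s = c(6, 13)), rules)
  expect_equal(nrow(out), 1)
  expect_equal(out$offset_s, 13)
  expect_false(out$retained)
  expect_true(has_flag(out$flags, "merged"))
  expect_true(has_flag(out$flags, "too_long"))
  # order sensitivity: two short candidates 1.5 s apart are NOT bridged
  # (gap > 0.1), die individually, and so never reach the merge step
  out <- bridge_and_filter(data.frame(onset_s = c(0, 2.0),
                                      offset_s = c(0.5, 2.5)), rules)
  expect_equal(nrow(out), 2)
  expect_false(any(out$retained))
})

test_that("bridge_and_filter is idempotent on its retained output", {
  set.seed(21)
  onsets <- sort(runif(40, 0, 600))
  ints <- data.frame(onset_s = onsets,
                     offset_s = onsets + runif(40, 0.1, 6))
  ints <- ints[c(TRUE, diff(ints$onset_s) > 6), ]     # keep sorted, disjoint
  once <- bridge_and_filter(ints, detector_rules())
  kept <- once[once$retained, c("onset_s", "offset_s", "flags")]
  twice <- bridge_and_filter(kept, detector_rules())
  expect_equal(twice[twice$retained, c("onset_s", "offset_s")],
               kept[, c("onset_s", "offset_s")], ignore_attr = TRUE)
})

test_that("AUC screen keeps stable movements and rejects myoclonic spikes", {
  n <- fs * 10
  prof <- static_profile(n)
  # constant 10 µV across [2, 4) s: normalized AUC 10 >= 4 -> kept
  x <- signal_trace(rep(10, n), fs)
  out <- auc_screen(x, data.frame(onset_s = 2, offset_s = 4), prof)
  expect_true(out$retained)
  expect_equal(out$auc_norm_uv, 10)
  # 0.8 s candidate with a 0.05 s 20 µV spike: normalized AUC ~1.25 -> rejected
  xs <- numeric(n); xs[301:305] <- 20
  out <- auc_screen(signal_trace(xs, fs),
                    data.frame(onset_s = 3, offset_s = 3.8), prof)
  expect_false(out$retained)
  expect_true(has_flag(out$flags, "auc_rejected"))
  expect_lt(out$auc_norm_uv, 4)
  # inverted mode keeps the myoclonus candidates instead
  out <- auc_screen(signal_trace(xs, fs),
                    data.frame(onset_s = 3, offset_s = 3.8), prof,
                    mode = "invert")
  expect_true(out$retained)
  # empty list passes through
  expect_equal(nrow(auc_screen(x, data.frame(onset_s = numeric(),
                                             offset_s = numeric()), prof)), 0)
})

test_that("detect_lm recovers planted bursts with small onset error", {
  psg <- quiet_fixture(duration_h = 0.5, seed = 30)
  det <- suppressWarnings(detect_lm(psg$recording, psg$hypnogram))
  ev <- det$events[det$events$retained, ]
  gt <- psg$truth$lm_intervals
  hits <- vapply(seq_len(nrow(gt)), function(i)
    any(abs(ev$onset_s - gt$onset_s[i]) <= 0.25), logical(1))
  expect_true(all(hits))
  expect_true(all(ev$duration_s >= 0.75 & ev$duration_s <= 10))
  expect_true(all(ev$state %in% c("W", "S1", "S2", "S3", "S4", "R")))
})

test_that("all-zero and shutoff-noise recordings yield no detections", {
  n <- fs * 1800
  rec <- recording(list(leg = signal_trace(numeric(n) , fs, "LEG")))
  hyp <- hypnogram(rep("S2", 60))
  det <- suppressWarnings(detect_lm(rec, hyp,
                                    plmad_config(adaptive = list(mode = "off"))))
  expect_equal(nrow(det$events), 0)
  # noise ramped above the 50 µV shutoff in the middle third
  sched <- data.frame(time_s = c(0, 600, 1200), sigma_uv = c(2, 70, 2))
  psg <- synth_psg(synth_spec(duration_h = 0.5, seed = 31,
    baseline_uv = sched, drift_frac = 0,
    bursts = data.frame(onset_s = c(100, 300, 700, 900, 1400, 1700),
                        duration_s = 1.5, amplitude_uv = 30),
    ecg = NULL))
  det <- suppressWarnings(detect_lm(psg$recording, psg$hypnogram))
  ev <- det$events[det$events$retained, ]
  mid <- ev$onset_s >= 630 & ev$onset_s < 1170
  expect_equal(sum(mid), 0)
  expect_gte(sum(ev$onset_s < 600), 2)          # outer thirds still detected
  expect_gte(sum(ev$onset_s >= 1200), 2)
})
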