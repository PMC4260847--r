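lm_at <- function(onsets) lm_events(onsets, onsets + 1)

test_that("PLM run rules on constructed onset sets", {
  runs <- find_plm_runs(lm_at(c(0, 30, 60, 90, 120)))
  expect_length(runs, 1)
  expect_length(runs[[1]]$lm_idx, 5)
  expect_equal(runs[[1]]$imis_s, rep(30, 4))
  expect_length(find_plm_runs(lm_at(c(0, 30, 60))), 0)   # 3 < 4
  # short IMI breaks at the offending movement, which anchors a new run
  runs <- find_plm_runs(lm_at(c(0, 3, 30, 60, 90, 120)))
  expect_length(runs, 1)
  expect_equal(runs[[1]]$onsets_s, c(3, 30, 60, 90, 120))
  # ignore mode skips the intervening movement instead
  runs <- find_plm_runs(lm_at(c(0, 3, 30, 60, 90)), short_imi = "ignore")
  expect_length(runs, 1)
  expect_equal(runs[[1]]$onsets_s, c(0, 30, 60, 90))
})

test_that("find_plm_runs agrees with exhaustive maximal-window search", {
  set.seed(50)
  for (i in 1:200) {
    n <- sample(2:200, 1)
    gaps <- sample(c(runif(n, 5, 90), runif(n, 0.5, 4.9),
                     runif(n, 91, 200)), n - 1)
    onsets <- cumsum(c(0, gaps))
    got <- lapply(find_plm_runs(lm_at(onsets)), `[[`, "lm_idx")
    want <- oracle_plm_runs(onsets)
    expect_equal(got, want)
  }
})

test_that("PLM indices split run members by stage at onset", {
  # 6 h of sleep after 1 h wake; 60 run-member LMs in sleep
  hyp <- hypnogram(c(rep("W", 120), rep("S2", 720)))
  onsets <- 3600 + seq(0, by = 30, length.out = 60)
  lms <- lm_at(onsets)
  runs <- find_plm_runs(lms)
  idx <- plm_indices(runs, lms, hyp)
  expect_equal(idx$plms_per_h, 60 / 6)
  expect_equal(idx$plmw_per_h, 0)
  expect_equal(idx$plm_count, 60)
  expect_equal(idx$lm_count, 60)
  # run straddling a wake epoch: 4 sleep + 1 wake member
  hyp2 <- hypnogram(c(rep("S2", 4), "W", rep("S2", 115)))
  onsets2 <- c(20, 50, 80, 110, 140)           # 5th onset in the W epoch
  lms2 <- lm_at(onsets2)
  runs2 <- find_plm_runs(lms2)
  expect_length(runs2, 1)                       # wake does not break the run
  idx2 <- plm_indices(runs2, lms2, hyp2)
  expect_equal(idx2$plms_per_h * idx2$hours_sleep, 4)
  expect_equal(idx2$plmw_per_h * idx2$hours_wake, 1)
  # no runs at all
  idx3 <- plm_indices(list(), lm_at(c(0, 200)), hyp)
  expect_equal(idx3$plms_per_h, 0)
  expect_equal(idx3$lm_count, 2)
})

test_that("periodicity index on constructed IMI sequences", {
  expect_equal(periodicity_index(lm_at(seq(0, by = 30, length.out = 10))), 1)
  alt <- cumsum(c(0, rep(c(30, 200), 5)))
  expect_equal(periodicity_index(lm_at(alt)), 0)
  expect_true(is.na(periodicity_index(lm_at(100))))
  # 3 qualifying in a row out of 5 IMIs -> 3/5
  onsets <- cumsum(c(0, 30, 30, 30, 200, 5))
  expect_equal(periodicity_index(lm_at(onsets)), 3 / 5)
  # bounds are closed-open: IMI of exactly 90 s does not qualify
  expect_equal(periodicity_index(lm_at(seq(0, by = 90, length.out = 6))), 0)
})

test_that("night ratio handles zero halves as undefined", {
  expect_equal(night_ratio(c(rep(1, 10), rep(9000, 5)), 14400), 2)
  expect_true(is.na(night_ratio(rep(9000, 5), 14400)))
  expect_true(is.na(night_ratio(numeric(), 14400)))
  expect_equal(night_ratio(c(rep(10, 7), rep(9000, 7)), 14400), 1)
})

test_that("R-peak detection recovers rate, skipped beats, and flat traces", {
  fs <- 256
  psg <- synth_psg(synth_spec(duration_h = 60 / 3600, fs_hz = fs, seed = 51,
                              ecg = list(hr_bpm = 60, amplitude_uv = 100,
                                         leak = 0, rr_jitter_s = 0)))
  pk <- detect_r_peaks(psg$recording$traces$ecg)
  truth <- psg$truth$r_peak_times_s
  expect_lte(abs(length(pk) - length(truth)), 1)
  rr <- diff(pk)
  expect_true(all(abs(rr - 1) < 0.02))
  # skipped beat leaves one ~2 s RR interval
  ecg <- psg$recording$traces$ecg
  skip <- truth[20]
  idx <- round((skip - 0.35) * fs):round((skip + 0.5) * fs)
  ecg$samples[idx] <- 0
  pk2 <- detect_r_peaks(ecg)
  expect_equal(sum(diff(pk2) > 1.5), 1)
  expect_warning(out <- detect_r_peaks(signal_trace(rep(0, fs * 10), fs)),
                 "flat")
  expect_length(out, 0)
})

test_that("heart-rate delta and slope reproduce direct arithmetic", {
  # constant 60 bpm: delta = slope = 0, baseline normalized to 0
  pk <- seq(0, 40, by = 1)
  hr <- hr_response(pk, plm_onset_s = 20.5)
  expect_equal(hr$delta, 0)
  expect_equal(hr$slope, 0)
  expect_equal(hr$pre_hr[10], 0)               # baseline cycle is 0
  # pre min -2 at position 8, post max +8 at position 13: slope 10/5
  hr_seq <- rep(60, 20)
  hr_seq[8] <- 58; hr_seq[13] <- 68
  rr <- 60 / hr_seq
  peaks <- cumsum(c(5, rr))                    # cycle i ends at peaks[i+1]
  onset <- peaks[11] + 0.01                    # 10 cycles before, 10 after
  hr <- hr_response(peaks, onset)
  expect_equal(hr$delta, 10)
  expect_equal(hr$slope, 2)
  expect_equal(hr$pre_hr[8], -2)
  expect_equal(hr$post_hr[3], 8)
  # insufficient cycles: skipped
  expect_null(hr_response(pk, plm_onset_s = 5))
  expect_null(hr_response(pk, plm_onset_s = 35))
})
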