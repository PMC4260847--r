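test_that("boundary windows exclude, event interiors do not", {
  resp <- resp_events(100, 130, "apnea")
  lms <- lm_events(c(96, 110, 131), c(97, 112, 132.5))
  out <- respiratory_exclude(lms, resp)
  expect_equal(has_flag(out$flags, "resp_excluded"), c(TRUE, FALSE, TRUE))
  expect_equal(out$retained, c(FALSE, TRUE, FALSE))
})

test_that("empty respiratory list is the identity", {
  lms <- lm_events(c(10, 20), c(11, 21))
  expect_identical(respiratory_exclude(lms, resp_events()), lms)
  expect_identical(respiratory_exclude(lms, NULL, mode = "off"), lms)
})

test_that("exclusion is monotone in the window widths", {
  set.seed(40)
  resp <- resp_events(seq(100, 2000, by = 150),
                      seq(100, 2000, by = 150) + 25, "hypopnea")
  onsets <- sort(runif(80, 0, 2100))
  lms <- lm_events(onsets, onsets + 1)
  base <- exclusion_windows()
  n_base <- sum(!respiratory_exclude(lms, resp, base)$retained)
  for (grow in list(c(2, 0, 0, 0), c(0, 2, 0, 0), c(0, 0, 2, 0),
                    c(0, 0, 0, 2))) {
    w <- exclusion_windows(base$pre_onset_s + grow[1],
                           base$post_onset_s + grow[2],
                           base$pre_offset_s + grow[3],
                           base$post_offset_s + grow[4])
    expect_gte(sum(!respiratory_exclude(lms, resp, w)$retained), n_base)
  }
})

test_that("AASM-2007 windows never exclude more than the default windows
           on boundary-lagged movements", {
  resp <- resp_events(c(300, 600, 900), c(325, 625, 925), "apnea")
  # movements 3 s after each respiratory offset: the motivating failure
  # mode -- respiratory-coupled activity beyond the AASM 0.5 s margin
  onsets <- resp$offset_s + 3
  lms <- lm_events(onsets, onsets + 1.5)
  n_splmad <- sum(!respiratory_exclude(lms, resp, mode = "splmad")$retained)
  n_aasm <- sum(!respiratory_exclude(lms, resp, mode = "aasm2007")$retained)
  expect_equal(n_splmad, 3)                    # the lagged movements
  expect_lt(n_aasm, n_splmad)
  # movements deep inside an event: kept by the boundary windows, removed
  # by the whole-event AASM rule
  inner <- lm_events(resp$onset_s + 10, resp$onset_s + 11.5)
  expect_true(all(respiratory_exclude(inner, resp, mode = "splmad")$retained))
  expect_false(any(respiratory_exclude(inner, resp, mode = "aasm2007")$retained))
})

test_that("time-locked profile has 120 bins and honours the event filters", {
  fs <- 100
  n <- fs * 3600
  x <- signal_trace(abs(rnorm(n, sd = 2)), fs)
  hyp <- hypnogram(rep("S2", 120))
  # two events within 30 s of each other: both dropped
  resp <- resp_events(c(100, 125), c(120, 145), "apnea")
  prof <- timelocked_emg_profile(x, resp, hyp)
  expect_equal(nrow(prof), 120)
  expect_equal(unique(prof$n_events), 0)
  # a short event (< 15 s) and one followed by wake are dropped too
  hyp2 <- hypnogram(c(rep("S2", 40), rep("W", 10), rep("S2", 70)))
  resp2 <- resp_events(c(300, 700, 1150), c(310, 725, 1175), "apnea")
  # 300-310: too short; 1150-1175: offset epoch ~ epoch 39, next is W
  prof2 <- timelocked_emg_profile(x, resp2, hyp2)
  expect_equal(unique(prof2$n_events), 1)
})

test_that("profile peaks at the planted post-offset lag", {
  resp_df <- data.frame(onset_s = seq(200, 1500, by = 100),
                        offset_s = seq(200, 1500, by = 100) + 20)
  psg <- synth_psg(synth_spec(duration_h = 0.5, seed = 41, ecg = NULL,
    resp_events = resp_df,
    resp_coupling = list(lag_s = 3, duration_s = 3, amplitude_uv = 25),
    hypnogram_stages = rep("S2", 60)))
  prof <- timelocked_emg_profile(psg$recording$traces$leg, psg$resp,
                                 psg$hypnogram, anchor = "offset")
  expect_gt(unique(prof$n_events), 0)
  peak_bin <- prof$bin_center_s[which.max(prof$mean_uv)]
  expect_gte(peak_bin, 2.5)                     # burst occupies +3..+6 s
  expect_lte(peak_bin, 6.5)
  # bins before the event offset stay at baseline
  expect_lt(max(prof$mean_uv[prof$bin_center_s < 0]),
            max(prof$mean_uv) / 2)
})
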