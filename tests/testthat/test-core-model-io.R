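test_that("EDF round-trip preserves samples within 16-bit quantization", {
  set.seed(11)
  fs <- 100
  rec <- recording(list(
    leg = signal_trace(rnorm(fs * 10, sd = 20), fs, "LEG"),
    ecg = signal_trace(rnorm(fs * 10, sd = 300), fs, "ECG")))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path)
  expect_setequal(names(back$traces), c("LEG", "ECG"))
  for (nm in c("LEG", "ECG")) {
    orig <- rec$traces[[tolower(nm)]]$samples
    got <- back$traces[[nm]]$samples[seq_along(orig)]
    q <- 2 * (max(abs(orig)) * 1.01 + 1) / 65535  # one digital step
    expect_lt(max(abs(got - orig)), q)
  }
})

test_that("EDF preserves per-channel sampling rates (512 Hz convention)", {
  rec <- recording(list(
    leg = signal_trace(sin(seq_len(1024) / 10), 512, "LAT"),
    ecg = signal_trace(cos(seq_len(1024) / 10), 512, "ECG")))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path, channel_map = c(leg = "LAT", ecg = "ECG"))
  expect_equal(back$traces$leg$fs, 512)
  expect_equal(back$traces$ecg$fs, 512)
})

test_that("missing channel errors and lists available labels", {
  rec <- recording(list(leg = signal_trace(rnorm(200), 100, "Leg")))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  expect_error(read_recording(path, channel_map = c(leg = "LAT")),
               "not found.*Leg")
  expect_error(read_edf(withr::local_tempfile(fileext = ".txt",
                                              lines = "not an edf")),
               "not an EDF")
})

test_that("merge_leg_channels follows mean/sum rules and validates inputs", {
  fs <- 100
  c1 <- signal_trace(rep(3, 200), fs, "LAT")
  expect_equal(merge_leg_channels(c1, c1)$samples, rep(3, 200))
  z <- signal_trace(rep(0, 200), fs, "LAT")
  r <- signal_trace(rnorm(200), fs, "RAT")
  expect_equal(merge_leg_channels(z, r)$samples, r$samples / 2)
  expect_equal(merge_leg_channels(z, r, rule = "sum")$samples, r$samples)
  # alternating bursts appear at half amplitude under the mean rule
  left <- numeric(400); left[51:100] <- 10
  right <- numeric(400); right[201:250] <- 8
  m <- merge_leg_channels(signal_trace(left, fs), signal_trace(right, fs))
  expect_equal(m$samples, (left + right) / 2)
  expect_error(merge_leg_channels(c1, signal_trace(rep(1, 200), 200)),
               "resample")
  expect_error(merge_leg_channels(c1, signal_trace(rep(1, 150), fs)),
               "length mismatch")
})

test_that("hypnogram/respiratory CSV parsing and span arithmetic", {
  hyp_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(epoch_index = 0:719,
                       stage = rep(c("W", "N2"), 360)),
            hyp_path, row.names = FALSE)
  h <- read_hypnogram(hyp_path)
  expect_equal(length(h$stages) * h$epoch_len_s, 6 * 3600)
  expect_true(all(h$stages %in% c("W", "S2")))     # N2 mapped to S2
  expect_error(hypnogram(c("W", "XX")), "unknown sleep stage")

  resp_path <- withr::local_tempfile(
    lines = c("onset_s,offset_s,type", "100,130,apnea"), fileext = ".csv")
  rr <- read_resp_events(resp_path)
  expect_equal(rr$onset_s, 100)
  expect_equal(rr$offset_s, 130)
  expect_warning(resp_events(c(0, 5), c(10, 20)), "overlapping")
})

test_that("LM events CSV round-trips exactly", {
  ev <- lm_events(c(10, 50.5), c(12, 52), peak_rms_uv = c(20, 15),
                  auc_norm_uv = c(9, 7), state = c("S2", "W"),
                  flags = c("", "merged;too_long"),
                  retained = c(TRUE, FALSE))
  out <- withr::local_tempdir()
  write_results(ev, NULL, out)
  back <- read_lm_events(file.path(out, "lm_events.csv"))
  expect_equal(as.data.frame(back), as.data.frame(ev))
})

test_that("metrics.json carries exactly the subject-metric fields", {
  m <- subject_metrics(plms_per_h = 10, plmw_per_h = 0, lm_count = 5L,
                       plm_count = 4L, hours_sleep = 6, hours_wake = 2,
                       reliable = TRUE)
  out <- withr::local_tempdir()
  write_results(lm_events(1, 2), m, out)
  j <- jsonlite::read_json(file.path(out, "metrics.json"))
  expect_setequal(names(j), names(unclass(m)))
  expect_equal(j$plms_per_h, 10)
  expect_null(j$night_ratio_plm)                  # undefined, not 0
})
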