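test_that("feature schema partitions into 11 + 11 + 16 per task", {
  expect_length(feature_names("FTAP"), 11)
  expect_length(feature_names("TTHP"), 11)
  expect_length(feature_names("GAIT"), 16)
  sch <- feature_schema()
  expect_equal(nrow(sch), 38 * 4)
  expect_false(anyDuplicated(sch$column) > 0)
})

test_that("excursion of a rectangular opening lobe is its analytic integral", {
  # 50 deg/s held for 0.5 s (51 samples incl. both edges) -> 25 deg
  gz <- c(numeric(100), rep(50, 51), numeric(10), rep(-50, 51), numeric(100))
  rec <- make_recording(length(gz), gz = gz)
  segs <- segment_taps(rec)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$excursion, 25)
  expect_equal(segs$peak_opening_velocity, 50)
  expect_equal(segs$peak_closing_velocity, 50)
})

test_that("jerk RMS matches the closed form for a sinusoidal magnitude", {
  n <- 3000; fs <- 100
  t <- (seq_len(n) - 1) / fs
  A <- 0.2; f <- 2
  rec <- make_recording(n, az = 2 + A * sin(2 * pi * f * t))
  fv <- tapping_features(tibble::tibble(), rec)
  expect_equal(fv$jerk_rms, 2 * pi * f * A / sqrt(2), tolerance = 0.01)
})

test_that("acceleration kurtosis uses the Pearson (non-excess) convention", {
  set.seed(77)
  n <- 1e5
  rec <- make_recording(n, az = 10 + rnorm(n))
  fv <- tapping_features(tibble::tibble(), rec)
  expect_equal(fv$acc_kurt, 3.0, tolerance = 0.05)
  expect_equal(fv$acc_skew, 0, tolerance = 0.05)
})

test_that("SMA is the time-normalized absolute gravity-removed acceleration", {
  n <- 1000
  rec <- make_recording(n, ax = rep(0.1, n), az = rep(1, n),
                        baseline = list(pose = c(0, 0, 1)))
  fv <- tapping_features(tibble::tibble(), rec)
  expect_equal(fv$sma, 0.1)
  # invariant under sensor-axis permutation
  rec2 <- rec
  rec2$accel <- rec$accel[, c(3, 1, 2)]
  rec2$baseline$pose <- rec$baseline$pose[c(3, 1, 2)]
  expect_equal(tapping_features(tibble::tibble(), rec2)$sma, fv$sma)
})

test_that("empty segment lists yield missing cycle aggregates, not zeros", {
  rec <- make_recording(500)
  fv <- tapping_features(tibble::tibble(excursion = numeric(),
                                        peak_opening_velocity = numeric(),
                                        peak_closing_velocity = numeric()),
                         rec)
  expect_equal(fv$ntaps, 0)
  expect_true(is.na(fv$exc_mean))
  expect_true(is.na(fv$wo_sd))
})

test_that("doubling tap amplitude doubles excursion and velocity, not counts or shape", {
  run <- function(exc) {
    r <- simulate_tapping_signal(noiseless_tap_params(period_s = 0.5,
                                                      excursion_deg = exc),
                                 "FTAP", "CL0", seed = 1)
    rb <- remove_baseline(lowpass_filter(r))
    tapping_features(segment_taps(rb), rb)
  }
  a <- run(15); b <- run(30)
  expect_equal(b$ntaps, a$ntaps)
  expect_equal(b$exc_mean / a$exc_mean, 2, tolerance = 0.01)
  expect_equal(b$wo_mean / a$wo_mean, 2, tolerance = 0.01)
  expect_lt(abs(b$acc_skew - a$acc_skew), 0.05)
})

test_that("noiseless recovery: counts exact, excursions and durations within 2%", {
  r <- simulate_tapping_signal(noiseless_tap_params(n_target = 15),
                               "FTAP", "CL0", seed = 4)
  rb <- remove_baseline(lowpass_filter(r))
  fv <- tapping_features(segment_taps(rb), rb)
  expect_equal(fv$ntaps, r$truth$n_taps)
  expect_equal(fv$exc_mean, mean(r$truth$exc_deg), tolerance = 0.02)

  g <- simulate_gait_signal(noiseless_gait_params(), "CL0", seed = 4)
  gf <- lowpass_filter(g)
  segs <- segment_strides(gf)
  fvg <- gait_features(segs, gf)
  expect_equal(attr(segs, "n_detected"), g$truth$n_strides)
  expect_equal(fvg$strd_mean, mean(g$truth$stride_duration_s),
               tolerance = 0.02)
})

test_that("gait features follow the uniform-stride arithmetic", {
  # 5 uniform strides of exactly 1.2 s over 10 m, built by hand
  fs <- 100
  starts <- seq(1, by = 120, length.out = 5)
  segs <- tibble::tibble(start = starts, end = starts + 120L,
                         duration = rep(1.2, 5),
                         peak_index = starts + 90L,
                         swing_peak_velocity = rep(250, 5))
  attr(segs, "n_detected") <- 5L
  n <- 700
  v <- numeric(n)
  for (p in segs$peak_index) v[(p - 20):(p + 20)] <- 250 * cos(seq(-pi / 2, pi / 2, length.out = 41))^2
  rec <- make_recording(n, gz = v, task = "GAIT")
  fv <- gait_features(segs, rec, distance_m = 10)
  expect_equal(fv$gt, 6.0)
  expect_equal(fv$strd_sd, 0)
  expect_equal(fv$strdl_mean, 2.0)
  expect_equal(fv$gvel, 10 / 6)
  expect_equal(fv$cadence, 50)
  expect_equal(fv$symmetry, 1)
  expect_equal(fv$nstrides, 5)
  expect_error(gait_features(segs[0, ], rec), "no retained strides")
})

test_that("stride-length presets are recovered from simulated CNA walks", {
  # CL0 CNA preset stride length 2.24 m -> 5 detected strides over 10 m
  r <- simulate_gait_signal(noiseless_gait_params(stride_length_m = 2.24,
                                                  stride_duration_s = 1.08),
                            "CL0", seed = 13)
  rf <- lowpass_filter(r)
  segs <- segment_strides(rf)
  fv <- gait_features(segs, rf)
  expect_equal(fv$strdl_mean, 10 / ceiling(10 / 2.24))
  expect_equal(fv$strdl_mean, 2.24, tolerance = 0.12)
})

test_that("the base table has 38 features x 4 loads per subject", {
  cohort <- small_cohort()
  base <- suppressMessages(build_base_features(cohort))
  expect_equal(nrow(base), nrow(cohort$subjects))
  feat_cols <- setdiff(names(base), c("subject_id", "group"))
  ca <- grepl("correct_answers", feat_cols)
  expect_equal(sum(!ca), 152)   # 38 x 4
  expect_equal(sum(ca), 9)      # 3 tasks x CL1-CL3
  # every schema column present
  expect_true(all(feature_schema()$column %in% names(base)))

  # a subject with a missing recording is excluded with a message
  broken <- cohort
  drop_key <- paste(cohort$subjects$subject_id[1], "GAIT", "CL2", sep = "_")
  broken$recordings[[drop_key]] <- NULL
  expect_message(b2 <- build_base_features(broken), "incomplete")
  expect_equal(nrow(b2), nrow(cohort$subjects) - 1)
})
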