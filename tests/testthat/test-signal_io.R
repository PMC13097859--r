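test_that("trial files round-trip through write_trial/read_trial", {
  rec <- random_trial(T = 1280, seed = 3, task = "Uneven ground",
                      sensor = "LF")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(rec, path)
  back <- read_trial(path)
  expect_equal(back$acc, rec$acc, tolerance = 1e-9)
  expect_equal(back$gyr, rec$gyr, tolerance = 1e-9)
  expect_identical(back$participant_id, rec$participant_id)
  expect_identical(back$task, "Uneven ground")
  expect_identical(back$sensor, "LF")
  expect_equal(back$sample_rate, 128)
  # 1280 rows at 128 Hz -> 10 s
  expect_equal(back$duration_s, 10.0)
  expect_equal(nrow(back$acc), 1280)
})

test_that("read_trial converts g to m/s^2 per header declaration", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# participant=P1 group=HS task=Walk sensor=HE fs=128 acc_unit=g gyr_unit=dps",
    "t_s,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z",
    "0,1,0,0,5,0,0",
    "0.0078125,1,0,0,5,0,0"), path)
  rec <- read_trial(path)
  expect_equal(rec$acc[1, 1], 9.80665)
  expect_equal(rec$gyr[1, 1], 5)
})

test_that("malformed headers and non-finite samples are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant=P1", "t_s,acc_x"), path)
  expect_error(read_trial(path), "malformed")
  writeLines(c(
    "# participant=P1 group=HS task=Walk sensor=HE fs=128 acc_unit=ms2 gyr_unit=dps",
    "t_s,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z",
    paste(0:11 / 128, "0,0,0,0,0,0", sep = ","),
    "0.09375,0,0,NaN,0,0,0"), path)
  expect_error(read_trial(path), "row 13")
})

test_that("trial validation enforces shape, finiteness and labels", {
  A <- matrix(0, 10, 3)
  expect_error(trial_recording("P", "XX", "Walk", "HE", A, A), "group")
  expect_error(trial_recording("P", "HS", "Jogging", "HE", A, A), "task")
  expect_error(trial_recording("P", "HS", "Walk", "HE", A, matrix(0, 9, 3)),
               "equal length")
  A2 <- A; A2[4, 2] <- Inf
  expect_error(trial_recording("P", "HS", "Walk", "HE", A2, A),
               "non-finite sample at row 4")
})

test_that("trim_edges removes floor(fraction*T) samples per side", {
  rec <- random_trial(T = 1000, seed = 1)
  tr <- trim_edges(rec, 0.05)
  expect_equal(nrow(tr$acc), 900)
  # samples 51..950 of the original (1-based) survive
  expect_equal(tr$acc, rec$acc[51:950, ])
  expect_equal(tr$duration_s, rec$duration_s)

  rec20 <- random_trial(T = 20, seed = 2)
  expect_equal(nrow(trim_edges(rec20, 0.05)$acc), 18)

  expect_equal(trim_edges(rec, 0)$acc, rec$acc)
  # zero trim after a trim is the identity
  expect_equal(trim_edges(tr, 0)$acc, tr$acc)
  expect_error(trim_edges(rec, 0.5), "fraction")
  expect_error(trim_edges(rec, -0.01), "fraction")
})

test_that("low-pass filter has unit DC gain and the analytic band response", {
  fs <- 128
  const <- trial_recording("P", "HS", "Walk", "HE",
                           matrix(2.5, 200, 3), matrix(-1, 200, 3), fs)
  out <- lowpass_filter(const)
  expect_lt(max(abs(out$acc - 2.5)), 1e-9)
  expect_lt(max(abs(out$gyr + 1)), 1e-9)

  # two-pass amplitude response of an order-n Butterworth low-pass is
  # 1 / (1 + (f/fc)^(2 n)); probe interior samples away from the edges
  t <- (0:1279) / fs
  probe <- function(f) {
    rec <- trial_recording("P", "HS", "Walk", "HE",
                           cbind(sin(2 * pi * f * t), 0, 0),
                           matrix(0, 1280, 3), fs)
    max(abs(lowpass_filter(rec)$acc[200:1080, 1]))
  }
  expect_gte(probe(1), 0.999)
  expect_lt(probe(30), 1e-4)
  expect_equal(probe(1), 1 / (1 + (1 / 6)^8), tolerance = 1e-5)

  expect_error(lowpass_filter(const, cutoff_hz = 64), "Nyquist")
})

test_that("zero-phase filtering is linear", {
  fs <- 128
  set.seed(11)
  x <- matrix(rnorm(512 * 3), ncol = 3)
  y <- matrix(rnorm(512 * 3), ncol = 3)
  g0 <- matrix(0, 512, 3)
  mk <- function(A) trial_recording("P", "HS", "Walk", "HE", A, g0, fs)
  fa <- lowpass_filter(mk(x))$acc
  fb <- lowpass_filter(mk(y))$acc
  fab <- lowpass_filter(mk(2 * x - 3 * y))$acc
  expect_lt(max(abs(fab - (2 * fa - 3 * fb))), 1e-9)
})

test_that("preprocessing runs trim before filter and marks the result", {
  rec <- random_trial(T = 400, seed = 5)
  pp <- preprocess_trial(rec, fraction = 0.05)
  expect_true(attr(pp, "preprocessed"))
  expect_equal(nrow(pp$acc), 360)
  # the canonical order differs from filter-then-trim
  alt <- trim_edges(lowpass_filter(rec), 0.05)
  expect_gt(max(abs(alt$acc - pp$acc)), 0)
  # and feature extraction refuses raw recordings
  md <- meta_row(task = "Walk")
  recs <- setNames(lapply(imu_sensors(), function(s) {
    r <- random_trial(T = 128, seed = 6, sensor = s)
    r
  }), imu_sensors())
  expect_error(extract_trial_features(recs, md), "not preprocessed")
})

test_that("metadata tables validate and round-trip", {
  md <- rbind(
    meta_row("P1", "BV", "Pants", 12.5, "difficult", TRUE),
    meta_row("P1", "BV", "Wood beam", 5.0, "impossible", FALSE),
    meta_row("P2", "HS", "Pants", 8.1, "easy", TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metadata(md, path)
  back <- read_metadata(path)
  expect_equal(back$duration_s, md$duration_s)
  expect_equal(back$difficulty_score, c(3L, 4L, 1L))
  bad <- md
  bad$completed[2] <- TRUE
  expect_error(write_metadata(bad, path), "impossible")
})
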