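test_that("vector norms and RMS match their closed forms", {
  expect_equal(vector_norm_series(matrix(c(0, 0, 0), 1)), 0)
  expect_equal(vector_norm_series(matrix(c(3, 4, 0), 1)), 5)
  set.seed(2)
  X <- matrix(rnorm(300), ncol = 3)
  byrow <- vapply(seq_len(100), function(r) sqrt(sum(X[r, ]^2)), numeric(1))
  expect_equal(vector_norm_series(X), byrow, tolerance = 1e-12)

  expect_equal(rms(rep(-3, 10)), 3)
  expect_equal(rms(numeric(5)), 0)
  t <- (0:1279) / 128
  expect_equal(rms(2 * sin(2 * pi * 2 * t)), 2 / sqrt(2), tolerance = 1e-3)
  expect_error(rms(numeric(0)), "empty")
})

test_that("jerk matches analytic values on ramps and sinusoids", {
  fs <- 128
  T <- 257                      # 2 s, integer cycles for f = 2
  t <- (0:(T - 1)) / fs
  zero <- matrix(0, T, 3)

  expect_equal(jerk_scalar(matrix(5, T, 3), fs), 0)
  expect_equal(jerk_rms(matrix(5, T, 3), fs), 0)

  # ramp acc_x = k t: constant jerk k, integral = k^2 T_end / 2
  k <- 3.7
  ramp <- cbind(k * t, 0, 0)
  T_end <- t[T]
  expect_equal(jerk_scalar(ramp, fs), k^2 * T_end / 2, tolerance = 1e-12)
  expect_equal(jerk_rms(ramp, fs), k, tolerance = 1e-12)

  # sinusoid: JERK = A^2 w^2 T / 4, RMS jerk = A w / sqrt(2)
  A <- 2; f <- 2; w <- 2 * pi * f
  sine <- cbind(A * sin(w * t), 0, 0)
  expect_equal(jerk_scalar(sine, fs), A^2 * w^2 * T_end / 4,
               tolerance = 0.005)
  expect_equal(jerk_rms(sine, fs), A * w / sqrt(2), tolerance = 0.005)

  expect_error(jerk_scalar(matrix(0, 2, 3), fs), "3 samples")
})

test_that("attenuation coefficient reproduces the analytic cases", {
  expect_equal(attenuation_coefficient(2, 2), 0)
  expect_equal(attenuation_coefficient(2, 1), 50)
  expect_equal(attenuation_coefficient(1, 2), -100)
  expect_error(attenuation_coefficient(0, 1), "positive")
})

test_that("per-trial extraction fills the 19-variable roster", {
  recs <- sensor_set(task = "Pants", seed = 4)
  md <- meta_row(task = "Pants", duration_s = 7.25)
  fr <- extract_trial_features(recs, md)
  expect_length(fr$values, 19)
  expect_setequal(names(fr$values), task_variables <- {
    c(outer(imu_sensors(), imu_parameters(),
            function(s, p) paste("Pants", s, p, sep = "|")),
      paste("Pants", c("AC_TH", "AC_SH", "AC_ST"), sep = "|"),
      "Pants|duration")
  })
  expect_equal(fr$values[["Pants|duration"]], 7.25)

  # AC recomputed from the extracted sensor RMS values
  rms_tr <- fr$values[["Pants|TR|NormLinAcc_RMS"]]
  rms_sa <- fr$values[["Pants|SA|NormLinAcc_RMS"]]
  expect_equal(fr$values[["Pants|AC_ST"]], (1 - rms_tr / rms_sa) * 100)
  expect_true(all(fr$values[c("Pants|AC_TH", "Pants|AC_SH",
                              "Pants|AC_ST")] <= 100))

  # impossible task: explicit all-missing record
  fr0 <- extract_trial_features(list(), meta_row(task = "Pants",
                                                 difficulty = "impossible",
                                                 completed = FALSE))
  expect_null(fr0$values)

  expect_error(extract_trial_features(recs[c("HE", "TR")], md),
               "missing required sensor")
})

test_that("extraction agrees with a straight-line reimplementation", {
  for (seed in 1:10) {
    recs <- sensor_set(task = "Tray", seed = seed, T = 128)
    md <- meta_row(task = "Tray", duration_s = 3 + seed)
    got <- extract_trial_features(recs, md)$values
    want <- features_oracle(recs, duration_s = 3 + seed)
    expect_equal(got[names(want)], want, tolerance = 1e-9)
  }
})

test_that("features are invariant under common 3D rotations", {
  recs <- sensor_set(task = "Walk", seed = 9)
  md <- meta_row(task = "Walk", duration_s = 4)
  base <- extract_trial_features(recs, md)$values
  for (seed in c(1, 2, 3)) {
    R <- random_rotation(seed)
    rot <- lapply(recs, function(rec) {
      rec$acc <- rec$acc %*% t(R)
      rec$gyr <- rec$gyr %*% t(R)
      rec
    })
    rotated <- extract_trial_features(rot, md)$values
    expect_equal(rotated, base, tolerance = 1e-9)
  }
})

test_that("features scale correctly with acceleration magnitude", {
  rec <- random_trial(T = 200, seed = 12)
  c0 <- 3.5
  scaled <- rec
  scaled$acc <- c0 * rec$acc
  expect_equal(rms(vector_norm_series(scaled$acc)),
               c0 * rms(vector_norm_series(rec$acc)))
  expect_equal(jerk_rms(scaled$acc, 128), c0 * jerk_rms(rec$acc, 128))
  expect_equal(jerk_scalar(scaled$acc, 128),
               c0^2 * jerk_scalar(rec$acc, 128))
  # AC built from commonly-scaled RMS values is unchanged
  expect_equal(attenuation_coefficient(c0 * 2, c0 * 1.2),
               attenuation_coefficient(2, 1.2))
})

test_that("feature matrix assembly is deterministic with stable columns", {
  tasks8 <- imu_tasks()[1:8]
  records <- list()
  for (p in 1:4) {
    for (task in tasks8) {
      recs <- sensor_set(task = task, seed = p * 100 + match(task, tasks8),
                         T = 64)
      md <- meta_row(sprintf("P%02d", p),
                     group = imu_groups()[(p %% 3) + 1], task = task,
                     duration_s = 5)
      records[[length(records) + 1]] <- local({
        r <- extract_trial_features(recs, md)
        r$participant_id <- sprintf("P%02d", p)
        r$group <- imu_groups()[(p %% 3) + 1]
        r
      })
    }
  }
  fm <- build_feature_matrix(records, tasks8)
  # 8 tasks x (5 sensors x 3 parameters + 3 AC + duration) = 152 variables
  expect_length(attr(fm, "variables"), 152)
  expect_equal(ncol(fm), 154)
  expect_false(anyDuplicated(names(fm)) > 0)
  fm2 <- build_feature_matrix(records, tasks8)
  expect_identical(names(fm), names(fm2))
  expect_identical(fm, fm2)

  expect_error(build_feature_matrix(list(), tasks8), "no feature records")
  expect_error(build_feature_matrix(c(records, records[1]), tasks8),
               "duplicate")
})

test_that("missing cells stay missing and wide/long files round-trip", {
  recs <- sensor_set(task = "Pants", seed = 1, T = 64)
  r1 <- extract_trial_features(recs, meta_row("P1", "BV", "Pants", 6))
  r1$participant_id <- "P1"; r1$group <- "BV"
  r2 <- extract_trial_features(list(),
                               meta_row("P2", "HS", "Pants", 6,
                                        "impossible", FALSE))
  r2$participant_id <- "P2"; r2$group <- "HS"
  fm <- build_feature_matrix(list(r1, r2), "Pants")
  expect_true(all(is.na(as_vals <- unlist(fm[2, -(1:2)]))))
  wide <- withr::local_tempfile(fileext = ".csv")
  long <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, wide, long)
  back <- read_feature_matrix(wide)
  expect_equal(attr(back, "variables"), attr(fm, "variables"))
  expect_equal(back[["Pants|HE|JERK_RMS"]], fm[["Pants|HE|JERK_RMS"]])
  lf <- read.csv(long)
  expect_equal(nrow(lf), 2 * 19)
})
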