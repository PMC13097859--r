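# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately written as straight-line textbook code,
# separate from the package's implementation paths.

# Random T x 3 trial recording.
random_trial <- function(T = 256, fs = 128, seed = 1,
                         task = "Walk", sensor = "HE") {
  set.seed(seed)
  trial_recording(participant_id = "P01", group = "HS", task = task,
                  sensor = sensor,
                  acc = matrix(rnorm(T * 3), ncol = 3),
                  gyr = matrix(rnorm(T * 3), ncol = 3),
                  sample_rate = fs)
}

# Uniformly random proper 3D rotation matrix.
random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_out <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_out)
  Q <- Q %*% diag(sign(diag(qr.R(qr_out))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Textbook Dunn z statistics (pooled ranks, tie correction), computed
# independently of the package: explicit rank table, loop over pairs.
dunn_oracle_z <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  lab <- rep(names(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  rk <- rank(x)
  # tie correction from the multiset of tied values
  tie_sum <- 0
  for (v in unique(x)) {
    tv <- sum(x == v)
    tie_sum <- tie_sum + (tv^3 - tv)
  }
  s2 <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  out <- c()
  gn <- names(groups)
  for (i in seq_along(gn)) {
    for (j in seq_along(gn)) {
      if (j <= i) next
      ni <- sum(lab == gn[i]); nj <- sum(lab == gn[j])
      mi <- mean(rk[lab == gn[i]]); mj <- mean(rk[lab == gn[j]])
      z <- (mi - mj) / sqrt(s2 * (1 / ni + 1 / nj))
      out[paste(gn[i], gn[j], sep = "-")] <- z
    }
  }
  out
}

# Straight-line reimplementation of the per-trial feature roster (loops,
# no shared helpers) for one set of sensor recordings.
features_oracle <- function(recordings, duration_s) {
  rms_loop <- function(v) {
    s <- 0
    for (vi in v) s <- s + vi^2
    sqrt(s / length(v))
  }
  norm_loop <- function(M) {
    out <- numeric(nrow(M))
    for (r in seq_len(nrow(M)))
      out[r] <- sqrt(M[r, 1]^2 + M[r, 2]^2 + M[r, 3]^2)
    out
  }
  deriv_loop <- function(v, dt) {
    T <- length(v)
    d <- numeric(T)
    d[1] <- (v[2] - v[1]) / dt
    d[T] <- (v[T] - v[T - 1]) / dt
    for (r in 2:(T - 1)) d[r] <- (v[r + 1] - v[r - 1]) / (2 * dt)
    d
  }
  vals <- c()
  acc_rms <- c()
  task <- recordings[[1]]$task
  for (s in names(recordings)) {
    rec <- recordings[[s]]
    dt <- 1 / rec$sample_rate
    a <- rms_loop(norm_loop(rec$acc))
    g <- rms_loop(norm_loop(rec$gyr))
    J <- cbind(deriv_loop(rec$acc[, 1], dt), deriv_loop(rec$acc[, 2], dt),
               deriv_loop(rec$acc[, 3], dt))
    j <- rms_loop(norm_loop(J))
    acc_rms[s] <- a
    vals[paste(task, s, "NormLinAcc_RMS", sep = "|")] <- a
    vals[paste(task, s, "NormAngVel_RMS", sep = "|")] <- g
    vals[paste(task, s, "JERK_RMS", sep = "|")] <- j
  }
  vals[paste0(task, "|AC_TH")] <- (1 - acc_rms[["HE"]] / acc_rms[["TR"]]) * 100
  vals[paste0(task, "|AC_SH")] <- (1 - acc_rms[["HE"]] / acc_rms[["SA"]]) * 100
  vals[paste0(task, "|AC_ST")] <- (1 - acc_rms[["TR"]] / acc_rms[["SA"]]) * 100
  vals[paste0(task, "|duration")] <- duration_s
  vals
}

# Five-sensor recording set for one participant x task, with sensor-specific
# amplitude scales; marked preprocessed for direct feature extraction.
sensor_set <- function(task = "Walk", seed = 1, T = 256, fs = 128,
                       scales = c(HE = 0.7, TR = 0.9, SA = 1.2,
                                  LF = 3, RF = 3)) {
  set.seed(seed)
  out <- list()
  for (s in imu_sensors()) {
    rec <- trial_recording("P01", "HS", task, s,
                           acc = scales[[s]] * matrix(rnorm(T * 3), ncol = 3),
                           gyr = scales[[s]] * matrix(rnorm(T * 3), ncol = 3),
                           sample_rate = fs)
    attr(rec, "preprocessed") <- TRUE
    out[[s]] <- rec
  }
  out
}

meta_row <- function(participant_id = "P01", group = "HS", task = "Walk",
                     duration_s = 2, difficulty = "easy",
                     completed = TRUE) {
  data.frame(participant_id = participant_id, group = group, task = task,
             duration_s = duration_s, difficulty = difficulty,
             completed = completed, stringsAsFactors = FALSE)
}

# Feature matrix built directly from a numeric matrix (for the PCA tests).
fm_from_matrix <- function(M, groups = NULL,
                           vars = paste0("Walk|HE|V", seq_len(ncol(M)))) {
  n <- nrow(M)
  if (is.null(groups))
    groups <- rep(imu_groups(), length.out = n)[order(rep(imu_groups(),
                                                          length.out = n))]
  fm <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                   group = groups, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (k in seq_len(ncol(M))) fm[[vars[k]]] <- M[, k]
  attr(fm, "variables") <- vars
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

# Group samples fixture with planted location shifts (BV, UV, HS).
shifted_groups <- function(n = 20, shift_bv = 0, shift_uv = 0, sd = 1,
                           seed = 1) {
  set.seed(seed)
  list(BV = rnorm(n, shift_bv, sd),
       UV = rnorm(n, shift_uv, sd),
       HS = rnorm(n, 0, sd))
}
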