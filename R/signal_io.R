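#' Construct a trial recording
#'
#' A trial is one participant performing one task while one IMU records 3D
#' linear acceleration (m/s^2) and 3D angular velocity (deg/s) at a fixed
#' sampling rate. `duration_s` is the full task duration before any edge
#' trimming and is the value that enters the feature matrix as the
#' `<task>|duration` variable.
#'
#' @param participant_id Character scalar.
#' @param group One of `"BV"`, `"UV"`, `"HS"`.
#' @param task One of [imu_tasks()].
#' @param sensor One of [imu_sensors()] or, for ingestion only,
#'   [imu_sensors_extra()].
#' @param acc,gyr Numeric T x 3 matrices (columns x, y, z), in m/s^2 and
#'   deg/s respectively.
#' @param sample_rate Sampling frequency in Hz (default 128).
#' @param duration_s Full task duration in seconds; defaults to
#'   `nrow(acc) / sample_rate`.
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(participant_id, group, task, sensor, acc, gyr,
                            sample_rate = 128,
                            duration_s = nrow(acc) / sample_rate) {
  acc <- as.matrix(acc)
  gyr <- as.matrix(gyr)
  rec <- structure(
    list(participant_id = as.character(participant_id),
         group = as.character(group), task = as.character(task),
         sensor = as.character(sensor), sample_rate = sample_rate,
         acc = acc, gyr = gyr, duration_s = duration_s),
    class = "trial_recording")
  validate_trial_recording(rec)
}

validate_trial_recording <- function(rec) {
  stopifnot(inherits(rec, "trial_recording"))
  if (!rec$group %in% imu_groups())
    stop("unknown group: ", rec$group)
  if (!rec$task %in% imu_tasks())
    stop("unknown task: ", rec$task)
  if (!rec$sensor %in% c(imu_sensors(), imu_sensors_extra()))
    stop("unknown sensor: ", rec$sensor)
  if (!is.matrix(rec$acc) || ncol(rec$acc) != 3 ||
      !is.matrix(rec$gyr) || ncol(rec$gyr) != 3)
    stop("acc and gyr must be T x 3 matrices")
  if (nrow(rec$acc) != nrow(rec$gyr))
    stop("acc and gyr must have equal length")
  if (nrow(rec$acc) < 2) stop("trial must contain at least 2 samples")
  if (!is.numeric(rec$sample_rate) || rec$sample_rate <= 0)
    stop("sample_rate must be positive")
  if (!is.numeric(rec$duration_s) || rec$duration_s <= 0)
    stop("duration_s must be positive")
  bad <- which(!is.finite(rec$acc) | !is.finite(rec$gyr), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite sample at row ", bad[1, 1],
         " (", if (any(!is.finite(rec$acc[bad[1, 1], ]))) "acc" else "gyr",
         ")")
  }
  rec
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> %s | %s | %s | %s\n  %d samples @ %g Hz (%.2f s), duration_s = %.2f%s\n",
    x$participant_id, x$group, x$task, x$sensor, nrow(x$acc), x$sample_rate,
    nrow(x$acc) / x$sample_rate, x$duration_s,
    if (isTRUE(attr(x, "preprocessed"))) ", preprocessed" else ""))
  invisible(x)
}

# ---- on-disk trial dialect ------------------------------------------------
# First line: "# participant=<id> group=<g> task=<name> sensor=<s> fs=<Hz>
#              acc_unit=<g|ms2> gyr_unit=<dps>"
# then CSV columns t_s,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z.
# Task names may contain spaces, so the header is parsed by key= positions.

parse_trial_header <- function(line) {
  if (!startsWith(line, "# "))
    stop("malformed trial header: expected leading '# '")
  body <- sub("^# ", "", line)
  m <- gregexpr("[A-Za-z_]+=", body)[[1]]
  if (m[1] == -1) stop("malformed trial header: no key=value pairs")
  keys <- character(0); vals <- character(0)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    keys[i] <- substr(body, starts[i], starts[i] + lens[i] - 2)
    vend <- if (i < length(starts)) starts[i + 1] - 2 else nchar(body)
    vals[i] <- trimws(substr(body, starts[i] + lens[i], vend))
  }
  out <- as.list(vals)
  names(out) <- keys
  required <- c("participant", "group", "task", "sensor", "fs",
                "acc_unit", "gyr_unit")
  missing <- setdiff(required, keys)
  if (length(missing))
    stop("malformed trial header: missing ", paste(missing, collapse = ", "))
  out
}

#' Read / write a trial file
#'
#' Trials are stored one per file: a metadata header line followed by a CSV
#' table with columns `t_s, acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z`.
#' Accelerations declared in `g` in the header are converted to m/s^2 on
#' reading; angular velocity is deg/s throughout.
#'
#' @param path File path.
#' @return `read_trial()` returns a validated [trial_recording()];
#'   `write_trial()` returns `path` invisibly.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  header <- parse_trial_header(readLines(path, n = 1L))
  df <- read.csv(path, skip = 1L, check.names = FALSE)
  expected <- c("t_s", "acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
  if (!identical(names(df), expected))
    stop("malformed trial file: expected columns ",
         paste(expected, collapse = ","))
  acc <- as.matrix(df[, c("acc_x", "acc_y", "acc_z")])
  gyr <- as.matrix(df[, c("gyr_x", "gyr_y", "gyr_z")])
  for (nm in c("acc", "gyr")) {
    X <- get(nm)
    bad <- which(rowSums(!is.finite(X)) > 0)
    if (length(bad))
      stop("non-finite ", nm, " sample in ", basename(path),
           " at data row ", bad[1])
  }
  if (!header$acc_unit %in% c("g", "ms2"))
    stop("malformed trial header: acc_unit must be g or ms2")
  if (header$acc_unit == "g") acc <- acc * GRAVITY_MS2
  if (header$gyr_unit != "dps")
    stop("malformed trial header: gyr_unit must be dps")
  fs <- as.numeric(header$fs)
  dimnames(acc) <- dimnames(gyr) <- NULL
  trial_recording(header$participant, header$group, header$task,
                  header$sensor, acc, gyr, sample_rate = fs,
                  duration_s = nrow(acc) / fs)
}

#' @rdname read_trial
#' @param rec A [trial_recording()].
#' @export
write_trial <- function(rec, path) {
  validate_trial_recording(rec)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  header <- sprintf(
    "# participant=%s group=%s task=%s sensor=%s fs=%s acc_unit=ms2 gyr_unit=dps",
    rec$participant_id, rec$group, rec$task, rec$sensor,
    format(rec$sample_rate, digits = 12))
  t_s <- (seq_len(nrow(rec$acc)) - 1) / rec$sample_rate
  df <- data.frame(t_s = t_s,
                   acc_x = rec$acc[, 1], acc_y = rec$acc[, 2],
                   acc_z = rec$acc[, 3],
                   gyr_x = rec$gyr[, 1], gyr_y = rec$gyr[, 2],
                   gyr_z = rec$gyr[, 3])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(names(df), collapse = ","), con)
  lines <- do.call(paste, c(lapply(df, format, digits = 15, trim = TRUE,
                                   scientific = FALSE),
                            sep = ","))
  writeLines(lines, con)
  invisible(path)
}

#' Remove the initiation and termination phases of a trial
#'
#' Drops `floor(fraction * T)` samples from each end of the recording, the
#' standard guard against start/stop artefacts. Metadata (including
#' `duration_s`) is unchanged.
#'
#' @param rec A [trial_recording()].
#' @param fraction Proportion removed from each end, in `[0, 0.5)`
#'   (default 0.05).
#' @return The trimmed [trial_recording()].
#' @export
trim_edges <- function(rec, fraction = 0.05) {
  validate_trial_recording(rec)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction < 0 || fraction >= 0.5)
    stop("fraction must lie in [0, 0.5)")
  T <- nrow(rec$acc)
  k <- floor(fraction * T)
  if (T - 2 * k < 2) stop("trial too short to trim")
  if (k > 0) {
    keep <- (k + 1):(T - k)
    rec$acc <- rec$acc[keep, , drop = FALSE]
    rec$gyr <- rec$gyr[keep, , drop = FALSE]
  }
  attr(rec, "trimmed") <- TRUE
  rec
}

# Steady-state initial filter state for a unit-amplitude step (direct-form II
# transposed), so that constant inputs pass through an IIR filter exactly.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  if (n == 1) return(numeric(0))
  comp <- matrix(0, n - 1, n - 1)       # companion matrix of a, transposed
  comp[1, ] <- -a[-1] / a[1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  IminusA <- diag(n - 1) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

# Zero-phase (forward-backward) IIR filtering of the columns of X with
# odd-reflection edge padding and steady-state initial conditions.
filtfilt_mat <- function(b, a, X) {
  T <- nrow(X)
  n <- max(length(a), length(b))
  pad <- min(3 * (n - 1) * 3, T - 1)     # generous reflection pad
  zi <- lfilter_zi(b, a)
  one_pass <- function(M) {
    zim <- outer(zi, M[1, ])
    df2t_filter_mat(b, a, M, zim)
  }
  head_pad <- 2 * matrix(X[1, ], pad, ncol(X), byrow = TRUE) -
    X[(pad + 1):2, , drop = FALSE]
  tail_pad <- 2 * matrix(X[T, ], pad, ncol(X), byrow = TRUE) -
    X[(T - 1):(T - pad), , drop = FALSE]
  Xp <- rbind(head_pad, X, tail_pad)
  Y <- one_pass(Xp)
  Y <- one_pass(Y[nrow(Y):1, , drop = FALSE])
  Y <- Y[nrow(Y):1, , drop = FALSE]
  Y[(pad + 1):(pad + T), , drop = FALSE]
}

#' Zero-phase Butterworth low-pass filtering
#'
#' Filters all six channels of a trial with an order-`order` Butterworth
#' low-pass filter applied forward and backward (zero phase, DC gain exactly
#' one). The effective amplitude attenuation is the squared single-pass
#' magnitude response.
#'
#' @param rec A [trial_recording()].
#' @param order Filter order (default 4).
#' @param cutoff_hz Cut-off frequency in Hz (default 6); must be below the
#'   Nyquist frequency.
#' @return The filtered [trial_recording()].
#' @export
lowpass_filter <- function(rec, order = 4, cutoff_hz = 6) {
  validate_trial_recording(rec)
  if (cutoff_hz >= rec$sample_rate / 2)
    stop("cutoff_hz must be below the Nyquist frequency (",
         rec$sample_rate / 2, " Hz)")
  if (cutoff_hz <= 0) stop("cutoff_hz must be positive")
  bf <- signal::butter(order, cutoff_hz / (rec$sample_rate / 2),
                       type = "low")
  X <- cbind(rec$acc, rec$gyr)
  Y <- filtfilt_mat(bf$b, bf$a, X)
  rec$acc <- Y[, 1:3, drop = FALSE]
  rec$gyr <- Y[, 4:6, drop = FALSE]
  attr(rec, "filtered") <- TRUE
  rec
}

#' Canonical trial preprocessing
#'
#' Applies the canonical preprocessing order: edge trimming first, zero-phase
#' Butterworth low-pass filtering second. Feature extraction requires
#' recordings preprocessed through this function (the order matters: the
#' filter's edge behaviour depends on what was trimmed).
#'
#' @inheritParams trim_edges
#' @inheritParams lowpass_filter
#' @return The preprocessed [trial_recording()] with attribute
#'   `preprocessed = TRUE`.
#' @export
preprocess_trial <- function(rec, fraction = 0.05, order = 4, cutoff_hz = 6) {
  rec <- trim_edges(rec, fraction)
  rec <- lowpass_filter(rec, order = order, cutoff_hz = cutoff_hz)
  attr(rec, "preprocessed") <- TRUE
  rec
}

#' Read / write the per-trial metadata table
#'
#' Columns: `participant_id, group, task, duration_s, difficulty, completed`.
#' `difficulty` is stored as the ordinal label (easy/medium/difficult/
#' impossible) and returned alongside its numeric encoding 1-4. A task rated
#' impossible was not completed and contributes no duration observation.
#'
#' @param path CSV file path.
#' @return A data frame of trial metadata.
#' @export
read_metadata <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param metadata Metadata data frame.
#' @export
write_metadata <- function(metadata, path) {
  validate_metadata(metadata)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(metadata[, c("participant_id", "group", "task", "duration_s",
                         "difficulty", "completed")],
            path, row.names = FALSE)
  invisible(path)
}

validate_metadata <- function(df) {
  required <- c("participant_id", "group", "task", "duration_s",
                "difficulty", "completed")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("metadata missing columns: ", paste(missing, collapse = ", "))
  if (!all(df$group %in% imu_groups())) stop("metadata contains unknown group")
  if (!all(df$task %in% imu_tasks())) stop("metadata contains unknown task")
  if (!all(df$difficulty %in% names(difficulty_levels())))
    stop("metadata difficulty must be one of ",
         paste(names(difficulty_levels()), collapse = "/"))
  df$completed <- as.logical(df$completed)
  df$difficulty_score <- unname(difficulty_levels()[df$difficulty])
  imp <- df$difficulty == "impossible"
  if (any(imp & df$completed))
    stop("impossible tasks cannot be marked completed")
  if (any(df$completed & !(df$duration_s > 0)))
    stop("completed trials must have positive duration_s")
  df
}
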