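#' Elementwise 3D vector norm
#'
#' Collapses a T x 3 signal (acceleration or angular velocity) into the time
#' series of its Euclidean norms, the basis of the movement-intensity
#' features.
#'
#' @param X Numeric T x 3 matrix.
#' @return Numeric vector of length T, non-negative.
#' @export
vector_norm_series <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) != 3) stop("X must have 3 columns")
  if (any(!is.finite(X))) stop("X must be finite")
  sqrt(rowSums(X^2))
}

#' Root mean square of a series
#'
#' @param x Numeric vector with at least one element.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  if (length(x) < 1) stop("rms of an empty series is undefined")
  if (any(!is.finite(x))) stop("x must be finite")
  sqrt(mean(x^2))
}

# Central-difference derivative with one-sided differences at the ends.
deriv_central <- function(x, dt) {
  T <- length(x)
  d <- numeric(T)
  d[1] <- (x[2] - x[1]) / dt
  d[T] <- (x[T] - x[T - 1]) / dt
  if (T > 2) d[2:(T - 1)] <- (x[3:T] - x[1:(T - 2)]) / (2 * dt)
  d
}

# T x 3 componentwise acceleration derivative (jerk components).
jerk_components <- function(acc, sample_rate) {
  acc <- as.matrix(acc)
  if (nrow(acc) < 3) stop("jerk requires at least 3 samples")
  if (ncol(acc) != 3) stop("acc must have 3 columns")
  dt <- 1 / sample_rate
  apply(acc, 2, deriv_central, dt = dt)
}

#' Sway jerkiness (integral form)
#'
#' Half the time-integral, over the trial, of the summed squared time
#' derivatives of the three acceleration components — a scalar
#' movement-smoothness index. Derivatives use central differences
#' (one-sided at the ends); the integral uses the trapezoidal rule.
#'
#' @param acc Numeric T x 3 acceleration matrix in m/s^2, T >= 3.
#' @param sample_rate Sampling frequency in Hz.
#' @return Scalar jerkiness, units m^2/s^5.
#' @export
jerk_scalar <- function(acc, sample_rate) {
  J <- jerk_components(acc, sample_rate)
  sq <- rowSums(J^2)
  t_axis <- (seq_len(nrow(J)) - 1) / sample_rate
  0.5 * pracma::trapz(t_axis, sq)
}

#' RMS sway jerkiness
#'
#' The RMS of the time series of 3D jerk norms (Euclidean norm of the
#' componentwise acceleration derivative). This is the `JERK_RMS` feature
#' that enters the feature matrix; [jerk_scalar()] is the companion
#' integral form.
#'
#' @inheritParams jerk_scalar
#' @return Scalar RMS jerk in m/s^3.
#' @export
jerk_rms <- function(acc, sample_rate) {
  J <- jerk_components(acc, sample_rate)
  rms(sqrt(rowSums(J^2)))
}

#' Segment-to-segment attenuation coefficient
#'
#' `AC = (1 - rms_upper / rms_lower) * 100`, comparing the RMS of the
#' acceleration-norm series of an upper body segment against a lower one.
#' Positive values indicate attenuation of accelerations from the lower to
#' the upper segment; negative values indicate amplification.
#'
#' @param rms_lower RMS of the lower segment (denominator), must be > 0.
#' @param rms_upper RMS of the upper segment, >= 0.
#' @return Percentage <= 100.
#' @export
attenuation_coefficient <- function(rms_lower, rms_upper) {
  if (!is.finite(rms_lower) || rms_lower <= 0)
    stop("rms_lower must be positive (degenerate lower-segment signal)")
  if (!is.finite(rms_upper) || rms_upper < 0)
    stop("rms_upper must be non-negative")
  (1 - rms_upper / rms_lower) * 100
}

#' Movement features for one participant x task
#'
#' Computes the per-trial variable roster from the five preprocessed sensor
#' recordings of one participant performing one task: per sensor the RMS of
#' the 3D linear-acceleration norm, the RMS of the 3D angular-velocity norm
#' and the RMS jerk; the three attenuation coefficients (trunk-head,
#' sacrum-head, sacrum-trunk) from the linear-acceleration norm RMS values;
#' and the task duration. For a task rated impossible (not completed) an
#' all-missing record is returned.
#'
#' @param recordings Named list of preprocessed [trial_recording()] objects,
#'   one per sensor in [imu_sensors()].
#' @param metadata One-row slice of the trial metadata (fields
#'   `participant_id, group, task, duration_s, difficulty, completed`).
#' @param require_preprocessed Assert that recordings went through
#'   [preprocess_trial()] (trim before filter); default `TRUE`.
#' @return A `feature_record`: list with `participant_id`, `group`, `task`,
#'   and `values` (named numeric vector of 19 variables, or `NULL` when the
#'   task was not completed).
#' @export
extract_trial_features <- function(recordings, metadata,
                                   require_preprocessed = TRUE) {
  rec0 <- list(participant_id = metadata$participant_id,
               group = metadata$group, task = metadata$task)
  if (!isTRUE(as.logical(metadata$completed))) {
    rec0$values <- NULL
    class(rec0) <- "feature_record"
    return(rec0)
  }
  missing_sensors <- setdiff(imu_sensors(), names(recordings))
  if (length(missing_sensors))
    stop("missing required sensor(s): ",
         paste(missing_sensors, collapse = ", "))
  task <- metadata$task
  vals <- c()
  acc_norm_rms <- c()
  for (s in imu_sensors()) {
    rec <- recordings[[s]]
    validate_trial_recording(rec)
    if (require_preprocessed && !isTRUE(attr(rec, "preprocessed")))
      stop("recording for sensor ", s, " is not preprocessed; ",
           "run preprocess_trial() (trim, then filter) first")
    a_rms <- rms(vector_norm_series(rec$acc))
    g_rms <- rms(vector_norm_series(rec$gyr))
    j_rms <- jerk_rms(rec$acc, rec$sample_rate)
    acc_norm_rms[s] <- a_rms
    vals[paste(task, s, "NormLinAcc_RMS", sep = "|")] <- a_rms
    vals[paste(task, s, "NormAngVel_RMS", sep = "|")] <- g_rms
    vals[paste(task, s, "JERK_RMS", sep = "|")] <- j_rms
  }
  for (ac in names(ac_pairs())) {
    pair <- ac_pairs()[[ac]]
    vals[paste(task, ac, sep = "|")] <-
      attenuation_coefficient(acc_norm_rms[[pair[["lower"]]]],
                              acc_norm_rms[[pair[["upper"]]]])
  }
  vals[paste(task, "duration", sep = "|")] <- metadata$duration_s
  rec0$values <- vals
  class(rec0) <- "feature_record"
  rec0
}

# Deterministic variable roster for one task: 5 sensors x 3 parameters,
# 3 attenuation coefficients, duration.
task_variables <- function(task) {
  c(as.vector(t(outer(imu_sensors(),
                      imu_parameters(),
                      function(s, p) paste(task, s, p, sep = "|")))),
    paste(task, names(ac_pairs()), sep = "|"),
    paste(task, "duration", sep = "|"))
}

#' Assemble the cohort feature matrix
#'
#' Builds the participants x variables matrix from per-trial feature records,
#' restricted to the selected tasks. Column order is deterministic: task,
#' then sensor, then parameter, then the attenuation coefficients and the
#' task duration. Cells for tasks a participant could not complete are
#' missing (`NA`), never zero.
#'
#' @param records List of `feature_record` objects (one per participant x
#'   task, see [extract_trial_features()]).
#' @param tasks Character vector of tasks to include (column blocks).
#' @return A `feature_matrix`: data frame with columns `participant_id`,
#'   `group`, then one column per variable; attribute `variables` holds the
#'   variable names in order.
#' @export
build_feature_matrix <- function(records, tasks) {
  if (!length(records)) stop("no feature records supplied")
  if (!length(tasks)) stop("no tasks selected")
  ids <- vapply(records, function(r) r$participant_id, character(1))
  grs <- vapply(records, function(r) r$group, character(1))
  tks <- vapply(records, function(r) r$task, character(1))
  if (anyDuplicated(paste(ids, tks)))
    stop("duplicate participant x task feature records")
  participants <- unique(ids)
  group_of <- setNames(grs, ids)[participants]
  variables <- unlist(lapply(tasks, task_variables), use.names = FALSE)
  M <- matrix(NA_real_, nrow = length(participants),
              ncol = length(variables),
              dimnames = list(participants, variables))
  for (r in records) {
    if (!r$task %in% tasks) next
    if (!is.null(r$values)) {
      known <- intersect(names(r$values), variables)
      M[r$participant_id, known] <- r$values[known]
    }
  }
  fm <- data.frame(participant_id = participants,
                   group = unname(group_of),
                   check.names = FALSE, stringsAsFactors = FALSE)
  fm <- cbind(fm, as.data.frame(M, check.names = FALSE))
  rownames(fm) <- NULL
  attr(fm, "variables") <- variables
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Variable names of a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @return Character vector of variable (column) names, excluding
#'   `participant_id` and `group`.
#' @export
feature_variables <- function(fm) {
  v <- attr(fm, "variables")
  if (is.null(v)) v <- setdiff(names(fm), c("participant_id", "group"))
  v
}

as_feature_values <- function(fm) {
  as.matrix(fm[, feature_variables(fm), drop = FALSE])
}

#' Write a feature matrix in wide and long form
#'
#' @param fm A `feature_matrix`.
#' @param path_wide,path_long Output CSV paths (`NULL` to skip one form).
#'   The long form has columns
#'   `participant_id, group, task, sensor, parameter, value` where
#'   attenuation coefficients and duration carry an empty sensor field.
#' @return Invisibly, the wide data frame.
#' @export
write_feature_matrix <- function(fm, path_wide = NULL, path_long = NULL) {
  if (!is.null(path_wide)) {
    dir.create(dirname(path_wide), recursive = TRUE, showWarnings = FALSE)
    write.csv(fm, path_wide, row.names = FALSE, na = "")
  }
  if (!is.null(path_long)) {
    vars <- feature_variables(fm)
    parts <- strsplit(vars, "|", fixed = TRUE)
    long <- do.call(rbind, lapply(seq_along(vars), function(i) {
      p <- parts[[i]]
      data.frame(participant_id = fm$participant_id, group = fm$group,
                 task = p[1],
                 sensor = if (length(p) == 3) p[2] else "",
                 parameter = p[length(p)],
                 value = fm[[vars[i]]],
                 stringsAsFactors = FALSE)
    }))
    dir.create(dirname(path_long), recursive = TRUE, showWarnings = FALSE)
    write.csv(long, path_long, row.names = FALSE, na = "")
  }
  invisible(fm)
}

#' Read a wide feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  fm <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  attr(fm, "variables") <- setdiff(names(fm), c("participant_id", "group"))
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}
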