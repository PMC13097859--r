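# Synthetic cohort generator: gravity-free oscillatory gait-like 6-axis
# signals with group-dependent amplitude, duration, smoothness and ordinal
# difficulty, plus a registry of planted ground-truth effects so every
# downstream stage can be validated without clinical recordings.

# Tasks whose foot signals share a participant-level locomotor latent factor.
locomotor_tasks <- function() {
  c("Heavy load", "Stairs", "Uneven ground", "Tray", "Walk",
    "Inclined plane", "Picture recognition", "Walk in the dark")
}

default_task_durations <- function() {
  c("Bed" = 8, "Pants" = 18, "Shoes" = 16, "Sorting" = 20,
    "Heavy load" = 14, "Bus" = 12, "Stairs" = 12, "Uneven ground" = 14,
    "Tray" = 12, "Walk" = 10, "Stepladder" = 10, "Wood beam" = 12,
    "Inclined plane" = 22, "Picture recognition" = 16,
    "Walk in the dark" = 12)
}

default_difficulty_base <- function() {
  base <- setNames(rep(0.2, length(imu_tasks())), imu_tasks())
  base[c("Pants", "Uneven ground", "Picture recognition",
         "Inclined plane", "Walk in the dark")] <- 0.6
  base["Wood beam"] <- 1.0
  base
}

empty_effects <- function() {
  data.frame(group = character(0), task = character(0),
             sensor = character(0), parameter = character(0),
             multiplier = numeric(0), stringsAsFactors = FALSE)
}

empty_difficulty_shifts <- function() {
  data.frame(group = character(0), task = character(0),
             shift = numeric(0), stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Assembles and validates the full parameterization of the synthetic
#' cohort: group sizes, task roster and per-task base durations, per-sensor
#' base signal amplitudes, the harmonic structure of the gait-like
#' oscillation, between-subject variability, the planted effect registry
#' (multiplicative group effects on intensity, smoothness or duration), and
#' the latent-normal threshold model for ordinal perceived difficulty. The
#' generator is a pure function of this configuration (including `seed`).
#'
#' @param n_per_group Participants per group (default 20, minimum 3).
#' @param tasks,sensors Task and sensor rosters.
#' @param sample_rate Sampling frequency, Hz (default 128).
#' @param step_freq_mean,step_freq_sd Participant step frequency, Hz
#'   (default 1.8 +- 0.1).
#' @param base_duration_s Named per-task base durations, seconds.
#' @param base_acc_amp,base_gyr_amp Named per-sensor base amplitudes of the
#'   fundamental harmonic (m/s^2, deg/s); feet largest, head smallest, so
#'   attenuation coefficients are positive at baseline.
#' @param harmonic_weights Relative amplitudes of the 1st-3rd step-frequency
#'   harmonics.
#' @param axis_weights Relative amplitude of the x, y, z axes.
#' @param jitter_freq_hz,jitter_rel High-frequency jitter component (below
#'   the 6 Hz analysis cut-off) whose relative amplitude controls movement
#'   smoothness, hence the jerk features.
#' @param noise_rel White-noise sd relative to the signal amplitude.
#' @param subject_sd Log-normal sd of the participant-level global amplitude
#'   factor.
#' @param loco_sd Log-normal sd of the participant-level locomotor factor
#'   applied to foot sensors during locomotor tasks (the planted common
#'   factor behind the first principal component).
#' @param sensor_sd Log-normal sd of the per-trial per-sensor amplitude
#'   wobble (drives attenuation-coefficient variability).
#' @param duration_subject_sd,duration_trial_sd Log-normal sds of the
#'   participant pace factor and the per-trial duration noise.
#' @param uv_var_inflation Multiplier on all between-subject sds for the UV
#'   group (UV is intermediate in mean but more heterogeneous).
#' @param effects Data frame `group, task, sensor, parameter, multiplier`
#'   (`sensor = "*"` matches all; parameter one of `NormLinAcc_RMS`,
#'   `NormAngVel_RMS`, `JERK_RMS`, `duration`). Multiplicative, > 0.
#' @param difficulty_base Named per-task latent difficulty for HS.
#' @param difficulty_shifts Data frame `group, task, shift` of latent
#'   difficulty shifts.
#' @param difficulty_noise_sd Latent noise sd of the threshold model.
#' @param difficulty_thresholds Three increasing cut-points mapping the
#'   latent score to easy/medium/difficult/impossible.
#' @param seed Master seed (integer).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_per_group = 20,
                              tasks = imu_tasks(),
                              sensors = imu_sensors(),
                              sample_rate = 128,
                              step_freq_mean = 1.8, step_freq_sd = 0.1,
                              base_duration_s = default_task_durations(),
                              base_acc_amp = c(HE = 0.7, TR = 0.9, SA = 1.2,
                                               LF = 3.0, RF = 3.0),
                              base_gyr_amp = c(HE = 25, TR = 30, SA = 40,
                                               LF = 150, RF = 150),
                              harmonic_weights = c(1, 0.5, 0.25),
                              axis_weights = c(1, 0.6, 0.4),
                              jitter_freq_hz = 5.2, jitter_rel = 0.45,
                              noise_rel = 0.05,
                              subject_sd = 0.05, loco_sd = 0.25,
                              sensor_sd = 0.10,
                              duration_subject_sd = 0.12,
                              duration_trial_sd = 0.10,
                              uv_var_inflation = 1.3,
                              effects = empty_effects(),
                              difficulty_base = default_difficulty_base(),
                              difficulty_shifts = empty_difficulty_shifts(),
                              difficulty_noise_sd = 0.8,
                              difficulty_thresholds = c(1, 2, 3),
                              seed = 1L) {
  cfg <- as.list(environment())
  if (n_per_group < 3) stop("n_per_group must be at least 3")
  if (!all(tasks %in% imu_tasks())) stop("unknown task in config")
  if (!all(sensors %in% imu_sensors())) stop("unknown sensor in config")
  if (!all(tasks %in% names(base_duration_s)))
    stop("base_duration_s must cover every task")
  if (any(base_duration_s <= 0)) stop("base durations must be positive")
  if (nrow(effects)) {
    if (!all(c("group", "task", "sensor", "parameter", "multiplier") %in%
             names(effects)))
      stop("effects needs columns group, task, sensor, parameter, multiplier")
    if (any(effects$multiplier <= 0))
      stop("effect multipliers must be positive")
    if (!all(effects$group %in% imu_groups()))
      stop("unknown group in effects")
    if (!all(effects$task %in% tasks)) stop("unknown task in effects")
    if (!all(effects$sensor %in% c("*", imu_sensors())))
      stop("unknown sensor in effects")
    if (!all(effects$parameter %in% c(imu_parameters(), "duration")))
      stop("unknown parameter in effects")
  }
  if (!identical(order(difficulty_thresholds),
                 seq_along(difficulty_thresholds)) ||
      length(difficulty_thresholds) != 3)
    stop("difficulty_thresholds must be 3 increasing cut-points")
  if (nrow(difficulty_shifts) &&
      !all(difficulty_shifts$group %in% imu_groups()))
    stop("unknown group in difficulty_shifts")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "simulation_config"
  cfg
}

# Product of all matching effect multipliers for one cell.
effect_multiplier <- function(cfg, group, task, sensor, parameter) {
  e <- cfg$effects
  if (!nrow(e)) return(1)
  hit <- e$group == group & e$task == task & e$parameter == parameter &
    (e$sensor == "*" | e$sensor == sensor)
  prod(e$multiplier[hit])
}

# Deterministic per-entity seed derivation (kept below 2^31).
derive_seed <- function(base, ...) {
  ix <- c(...)
  s <- as.double(base) %% 2147483629
  for (k in seq_along(ix))
    s <- (s * 48271 + as.double(ix[k]) * 2654435761) %% 2147483629
  as.integer(s)
}

# Participant-level latent parameters. UV draws use inflated sds.
participant_params <- function(cfg, group, p_idx) {
  set.seed(derive_seed(cfg$seed, 1L, p_idx))
  infl <- if (group == "UV") cfg$uv_var_inflation else 1
  list(group = group, p_idx = p_idx,
       step_freq = max(0.5, rnorm(1, cfg$step_freq_mean,
                                  cfg$step_freq_sd * infl)),
       amp_mult = exp(rnorm(1, 0, cfg$subject_sd * infl)),
       loco_mult = exp(rnorm(1, 0, cfg$loco_sd * infl)),
       dur_mult = exp(rnorm(1, 0, cfg$duration_subject_sd * infl)))
}

#' Simulate one trial recording
#'
#' Builds the gravity-free oscillation for one participant x task x sensor:
#' per axis, the sum of the first three harmonics of the participant's step
#' frequency, a high-frequency jitter tone (smoothness degradation) and
#' white noise; angular velocity analogous in deg/s. Amplitudes combine the
#' sensor base amplitude, planted group effect multipliers, the
#' participant's global (and, for feet during locomotor tasks, locomotor)
#' factors, and a per-trial sensor wobble. Deterministic given `seed`.
#'
#' @param pp Participant parameter list (internal; see
#'   [simulate_cohort()]).
#' @param task,sensor Task and sensor names.
#' @param cfg A [simulation_config()].
#' @param duration_s Trial duration, seconds.
#' @param seed Integer seed for this trial.
#' @param participant_id Identifier stored on the recording.
#' @return A [trial_recording()].
#' @export
simulate_trial <- function(pp, task, sensor, cfg, duration_s,
                           seed = cfg$seed,
                           participant_id = sprintf("%s%02d", pp$group,
                                                    pp$p_idx)) {
  set.seed(as.integer(seed))
  fs <- cfg$sample_rate
  T <- max(3L, round(duration_s * fs))
  t <- (seq_len(T) - 1) / fs
  loco <- sensor %in% c("LF", "RF") && task %in% locomotor_tasks()
  wobble <- exp(rnorm(1, 0, cfg$sensor_sd))
  shared <- pp$amp_mult * (if (loco) pp$loco_mult else 1) * wobble
  amp_acc <- cfg$base_acc_amp[[sensor]] * shared *
    effect_multiplier(cfg, pp$group, task, sensor, "NormLinAcc_RMS")
  amp_gyr <- cfg$base_gyr_amp[[sensor]] * shared *
    effect_multiplier(cfg, pp$group, task, sensor, "NormAngVel_RMS")
  jit_mult <- effect_multiplier(cfg, pp$group, task, sensor, "JERK_RMS")
  f <- pp$step_freq
  one_block <- function(amp, jitter_rel) {
    X <- matrix(0, T, 3)
    for (ax in 1:3) {
      a_ax <- amp * cfg$axis_weights[ax]
      for (h in seq_along(cfg$harmonic_weights)) {
        X[, ax] <- X[, ax] + a_ax * cfg$harmonic_weights[h] *
          sin(2 * pi * h * f * t + runif(1, 0, 2 * pi))
      }
      X[, ax] <- X[, ax] + a_ax * jitter_rel * jit_mult *
        sin(2 * pi * cfg$jitter_freq_hz * t + runif(1, 0, 2 * pi))
      X[, ax] <- X[, ax] + rnorm(T, 0, cfg$noise_rel * a_ax)
    }
    X
  }
  acc <- one_block(amp_acc, cfg$jitter_rel)
  gyr <- one_block(amp_gyr, cfg$jitter_rel * 0.5)
  trial_recording(participant_id, pp$group, task, sensor, acc, gyr,
                  sample_rate = fs, duration_s = duration_s)
}

# Draw duration, difficulty and completion for one participant x task.
draw_task_outcome <- function(pp, task, cfg, seed) {
  set.seed(seed)
  shift <- 0
  ds <- cfg$difficulty_shifts
  if (nrow(ds)) {
    hit <- ds$group == pp$group & ds$task == task
    if (any(hit)) shift <- sum(ds$shift[hit])
  }
  latent <- cfg$difficulty_base[[task]] + shift +
    rnorm(1, 0, cfg$difficulty_noise_sd *
            (if (pp$group == "UV") cfg$uv_var_inflation else 1))
  level <- 1L + sum(latent > cfg$difficulty_thresholds)
  completed <- level < 4L
  dur <- cfg$base_duration_s[[task]] * pp$dur_mult *
    effect_multiplier(cfg, pp$group, task, "*", "duration") *
    exp(rnorm(1, 0, cfg$duration_trial_sd))
  list(duration_s = dur,
       difficulty = names(difficulty_levels())[level],
       completed = completed)
}

#' Simulate a full cohort
#'
#' Generates metadata (duration, perceived difficulty, completion) for every
#' participant x task and, unless `signals = FALSE`, the 6-axis recordings
#' for every completed trial on the analysis sensors. Tasks rated impossible
#' yield metadata-only entries. Generation is a pure function of the
#' configuration: per-participant and per-trial seeds are derived
#' deterministically from the master seed, so any subset regenerates
#' identically.
#'
#' @param cfg A [simulation_config()].
#' @param signals Generate signal recordings (default `TRUE`); `FALSE`
#'   produces metadata only (cheap, e.g. for task selection).
#' @param tasks_signals Tasks for which to generate signals (default: all
#'   configured tasks); metadata always covers every task.
#' @param write_dir Optional directory: writes the on-disk layout
#'   `<dir>/<participant>/<task>/<sensor>.csv` plus `metadata.csv`.
#' @return A `synthetic_cohort` list: `trials` (nested
#'   participant -> task -> sensor list of [trial_recording()], `NULL`
#'   without signals), `metadata` data frame, `ground_truth` (attribute of
#'   the config's effect registry, see [default_paper_scenario()]), and
#'   `config`.
#' @export
simulate_cohort <- function(cfg, signals = TRUE, tasks_signals = cfg$tasks,
                            write_dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  meta_rows <- list()
  trials <- if (signals) list() else NULL
  p_global <- 0L
  for (g in imu_groups()) {
    for (i in seq_len(cfg$n_per_group)) {
      p_global <- p_global + 1L
      pp <- participant_params(cfg, g, p_global)
      pid <- sprintf("%s%02d", g, i)
      if (signals) trials[[pid]] <- list()
      for (ti in seq_along(cfg$tasks)) {
        task <- cfg$tasks[ti]
        out <- draw_task_outcome(pp, task, cfg,
                                 derive_seed(cfg$seed, 2L, p_global, ti))
        meta_rows[[length(meta_rows) + 1L]] <- data.frame(
          participant_id = pid, group = g, task = task,
          duration_s = out$duration_s, difficulty = out$difficulty,
          completed = out$completed, stringsAsFactors = FALSE)
        if (signals && out$completed && task %in% tasks_signals) {
          trials[[pid]][[task]] <- lapply(
            setNames(nm = cfg$sensors), function(s) {
              si <- match(s, imu_sensors())
              simulate_trial(pp, task, s, cfg, out$duration_s,
                             seed = derive_seed(cfg$seed, 3L, p_global,
                                                ti, si),
                             participant_id = pid)
            })
        }
      }
    }
  }
  metadata <- do.call(rbind, meta_rows)
  cohort <- structure(list(trials = trials, metadata = metadata,
                           ground_truth = attr(cfg, "ground_truth"),
                           config = cfg),
                      class = "synthetic_cohort")
  if (!is.null(write_dir)) write_cohort(cohort, write_dir)
  cohort
}

#' Write a cohort to the on-disk layout
#'
#' @param cohort A `synthetic_cohort` with signals.
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_metadata(cohort$metadata, file.path(dir, "metadata.csv"))
  for (pid in names(cohort$trials)) {
    for (task in names(cohort$trials[[pid]])) {
      for (s in names(cohort$trials[[pid]][[task]])) {
        write_trial(cohort$trials[[pid]][[task]][[s]],
                    file.path(dir, pid, task, paste0(s, ".csv")))
      }
    }
  }
  invisible(dir)
}

#' Read a cohort from the on-disk layout
#'
#' Expects `<dir>/metadata.csv` and, per completed trial,
#' `<dir>/<participant>/<task>/<sensor>.csv`. This is also the entry point
#' for external (non-synthetic) cohorts stored in the trial-CSV dialect.
#'
#' @param dir Cohort directory.
#' @param sensors Sensors to load (default: the five analysis sensors).
#' @return A `synthetic_cohort`-shaped list (`ground_truth` and `config`
#'   are `NULL` for external data).
#' @export
read_cohort <- function(dir, sensors = imu_sensors()) {
  metadata <- read_metadata(file.path(dir, "metadata.csv"))
  trials <- list()
  for (r in seq_len(nrow(metadata))) {
    if (!metadata$completed[r]) next
    pid <- metadata$participant_id[r]
    task <- metadata$task[r]
    tdir <- file.path(dir, pid, task)
    if (!dir.exists(tdir)) next
    trials[[pid]][[task]] <- lapply(setNames(nm = sensors), function(s) {
      f <- file.path(tdir, paste0(s, ".csv"))
      if (!file.exists(f)) stop("missing trial file: ", f)
      read_trial(f)
    })
  }
  structure(list(trials = trials, metadata = metadata,
                 ground_truth = NULL, config = NULL),
            class = "synthetic_cohort")
}

#' Default study-like scenario with planted effects
#'
#' The configuration used throughout the package's validation: three groups
#' of 20, the full 15-task roster, and a ground-truth registry of effects
#' mirroring the qualitative clinical picture — reduced foot-signal
#' intensity in patients during challenging locomotion (uneven ground,
#' inclined plane, walking in the dark), reduced trunk intensity on the
#' inclined plane, longer patient durations on the demanding tasks, elevated
#' bilateral-patient head jerk while putting on pants and sacrum jerk on the
#' wood beam, and higher perceived difficulty (with occasional
#' impossible-task ratings) on the same tasks. Walking in the dark carries a
#' difficulty effect but deliberately no duration effect. UV effects are
#' intermediate between BV and HS with inflated variance.
#'
#' @param n_per_group Participants per group (default 20).
#' @param seed Master seed (default 1).
#' @return A [simulation_config()] whose attribute `ground_truth` is a data
#'   frame of planted variables (`variable`, `group`, `multiplier`,
#'   `direction`).
#' @export
default_paper_scenario <- function(n_per_group = 20, seed = 1L) {
  loco3 <- c("Uneven ground", "Inclined plane", "Walk in the dark")
  eff <- list()
  add <- function(group, task, sensor, parameter, multiplier) {
    eff[[length(eff) + 1L]] <<- data.frame(
      group = group, task = task, sensor = sensor, parameter = parameter,
      multiplier = multiplier, stringsAsFactors = FALSE)
  }
  for (task in loco3) {
    for (s in c("LF", "RF")) {
      for (p in c("NormLinAcc_RMS", "NormAngVel_RMS")) {
        add("BV", task, s, p, 0.65)
        add("UV", task, s, p, 0.80)
      }
    }
  }
  add("BV", "Inclined plane", "TR", "NormLinAcc_RMS", 0.70)
  add("UV", "Inclined plane", "TR", "NormLinAcc_RMS", 0.82)
  add("BV", "Picture recognition", "RF", "NormAngVel_RMS", 0.70)
  dur_tasks <- c("Pants", "Heavy load", "Uneven ground", "Stepladder",
                 "Wood beam", "Inclined plane")
  for (task in dur_tasks) {
    add("BV", task, "*", "duration", 1.45)
    add("UV", task, "*", "duration", 1.15)
  }
  add("BV", "Picture recognition", "*", "duration", 1.25)
  add("BV", "Pants", "HE", "JERK_RMS", 2.0)
  add("BV", "Wood beam", "SA", "JERK_RMS", 2.0)
  effects <- do.call(rbind, eff)

  sel7 <- c("Pants", "Heavy load", "Uneven ground", "Stepladder",
            "Wood beam", "Inclined plane", "Picture recognition")
  shifts <- rbind(
    data.frame(group = "BV", task = sel7, shift = 1.4),
    data.frame(group = "UV", task = sel7, shift = 0.7),
    data.frame(group = "BV", task = "Walk in the dark", shift = 1.0),
    data.frame(group = "UV", task = "Walk in the dark", shift = 0.4))

  cfg <- simulation_config(n_per_group = n_per_group, effects = effects,
                           difficulty_shifts = shifts, seed = seed)
  sig <- effects[effects$parameter != "duration", ]
  gt_sig <- data.frame(
    variable = paste(sig$task, sig$sensor, sig$parameter, sep = "|"),
    group = sig$group, multiplier = sig$multiplier,
    stringsAsFactors = FALSE)
  dur <- effects[effects$parameter == "duration", ]
  gt_dur <- data.frame(
    variable = paste(dur$task, "duration", sep = "|"),
    group = dur$group, multiplier = dur$multiplier,
    stringsAsFactors = FALSE)
  gt <- rbind(gt_sig, gt_dur)
  gt$direction <- ifelse(gt$multiplier < 1, paste0(gt$group, " < HS"),
                         paste0(gt$group, " > HS"))
  attr(cfg, "ground_truth") <- gt
  cfg
}

#' Serialize / restore a simulation configuration
#'
#' JSON round-trip for [simulation_config()] objects (including the effect
#' registry and any ground-truth attribute), so scenarios can be stored
#' alongside pipeline configurations and rerun exactly.
#'
#' @param cfg A `simulation_config`.
#' @param path JSON file path.
#' @return `write_simulation_config()` returns `path` invisibly;
#'   `read_simulation_config()` returns the restored `simulation_config`.
#' @export
write_simulation_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "simulation_config"))
  payload <- unclass(cfg)
  # named vectors as JSON objects, so names survive the round trip
  for (nm in c("base_duration_s", "base_acc_amp", "base_gyr_amp",
               "difficulty_base"))
    payload[[nm]] <- as.list(payload[[nm]])
  payload$ground_truth <- attr(cfg, "ground_truth")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt <- payload$ground_truth
  payload$ground_truth <- NULL
  for (nm in c("base_duration_s", "base_acc_amp", "base_gyr_amp",
               "difficulty_base"))
    payload[[nm]] <- unlist(payload[[nm]])
  for (nm in c("effects", "difficulty_shifts"))
    payload[[nm]] <- as.data.frame(payload[[nm]],
                                   stringsAsFactors = FALSE)
  cfg <- do.call(simulation_config, payload)
  if (!is.null(gt))
    attr(cfg, "ground_truth") <- as.data.frame(gt,
                                               stringsAsFactors = FALSE)
  cfg
}
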