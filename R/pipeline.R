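#' Extract the feature matrix from a cohort
#'
#' Preprocesses every completed trial (edge trim, then zero-phase low-pass —
#' the canonical order) and computes the per-trial feature roster, then
#' assembles the participants x variables matrix for the requested tasks.
#' Works from an in-memory cohort ([simulate_cohort()]) or a cohort
#' directory ([read_cohort()]).
#'
#' @param cohort A `synthetic_cohort` (or the result of [read_cohort()]).
#' @param tasks Tasks to include (default: every task present).
#' @param trim_fraction,filter_order,cutoff_hz Preprocessing settings.
#' @return A `feature_matrix`.
#' @export
extract_cohort_features <- function(cohort,
                                    tasks = unique(cohort$metadata$task),
                                    trim_fraction = 0.05, filter_order = 4,
                                    cutoff_hz = 6) {
  metadata <- validate_metadata(cohort$metadata)
  records <- list()
  for (r in seq_len(nrow(metadata))) {
    md <- metadata[r, ]
    if (!md$task %in% tasks) next
    if (!md$completed) {
      records[[length(records) + 1L]] <-
        extract_trial_features(list(), md)
      next
    }
    recs <- cohort$trials[[md$participant_id]][[md$task]]
    if (is.null(recs))
      stop("no recordings for completed trial ", md$participant_id,
           " / ", md$task)
    recs <- lapply(recs[imu_sensors()], preprocess_trial,
                   fraction = trim_fraction, order = filter_order,
                   cutoff_hz = cutoff_hz)
    records[[length(records) + 1L]] <- extract_trial_features(recs, md)
  }
  build_feature_matrix(records, tasks)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the staged analysis: preprocessing settings,
#' the significance level, the forced-inclusion task list, the imputation
#' strategy, permutation/bootstrap iteration counts, the loading-selection
#' rule and the cumulative-VAF threshold, plus a master seed from which all
#' per-stage seeds are derived deterministically. Round-trips losslessly
#' through JSON.
#'
#' @param alpha Significance level (default 0.05).
#' @param trim_fraction,filter_order,cutoff_hz Preprocessing settings.
#' @param forced_tasks Force-included tasks (default `"Walk in the dark"`).
#' @param imputation One of `"group_median"`, `"overall_median"`,
#'   `"complete_case"`.
#' @param n_perm,n_boot Permutation and bootstrap iteration counts
#'   (default 1000 each).
#' @param loading_pct,loading_cap Loading-selection rule (default top 10%,
#'   max 10 per component).
#' @param vaf_threshold Cumulative-VAF cut (default 0.5).
#' @param seed Master seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05, trim_fraction = 0.05,
                            filter_order = 4, cutoff_hz = 6,
                            forced_tasks = "Walk in the dark",
                            imputation = "group_median",
                            n_perm = 1000, n_boot = 1000,
                            loading_pct = 0.10, loading_cap = 10,
                            vaf_threshold = 0.5, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(alpha > 0, alpha <= 1,
            trim_fraction >= 0, trim_fraction < 0.5,
            filter_order >= 1, cutoff_hz > 0,
            n_perm >= 1, n_boot >= 1,
            loading_pct > 0, loading_pct <= 1, loading_cap >= 1,
            vaf_threshold > 0, vaf_threshold <= 1)
  if (!imputation %in% c("group_median", "overall_median", "complete_case"))
    stop("unknown imputation strategy: ", imputation)
  unknown <- setdiff(forced_tasks, imu_tasks())
  if (length(unknown))
    stop("unknown forced task(s): ", paste(unknown, collapse = ", "))
  cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the staged analysis end to end
#'
#' Task selection (dual criterion on duration and perceived difficulty) from
#' the metadata; feature extraction for the selected tasks; group-median
#' imputation and standardization; PCA with permutation-based retention and
#' the cumulative-VAF cut; top-loading variable selection; bootstrap
#' stability of the final components; and the three-group discriminant
#' screen of the selected variables. When `out_dir` is given, every stage's
#' interface files plus a machine-readable run manifest are written.
#'
#' @param cohort A `synthetic_cohort` (in memory or from [read_cohort()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A `pipeline_result` list: `task_selection`, `features`,
#'   `features_imputed`, `pca`, `retention`, `loading_selection`,
#'   `stability`, `screen`, `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()

  metadata <- cohort$metadata
  sel <- select_tasks(group_samples(metadata, "duration"),
                      group_samples(metadata, "difficulty"),
                      alpha = config$alpha, forced = config$forced_tasks)
  tasks <- sel$task[sel$selected]
  if (!length(tasks)) stop("no task passed the dual selection criterion")

  fm <- extract_cohort_features(cohort, tasks = tasks,
                                trim_fraction = config$trim_fraction,
                                filter_order = config$filter_order,
                                cutoff_hz = config$cutoff_hz)
  fmi <- impute_missing(fm, config$imputation)
  fmz <- standardize(fmi)

  model <- fit_pca(fmz)
  perm <- permutation_vaf_test(fmz, n_perm = config$n_perm,
                               alpha = config$alpha,
                               seed = derive_seed(config$seed, 11L))
  k_final <- cumulative_vaf_cut(model$vaf, config$vaf_threshold,
                                perm$retained)
  loadsel <- if (k_final > 0)
    select_loading_variables(model, k_final, pct = config$loading_pct,
                             cap = config$loading_cap) else NULL
  stability <- if (k_final > 0)
    bootstrap_stability(fmi, model, k_final, n_boot = config$n_boot,
                        seed = derive_seed(config$seed, 12L)) else NULL

  screen <- if (!is.null(loadsel)) {
    comp_of <- unlist(lapply(names(loadsel$per_component), function(pc)
      setNames(rep(pc, nrow(loadsel$per_component[[pc]])),
               loadsel$per_component[[pc]]$variable)))
    comp_of <- comp_of[!duplicated(names(comp_of))]
    screen_variables(fmi, loadsel$union, alpha = config$alpha,
                     components = comp_of)
  } else screen_variables(fmi, character(0))

  result <- structure(
    list(task_selection = sel, tasks = tasks, features = fm,
         features_imputed = fmi, pca = model, retention = perm,
         n_components = k_final, loading_selection = loadsel,
         stability = stability, screen = screen, config = config,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' Write all stage outputs and the run manifest
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_task_selection(result$task_selection,
                       file.path(out_dir, "task_selection.csv"))
  write_feature_matrix(result$features,
                       path_wide = file.path(out_dir, "features_wide.csv"),
                       path_long = file.path(out_dir, "features_long.csv"))
  model <- result$pca
  ld <- data.frame(variable = model$variables, model$loadings,
                   check.names = FALSE)
  write.csv(ld, file.path(out_dir, "pca_loadings.csv"), row.names = FALSE)
  pca_report <- list(
    vaf = model$vaf,
    permutation_retained = result$retention$retained,
    final_components = result$n_components,
    cumulative_vaf = if (result$n_components > 0)
      sum(model$vaf[seq_len(result$n_components)]) else 0,
    thresholds = as.list(result$loading_selection$thresholds),
    selected = lapply(result$loading_selection$per_component,
                      function(d) d$variable),
    union = result$loading_selection$union)
  jsonlite::write_json(pca_report, file.path(out_dir, "pca_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(result$stability)) {
    st <- result$stability
    st$n_boot <- attr(st, "n_boot")
    st$seed <- attr(st, "seed")
    write.csv(st, file.path(out_dir, "stability.csv"), row.names = FALSE)
  }
  write_screen(result$screen, file.path(out_dir, "screen.csv"))
  cfg <- result$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("imusway")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(cfg),
    n_participants = nrow(result$features),
    n_tasks_selected = length(result$tasks),
    n_variables = length(feature_variables(result$features)),
    n_components = result$n_components,
    elapsed_s = result$elapsed_s)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  tasks selected:", length(x$tasks),
      sprintf("(%s)\n", paste(x$tasks, collapse = ", ")))
  cat("  variables:", length(feature_variables(x$features)), "\n")
  cat(sprintf("  components: %d permutation-retained, %d after %d%% VAF cut\n",
              x$retention$retained, x$n_components,
              round(100 * x$config$vaf_threshold)))
  if (!is.null(x$loading_selection))
    cat("  selected variables (union):", length(x$loading_selection$union),
        "\n")
  cat("  significant in screen:", sum(x$screen$significant), "of",
      nrow(x$screen), "\n")
  invisible(x)
}

# ---- file-based stage commands (thin CLI layer) ---------------------------

#' File-based pipeline stages
#'
#' Thin command-style wrappers chaining the module functions through the
#' on-disk interface formats, for shell use (see `inst/cli/imusway.R`).
#' `cmd_simulate` writes a synthetic cohort; `cmd_extract` reads a cohort
#' directory and writes the wide/long feature matrices; `cmd_select_tasks`
#' reads `metadata.csv` and writes the selection report; `cmd_pca` reads the
#' features and selection and writes the PCA report, loadings and stability
#' tables; `cmd_screen` reads the PCA report and features and writes the
#' discriminant screen; `cmd_run_all` chains everything via
#' [run_pipeline()]. Each stage fails with a named missing artifact if its
#' inputs are absent.
#'
#' @param in_dir Cohort directory (trial CSVs + `metadata.csv`).
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param sim_config A [simulation_config()] (for `cmd_simulate`).
#' @return Invisibly, the main artifact path of the stage.
#' @name pipeline_cli
NULL

require_artifact <- function(path, what) {
  if (!file.exists(path))
    stop("missing ", what, ": ", path, call. = FALSE)
  path
}

#' @rdname pipeline_cli
#' @export
cmd_simulate <- function(sim_config, out_dir) {
  simulate_cohort(sim_config, write_dir = out_dir)
  invisible(out_dir)
}

#' @rdname pipeline_cli
#' @export
cmd_extract <- function(in_dir, out_dir, config = pipeline_config()) {
  require_artifact(file.path(in_dir, "metadata.csv"), "metadata table")
  cohort <- read_cohort(in_dir)
  fm <- extract_cohort_features(cohort,
                                trim_fraction = config$trim_fraction,
                                filter_order = config$filter_order,
                                cutoff_hz = config$cutoff_hz)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_matrix(fm,
                       path_wide = file.path(out_dir, "features_wide.csv"),
                       path_long = file.path(out_dir, "features_long.csv"))
  invisible(file.path(out_dir, "features_wide.csv"))
}

#' @rdname pipeline_cli
#' @export
cmd_select_tasks <- function(in_dir, out_dir, config = pipeline_config()) {
  md <- read_metadata(require_artifact(file.path(in_dir, "metadata.csv"),
                                       "metadata table"))
  sel <- select_tasks(group_samples(md, "duration"),
                      group_samples(md, "difficulty"),
                      alpha = config$alpha, forced = config$forced_tasks)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_task_selection(sel, file.path(out_dir, "task_selection.csv"))
  invisible(file.path(out_dir, "task_selection.csv"))
}

#' @rdname pipeline_cli
#' @export
cmd_pca <- function(out_dir, config = pipeline_config()) {
  fm <- read_feature_matrix(
    require_artifact(file.path(out_dir, "features_wide.csv"),
                     "feature matrix (run the extract stage first)"))
  selp <- file.path(out_dir, "task_selection.csv")
  if (file.exists(selp)) {
    sel <- read.csv(selp, stringsAsFactors = FALSE)
    keep_tasks <- sel$task[sel$selected]
    vars <- feature_variables(fm)
    keep <- vapply(strsplit(vars, "|", fixed = TRUE),
                   function(p) p[1] %in% keep_tasks, logical(1))
    fm <- fm[, c("participant_id", "group", vars[keep]), drop = FALSE]
    attr(fm, "variables") <- vars[keep]
    class(fm) <- c("feature_matrix", "data.frame")
  }
  fmi <- impute_missing(fm, config$imputation)
  fmz <- standardize(fmi)
  model <- fit_pca(fmz)
  perm <- permutation_vaf_test(fmz, n_perm = config$n_perm,
                               alpha = config$alpha,
                               seed = derive_seed(config$seed, 11L))
  k <- cumulative_vaf_cut(model$vaf, config$vaf_threshold, perm$retained)
  if (k < 1) stop("no component retained")
  loadsel <- select_loading_variables(model, k, pct = config$loading_pct,
                                      cap = config$loading_cap)
  stab <- bootstrap_stability(fmi, model, k, n_boot = config$n_boot,
                              seed = derive_seed(config$seed, 12L))
  ld <- data.frame(variable = model$variables, model$loadings,
                   check.names = FALSE)
  write.csv(ld, file.path(out_dir, "pca_loadings.csv"), row.names = FALSE)
  write.csv(stab, file.path(out_dir, "stability.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(vaf = model$vaf, permutation_retained = perm$retained,
         final_components = k,
         thresholds = as.list(loadsel$thresholds),
         selected = lapply(loadsel$per_component, function(d) d$variable),
         union = loadsel$union),
    file.path(out_dir, "pca_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(out_dir, "pca_report.json"))
}

#' @rdname pipeline_cli
#' @export
cmd_screen <- function(out_dir, config = pipeline_config()) {
  rpt <- jsonlite::read_json(
    require_artifact(file.path(out_dir, "pca_report.json"),
                     "PCA report (run the pca stage first)"),
    simplifyVector = TRUE)
  fm <- read_feature_matrix(
    require_artifact(file.path(out_dir, "features_wide.csv"),
                     "feature matrix (run the extract stage first)"))
  fmi <- impute_missing(fm, config$imputation)
  comp_of <- unlist(lapply(names(rpt$selected), function(pc)
    setNames(rep(pc, length(rpt$selected[[pc]])), rpt$selected[[pc]])))
  comp_of <- comp_of[!duplicated(names(comp_of))]
  scr <- screen_variables(fmi, rpt$union, alpha = config$alpha,
                          components = comp_of)
  write_screen(scr, file.path(out_dir, "screen.csv"))
  invisible(file.path(out_dir, "screen.csv"))
}

#' @rdname pipeline_cli
#' @export
cmd_run_all <- function(in_dir, out_dir, config = pipeline_config()) {
  require_artifact(file.path(in_dir, "metadata.csv"), "metadata table")
  cohort <- read_cohort(in_dir)
  run_pipeline(cohort, config, out_dir = out_dir)
  invisible(file.path(out_dir, "manifest.json"))
}
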