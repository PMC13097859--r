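#' Kruskal-Wallis rank test across the three groups
#'
#' Thin, validated wrapper around [stats::kruskal.test()] for named lists of
#' group samples. The H statistic carries the usual tie correction; the
#' p-value comes from the chi-square distribution with `k - 1` degrees of
#' freedom. When every observation is identical the test is undefined and
#' the convention `H = 0, p = 1` is returned.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, >= 2
#'   observations each).
#' @return List with elements `H`, `p`, `df` and `n`.
#' @export
kruskal_wallis <- function(groups) {
  check_group_samples(groups)
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = length(groups) - 1L, n = length(x)))
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), n = length(x))
}

check_group_samples <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("groups must be a list of at least 2 sample vectors")
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop("each group needs at least 2 observations")
  if (any(!vapply(groups, function(g) all(is.finite(g)), logical(1))))
    stop("group samples must be finite")
  invisible(sizes)
}

#' Dunn's post-hoc test with Holm correction
#'
#' Pairwise z statistics from the pooled ranks of all groups, with the
#' standard tie correction, following a Kruskal-Wallis test:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) *
#' (1/n_i + 1/n_j))`. Two-sided p-values are Holm-adjusted within the
#' family of all pairwise comparisons.
#'
#' @param groups Named list of numeric group samples (same data the
#'   Kruskal-Wallis test was run on).
#' @return Data frame with one row per pair: `pair`, `z`, `p`, `p_holm`.
#' @export
dunn_posthoc <- function(groups) {
  sizes <- check_group_samples(groups)
  k <- length(groups)
  gnames <- names(groups)
  if (is.null(gnames)) gnames <- paste0("G", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(gnames, lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, factor(g, levels = gnames), mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2_base <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(gnames, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(sigma2_base * (1 / sizes[[i]] + 1 / sizes[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  out <- data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
                    z = res["z", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_holm <- holm_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Holm step-down adjustment
#'
#' Validated wrapper around `p.adjust(method = "holm")`: step-down with
#' monotonicity enforcement, capped at 1, order-preserving.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(pvals) {
  if (!is.numeric(pvals) || any(!is.finite(pvals)) ||
      any(pvals < 0 | pvals > 1))
    stop("p-values must be finite and in [0, 1]")
  p.adjust(pvals, method = "holm")
}

#' Build per-task group samples from trial metadata
#'
#' For `parameter = "duration"` only completed trials contribute (a task
#' rated impossible has no duration observation); for
#' `parameter = "difficulty"` every trial contributes its ordinal score 1-4.
#'
#' @param metadata Metadata data frame (see [read_metadata()]).
#' @param parameter `"duration"` or `"difficulty"`.
#' @param tasks Tasks to include (default: all present).
#' @return Named list (by task) of named lists (by group) of numeric samples.
#' @export
group_samples <- function(metadata, parameter = c("duration", "difficulty"),
                          tasks = unique(metadata$task)) {
  parameter <- match.arg(parameter)
  metadata <- validate_metadata(metadata)
  out <- lapply(tasks, function(tk) {
    sub <- metadata[metadata$task == tk, ]
    lapply(setNames(nm = imu_groups()), function(g) {
      rows <- sub[sub$group == g, ]
      if (parameter == "duration") rows$duration_s[rows$completed]
      else as.numeric(rows$difficulty_score)
    })
  })
  names(out) <- tasks
  out
}

#' Dual-criterion task selection
#'
#' A task enters the analysis set only if the three groups differ
#' significantly (Kruskal-Wallis, `p < alpha`) in **both** task duration and
#' perceived difficulty. Tasks on the `forced` list are included regardless,
#' flagged `forced = TRUE` (clinical relevance overriding the statistical
#' rule). Dunn-Holm pairwise p-values are reported only where the omnibus
#' test is significant.
#'
#' @param durations,difficulties Per-task group samples as produced by
#'   [group_samples()].
#' @param alpha Significance level (default 0.05).
#' @param forced Character vector of force-included tasks (default
#'   `"Walk in the dark"`).
#' @return A `task_selection` data frame: one row per task with columns
#'   `task`, `p_duration`, `p_difficulty`, the six Dunn-Holm pairwise
#'   p-values (`<param>_BV_HS` etc., `NA` where the omnibus test was not
#'   significant), `selected` and `forced`.
#' @export
select_tasks <- function(durations, difficulties, alpha = 0.05,
                         forced = "Walk in the dark") {
  tasks <- names(durations)
  if (!identical(tasks, names(difficulties)))
    stop("durations and difficulties must cover the same tasks")
  unknown <- setdiff(forced, imu_tasks())
  if (length(unknown))
    stop("unknown forced task(s): ", paste(unknown, collapse = ", "))
  pair_cols <- c("BV_HS", "UV_HS", "BV_UV")
  one_param <- function(samples) {
    if (any(lengths(samples) < 2)) {
      # a group without enough observations (e.g. most participants rated
      # the task impossible): the test is not computable
      return(list(p = NA_real_,
                  posthoc = setNames(rep(NA_real_, 3), pair_cols)))
    }
    kw <- kruskal_wallis(samples)
    ph <- rep(NA_real_, 3)
    names(ph) <- pair_cols
    if (is.finite(kw$p) && kw$p < alpha) {
      dn <- dunn_posthoc(samples[imu_groups()])
      ph["BV_HS"] <- dn$p_holm[dn$pair == "BV-HS"]
      ph["UV_HS"] <- dn$p_holm[dn$pair == "UV-HS"]
      ph["BV_UV"] <- dn$p_holm[dn$pair == "BV-UV"]
    }
    list(p = kw$p, posthoc = ph)
  }
  rows <- lapply(tasks, function(tk) {
    dur <- one_param(durations[[tk]])
    dif <- one_param(difficulties[[tk]])
    is_forced <- tk %in% forced
    data.frame(task = tk,
               p_duration = dur$p, p_difficulty = dif$p,
               duration_BV_HS = dur$posthoc[["BV_HS"]],
               duration_UV_HS = dur$posthoc[["UV_HS"]],
               duration_BV_UV = dur$posthoc[["BV_UV"]],
               difficulty_BV_HS = dif$posthoc[["BV_HS"]],
               difficulty_UV_HS = dif$posthoc[["UV_HS"]],
               difficulty_BV_UV = dif$posthoc[["BV_UV"]],
               selected = (isTRUE(dur$p < alpha) && isTRUE(dif$p < alpha)) ||
                 is_forced,
               forced = is_forced,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("task_selection", "data.frame")
  out
}

#' @rdname select_tasks
#' @param selection A `task_selection` data frame.
#' @param path Output CSV path.
#' @export
write_task_selection <- function(selection, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(selection, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Shapiro-Wilk normality diagnostic
#'
#' Normality screen over feature-matrix columns, offered as the diagnostic
#' that motivates the nonparametric testing path (the pipeline itself always
#' uses rank tests).
#'
#' @param fm A `feature_matrix`.
#' @return Data frame `variable`, `W`, `p`.
#' @export
shapiro_screen <- function(fm) {
  vars <- feature_variables(fm)
  res <- lapply(vars, function(v) {
    x <- fm[[v]]
    x <- x[is.finite(x)]
    if (length(unique(x)) < 3 || length(x) < 3 || length(x) > 5000)
      return(data.frame(variable = v, W = NA_real_, p = NA_real_))
    sw <- stats::shapiro.test(x)
    data.frame(variable = v, W = unname(sw$statistic), p = sw$p.value)
  })
  do.call(rbind, res)
}
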