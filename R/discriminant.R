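#' Three-group discriminant screen of selected variables
#'
#' For each variable, runs a Kruskal-Wallis test across the BV/UV/HS groups
#' and, only when significant, Dunn's post-hoc test with Holm correction
#' within the variable's three pairwise comparisons. No correction is
#' applied across variables (per-variable reporting). Group medians and
#' interquartile ranges accompany each result.
#'
#' @param fm A `feature_matrix` with a `group` column.
#' @param variables Variables to screen (must all be matrix columns).
#' @param alpha Significance level (default 0.05).
#' @param components Optional named vector mapping variable -> source
#'   component label (e.g. from a `loading_selection`).
#' @return A `group_screen` data frame: one row per variable with `kw_p`,
#'   pairwise Holm p-values (`NA` unless significant), `significant`,
#'   per-group medians and IQRs, and `component` when supplied.
#' @export
screen_variables <- function(fm, variables, alpha = 0.05,
                             components = NULL) {
  if (!length(variables)) {
    out <- data.frame(variable = character(0), kw_p = numeric(0),
                      significant = logical(0))
    class(out) <- c("group_screen", "data.frame")
    return(out)
  }
  absent <- setdiff(variables, feature_variables(fm))
  if (length(absent))
    stop("variable(s) absent from feature matrix: ",
         paste(absent, collapse = ", "))
  rows <- lapply(variables, function(v) {
    samples <- lapply(setNames(nm = imu_groups()), function(g) {
      x <- fm[[v]][fm$group == g]
      x[is.finite(x)]
    })
    kw <- kruskal_wallis(samples)
    ph <- c(BV_HS = NA_real_, UV_HS = NA_real_, BV_UV = NA_real_)
    sig <- is.finite(kw$p) && kw$p < alpha
    if (sig) {
      dn <- dunn_posthoc(samples)
      ph["BV_HS"] <- dn$p_holm[dn$pair == "BV-HS"]
      ph["UV_HS"] <- dn$p_holm[dn$pair == "UV-HS"]
      ph["BV_UV"] <- dn$p_holm[dn$pair == "BV-UV"]
    }
    stats_g <- unlist(lapply(samples, function(x)
      c(median = median(x), iqr = stats::IQR(x))))
    data.frame(variable = v,
               component = if (!is.null(components))
                 unname(components[v]) else NA_character_,
               kw_p = kw$p,
               p_bv_hs = ph[["BV_HS"]], p_uv_hs = ph[["UV_HS"]],
               p_bv_uv = ph[["BV_UV"]],
               significant = sig,
               median_BV = stats_g[["BV.median"]],
               iqr_BV = stats_g[["BV.iqr"]],
               median_UV = stats_g[["UV.median"]],
               iqr_UV = stats_g[["UV.iqr"]],
               median_HS = stats_g[["HS.median"]],
               iqr_HS = stats_g[["HS.iqr"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("group_screen", "data.frame")
  out
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty
#' otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Tabular summary of a discriminant screen
#'
#' Orders results by source component, then ascending Kruskal-Wallis
#' p-value, and annotates significance stars; the tabular counterpart of a
#' per-variable boxplot figure.
#'
#' @param results A `group_screen` data frame.
#' @return Data frame with added `stars` column, reordered.
#' @export
summarize_screen <- function(results) {
  if (!nrow(results)) return(results)
  ord <- order(if (all(is.na(results$component))) rep(1, nrow(results))
               else results$component,
               results$kw_p)
  out <- results[ord, , drop = FALSE]
  out$stars <- significance_stars(out$kw_p)
  rownames(out) <- NULL
  out
}

#' @rdname summarize_screen
#' @param path Output CSV path.
#' @export
write_screen <- function(results, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(summarize_screen(results), path, row.names = FALSE, na = "")
  invisible(path)
}
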