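#' Impute missing feature-matrix cells
#'
#' Tasks rated impossible leave missing cells in the feature matrix. The
#' default strategy replaces a missing cell with the median of the
#' participant's own group for that variable (preserving group structure and
#' all participants); `overall_median` ignores groups; `complete_case` drops
#' incomplete participants.
#'
#' @param fm A `feature_matrix`.
#' @param strategy One of `"group_median"`, `"overall_median"`,
#'   `"complete_case"`.
#' @return The completed `feature_matrix`, with attribute `imputation_log`
#'   (data frame of filled cells, or dropped participants).
#' @export
impute_missing <- function(fm, strategy = c("group_median", "overall_median",
                                            "complete_case")) {
  strategy <- match.arg(strategy)
  vars <- feature_variables(fm)
  M <- as_feature_values(fm)
  if (strategy == "complete_case") {
    keep <- complete.cases(M)
    log <- data.frame(participant_id = fm$participant_id[!keep])
    fm <- fm[keep, , drop = FALSE]
    rownames(fm) <- NULL
    attr(fm, "variables") <- vars
    attr(fm, "imputation_log") <- log
    class(fm) <- c("feature_matrix", "data.frame")
    if (!nrow(fm)) stop("complete_case imputation removed every participant")
    return(fm)
  }
  n_miss <- colSums(is.na(M))
  if (any(n_miss == nrow(M)))
    stop("column(s) entirely missing: ",
         paste(vars[n_miss == nrow(M)], collapse = ", "))
  if (any(n_miss > nrow(M) / 2))
    warning("column(s) with >50% missing cells: ",
            paste(vars[n_miss > nrow(M) / 2], collapse = ", "))
  log <- list()
  for (v in vars[n_miss > 0]) {
    miss <- which(is.na(fm[[v]]))
    for (i in miss) {
      pool <- if (strategy == "group_median")
        fm[[v]][fm$group == fm$group[i]] else fm[[v]]
      fill <- median(pool, na.rm = TRUE)
      if (!is.finite(fill))
        stop("cannot impute ", v, ": no observed values in group ",
             fm$group[i])
      fm[[v]][i] <- fill
      log[[length(log) + 1]] <- data.frame(
        participant_id = fm$participant_id[i], variable = v, value = fill,
        stringsAsFactors = FALSE)
    }
  }
  attr(fm, "imputation_log") <-
    if (length(log)) do.call(rbind, log) else
      data.frame(participant_id = character(0), variable = character(0),
                 value = numeric(0))
  fm
}

#' Column-standardize a feature matrix
#'
#' Centers every variable to mean 0 and scales to sd 1 so that the PCA
#' operates on the correlation structure (variables mix m/s^2, deg/s,
#' percentages and seconds). Requires a complete matrix — impute first.
#'
#' @param fm A complete `feature_matrix`.
#' @return The standardized `feature_matrix`.
#' @export
standardize <- function(fm) {
  vars <- feature_variables(fm)
  M <- as_feature_values(fm)
  if (any(is.na(M)))
    stop("feature matrix contains missing cells; run impute_missing() first")
  sds <- apply(M, 2, sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(vars[sds == 0], collapse = ", "))
  Z <- scale(M)
  for (i in seq_along(vars)) fm[[vars[i]]] <- Z[, i]
  attr(fm, "standardized") <- TRUE
  fm
}

# Core decomposition of an already-standardized matrix. Loadings are
# correlation-scaled: eigenvector * component sd (for z-scored input these
# are the variable-component correlations). Sign convention: the
# largest-|loading| entry of each component is positive.
pca_core <- function(Z) {
  n <- nrow(Z)
  sv <- svd(scale(Z, center = TRUE, scale = FALSE))
  lambda <- sv$d^2 / (n - 1)
  keep <- lambda > max(lambda) * 1e-12
  lambda <- lambda[keep]
  V <- sv$v[, keep, drop = FALSE]
  U <- sv$u[, keep, drop = FALSE]
  d <- sv$d[keep]
  loadings <- sweep(V, 2, sqrt(lambda), `*`)
  flip <- vapply(seq_len(ncol(loadings)), function(k) {
    lk <- loadings[, k]
    sign(lk[which.max(abs(lk))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(loadings, 2, flip, `*`)
  scores <- sweep(U, 2, d * flip, `*`)
  vaf <- 100 * lambda / sum(lambda)
  list(loadings = loadings, scores = scores, vaf = vaf, lambda = lambda)
}

#' Principal component analysis of the standardized feature matrix
#'
#' Components are ordered by decreasing variance accounted for (VAF, in
#' percent of total variance; the VAF of all components sums to 100).
#' Loadings are correlation-scaled (eigenvector times component standard
#' deviation) and carry a deterministic sign convention: the entry of
#' largest absolute loading in each component is positive, making repeated
#' fits bit-identical. When there are more variables than the sample rank
#' supports, the component count is capped at the rank.
#'
#' @param fm A standardized `feature_matrix` (see [standardize()]).
#' @return A `pca_model`: list with `loadings` (variables x components),
#'   `vaf`, `scores`, `variables`, `n_components`, `n`.
#' @export
fit_pca <- function(fm) {
  vars <- feature_variables(fm)
  Z <- as_feature_values(fm)
  if (any(is.na(Z))) stop("feature matrix contains missing cells")
  if (!isTRUE(attr(fm, "standardized")))
    Z <- scale(Z)
  core <- pca_core(Z)
  rownames(core$loadings) <- vars
  colnames(core$loadings) <- paste0("PC", seq_len(ncol(core$loadings)))
  structure(list(loadings = core$loadings, vaf = core$vaf,
                 scores = core$scores, variables = vars,
                 n_components = ncol(core$loadings), n = nrow(Z),
                 groups = fm$group, participant_id = fm$participant_id),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d participants x %d variables, %d components\n",
              x$n, length(x$variables), x$n_components))
  k <- min(6, x$n_components)
  cat("  VAF (%):", paste(sprintf("%.1f", x$vaf[1:k]), collapse = ", "),
      if (x$n_components > k) "..." else "", "\n")
  invisible(x)
}

#' Permutation test for component retention
#'
#' Determines how many leading components carry more variance than expected
#' under independence. Each permuted dataset shuffles every column
#' independently, destroying between-variable correlation while preserving
#' marginals; component `k` is retained if its observed VAF exceeds the
#' `(1 - alpha)` quantile of the permuted VAF at the same index. Testing is
#' sequential and stops at the first non-significant component.
#'
#' @param fm Standardized `feature_matrix`.
#' @param n_perm Number of permutations (default 1000; a warning is logged
#'   below 100).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed for the permutation stream.
#' @return List with `retained` (component count), `observed_vaf`,
#'   `null_quantiles` and `p` (per-component permutation p-values up to the
#'   stopping point).
#' @export
permutation_vaf_test <- function(fm, n_perm = 1000, alpha = 0.05,
                                 seed = 1L) {
  if (n_perm < 100) warning("n_perm < 100: retention quantiles are coarse")
  Z <- as_feature_values(fm)
  if (!isTRUE(attr(fm, "standardized"))) Z <- scale(Z)
  obs <- pca_core(Z)$vaf
  if (alpha >= 1) {
    return(list(retained = length(obs), observed_vaf = obs,
                null_quantiles = rep(0, length(obs)),
                p = rep(0, length(obs)), n_perm = n_perm, alpha = alpha,
                seed = seed))
  }
  n <- nrow(Z)
  set.seed(as.integer(seed))
  null_vaf <- matrix(NA_real_, n_perm, length(obs))
  for (b in seq_len(n_perm)) {
    P <- apply(Z, 2, function(col) col[sample.int(n)])
    v <- pca_core(P)$vaf
    null_vaf[b, seq_len(min(length(v), ncol(null_vaf)))] <-
      v[seq_len(min(length(v), ncol(null_vaf)))]
  }
  qs <- apply(null_vaf, 2, quantile, probs = 1 - alpha, na.rm = TRUE)
  pvals <- numeric(0)
  retained <- 0L
  for (k in seq_along(obs)) {
    pvals[k] <- mean(null_vaf[, k] >= obs[k], na.rm = TRUE)
    if (obs[k] > qs[k]) retained <- k else break
  }
  list(retained = retained, observed_vaf = obs, null_quantiles = qs,
       p = pvals, n_perm = n_perm, alpha = alpha, seed = seed)
}

#' Cut retained components at a cumulative-VAF threshold
#'
#' Among the permutation-retained components, keeps the smallest leading set
#' whose cumulative VAF reaches the threshold (default 50% of total
#' variance). If even all retained components fall short, all are kept with
#' a warning.
#'
#' @param vaf Per-component VAF in percent, sorted decreasing.
#' @param threshold Cumulative proportion of variance required (default 0.5).
#' @param permutation_retained Component count from
#'   [permutation_vaf_test()].
#' @return Final component count.
#' @export
cumulative_vaf_cut <- function(vaf, threshold = 0.5, permutation_retained) {
  if (permutation_retained < 1) return(0L)
  cum <- cumsum(vaf[seq_len(permutation_retained)])
  k <- which(cum >= threshold * 100)
  if (!length(k)) {
    warning("retained components reach only ",
            sprintf("%.1f%%", cum[permutation_retained]),
            " cumulative VAF (< ", threshold * 100, "%)")
    return(as.integer(permutation_retained))
  }
  as.integer(k[1])
}

#' Select top-loading variables per component
#'
#' For each retained component, keeps the variables with the `pct` (default
#' 10%) highest absolute loadings, capped at `cap` (default 10) per
#' component; exact ties at the cut are all included (and logged). Reports
#' the per-component loading threshold (smallest retained absolute loading)
#' and the union of selected variables across components.
#'
#' @param model A `pca_model`.
#' @param components Number of leading components to select from.
#' @param pct Proportion of variables to retain per component (default 0.10).
#' @param cap Maximum variables per component (default 10).
#' @return A `loading_selection`: list with `per_component` (list of data
#'   frames `variable`, `loading`), `thresholds`, `union`, `m`, `ties`.
#' @export
select_loading_variables <- function(model, components, pct = 0.10,
                                     cap = 10) {
  if (components < 1 || components > model$n_components)
    stop("components must be between 1 and ", model$n_components)
  nv <- length(model$variables)
  m <- min(ceiling(pct * nv), cap)
  per <- list(); thresholds <- numeric(0); ties <- character(0)
  for (k in seq_len(components)) {
    lk <- model$loadings[, k]
    ord <- order(abs(lk), decreasing = TRUE)
    cut_val <- abs(lk[ord[m]])
    keep <- which(abs(lk) >= cut_val)
    if (length(keep) > m)
      ties <- c(ties, sprintf("PC%d: %d variables tied at |loading| = %g",
                              k, length(keep), cut_val))
    keep <- keep[order(abs(lk[keep]), decreasing = TRUE)]
    per[[paste0("PC", k)]] <- data.frame(
      variable = model$variables[keep], loading = unname(lk[keep]),
      stringsAsFactors = FALSE)
    thresholds[paste0("PC", k)] <- min(abs(lk[keep]))
  }
  union_vars <- unique(unlist(lapply(per, `[[`, "variable"),
                              use.names = FALSE))
  structure(list(per_component = per, thresholds = thresholds,
                 union = union_vars, m = m, ties = ties),
            class = "loading_selection")
}

#' Tucker congruence coefficient
#'
#' Cosine-type similarity between two loading vectors:
#' `sum(x * y) / sqrt(sum(x^2) * sum(y^2))`, in `[-1, 1]`.
#'
#' @param x,y Numeric vectors of equal length, not both all-zero.
#' @return Scalar congruence.
#' @export
congruence_coefficient <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  nx <- sum(x^2); ny <- sum(y^2)
  if (nx == 0 || ny == 0)
    stop("congruence coefficient undefined for a zero vector")
  sum(x * y) / sqrt(nx * ny)
}

#' Cattell's salient-variable similarity
#'
#' Classifies each loading as salient-positive (`> cut`), salient-negative
#' (`< -cut`) or hyperplane, and computes
#' `s = (c_pp + c_nn - c_pn - c_np) / (n - c_hh)` where `c_ab` counts joint
#' classifications and `c_hh` the pairs classified hyperplane in both
#' vectors. Mixed salient/hyperplane pairs dilute the denominator without
#' entering the numerator.
#'
#' @param x,y Loading vectors of equal length.
#' @param hyperplane_cut Salience threshold on |loading| (default 0.1).
#' @return Scalar in `[-1, 1]`.
#' @export
cattell_s <- function(x, y, hyperplane_cut = 0.1) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  cls <- function(v) ifelse(v > hyperplane_cut, 1L,
                            ifelse(v < -hyperplane_cut, -1L, 0L))
  cx <- cls(x); cy <- cls(y)
  c_pp <- sum(cx == 1 & cy == 1)
  c_nn <- sum(cx == -1 & cy == -1)
  c_pn <- sum(cx == 1 & cy == -1)
  c_np <- sum(cx == -1 & cy == 1)
  c_hh <- sum(cx == 0 & cy == 0)
  denom <- length(x) - c_hh
  if (denom == 0)
    stop("Cattell's s undefined: all loadings in the hyperplane")
  (c_pp + c_nn - c_pn - c_np) / denom
}

#' Bootstrap stability of the retained components
#'
#' Resamples participants with replacement (stratified by group), refits the
#' PCA, matches each original component to the bootstrap component of
#' maximal absolute congruence (greedy from PC1, without replacement),
#' aligns signs, and accumulates four per-component similarity metrics
#' against the original loadings: Pearson r, RMS of loading differences,
#' Tucker congruence CC and Cattell's s. A robust component changes little
#' under resampling. Bootstrap samples producing a zero-variance column are
#' redrawn (and counted).
#'
#' @param fm The (imputed, unstandardized or standardized) `feature_matrix`
#'   the model was fitted on.
#' @param model The original `pca_model`.
#' @param components Number of leading components to assess.
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @param hyperplane_cut Salience threshold for Cattell's s (default 0.1).
#' @return A `stability_report` data frame: one row per component with mean
#'   `r`, `rms`, `cc`, `cattell_s` over iterations, plus attributes
#'   `n_boot`, `seed`, `redrawn`.
#' @export
bootstrap_stability <- function(fm, model, components, n_boot = 1000,
                                seed = 1L, hyperplane_cut = 0.1) {
  if (components < 1 || components > model$n_components)
    stop("components must be between 1 and ", model$n_components)
  M <- as_feature_values(fm)
  if (any(is.na(M))) stop("feature matrix contains missing cells")
  groups <- fm$group
  idx_by_group <- split(seq_len(nrow(M)), groups)
  orig <- model$loadings[, seq_len(components), drop = FALSE]
  acc <- matrix(0, components, 4,
                dimnames = list(paste0("PC", seq_len(components)),
                                c("r", "rms", "cc", "cattell_s")))
  set.seed(as.integer(seed))
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- unlist(lapply(idx_by_group, function(ii)
        ii[sample.int(length(ii), replace = TRUE)]), use.names = FALSE)
      Mb <- M[idx, , drop = FALSE]
      sds <- apply(Mb, 2, sd)
      if (all(sds > 0)) break
      redrawn <- redrawn + 1L
    }
    core <- pca_core(scale(Mb))
    Lb <- core$loadings
    kb <- ncol(Lb)
    avail <- seq_len(kb)
    for (k in seq_len(components)) {
      ccs <- vapply(avail, function(j)
        congruence_coefficient(orig[, k], Lb[, j]), numeric(1))
      pick <- avail[which.max(abs(ccs))]
      cc_val <- ccs[which.max(abs(ccs))]
      avail <- setdiff(avail, pick)
      bl <- Lb[, pick] * sign(cc_val)
      acc[k, "r"] <- acc[k, "r"] + cor(orig[, k], bl)
      acc[k, "rms"] <- acc[k, "rms"] + sqrt(mean((orig[, k] - bl)^2))
      acc[k, "cc"] <- acc[k, "cc"] + abs(cc_val)
      acc[k, "cattell_s"] <- acc[k, "cattell_s"] +
        cattell_s(orig[, k], bl, hyperplane_cut)
      if (!length(avail)) break
    }
  }
  out <- as.data.frame(acc / n_boot)
  out <- cbind(component = rownames(acc), out)
  rownames(out) <- NULL
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  attr(out, "redrawn") <- redrawn
  class(out) <- c("stability_report", "data.frame")
  out
}
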