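test_that("standardize centers, scales, and is idempotent", {
  fm <- fm_from_matrix(cbind(c(1, 2, 3), c(10, 20, 60)))
  z <- standardize(fm)
  expect_equal(z[["Walk|HE|V1"]], c(-1, 0, 1))
  M <- as.matrix(z[, 3:4])
  expect_lt(max(abs(colMeans(M))), 1e-12)
  expect_lt(max(abs(apply(M, 2, sd) - 1)), 1e-12)
  z2 <- standardize(z)
  expect_equal(as.matrix(z2[, 3:4]), M, tolerance = 1e-12)

  fm0 <- fm_from_matrix(cbind(1:5, rep(2, 5)))
  expect_error(standardize(fm0), "Walk\\|HE\\|V2")
})

test_that("imputation strategies fill or drop as documented", {
  M <- cbind(c(1, 2, NA, 10, 11, 12), c(5, 6, 7, 8, 9, 10))
  fm <- fm_from_matrix(M, groups = rep(c("BV", "HS"), each = 3))
  gi <- impute_missing(fm, "group_median")
  expect_equal(gi[["Walk|HE|V1"]][3], median(c(1, 2)))
  expect_equal(nrow(attr(gi, "imputation_log")), 1)

  oi <- impute_missing(fm, "overall_median")
  expect_equal(oi[["Walk|HE|V1"]][3], median(c(1, 2, 10, 11, 12)))

  cc <- impute_missing(fm, "complete_case")
  expect_equal(nrow(cc), 5)

  full <- fm_from_matrix(matrix(1:12, 6))
  expect_identical(as_vals <- impute_missing(full)[["Walk|HE|V1"]],
                   full[["Walk|HE|V1"]])
})

test_that("PCA matches an independent eigendecomposition", {
  set.seed(31)
  n <- 40
  f <- rnorm(n)
  M <- cbind(f + rnorm(n, 0, 0.5), -f + rnorm(n, 0, 0.8), rnorm(n))
  fm <- standardize(fm_from_matrix(M))
  model <- fit_pca(fm)
  ev <- eigen(cor(M), symmetric = TRUE)$values
  expect_equal(model$vaf, 100 * ev / sum(ev), tolerance = 1e-9)
  expect_equal(sum(model$vaf), 100, tolerance = 1e-9)

  # rank-1 data: first component carries everything
  r1 <- fm_from_matrix(cbind(f, 2 * f, -f))
  m1 <- fit_pca(standardize(r1))
  expect_equal(m1$vaf[1], 100, tolerance = 1e-9)

  # isotropy: two independent columns share the variance evenly
  set.seed(32)
  iso <- fit_pca(standardize(fm_from_matrix(matrix(rnorm(4000), ncol = 2))))
  expect_equal(iso$vaf, c(50, 50), tolerance = 5)

  # deterministic sign convention, bit-identical refits
  model2 <- fit_pca(fm)
  expect_identical(model$loadings, model2$loadings)
  peaks <- apply(model$loadings, 2, function(l) l[which.max(abs(l))])
  expect_true(all(peaks > 0))
})

test_that("loadings are correlation-scaled", {
  set.seed(33)
  f <- rnorm(60)
  M <- cbind(f + rnorm(60, 0, 0.3), f + rnorm(60, 0, 0.3), rnorm(60))
  fm <- standardize(fm_from_matrix(M))
  model <- fit_pca(fm)
  # loading of variable j on PC k equals cor(variable, score_k)
  expect_equal(model$loadings[1, 1],
               cor(M[, 1], model$scores[, 1]), tolerance = 1e-9)
  expect_true(all(abs(model$loadings) <= 1 + 1e-9))
})

test_that("permutation retention behaves at the boundaries", {
  set.seed(34)
  noise <- standardize(fm_from_matrix(matrix(rnorm(30 * 8), ncol = 8)))
  all_in <- permutation_vaf_test(noise, n_perm = 100, alpha = 1, seed = 1)
  expect_equal(all_in$retained, fit_pca(noise)$n_components)
  expect_warning(permutation_vaf_test(noise, n_perm = 50, seed = 1),
                 "n_perm")
})

test_that("permutation retention recovers planted factors", {
  retained <- integer(0)
  for (seed in 1:10) {
    set.seed(seed)
    n <- 60
    f1 <- rnorm(n); f2 <- rnorm(n)
    L <- matrix(0, 20, 2)
    L[1:10, 1] <- 0.8
    L[11:20, 2] <- 0.8
    M <- cbind(f1, f2) %*% t(L) +
      matrix(rnorm(n * 20), n) %*% diag(sqrt(1 - rowSums(L^2)))
    fm <- standardize(fm_from_matrix(M, vars = paste0("Walk|HE|V", 1:20)))
    retained[seed] <- permutation_vaf_test(fm, n_perm = 200,
                                           seed = seed)$retained
  }
  expect_gte(sum(retained >= 2), 9)
})

test_that("cumulative VAF cut keeps the smallest sufficient set", {
  # study-shaped spectrum: 4 components reach 56%
  vaf <- c(32.5, 9.4, 7.1, 7.0, 4, 3, 2.5)
  expect_equal(cumulative_vaf_cut(vaf, 0.5, permutation_retained = 7), 4)
  expect_equal(cumulative_vaf_cut(c(60, 10), 0.5, 2), 1)
  expect_equal(cumulative_vaf_cut(c(30, 15, 10), 0.5, 3), 3)
  expect_warning(k <- cumulative_vaf_cut(c(30, 10), 0.5, 2), "cumulative")
  expect_equal(k, 2)
  expect_equal(cumulative_vaf_cut(vaf, 0.5, 0), 0L)
})

test_that("top-loading selection honours the 10%-capped-at-10 rule", {
  mk_model <- function(L) {
    structure(list(loadings = L, variables = rownames(L),
                   n_components = ncol(L)), class = "pca_model")
  }
  # union arithmetic: 4 sets of 10 with 13 duplicates -> union of 27
  # (100 variables so that the 10% rule saturates the cap of 10)
  nv <- 100
  L <- matrix(0.01, nv, 4,
              dimnames = list(paste0("Walk|HE|V", 1:nv),
                              paste0("PC", 1:4)))
  sets <- list(1:10, 8:17, 13:22, 18:27)
  for (k in 1:4) L[sets[[k]], k] <- seq(0.95, 0.5, length.out = 10)
  sel <- select_loading_variables(mk_model(L), 4, pct = 0.10, cap = 10)
  expect_equal(sel$m, min(ceiling(0.1 * nv), 10))
  expect_length(sel$union, 27)
  for (k in 1:4) {
    got <- sel$per_component[[k]]$variable
    expect_setequal(got, paste0("Walk|HE|V", sets[[k]]))
    # reported threshold equals the smallest retained |loading|
    expect_equal(sel$thresholds[[k]],
                 min(abs(sel$per_component[[k]]$loading)))
  }

  # m arithmetic at the study scale and for small rosters
  L152 <- matrix(rnorm(152 * 2), 152, 2,
                 dimnames = list(paste0("Walk|HE|V", 1:152), NULL))
  s152 <- select_loading_variables(mk_model(L152), 1)
  expect_equal(s152$m, 10)
  L20 <- matrix(rnorm(20 * 2), 20, 2,
                dimnames = list(paste0("Walk|HE|V", 1:20), NULL))
  expect_equal(select_loading_variables(mk_model(L20), 1)$m, 2)

  # exact ties at the cut are all retained and logged
  Lt <- matrix(0.01, 20, 1, dimnames = list(paste0("Walk|HE|V", 1:20), NULL))
  Lt[1:4, 1] <- c(0.9, 0.5, 0.5, 0.5)
  st <- select_loading_variables(mk_model(Lt), 1, pct = 0.10, cap = 10)
  expect_equal(st$m, 2)
  expect_length(st$per_component[[1]]$variable, 4)
  expect_length(st$ties, 1)
})

test_that("congruence and Cattell similarity match their definitions", {
  x <- c(0.8, -0.3, 0.1)
  expect_equal(congruence_coefficient(x, x), 1)
  expect_equal(congruence_coefficient(x, -x), -1)
  expect_equal(congruence_coefficient(c(1, 0), c(0, 1)), 0)
  for (cc in c(-2, -0.1, 0.5, 3))
    expect_equal(congruence_coefficient(x, cc * x), sign(cc))
  expect_error(congruence_coefficient(x, c(0, 0, 0)), "zero vector")

  expect_equal(cattell_s(x, x), 1)
  y_all <- c(0.8, -0.3, 0.4)
  expect_equal(cattell_s(y_all, -y_all), -1)
  # hand-classified mixed case
  expect_equal(cattell_s(c(0.5, 0.05, -0.5, 0.3),
                         c(0.4, 0.02, -0.45, -0.2), 0.1), 1 / 3)
  expect_error(cattell_s(c(0.01, 0.02), c(0.03, -0.04)), "hyperplane")
})

test_that("bootstrap of singleton strata is an exact self-comparison", {
  M <- matrix(c(1, 5, 9,
                2, 1, 4,
                3, 8, 2,
                7, 2, 6), 3, 4)
  fm <- fm_from_matrix(M, groups = c("BV", "UV", "HS"),
                       vars = paste0("Walk|HE|V", 1:4))
  model <- fit_pca(standardize(fm))
  st <- bootstrap_stability(fm, model, components = 1, n_boot = 20,
                            seed = 5)
  expect_equal(st$r, 1, tolerance = 1e-12)
  expect_equal(st$rms, 0, tolerance = 1e-12)
  expect_equal(st$cc, 1, tolerance = 1e-12)
  expect_equal(st$cattell_s, 1, tolerance = 1e-12)
})

test_that("bootstrap stability separates planted structure from noise", {
  one_factor <- function(seed) {
    set.seed(seed)
    n <- 60
    f <- rnorm(n)
    M <- 0.8 * matrix(f, n, 20) + 0.6 * matrix(rnorm(n * 20), n)
    fm_from_matrix(M, vars = paste0("Walk|HE|V", 1:20))
  }
  ccs_strong <- ccs_noise <- numeric(0)
  for (seed in 1:5) {
    fm <- one_factor(seed)
    m <- fit_pca(standardize(fm))
    ccs_strong[seed] <- bootstrap_stability(fm, m, 1, n_boot = 50,
                                            seed = seed)$cc
    set.seed(1000 + seed)
    fmn <- fm_from_matrix(matrix(rnorm(60 * 20), 60),
                          vars = paste0("Walk|HE|V", 1:20))
    mn <- fit_pca(standardize(fmn))
    ccs_noise[seed] <- bootstrap_stability(fmn, mn, 1, n_boot = 50,
                                           seed = seed)$cc
  }
  expect_true(all(ccs_strong > ccs_noise))
  expect_gt(mean(ccs_strong), 0.95)
})
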