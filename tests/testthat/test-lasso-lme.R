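six_vois <- c("voi_cbl_lobule_6", "voi_cbl_wm_deep_nuclei", "voi_caudate",
              "voi_putamen", "voi_pallidum", "voi_pons")

test_that("the design has the documented column structure and unit scales", {
  x <- study_cohort(seed = 41)
  des <- build_design(x$cohort, six_vois)
  # intercept + 6 mains + 6 interactions + 3 covariates
  expect_equal(ncol(des$X), 16)
  expect_equal(sum(des$penalized), 15)
  expect_false(des$penalized[["(Intercept)"]])
  sds <- apply(des$X[, -1], 2, sd)
  expect_equal(unname(sds), rep(1, 15), tolerance = 1e-12)
  # follow-up rows only (elapsed time strictly positive)
  expect_true(all(des$X[, "time"] * des$scale["time"] + des$center["time"] > 0))
  # the affected-only subset drops the unaffected rows
  des_aff <- build_design(x$cohort, six_vois, subset = "affected")
  expect_lt(nrow(des_aff$X), nrow(des$X))
  des2 <- build_design(x$cohort, six_vois, penalize_covariates = FALSE)
  expect_equal(sum(des2$penalized), 12)
  expect_error(build_design(x$cohort, character(0)), "empty")
  expect_error(build_design(x$cohort, "voi_nonexistent"), "voi_nonexistent")
})

test_that("lambda = 0 reproduces the unpenalized mixed-model fit", {
  for (seed in 1:3) {
    rd <- random_design(seed = seed)
    f0 <- fit_penalized_lme(rd$design, 0)
    fl <- lme4_ml_fit(rd$design)
    b_ref <- lme4::fixef(fl)
    expect_lt(max(abs(f0$beta_std - b_ref) / pmax(abs(b_ref), 1e-6)), 1e-4)
    expect_equal(f0$logLik, as.numeric(logLik(fl)), tolerance = 1e-6)
  }
})

test_that("a large penalty zeroes every penalized term and leaves the null model", {
  rd <- random_design(seed = 4)
  f <- fit_penalized_lme(rd$design, 1e6)
  expect_true(all(abs(f$beta_std[rd$design$penalized]) < 1e-10))
  expect_equal(length(f$active), 0)
  # intercept equals the intercept-only mixed-model estimate
  d0 <- rd$design; d0$X <- d0$X[, 1, drop = FALSE]
  d0$penalized <- d0$penalized[1]; d0$center <- d0$center[1]; d0$scale <- d0$scale[1]
  f0 <- fit_penalized_lme(d0, 0)
  expect_equal(unname(f$beta_std[1]), unname(f0$beta_std[1]), tolerance = 1e-6)
})

test_that("solutions satisfy the soft-thresholding stationarity conditions", {
  rd <- random_design(seed = 5, sd_b = 0)  # data generated without clustering
  lambda <- 20
  f <- fit_penalized_lme(rd$design, lambda)
  # KKT oracle on the whitened problem at the returned variance components
  g <- f$gamma
  subj <- rd$design$subject
  wh <- function(M) {
    M <- as.matrix(M)
    if (g == 0) return(M)
    fint <- as.integer(factor(subj, levels = unique(subj)))
    n_i <- tabulate(fint)
    c_i <- 1 - 1 / sqrt(1 + n_i * g)
    M - (c_i * (rowsum(M, fint, reorder = TRUE) / n_i))[fint, , drop = FALSE]
  }
  Xt <- wh(rd$design$X); yt <- wh(rd$design$y)
  r <- as.vector(yt) - as.vector(Xt %*% f$beta_std)
  grad <- as.vector(crossprod(Xt, r))
  thr <- lambda * f$sigma2
  for (j in seq_along(grad)) {
    if (!rd$design$penalized[j]) {
      expect_lt(abs(grad[j]), 1e-4 * (1 + abs(thr)))
    } else if (abs(f$beta_std[j]) > 1e-8) {
      expect_lt(abs(grad[j] - sign(unname(f$beta_std[j])) * thr),
                1e-4 * (1 + thr))
    } else {
      expect_lte(abs(grad[j]), thr * (1 + 1e-4))
    }
  }
})

test_that("the single-predictor solution is the analytic soft-threshold when gamma = 0", {
  set.seed(6)
  n <- 150
  x <- scale(rnorm(n))[, 1]
  y <- 0.4 * x + rnorm(n, 0, 1)
  d <- list(y = y, X = cbind(`(Intercept)` = 1, x = x),
            subject = sprintf("S%03d", 1:n),  # one row each: gamma profile flat
            penalized = c(`(Intercept)` = FALSE, x = TRUE),
            center = c(0, 0), scale = c(1, 1), terms = c("(Intercept)", "x"))
  class(d) <- "lasso_design"
  lambda <- 10
  f <- fit_penalized_lme(d, lambda)
  # oracle: with independent rows the whitened problem is OLS-scaled, and the
  # lasso coordinate solution is S(x'y, lambda * sigma2) / x'x, rescaled by
  # the flat-profile factor (1 + n_i * gamma) that cancels between numerator
  # and denominator; with n_i = 1 the factor is common and the fixed point is
  # S(b_ols * xtx, lambda * sigma2 * (1 + gamma)) / xtx
  sc <- 1 + f$gamma
  xtx <- sum(x^2) / sc
  z <- sum(x * (y - f$beta_std[1])) / sc
  expected <- sign(z) * max(abs(z) - lambda * f$sigma2, 0) / xtx
  expect_equal(unname(f$beta_std["x"]), expected, tolerance = 1e-4)
})

test_that("active sets shrink along the path and the BIC curve is finite", {
  rd <- random_design(seed = 7, beta = c(1, 2, -1.5, 0, 0, 0, 0))
  path <- lambda_path(rd$design, c(1, 2, 5, 10, 20, 50, 100, 200, 500, 2000))
  expect_true(all(is.finite(path$bic)))
  sizes <- path$active_size
  expect_true(all(diff(sizes) <= 1))  # non-increasing up to solver tolerance
  expect_equal(sizes[length(sizes)], 0)
  expect_true(path$lambda_star %in% path$lambdas)
})

test_that("sparse truth is recovered exactly by BIC on a constructed design", {
  # well-posed regime (300 rows, 7 columns): the relaxed-fit BIC applies
  hits <- sapply(1:10, function(seed) {
    rd <- random_design(n_sub = 100, seed = 100 + seed,
                        beta = c(1, 3, -2.5, 0, 0, 0, 0), sd_e = 0.7)
    path <- suppressWarnings(lambda_path(rd$design, c(1:10, seq(12, 60, 2)),
                                         bic_loglik = "refit"))
    star <- path$fits[[match(path$lambda_star, path$lambdas)]]
    setequal(star$active, c("x1", "x2"))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("cross-validation folds respect subjects and reproduce under a seed", {
  rd <- random_design(n_sub = 30, seed = 8)
  grid <- c(1, 5, 20, 100)
  cv1 <- cross_validate(rd$design, grid, n_folds = 5, seed = 3)
  cv2 <- cross_validate(rd$design, grid, n_folds = 5, seed = 3)
  expect_identical(cv1, cv2)
  expect_error(cross_validate(rd$design, grid, n_folds = 50, seed = 1),
               "fewer subjects")
})

test_that("cv error is smallest at weak penalties for a noise-free linear truth", {
  rd <- random_design(n_sub = 40, seed = 9, sd_b = 0, sd_e = 1e-6,
                      beta = c(0, 2, -1, 1, 0, 0, 0))
  cv <- cross_validate(rd$design, c(1, 200), n_folds = 4, seed = 1)
  expect_lt(cv$cv_error[1], cv$cv_error[2])
})

test_that("a permuted response yields a flat cv curve and an empty selection", {
  rd <- random_design(n_sub = 40, seed = 10, beta = c(0, rep(0, 6)))
  path <- suppressWarnings(lambda_path(rd$design, c(1, 5, 10, 20, 50, 100)))
  star <- path$fits[[match(path$lambda_star, path$lambdas)]]
  expect_lte(length(star$active), 1)
  rep <- suppressWarnings(report_selection(path, rd$design))
  expect_lte(nrow(rep$selected), 1)
})

test_that("selection report inverts the standardization and lists zeroed terms", {
  x <- study_cohort(seed = 42)
  des <- build_design(x$cohort, six_vois)
  path <- suppressWarnings(lambda_path(des, c(5, 20, 50)))
  rep <- suppressWarnings(report_selection(path, des))
  expect_equal(rep$lambda_star, path$lambda_star)
  expect_setequal(c(rep$selected$term, rep$zeroed),
                  names(des$penalized)[des$penalized])
  if (nrow(rep$selected) > 0) {
    expect_true(all(is.finite(rep$selected$z)))
    expect_equal(rep$selected$z,
                 rep$selected$beta / rep$selected$se, tolerance = 1e-8)
  }
})

test_that("report at lambda = 0 is the unpenalized inference table", {
  rd <- random_design(n_sub = 50, seed = 11)
  path <- lambda_path(rd$design, 0)
  expect_warning(rep <- report_selection(path, rd$design), "post-selection")
  expect_equal(nrow(rep$selected), 6)
  fl <- lme4_ml_fit(rd$design)
  b_ref <- lme4::fixef(fl)[rep$selected$term]
  expect_equal(rep$selected$beta, unname(b_ref), tolerance = 1e-3)
})
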