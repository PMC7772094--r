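test_that("age decomposition splits baseline and within-subject components", {
  co <- data.frame(subject = rep("A", 3), visit = 1:3,
                   time = c(0, 1.5, 3), age = c(50, 51.5, 53))
  out <- decompose_age(co)
  expect_equal(out$baseline_age, rep(50, 3))
  expect_equal(out$delta_age, c(0, 1.5, 3))
  # single-visit subject
  one <- decompose_age(data.frame(subject = "B", visit = 1, time = 0, age = 61))
  expect_equal(one$delta_age, 0)
})

test_that("age reconstruction identity holds on a simulated cohort", {
  x <- study_cohort(seed = 31, regions = small_regions())
  out <- decompose_age(x$cohort)
  expect_equal(out$baseline_age + out$delta_age, out$age, tolerance = 1e-12)
  # baseline_age constant within subject
  nbase <- tapply(out$baseline_age, out$subject, function(v) length(unique(v)))
  expect_true(all(nbase == 1))
})

test_that("change from baseline is zero at baseline and idempotent", {
  co <- data.frame(subject = rep("A", 3), visit = 1:3,
                   time = c(0, 1.5, 3), age = c(50, 51.5, 53),
                   voi_x = c(100, 98, 95))
  out <- change_from_baseline(co, "voi_x")
  expect_equal(out$d_voi_x, c(0, -2, -5))
  # constant series
  co$voi_x <- 7
  expect_equal(change_from_baseline(co, "voi_x")$d_voi_x, rep(0, 3))
  # differencing an already-differenced series (baseline 0) changes nothing
  out$voi_x <- out$d_voi_x
  again <- change_from_baseline(out[, names(out) != "d_voi_x"], "voi_x")
  expect_equal(again$d_voi_x, c(0, -2, -5))
})

test_that("subjects without a unique baseline are rejected", {
  co <- data.frame(subject = c("A", "A"), visit = c(1, 2),
                   time = c(1, 1), age = c(50, 50), voi_x = c(1, 2))
  expect_error(change_from_baseline(co, "voi_x"), "baseline")
})

test_that("Bonferroni correction reproduces the published corrected values", {
  expect_equal(bonferroni(5.91e-12, 34), 2.0094e-10, tolerance = 1e-15)
  expect_equal(signif(bonferroni(5.91e-12, 34), 3), 2.01e-10)
  expect_equal(bonferroni(0.5, 34), 1)
  expect_equal(signif(bonferroni(0.000321, 34), 3), 0.0109)
  expect_equal(bonferroni(c(0.001, 0.5), 10), c(0.01, 1))
  expect_error(bonferroni(0.01, 0))
})

test_that("baseline model standardizes the group coefficient", {
  # constructed gap: affected exactly 'gap' mm^3 below unaffected
  x <- study_cohort(seed = 32, regions = small_regions())
  co <- x$cohort
  gap <- 2 * sd(co$voi_pons)
  co$voi_gap <- co$voi_pons * 0 + 1000 + rnorm(nrow(co), 0, 1) -
    gap * (co$group == "affected")
  co2 <- decompose_age(co)
  co2$group <- factor(co2$group, levels = c("unaffected", "affected"))
  base_rows <- co2[co2$delta_age == 0, ]
  res <- fit_baseline_model("voi_gap", co)
  # oracle: the standardized coefficient is the raw OLS group coefficient
  # divided by the baseline-sample SD of the volume
  raw <- lm(voi_gap ~ group + baseline_age + gender, data = base_rows)
  expect_equal(res$std_beta,
               unname(coef(raw)["groupaffected"]) / sd(base_rows$voi_gap),
               tolerance = 1e-8)
  expect_true(res$ci95[1] <= res$std_beta && res$std_beta <= res$ci95[2])
  # identical groups give a near-zero standardized difference
  co$voi_same <- 1000 + rnorm(nrow(co))
  res0 <- fit_baseline_model("voi_same", co)
  expect_lt(abs(res0$std_beta), 1)
  expect_gt(res0$p, 0.05)
})

test_that("mixed-model screen recovers a planted interaction and t = beta/se", {
  # recovery is assessed on raw volumes, the scale the slopes are planted on
  x <- study_cohort(seed = 33)
  res <- fit_lme("voi_pons", x$cohort, "all", m = 34)
  # truth: published pons interaction -348.144 mm^3/yr
  expect_lt(abs(res$beta - (-348.144)) / 348.144, 0.5)
  expect_lt(res$p_bonferroni, 0.001)
  expect_equal(res$t, res$beta / res$se, tolerance = 1e-12)
  expect_true(res$df > 10 && res$df < 99)
  aff <- fit_lme("voi_pons", x$cohort, "affected", m = 34)
  expect_equal(aff$term, "delta_age")
  expect_lt(aff$beta, 0)
  expect_true(all(c("(Intercept)", "delta_age") %in% rownames(aff$fixed_cov)))
})

test_that("estimates are invariant to subject relabelling", {
  x <- study_cohort(seed = 34, regions = small_regions())
  adj <- adjust_all(x$cohort)$cohort
  r1 <- fit_lme("voi_pons", adj, "all")
  relab <- adj
  key <- setNames(sprintf("Z%03d", rev(seq_along(unique(adj$subject)))),
                  unique(adj$subject))
  relab$subject <- unname(key[adj$subject])
  r2 <- fit_lme("voi_pons", relab, "all")
  expect_equal(r1$beta, r2$beta, tolerance = 1e-8)
  expect_equal(r1$se, r2$se, tolerance = 1e-8)
})

test_that("affected-only slope agrees with group-model time + interaction when slopes match", {
  x <- study_cohort(seed = 35, regions = small_regions())
  adj <- adjust_all(x$cohort)$cohort
  g <- fit_lme("voi_putamen", adj, "all")
  a <- fit_lme("voi_putamen", adj, "affected")
  sum_g <- g$fixef[["delta_age"]] + g$fixef[["groupaffected:delta_age"]]
  expect_lt(abs(a$beta - sum_g), 2 * a$se)
})

test_that("screen_all returns one row per VOI with family-wide correction", {
  x <- study_cohort(seed = 36)
  adj <- adjust_all(x$cohort)$cohort
  res <- screen_all(adj, "group_by_time")
  expect_equal(nrow(res$table), 34)
  expect_equal(res$m, 34)
  ok <- res$table$ok
  expect_equal(res$table$p_bonferroni[ok], pmin(1, 34 * res$table$p[ok]),
               tolerance = 1e-12)
  expect_equal(res$table$t[ok], res$table$beta[ok] / res$table$se[ok],
               tolerance = 1e-12)
})

test_that("per-VOI failures are flagged while the remainder completes", {
  x <- study_cohort(seed = 37, regions = small_regions())
  co <- x$cohort
  co$voi_flat <- 1000  # zero-variance change cannot be modelled
  res <- screen_all(co, "affected_only")
  flat <- res$table[res$table$voi == "voi_flat", ]
  expect_false(flat$ok)
  expect_true(nzchar(flat$message))
  expect_true(all(res$table$ok[res$table$voi != "voi_flat"]))
})

test_that("screen tables serialize with the published column layout", {
  x <- study_cohort(seed = 38, regions = small_regions())
  res <- screen_all(x$cohort, "affected_only")
  path <- tempfile(fileext = ".tsv")
  write_screen_table(res, path)
  tab <- read.delim(path)
  expect_equal(names(tab), c("VOI", "beta", "SE", "df", "t", "P", "P_bonferroni"))
  expect_equal(nrow(tab), nrow(res$table))
  unlink(path)
  # machine-readable JSON keeps the fixed-effect covariance for downstream use
  jpath <- tempfile(fileext = ".json")
  write_screen_json(res, jpath)
  j <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(j$m, res$m)
  f1 <- j$fits[[1]]
  expect_equal(as.vector(unlist(f1$fixed_cov)),
               as.vector(res$fits[[f1$voi]]$fixed_cov), tolerance = 1e-12)
  expect_identical(unlist(f1$fixed_cov_terms),
                   rownames(res$fits[[f1$voi]]$fixed_cov))
  unlink(jpath)
})
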