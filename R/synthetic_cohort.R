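#' Study-condition region table
#'
#' The 34 volumes of interest (VOIs) screened in the SCA1 longitudinal study,
#' with generator ground truth: a typical adult volume at the reference ICV,
#' an allometric scaling exponent `beta` (near 1 for cortical aggregates,
#' below 1 for subcortical/cerebellar structures), per-group linear atrophy
#' slopes in mm^3/year, an optional quadratic acceleration term, and a
#' measurement-level residual SD.
#'
#' Affected-group slopes are the published within-affected elapsed-time
#' estimates; unaffected slopes are affected slope minus the published
#' group-by-time interaction, so the interaction contrast equals the
#' published magnitudes by construction. Mean volumes are literature-typical
#' values. The residual SD is calibrated so that the expected standard error
#' of the group-by-time interaction under the default design matches the
#' published SE: for this design SE ~= 0.24 x residual SD, hence
#' `residual_sd = interaction_se / 0.24` (see the methods vignette).
#'
#' @param icv_reference ICV (mm^3) at which `mean_volume` is attained; used to
#'   derive the power-law scale constant `alpha = mean_volume / icv_reference^beta`.
#' @return data.frame with columns `region`, `mean_volume`, `alpha`, `beta`,
#'   `slope_affected`, `slope_unaffected`, `accel`, `residual_sd`.
#' @export
sca1_study_regions <- function(icv_reference = 1510000) {
  # region, mean mm^3, beta, affected slope, group-by-time interaction, its SE
  tab <- read.csv(text = "region,mean_volume,beta,slope_affected,interaction,interaction_se
whole_brain,1200000,1.05,-12584.624,-8417.702,6623.368
cerebrum,1050000,1.05,-10848.905,-6864.891,6402.336
cerebral_gm,600000,1.00,-6523.224,-5325.858,3680.643
cerebral_wm,450000,1.10,-1610.601,82.611,2117.327
cerebellum,130000,0.90,-971.808,-1111.813,337.35
cbl_lobules_1_2,300,0.70,1.645,6.182,2.126
cbl_lobule_3,1500,0.70,5.003,-3.674,10.721
cbl_lobule_4,3500,0.70,-26.158,-14.073,19.859
cbl_lobule_5,6500,0.75,-40.215,-104.775,40.724
cbl_lobule_6,12000,0.75,-210.984,-191.258,41.204
cbl_crus_1,20000,0.80,-129.373,-212.965,121.987
cbl_crus_2,15000,0.80,-193.729,-397.944,197.379
cbl_lobule_7b,8500,0.75,11.347,-5.103,106.154
cbl_lobule_8a,8000,0.75,19.061,154.298,91.619
cbl_lobule_8b,6500,0.75,-18.594,57.53,61.447
cbl_lobule_9,7000,0.75,-5.616,-45.321,41.75
cbl_lobule_10,1200,0.70,31.742,28.049,17.78
cbl_wm_deep_nuclei,25000,0.80,-308.859,-258.66,56.339
corpus_callosum,20000,0.95,-46.005,-26.852,15.458
frontal_lobe,330000,1.05,-5454.899,-5563.115,2729.405
occipital_lobe,110000,1.00,-284.578,521.456,740.068
parietal_lobe,190000,1.05,-2305.137,-480.415,1743.822
temporal_lobe,200000,1.05,1395.581,1107.655,1093.294
caudate,7500,0.75,-106.709,-106.223,25.915
putamen,9500,0.75,-141.078,-136.797,28.651
pallidum,3200,0.75,-58.671,-75.485,14.032
accumbens,1100,0.70,3.968,12.328,31.652
hippocampus,8000,0.80,1.551,-4.378,11.367
amygdala,3000,0.75,-9.143,-8.45,7.248
thalamus,15000,0.80,-210.56,-59.833,49.289
hypothalamus_plus,2500,0.70,-89.29,-78.27,41.578
medulla,7500,0.75,11.577,-29.044,58.287
pons,22000,0.80,-304.985,-348.144,40.743
scp,600,0.70,-8.247,-4.505,2.773
", stringsAsFactors = FALSE)
  data.frame(
    region          = tab$region,
    mean_volume     = tab$mean_volume,
    alpha           = tab$mean_volume / icv_reference^tab$beta,
    beta            = tab$beta,
    slope_affected  = tab$slope_affected,
    slope_unaffected = tab$slope_affected - tab$interaction,
    accel           = 0,
    residual_sd     = tab$interaction_se / 0.24,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for a longitudinal SCA1-like cohort
#'
#' Defaults reproduce the study conditions: 13 affected / 20 unaffected
#' subjects, visits near 0, 1.5 and 3.0 years, group ICV distributions
#' matching the published means/SDs, regional volumes following
#' `VOI = alpha * ICV^beta * (1 + b_i) + slope_g * t + accel * t^2 + e`,
#' with a multiplicative subject random intercept `b_i`, and SARA change
#' driven by pontine change and putamen rate of change.
#'
#' @param n_affected,n_unaffected subject counts per group.
#' @param visit_times nominal elapsed-time grid in years, starting at 0.
#' @param visit_jitter_sd SD (years) of per-subject jitter on follow-up times.
#' @param icv_mean,icv_sd named (`affected`, `unaffected`) ICV moments, mm^3.
#' @param regions region ground-truth table, see [sca1_study_regions()].
#' @param subject_intercept_sd SD of the relative (multiplicative) subject
#'   intercept on the power-law mean.
#' @param slope_cv coefficient of variation of subject-specific atrophy
#'   slopes around the group slope (progression rates vary between
#'   individuals); 0 gives deterministic group slopes.
#' @param age_mean,age_sd baseline age distribution (years) per group.
#' @param p_female named per-group probability that a subject is female.
#' @param dropout logical; thin third visits (affected dropout + unaffected cap)?
#' @param dropout_p_affected probability an affected subject misses visit 3.
#' @param max_unaffected_visit3 cap on unaffected subjects with a third visit.
#' @param sara_baseline_mean,sara_baseline_sd baseline SARA distribution
#'   (points); affected default reflects an early-stage cohort (SARA < 15).
#' @param sara_coefficients named vector: `pons` (points per mm^3 of pontine
#'   change) and `putamen_rate` (points per mm^3/year of putamen rate of
#'   change, applied as rate x elapsed time).
#' @param sara_noise_sd SD of visit-level SARA noise (points).
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_affected = 13,
                       n_unaffected = 20,
                       visit_times = c(0, 1.5, 3.0),
                       visit_jitter_sd = 0.1,
                       icv_mean = c(affected = 1472062.4, unaffected = 1535453.8),
                       icv_sd = c(affected = 116358.8, unaffected = 135385.6),
                       regions = sca1_study_regions(),
                       subject_intercept_sd = 0.07,
                       slope_cv = 0.3,
                       age_mean = c(affected = 53.3, unaffected = 52.5),
                       age_sd = 9,
                       p_female = c(affected = 8 / 13, unaffected = 8 / 20),
                       dropout = TRUE,
                       dropout_p_affected = 3 / 16,
                       max_unaffected_visit3 = 15,
                       sara_baseline_mean = c(affected = 9, unaffected = 0.4),
                       sara_baseline_sd = 3,
                       sara_coefficients = c(pons = -0.00272, putamen_rate = -0.003),
                       sara_noise_sd = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_affected = n_affected, n_unaffected = n_unaffected,
    visit_times = visit_times, visit_jitter_sd = visit_jitter_sd,
    icv_mean = icv_mean, icv_sd = icv_sd, regions = regions,
    subject_intercept_sd = subject_intercept_sd, slope_cv = slope_cv,
    age_mean = age_mean, age_sd = age_sd, p_female = p_female,
    dropout = dropout, dropout_p_affected = dropout_p_affected,
    max_unaffected_visit3 = max_unaffected_visit3,
    sara_baseline_mean = sara_baseline_mean,
    sara_baseline_sd = sara_baseline_sd,
    sara_coefficients = sara_coefficients,
    sara_noise_sd = sara_noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_finite <- function(x, name) {
    if (!all(is.finite(x))) stop("non-finite value in config field '", name, "'", call. = FALSE)
  }
  if (cfg$n_affected < 1 || cfg$n_unaffected < 1)
    stop("subject counts must be >= 1 ('n_affected'/'n_unaffected')", call. = FALSE)
  chk_finite(cfg$visit_times, "visit_times")
  if (cfg$visit_times[1] != 0 || is.unsorted(cfg$visit_times, strictly = TRUE))
    stop("'visit_times' must be strictly increasing and start at 0", call. = FALSE)
  for (f in c("visit_jitter_sd", "icv_mean", "icv_sd", "subject_intercept_sd",
              "slope_cv", "age_mean", "age_sd", "p_female", "sara_baseline_mean",
              "sara_baseline_sd", "sara_coefficients", "sara_noise_sd"))
    chk_finite(cfg[[f]], f)
  for (f in c("visit_jitter_sd", "icv_sd", "subject_intercept_sd", "slope_cv",
              "age_sd", "sara_baseline_sd", "sara_noise_sd"))
    if (any(cfg[[f]] < 0)) stop("SD field '", f, "' must be >= 0", call. = FALSE)
  reg <- cfg$regions
  need <- c("region", "alpha", "beta", "slope_affected", "slope_unaffected",
            "accel", "residual_sd")
  if (!all(need %in% names(reg)))
    stop("config field 'regions' lacks columns: ",
         paste(setdiff(need, names(reg)), collapse = ", "), call. = FALSE)
  for (col in setdiff(need, "region")) chk_finite(reg[[col]], paste0("regions$", col))
  if (any(reg$residual_sd < 0)) stop("SD field 'regions$residual_sd' must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Simulate a longitudinal volumetric cohort
#'
#' One row per subject-visit. ICV is constant within subject; each regional
#' volume follows the allometric power law with a multiplicative subject
#' intercept, a group-specific linear atrophy slope, an optional quadratic
#' term and iid Gaussian measurement noise:
#' `VOI(i, t) = alpha * ICV_i^beta * (1 + b_i) + slope_g * t + accel * t^2 + e`.
#' Output is deterministic for a fixed config (the seed lives in the config).
#'
#' @param config a [sim_config()] object.
#' @return list with `cohort` (data.frame: subject, group, gender, visit,
#'   time, age, baseline_age, icv, one `voi_*` column per region) and
#'   `params` (ground truth of class `true_params`: the region table, the
#'   realized subject intercepts, variance components, SARA coefficients and
#'   the generating config).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  n <- config$n_affected + config$n_unaffected
  group <- rep(c("affected", "unaffected"), c(config$n_affected, config$n_unaffected))
  subject <- sprintf("S%03d", seq_len(n))
  gender <- ifelse(stats::runif(n) < config$p_female[group], "F", "M")
  icv <- stats::rnorm(n, config$icv_mean[group], config$icv_sd[group])
  age0 <- stats::rnorm(n, config$age_mean[group], config$age_sd)
  b_i <- stats::rnorm(n, 0, config$subject_intercept_sd)

  nv <- length(config$visit_times)
  # follow-up times jittered per subject; baseline pinned at 0
  times <- matrix(rep(config$visit_times, each = n), nrow = n)
  if (nv > 1) {
    jit <- matrix(stats::rnorm(n * (nv - 1), 0, config$visit_jitter_sd), nrow = n)
    times[, -1] <- times[, -1] + jit
    times <- t(apply(times, 1, sort))
  }

  keep <- matrix(TRUE, n, nv)
  if (config$dropout && nv >= 3) {
    aff <- which(group == "affected")
    keep[aff, nv] <- stats::runif(length(aff)) >= config$dropout_p_affected
    unaff <- which(group == "unaffected")
    if (length(unaff) > config$max_unaffected_visit3) {
      drop_out <- sample(unaff, length(unaff) - config$max_unaffected_visit3)
      keep[drop_out, nv] <- FALSE
    }
  }

  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  i <- idx[, 1]; v <- idx[, 2]
  t_ij <- times[idx]

  reg <- config$regions
  # subject-specific atrophy slopes around the group slope
  g_slope <- cbind(affected = reg$slope_affected, unaffected = reg$slope_unaffected)
  slope_i <- matrix(NA_real_, n, nrow(reg),
                    dimnames = list(subject, reg$region))
  for (r in seq_len(nrow(reg))) {
    mu_s <- g_slope[r, ifelse(group == "affected", 1L, 2L)]
    slope_i[, r] <- stats::rnorm(n, mu_s, config$slope_cv * abs(mu_s))
  }
  voi <- matrix(NA_real_, length(i), nrow(reg),
                dimnames = list(NULL, paste0("voi_", reg$region)))
  for (r in seq_len(nrow(reg))) {
    mu <- reg$alpha[r] * icv[i]^reg$beta[r] * (1 + b_i[i]) +
      slope_i[i, r] * t_ij + reg$accel[r] * t_ij^2
    voi[, r] <- mu + stats::rnorm(length(i), 0, reg$residual_sd[r])
  }

  cohort <- data.frame(
    subject = subject[i], group = group[i], gender = gender[i],
    visit = v, time = t_ij, age = age0[i] + t_ij, baseline_age = age0[i],
    icv = icv[i], stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, as.data.frame(voi))
  rownames(cohort) <- NULL

  params <- list(
    regions = reg,
    subject_slopes = slope_i,
    subject_intercepts = stats::setNames(b_i, subject),
    subject_intercept_sd = config$subject_intercept_sd,
    sara_coefficients = config$sara_coefficients,
    sara_baseline_mean = config$sara_baseline_mean,
    sara_baseline_sd = config$sara_baseline_sd,
    sara_noise_sd = config$sara_noise_sd,
    config = config
  )
  class(params) <- "true_params"
  list(cohort = cohort, params = params)
}

#' Add simulated SARA scores to a cohort
#'
#' Baseline SARA is drawn per subject (clamped to the 0-40 scale range);
#' follow-up change is `dSARA = c1 * d_pons + c2 * (d_putamen / dt) * dt + noise`,
#' i.e. pontine cumulative change plus putamen rate of change accumulated over
#' elapsed time, per the generative model the selection stage is meant to
#' recover. SARA is clamped to [0, 40].
#'
#' @param cohort data.frame from [simulate_cohort()] containing `voi_pons`
#'   and `voi_putamen`.
#' @param params the matching `true_params`.
#' @param seed optional seed; defaults to the config seed + 1 so that cohort
#'   and SARA noise streams are reproducible yet distinct.
#' @return the cohort with a `sara` column.
#' @export
simulate_sara <- function(cohort, params, seed = NULL) {
  stopifnot(inherits(params, "true_params"))
  for (col in c("voi_pons", "voi_putamen"))
    if (!col %in% names(cohort))
      stop("cohort lacks required region column '", col, "'", call. = FALSE)
  if (is.null(seed)) seed <- params$config$seed + 1L
  set.seed(seed)

  subj <- unique(cohort$subject)
  grp <- cohort$group[match(subj, cohort$subject)]
  base <- stats::rnorm(length(subj),
                       params$sara_baseline_mean[grp],
                       params$sara_baseline_sd)
  base <- pmin(pmax(base, 0), 40)
  names(base) <- subj

  c1 <- params$sara_coefficients[["pons"]]
  c2 <- params$sara_coefficients[["putamen_rate"]]

  ord <- order(cohort$subject, cohort$time)
  sara <- numeric(nrow(cohort))
  for (s in subj) {
    rows <- ord[cohort$subject[ord] == s]
    t0 <- rows[1]
    dt <- cohort$time[rows] - cohort$time[t0]
    dpons <- cohort$voi_pons[rows] - cohort$voi_pons[t0]
    dput <- cohort$voi_putamen[rows] - cohort$voi_putamen[t0]
    rate_term <- ifelse(dt > 0, (dput / dt) * dt, 0)
    noise <- c(0, stats::rnorm(length(rows) - 1, 0, params$sara_noise_sd))
    dsara <- c1 * dpons + c2 * rate_term + noise
    sara[rows] <- pmin(pmax(base[s] + dsara, 0), 40)
  }
  cohort$sara <- sara
  cohort
}
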