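# Shared fixtures, built in code at test time.

# study-scale cohort with SARA, default conditions
study_cohort <- function(seed = 11, ...) {
  cfg <- sim_config(seed = seed, ...)
  sim <- simulate_cohort(cfg)
  list(cohort = simulate_sara(sim$cohort, sim$params),
       params = sim$params, config = cfg)
}

# reduced region table (keeps tests that do not need all 34 regions fast)
small_regions <- function() {
  reg <- sca1_study_regions()
  reg[reg$region %in% c("pons", "putamen", "caudate", "pallidum",
                        "cbl_lobule_6", "cbl_wm_deep_nuclei"), ]
}

# random penalized design with iid or clustered response and known truth
random_design <- function(n_sub = 60, n_per = 3, p = 6, seed = 1,
                          sd_b = 1, sd_e = 0.7, beta = NULL) {
  set.seed(seed)
  n <- n_sub * n_per
  subject <- rep(sprintf("S%03d", seq_len(n_sub)), each = n_per)
  X <- cbind(1, matrix(rnorm(n * p), ncol = p))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(p)))
  if (is.null(beta)) beta <- c(1, rnorm(p))
  y <- as.vector(X %*% beta) + rep(rnorm(n_sub, 0, sd_b), each = n_per) +
    rnorm(n, 0, sd_e)
  d <- list(y = y, X = X, subject = subject,
            penalized = stats::setNames(c(FALSE, rep(TRUE, p)), colnames(X)),
            center = stats::setNames(rep(0, p + 1), colnames(X)),
            scale = stats::setNames(rep(1, p + 1), colnames(X)),
            terms = colnames(X))
  class(d) <- "lasso_design"
  list(design = d, beta = beta, sd_b = sd_b, sd_e = sd_e)
}

# lme4 maximum-likelihood fit of a lasso_design (independent oracle)
lme4_ml_fit <- function(design) {
  df <- data.frame(y = design$y, design$X[, -1, drop = FALSE],
                   subject = design$subject, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "y ~", paste(sprintf("`%s`", colnames(design$X)[-1]), collapse = " + "),
    "+ (1 | subject)"))
  suppressWarnings(suppressMessages(
    lme4::lmer(fml, data = df, REML = FALSE)))
}
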