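# Power-proportion adjustment of regional volumes for intracranial volume:
# fit VOI = alpha * ICV^beta by nonlinear least squares, divide by ICV^beta,
# then rescale back to natural units (raw mean and SD).

#' Fit the allometric power law VOI = alpha * ICV^beta
#'
#' Nonlinear least squares on the original mm^3 scale, warm-started from the
#' closed-form log-log ordinary least squares fit. Levenberg-Marquardt is
#' used so that exact (zero-residual) data converge cleanly.
#'
#' @param voi,icv positive numeric vectors of equal length (n >= 3).
#' @return list of class `power_law_fit`: `alpha`, `beta`, `r_pre`
#'   (cor(voi, icv)), `r_post` (cor(voi/icv^beta, icv)), `n_obs`, `converged`.
#' @export
fit_power_law <- function(voi, icv) {
  if (length(voi) != length(icv)) stop("'voi' and 'icv' lengths differ")
  if (length(voi) < 3) stop("need at least 3 observations to fit the power law")
  if (any(!is.finite(voi)) || any(!is.finite(icv)) || any(voi <= 0) || any(icv <= 0))
    stop("power-law fit requires finite, strictly positive 'voi' and 'icv'")

  # closed-form start on the log-log scale
  lx <- log(icv); ly <- log(voi)
  vx <- stats::var(lx)
  if (vx == 0) stop("ICV is constant; the scaling exponent is unidentifiable")
  b0 <- stats::cov(lx, ly) / vx
  mlx <- mean(lx)

  # same model, original mm^3 scale, but parameterized as
  # exp(la + beta * (log ICV - mean log ICV)): centring keeps the Jacobian
  # well conditioned because log ICV varies little around its mean
  clx <- lx - mlx
  fit <- minpack.lm::nlsLM(
    voi ~ exp(la + beta * clx),
    data = data.frame(voi = voi, clx = clx),
    start = list(la = mean(ly), beta = b0),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-10)
  )
  cf <- stats::coef(fit)
  if (!isTRUE(fit$convInfo$isConv))
    stop("power-law fit did not converge: ", fit$convInfo$stopMessage)
  cf <- c(alpha = exp(cf[["la"]] - cf[["beta"]] * mlx), beta = cf[["beta"]])

  adj <- voi / icv^cf[["beta"]]
  out <- list(
    alpha = cf[["alpha"]], beta = cf[["beta"]],
    r_pre = if (stats::sd(voi) > 0) stats::cor(voi, icv) else NA_real_,
    r_post = if (stats::sd(adj) > 0) stats::cor(adj, icv) else NA_real_,
    n_obs = length(voi), converged = TRUE
  )
  class(out) <- "power_law_fit"
  out
}

#' Divide volumes by ICV raised to the fitted exponent
#'
#' @param voi volumes (mm^3).
#' @param icv intracranial volumes (mm^3, > 0).
#' @param beta finite scaling exponent.
#' @return `voi / icv^beta`.
#' @export
adjust_voi <- function(voi, icv, beta) {
  if (!is.finite(beta)) stop("'beta' must be finite")
  if (any(icv <= 0)) stop("'icv' must be strictly positive")
  voi / icv^beta
}

#' Rescale adjusted volumes to natural units
#'
#' Centres on the adjusted mean, scales by the adjusted SD, then restores the
#' raw SD and mean: `((adjusted - mu_adj) / sigma_adj) * sigma_raw + mu_raw`.
#' Over the fitting sample the output reproduces the raw mean and SD exactly.
#'
#' @param adjusted adjusted volumes.
#' @param mu_adj,sigma_adj mean and SD of the adjusted volumes (sigma_adj > 0).
#' @param mu_raw,sigma_raw mean and SD of the raw volumes.
#' @return rescaled volumes in mm^3.
#' @export
rescale_natural_units <- function(adjusted, mu_adj, sigma_adj, mu_raw, sigma_raw) {
  if (!is.finite(sigma_adj) || sigma_adj <= 0)
    stop("'sigma_adj' must be > 0 (adjusted volumes are constant?)")
  (adjusted - mu_adj) / sigma_adj * sigma_raw + mu_raw
}

#' Power-proportion adjust every VOI column of a cohort
#'
#' For each `voi_*` column (pooled over subjects, groups and visits by
#' default): fit the power law, divide by `ICV^beta`, rescale to natural
#' units, and record pre-/post-adjustment correlations with ICV. Per-VOI fit
#' failures are flagged and the remaining VOIs are completed.
#'
#' @param cohort cohort data.frame with `icv` and `voi_*` columns.
#' @param voi_cols columns to adjust; default all `voi_*` columns.
#' @param baseline_only fit alpha/beta on baseline rows only (applied to all
#'   rows); default FALSE (pooled fit).
#' @return list: `cohort` (adjusted volumes in natural units) and `summary`
#'   (data.frame of class `adjustment_summary`: per-VOI alpha, beta, r_pre,
#'   r_post, raw/adjusted moments, ok flag, message).
#' @export
adjust_all <- function(cohort, voi_cols = NULL, baseline_only = FALSE) {
  if (!"icv" %in% names(cohort)) stop("cohort lacks an 'icv' column")
  if (is.null(voi_cols)) voi_cols <- grep("^voi_", names(cohort), value = TRUE)
  if (length(voi_cols) == 0) stop("no VOI columns to adjust")

  fit_rows <- if (baseline_only) {
    if (!"time" %in% names(cohort)) stop("'baseline_only' requires a 'time' column")
    stats::ave(cohort$time, cohort$subject, FUN = min) == cohort$time
  } else rep(TRUE, nrow(cohort))

  out <- cohort
  summ <- data.frame(voi = voi_cols, alpha = NA_real_, beta = NA_real_,
                     r_pre = NA_real_, r_post = NA_real_,
                     mu_raw = NA_real_, sigma_raw = NA_real_,
                     mu_adj = NA_real_, sigma_adj = NA_real_,
                     n_obs = NA_integer_, ok = FALSE, message = "",
                     stringsAsFactors = FALSE)
  for (j in seq_along(voi_cols)) {
    col <- voi_cols[j]
    res <- tryCatch({
      fit <- fit_power_law(cohort[[col]][fit_rows], cohort$icv[fit_rows])
      adj <- adjust_voi(cohort[[col]], cohort$icv, fit$beta)
      mu_raw <- mean(cohort[[col]][fit_rows]); sigma_raw <- stats::sd(cohort[[col]][fit_rows])
      mu_adj <- mean(adj[fit_rows]); sigma_adj <- stats::sd(adj[fit_rows])
      out[[col]] <- rescale_natural_units(adj, mu_adj, sigma_adj, mu_raw, sigma_raw)
      summ[j, c("alpha", "beta", "r_pre", "r_post", "mu_raw", "sigma_raw",
                "mu_adj", "sigma_adj")] <-
        c(fit$alpha, fit$beta, fit$r_pre, fit$r_post, mu_raw, sigma_raw,
          mu_adj, sigma_adj)
      summ$n_obs[j] <- fit$n_obs
      summ$ok[j] <- TRUE
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) summ$message[j] <- res
  }
  if (any(!summ$ok))
    warning("power-law adjustment failed for: ",
            paste(summ$voi[!summ$ok], collapse = ", "))
  class(summ) <- c("adjustment_summary", class(summ))
  list(cohort = out, summary = summ)
}

#' Write an adjustment summary as JSON
#' @param summary from [adjust_all()].
#' @param path output file.
#' @export
write_adjustment_summary <- function(summary, path) {
  jsonlite::write_json(as.data.frame(unclass(summary)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
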