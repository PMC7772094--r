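# Detectability horizon: earliest elapsed time at which the predicted
# cumulative volume change within affected individuals is non-zero at a
# stated confidence level, using the fixed-effect covariance of an
# affected-only mixed-model fit.

#' Earliest time at which predicted volume change is detectably non-zero
#'
#' Under the default `"cumulative"` method, the predicted change at elapsed
#' time t is `c(t) = beta0 + beta_time * t` with variance
#' `v00 + t^2 * v_tt + 2 t * v0t` from the fixed-effect covariance; the
#' detectability horizon is the smallest t in (0, horizon] at which the
#' two-sided confidence interval for `c(t)` excludes zero, located by grid
#' scan plus bisection to `tol` years. The critical value comes from the t
#' distribution at the fit's denominator df (normal when `df = Inf`).
#'
#' The alternative `"slope"` method implements the literal reading of a
#' confidence interval on the slope alone, which is time-invariant: it
#' returns detectable-at-any-t (t_detect ~ 0) when the slope CI excludes
#' zero and not-detectable otherwise.
#'
#' @param fit an `lme_result` from [fit_lme()] (affected-only screen), or a
#'   list with elements `beta0`, `beta_time`, `cov` (2x2, order intercept then
#'   time) and optionally `df`.
#' @param confidence confidence level, default 0.99.
#' @param horizon search horizon in years.
#' @param method `"cumulative"` (default) or `"slope"`.
#' @param tol bisection tolerance in years.
#' @return list of class `detectability_result`: `voi`, `t_detect` (years, NA
#'   if not detectable within the horizon), `detectable`, `confidence`,
#'   `method`.
#' @export
time_to_detectable_change <- function(fit, confidence = 0.99, horizon = 5,
                                      method = c("cumulative", "slope"),
                                      tol = 1e-4) {
  method <- match.arg(method)
  par <- extract_change_model(fit)
  V <- par$cov
  if (any(!is.finite(V)) || V[1, 1] < 0 || V[2, 2] < 0 ||
      abs(V[1, 2]) > sqrt(V[1, 1] * V[2, 2]) + 1e-12)
    stop("fixed-effect covariance is not positive semi-definite")
  zc <- crit_value(confidence, par$df)

  if (method == "slope") {
    detectable <- abs(par$beta_time) > zc * sqrt(V[2, 2])
    out <- list(voi = par$voi, t_detect = if (detectable) 0 else NA_real_,
                detectable = detectable, confidence = confidence,
                method = method)
    class(out) <- "detectability_result"
    return(out)
  }

  g <- function(t) abs(par$beta0 + par$beta_time * t) -
    zc * sqrt(V[1, 1] + t^2 * V[2, 2] + 2 * t * V[1, 2])

  # grid scan for the first sign change, then bisection
  grid <- seq(0, horizon, length.out = 2048)
  gv <- g(grid)
  pos <- which(gv > 0 & grid > 0)
  if (length(pos) == 0) {
    t_detect <- NA_real_
  } else {
    hi <- grid[pos[1]]
    lo <- if (pos[1] == 1) 0 else grid[pos[1] - 1]
    if (g(lo) > 0) {
      t_detect <- lo
    } else {
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (g(mid) > 0) hi <- mid else lo <- mid
      }
      t_detect <- (lo + hi) / 2
    }
  }
  out <- list(voi = par$voi, t_detect = t_detect,
              detectable = is.finite(t_detect), confidence = confidence,
              method = method)
  class(out) <- "detectability_result"
  out
}

#' Closed-form detectability horizon
#'
#' Smallest positive root of
#' `(beta_time^2 - z^2 v_tt) t^2 + 2 (beta0 beta_time - z^2 v0t) t +
#'  (beta0^2 - z^2 v00) = 0`
#' beyond which the CI for the predicted change excludes zero; independent
#' oracle for the bisection solver. Returns NA when no real positive root
#' yields detection.
#'
#' @inheritParams time_to_detectable_change
#' @param horizon years; roots beyond it are treated as not detectable.
#' @export
detect_time_closed_form <- function(fit, confidence = 0.99, horizon = 5) {
  par <- extract_change_model(fit)
  V <- par$cov
  z2 <- crit_value(confidence, par$df)^2
  a <- par$beta_time^2 - z2 * V[2, 2]
  b <- 2 * (par$beta0 * par$beta_time - z2 * V[1, 2])
  cc <- par$beta0^2 - z2 * V[1, 1]
  roots <- if (abs(a) < 1e-300) {
    if (b == 0) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0) else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  g <- function(t) abs(par$beta0 + par$beta_time * t) -
    sqrt(z2) * sqrt(V[1, 1] + t^2 * V[2, 2] + 2 * t * V[1, 2])
  roots <- sort(roots[is.finite(roots) & roots > 0 & roots <= horizon])
  for (r in roots) {
    if (g(min(r + 1e-9 + 1e-6 * r, horizon)) > 0) return(r)
  }
  NA_real_
}

crit_value <- function(confidence, df) {
  stopifnot(confidence > 0, confidence < 1)
  pr <- 1 - (1 - confidence) / 2
  if (is.null(df) || !is.finite(df)) stats::qnorm(pr) else stats::qt(pr, df)
}

# normalize an lme_result or bare list into (voi, beta0, beta_time, cov, df)
extract_change_model <- function(fit) {
  if (inherits(fit, "lme_result")) {
    fe <- fit$fixef
    if (!all(c("(Intercept)", "delta_age") %in% names(fe)))
      stop("fit lacks intercept/elapsed-time coefficients")
    # predicted change for the average modeled participant: evaluate the
    # non-time part of the fixed effects at the sample-mean covariate vector
    x0 <- fit$xbar
    x0["delta_age"] <- 0
    et <- as.numeric(names(fe) == "delta_age")
    Vfull <- fit$fixed_cov[names(fe), names(fe)]
    V <- matrix(c(
      drop(x0 %*% Vfull %*% x0), drop(x0 %*% Vfull %*% et),
      drop(x0 %*% Vfull %*% et), drop(et %*% Vfull %*% et)), 2, 2)
    list(voi = fit$voi, beta0 = drop(x0 %*% fe),
         beta_time = unname(fe["delta_age"]), cov = V, df = fit$df)
  } else {
    stopifnot(all(c("beta0", "beta_time", "cov") %in% names(fit)))
    list(voi = if (is.null(fit$voi)) NA_character_ else fit$voi,
         beta0 = fit$beta0, beta_time = fit$beta_time,
         cov = fit$cov, df = if (is.null(fit$df)) Inf else fit$df)
  }
}

#' Detectability table across VOIs
#'
#' Applies [time_to_detectable_change()] to each affected-only fit, sorts by
#' the detection time, and flags which VOIs also passed the group screen
#' (the solid-versus-dashed distinction in interval plots).
#'
#' @param results a `screen_results` from the affected-only family (or a list
#'   of `lme_result`s).
#' @param group_significant character vector of VOI names that passed the
#'   group-by-time screen.
#' @param ... passed to [time_to_detectable_change()].
#' @return data.frame: voi, t_detect_years, detectable, confidence, method,
#'   group_significant; sorted by t_detect ascending (NA last).
#' @export
detectability_table <- function(results, group_significant = character(0), ...) {
  fits <- if (inherits(results, "screen_results")) results$fits else results
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("no fits supplied")
  rows <- lapply(fits, function(f) {
    d <- time_to_detectable_change(f, ...)
    data.frame(voi = d$voi, t_detect_years = d$t_detect,
               detectable = d$detectable, confidence = d$confidence,
               method = d$method,
               group_significant = d$voi %in% group_significant)
  })
  out <- do.call(rbind, rows)
  out <- out[order(is.na(out$t_detect_years), out$t_detect_years), ]
  rownames(out) <- NULL
  out
}
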