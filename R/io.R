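# Cohort readers/writers and the pipeline orchestrator.

COHORT_MANDATORY <- c("subject", "group", "gender", "visit", "age", "icv")

#' Read a cohort table from CSV/TSV
#'
#' Validates mandatory columns (`subject`, `group`, `gender`, `visit`, `age`,
#' `icv`), requires at least one `voi_*` column, rejects duplicated
#' subject-visit keys, and warns when ICV falls outside a plausible adult
#' band (0.8-2.2 x 10^6 mm^3).
#'
#' @param path CSV (default) or TSV file (by extension).
#' @return validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  cohort <- utils::read.table(path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
  validate_cohort(cohort)
}

validate_cohort <- function(cohort) {
  missing <- setdiff(COHORT_MANDATORY, names(cohort))
  if (length(missing))
    stop("cohort lacks mandatory column(s): ", paste(missing, collapse = ", "))
  if (!any(grepl("^voi_", names(cohort))))
    stop("cohort has no 'voi_*' columns")
  key <- paste(cohort$subject, cohort$visit)
  if (anyDuplicated(key))
    stop("duplicated subject-visit key(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  bad <- cohort$icv < 0.8e6 | cohort$icv > 2.2e6
  if (any(bad))
    warning(sum(bad), " row(s) with ICV outside the plausible band ",
            "0.8e6-2.2e6 mm^3")
  cohort
}

#' Write a cohort table as CSV
#' @param cohort cohort data.frame.
#' @param path output file.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write / read ground-truth simulation parameters as JSON
#' @param params a `true_params` object.
#' @param path JSON file.
#' @export
write_true_params <- function(params, path) {
  x <- unclass(params)
  x$config <- unclass(x$config)
  x$config$regions <- NULL  # stored once at top level
  # named vectors serialize as JSON objects, not bare arrays
  for (f in c("sara_coefficients", "sara_baseline_mean", "subject_intercepts"))
    x[[f]] <- as.list(x[[f]])
  for (f in c("icv_mean", "icv_sd", "age_mean", "p_female",
              "sara_baseline_mean", "sara_coefficients"))
    x$config[[f]] <- as.list(x$config[[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# stable hash of a configuration (FNV-1a over its serialized JSON)
config_hash <- function(config) {
  s <- jsonlite::serializeJSON(config)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 2^32
  sprintf("%08x", h)
}

#' Run the full analysis pipeline on a cohort
#'
#' Stages, in order: ICV power-proportion adjustment; baseline group
#' comparison; group-by-time and affected-only mixed-effects screens;
#' detectability horizons; penalized SARA selection. Each stage's output is
#' written under `out_dir` together with a run log carrying the config hash
#' and seed, so reruns with the same config are bit-identical.
#'
#' @param cohort cohort data.frame (or a path readable by [read_cohort()]).
#' @param out_dir output directory.
#' @param stages character subset of
#'   `c("adjust", "baseline", "screens", "detectability", "lasso")`.
#' @param m Bonferroni family size (default: number of VOI columns).
#' @param confidence detectability confidence level.
#' @param lambdas penalty grid for the selection stage.
#' @param alpha_screen Bonferroni-corrected significance threshold used to
#'   carry VOIs from the screens into the selection stage.
#' @param seed seed recorded in the run log and used for fold assignment.
#' @return invisibly, a list with every stage's in-memory results.
#' @export
run_pipeline <- function(cohort, out_dir,
                         stages = c("adjust", "baseline", "screens",
                                    "detectability", "lasso"),
                         m = NULL, confidence = 0.99, lambdas = 1:100,
                         alpha_screen = 0.05, seed = 1L) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  validate_cohort(cohort)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(stages = stages, m = m, confidence = confidence,
                 lambdas = lambdas, alpha_screen = alpha_screen, seed = seed)
  hash <- config_hash(config)
  results <- list(config = config, config_hash = hash)

  cohort <- decompose_age(cohort)
  cohort <- change_from_baseline(cohort)

  if ("adjust" %in% stages) {
    adj <- adjust_all(cohort)
    cohort <- change_from_baseline(adj$cohort[, setdiff(names(adj$cohort), grep("^d_", names(adj$cohort), value = TRUE))])
    write_cohort(cohort, file.path(out_dir, "adjusted_cohort.csv"))
    write_adjustment_summary(adj$summary, file.path(out_dir, "adjustment_summary.json"))
    results$adjustment <- adj$summary
  }
  vois <- grep("^voi_", names(cohort), value = TRUE)
  if (is.null(m)) m <- length(vois)

  if ("baseline" %in% stages) {
    bl <- screen_all(cohort, "baseline", m = m)
    write_screen_table(bl, file.path(out_dir, "baseline_comparison.tsv"))
    results$baseline <- bl
  }
  if (any(c("screens", "detectability", "lasso") %in% stages)) {
    grp <- screen_all(cohort, "group_by_time", m = m)
    aff <- screen_all(cohort, "affected_only", m = m)
    write_screen_table(grp, file.path(out_dir, "group_by_time_screen.tsv"))
    write_screen_table(aff, file.path(out_dir, "affected_only_screen.tsv"))
    results$group_screen <- grp
    results$affected_screen <- aff
  }
  if ("detectability" %in% stages) {
    sig_grp <- results$group_screen$table$voi[
      results$group_screen$table$ok &
        results$group_screen$table$p_bonferroni < alpha_screen]
    det <- detectability_table(results$affected_screen,
                               group_significant = sig_grp,
                               confidence = confidence)
    utils::write.table(det, file.path(out_dir, "detectability.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results$detectability <- det
  }
  if ("lasso" %in% stages && "sara" %in% names(cohort)) {
    sig_grp <- results$group_screen$table$voi[
      results$group_screen$table$ok &
        results$group_screen$table$p_bonferroni < alpha_screen]
    sig_aff <- results$affected_screen$table$voi[
      results$affected_screen$table$ok &
        results$affected_screen$table$p_bonferroni < alpha_screen]
    selected <- intersect(sig_grp, sig_aff)
    if (length(selected) > 0) {
      design <- build_design(cohort, selected)
      path <- lambda_path(design, lambdas)
      cv <- tryCatch(cross_validate(design, lambdas, seed = seed),
                     error = function(e) NULL)
      report <- suppressWarnings(report_selection(path, design))
      path_tab <- data.frame(lambda = path$lambdas, bic = path$bic,
                             logLik = path$logLik,
                             active_size = path$active_size)
      if (!is.null(cv)) path_tab$cv_error <- cv$cv_error
      utils::write.table(path_tab, file.path(out_dir, "lasso_path.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(lambda_star = report$lambda_star, selected = report$selected,
             zeroed = report$zeroed),
        file.path(out_dir, "lasso_selection.json"),
        auto_unbox = TRUE, digits = NA)
      results$lasso <- list(path = path, cv = cv, report = report,
                            selected_vois = selected)
    } else {
      results$lasso <- list(selected_vois = character(0))
    }
  }

  log <- list(config = config, config_hash = hash, seed = seed,
              r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("sca1vol")))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Run the pipeline from a YAML configuration file
#'
#' The YAML file supplies [run_pipeline()]'s arguments: `cohort` (a CSV/TSV
#' path), `out_dir`, and optionally `stages`, `m`, `confidence`, `lambdas`
#' (either a vector or `list(from, to)`), `alpha_screen` and `seed`.
#'
#' @param path YAML file.
#' @return invisibly, the pipeline results (see [run_pipeline()]).
#' @export
run_pipeline_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  cfg <- yaml::read_yaml(path)
  for (f in c("cohort", "out_dir"))
    if (is.null(cfg[[f]])) stop("config lacks required field '", f, "'")
  if (!file.exists(cfg$cohort)) stop("cohort file not found: ", cfg$cohort)
  if (is.list(cfg$lambdas)) cfg$lambdas <- seq(cfg$lambdas$from, cfg$lambdas$to)
  args <- cfg[intersect(names(cfg), names(formals(run_pipeline)))]
  do.call(run_pipeline, args)
}
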