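#!/usr/bin/env Rscript
# Penalized mixed-effects selection of volumetric predictors of SARA change:
# integer penalty grid 1-100, BIC selection, subject-grouped cross-validation,
# naive post-selection Wald inference at the selected penalty.

suppressMessages(library(sca1vol))

cohort <- read_cohort("results/cohort_adjusted.csv")
grp <- screen_all(cohort, "group_by_time")
aff <- screen_all(cohort, "affected_only")
sig <- function(s) s$table$voi[s$table$ok & s$table$p_bonferroni < 0.05]
selected_vois <- intersect(sig(grp), sig(aff))
cat("candidate regions (passed both screens):", selected_vois, "\n")

design <- build_design(cohort, selected_vois)
path <- suppressWarnings(lambda_path(design, 1:100))
cv <- cross_validate(design, 1:100, n_folds = 5, seed = 20260901L)
report <- suppressWarnings(report_selection(path, design))

tab <- data.frame(lambda = path$lambdas, bic = path$bic,
                  active_size = path$active_size, cv_error = cv$cv_error)
write.table(tab, "results/lasso_path.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
jsonlite::write_json(list(lambda_star = report$lambda_star,
                          selected = report$selected, zeroed = report$zeroed),
                     "results/lasso_selection.json",
                     auto_unbox = TRUE, digits = NA)

cat("BIC-optimal lambda:", report$lambda_star, "\n")
if (nrow(report$selected)) {
  cat("selected terms:\n")
  print(report$selected, row.names = FALSE)
} else cat("no penalized term survives the selected penalty\n")
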