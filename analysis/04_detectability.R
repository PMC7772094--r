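#!/usr/bin/env Rscript
# Detectability horizon: the earliest elapsed time at which the 99% CI of the
# predicted within-affected volume change excludes zero, from the affected-only
# mixed-model fits.

suppressMessages(library(sca1vol))

cohort <- read_cohort("results/cohort_adjusted.csv")
grp <- screen_all(cohort, "group_by_time")
aff <- screen_all(cohort, "affected_only")
sig <- grp$table$voi[grp$table$ok & grp$table$p_bonferroni < 0.05]

det <- detectability_table(aff, group_significant = sig, confidence = 0.99)
write.table(det, "results/detectability.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

top <- det[det$detectable, ][1:6, ]
cat("fastest detectable regions (99% confidence):\n")
print(top[, c("voi", "t_detect_years", "group_significant")], row.names = FALSE)
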