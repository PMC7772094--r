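#!/usr/bin/env Rscript
# Three screens over the 34 adjusted regional volumes with Bonferroni m = 34:
# (a) baseline cross-sectional group comparison (standardized coefficients),
# (b) group-by-elapsed-time interaction (differential atrophy),
# (c) elapsed-time effect within affected individuals only.

suppressMessages(library(sca1vol))

cohort <- read_cohort("results/cohort_adjusted.csv")

bl <- screen_all(cohort, "baseline")
grp <- screen_all(cohort, "group_by_time")
aff <- screen_all(cohort, "affected_only")

write_screen_table(bl, "results/baseline_comparison.tsv")
write_screen_table(grp, "results/group_by_time_screen.tsv")
write_screen_table(aff, "results/affected_only_screen.tsv")

sig <- function(s) s$table$voi[s$table$ok & s$table$p_bonferroni < 0.05]
cat("baseline group differences (Bonferroni):", sig(bl), "\n")
cat("group x time interactions (Bonferroni):", sig(grp), "\n")
cat("within-affected change (Bonferroni):", sig(aff), "\n")
cat("regions passing both longitudinal screens:",
    intersect(sig(grp), sig(aff)), "\n")
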