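#!/usr/bin/env Rscript
# Desk-scale multi-atlas labelling: Jacobian-similarity exemplar selection,
# similarity-weighted majority-vote fusion over 10 exemplars x 5 label sets,
# and regional volume extraction, on a 32^3 synthetic atlas stack.

suppressMessages(library(sca1vol))
dir.create("results/atlas", showWarnings = FALSE, recursive = TRUE)

st <- simulate_atlas_stack(c(32, 32, 32), n_candidates = 10, n_label_sets = 5,
                           disagreement = 0.1, seed = 20260901L)
write_atlas_stack(st, "results/atlas/stack")

res <- magma_label(st, k = 10)
cat("exemplar similarity scores:", round(res$scores, 3), "\n")
cat("chosen exemplars:", res$selection$chosen, "\n")

lab <- RNifti::asNifti(res$label_map$labels * 1L)
RNifti::writeNifti(lab, "results/atlas/magma_labels.nii.gz")
write_region_dictionary(res$label_map$region_dictionary,
                        "results/atlas/region_dictionary.tsv")
vol <- data.frame(region = names(res$voi_record$volumes),
                  volume_mm3 = as.numeric(res$voi_record$volumes))
write.csv(vol, "results/atlas/volumes.csv", row.names = FALSE)

cat("labelling accuracy vs ground truth:",
    round(mean(res$label_map$labels[st$mask] == st$true_labels[st$mask]), 4), "\n")
cat("ICV (mm^3):", res$voi_record$icv, "\n")
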