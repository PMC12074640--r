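#!/usr/bin/env Rscript
# Log-rank survival tree on the OS-associated TC activities plus age and
# stage, with subsample robustness of the root classifier ranking and
# Harrell's concordance of the leaf ordering.

suppressMessages(library(cicasurv))

sim <- "scratch/sim"
dec <- "scratch/decompose"
srv <- "results/survival"
out <- "results/tree"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

M <- as.matrix(read.delim(file.path(dec, "mixing_matrix.tsv"), row.names = 1,
                          check.names = FALSE))
clinical <- read_clinical(file.path(sim, "clinical.tsv"))
sel <- jsonlite::read_json(file.path(srv, "selection.json"),
                           simplifyVector = TRUE)

tcs <- union(sel$univariate_selected, sel$adjusted_selected)
classifiers <- cbind(M[clinical$sample_id, tcs, drop = FALSE],
                     age = clinical$age, stage = clinical$stage)

tree <- grow_tree(clinical, classifiers)
print(tree)

cc <- tree_concordance(tree, clinical, classifiers)
cat(sprintf("concordance of leaf risk ordering: C = %.3f (SE %.3f, %d pairs)\n",
            cc$c_index, cc$se, cc$n_pairs))

rb <- tree_robustness(clinical, classifiers, n_iter = 2000, seed = 501)
cat(sprintf("subsample robustness: median rank correlation %.2f (IQR %.2f), %d/%d iterations missing\n",
            rb$median, rb$iqr, rb$n_missing, 2000))

leaf <- assign_leaves(tree, clinical, classifiers)
write.table(data.frame(sample_id = clinical$sample_id, leaf = leaf,
                       risk = cc$risk),
            file.path(out, "cohort_assignment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
km <- do.call(rbind, lapply(tree$nodes[tree$leaves], function(nd) {
  data.frame(leaf = nd$leaf_label, n = nd$km$n, events = nd$km$events,
             median_os = nd$km$median_os)
}))
write.table(km, file.path(out, "leaf_km.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(list(
  n_leaves = length(tree$leaves), concordance = cc$c_index,
  concordance_se = cc$se, robustness_median = rb$median,
  robustness_iqr = rb$iqr,
  root_classifier = tree$nodes[[tree$root]]$split$classifier_name,
  root_cutoff = tree$nodes[[tree$root]]$split$cutoff
), file.path(out, "summary.json"), auto_unbox = TRUE, digits = 6)
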