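#!/usr/bin/env Rscript
# Annotate the consensus TCs: gene-set enrichment Z-scores (Bonferroni over
# the collection), CNA footprint calls from the genomic sliding-window scan,
# and co-functionality clusters among each TC's top 100 genes using a
# similarity derived from gene-gene correlation across the compendium.

suppressMessages(library(cicasurv))

sim <- "scratch/sim"
dec <- "scratch/decompose"
out <- "results/annotate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

S <- as.matrix(read.delim(file.path(dec, "tc_weights.tsv"), row.names = 1,
                          check.names = FALSE))
X <- read_expression(file.path(sim, "expression.tsv"))
ann <- read_gene_annotation(file.path(sim, "annotation.tsv"))
sets <- read_gmt(file.path(sim, "gene_sets.gmt"))
truth <- jsonlite::read_json(file.path(sim, "truth.json"), simplifyVector = TRUE)

## gene-set enrichment
enr <- enrich_collection(S, sets)
sig <- enr[!enr$untestable & abs(enr$z) > 2 & enr$p_bonferroni < 0.05, ]
cat(sprintf("enrichment: %d significant (|Z|>2, Bonferroni<0.05) of %d tests\n",
            nrow(sig), nrow(enr)))
cat(sprintf("  planted sets among significant hits: %d of %d\n",
            sum(grepl("^enriched", sig$set_name)),
            sum(grepl("^enriched", names(sets)))))
write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

## CNA footprints
calls <- list()
flags <- logical(ncol(S))
for (j in seq_len(ncol(S))) {
  res <- detect_cna_regions(S, j, ann, n_perm = 1000, seed = 300 + j)
  flags[j] <- res$is_cna_tc
  if (nrow(res$calls)) {
    res$calls$tc_id <- colnames(S)[j]
    calls[[length(calls) + 1]] <- res$calls
  }
}
calls <- if (length(calls)) do.call(rbind, calls) else data.frame()
cat(sprintf("CNA scan: %d of %d TCs carry a genomic footprint (%d planted)\n",
            sum(flags), ncol(S), length(truth$cna_components)))
write.table(calls[, c("chromosome", "start", "end", "tc_id",
                      "window_mean_weight", "p_perm")],
            file.path(out, "cna_calls.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

## co-functionality clusters on each TC's top 100 genes
Xc <- X - rowMeans(X)
similarity <- cor(t(Xc))
clusters <- list()
for (j in seq_len(ncol(S))) {
  tg <- top_genes(S, j, 100)
  cl <- cofunctionality_clusters(tg, similarity, r_threshold = 0.7,
                                 min_size = 5, sets = sets,
                                 universe = rownames(S))
  if (length(cl)) {
    clusters[[colnames(S)[j]]] <- lapply(cl, function(x) {
      list(members = x$members,
           top_set = x$enrichment$set_name[which.max(abs(x$enrichment$z))])
    })
  }
}
cat(sprintf("co-functionality: %d TCs have >=1 cluster of >=5 correlated top genes\n",
            length(clusters)))
jsonlite::write_json(clusters, file.path(out, "cofunctionality.json"),
                     auto_unbox = TRUE)
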