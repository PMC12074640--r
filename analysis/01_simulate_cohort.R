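#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a bulk expression compendium mixed
# from planted sparse sources (two of them CNA-like genomic blocks), a
# clinical table whose hazards are driven by three of the planted component
# activities plus age and stage, a gene-set collection with planted
# enrichment, and a Visium-like spatial sample in which two components are
# confined to tissue regions. Everything downstream is scored against the
# ground truth saved here.

suppressMessages(library(cicasurv))

out <- "scratch/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

n_genes <- 2000L
k <- 10L
n_samples <- 300L

ann <- make_gene_annotation(n_genes, n_chrom = 4L)
S <- make_sources(n_genes, k, sparsity = 0.025, cna_fraction = 0.2,
                  annotation = ann, seed = 101)
M <- make_mixing(n_samples, k, seed = 102)
X <- make_expression(S, M, noise_sd = 0.2, seed = 103)

betas <- setNames(c(log(2.5), log(2), log(0.5)), colnames(M)[c(1, 3, 5)])
clinical <- make_clinical(M, survival_betas = betas, seed = 104)

sets <- make_gene_sets(S, n_enriched_per_component = 1, n_null = 50,
                       set_size = 30, seed = 105)

regions <- matrix(1L, 12, 12)
regions[, 7:12] <- 2L
spatial <- make_spatial(S, c(12, 12), regions,
                        region_components = list(1L, 3L), depth = 4000,
                        seed = 106)

write_expression(X, file.path(out, "expression.tsv"))
write_gene_annotation(ann, file.path(out, "annotation.tsv"))
write_clinical(clinical, file.path(out, "clinical.tsv"))
write_gmt(sets, file.path(out, "gene_sets.gmt"))
write_visium(spatial, file.path(out, "visium"), file.path(out, "positions.csv"))
jsonlite::write_json(list(
  k = k, n_genes = n_genes, n_samples = n_samples,
  cna_components = attr(S, "cna_components"),
  cna_blocks = lapply(attr(S, "cna_blocks"), function(b) if (is.null(b)) integer(0) else b),
  survival_betas = as.list(betas),
  spatial_regions = as.list(attr(spatial, "regions")),
  spatial_components = list(region1 = 1L, region2 = 3L)
), file.path(out, "truth.json"), auto_unbox = TRUE)
# planted sources and activities as TSVs for the recovery checks
write.table(data.frame(gene_id = rownames(S), S, check.names = FALSE),
            file.path(out, "S_true.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = rownames(M), M, check.names = FALSE),
            file.path(out, "M_true.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d genes x %d samples, %d components (%d CNA-like)\n",
            n_genes, n_samples, k, length(attr(S, "cna_components"))))
cat(sprintf("clinical: %d patients, %.0f%% events; %d gene sets; spatial: %d spots\n",
            nrow(clinical), 100 * mean(clinical$os_event), length(sets),
            ncol(spatial$counts)))
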