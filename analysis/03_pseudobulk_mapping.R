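#!/usr/bin/env Rscript
# Sample-level comparison of the five groups: pseudo-bulk profiles, PCA,
# transcriptome-distance clustering, and rank-correlation mapping of query
# profiles onto a reference panel.

suppressMessages(library(xenofate))
data_dir <- "results/data"
out <- "results"

cm <- read_10x_counts(file.path(data_dir, "grouped"))
design <- read.delim(file.path(data_dir, "grouped_design.tsv"))
cm$cell_sample <- design$group[match(colnames(cm$counts), design$barcode)]

pb <- aggregate_pseudobulk(cm)
write.table(pb$logcpm, file.path(out, "pseudobulk_log2cpm.tsv"),
            sep = "\t", quote = FALSE)

pc <- pseudobulk_pca(pb, n_components = 3)
coords <- data.frame(sample = rownames(pc$coords), pc$coords)
write.table(coords, file.path(out, "pseudobulk_pca.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance",
                100 * pc$var_explained[1], 100 * pc$var_explained[2]))

dc <- distance_cluster(pb)
write.table(round(dc$distance, 6),
            file.path(out, "pseudobulk_distance.tsv"),
            sep = "\t", quote = FALSE)
merge_order <- pb$samples[dc$hclust$order]
message("distance-clustering leaf order: ",
        paste(merge_order, collapse = " | "))

panel <- as.matrix(read.delim(file.path(data_dir, "reference_panel.tsv")))
queries <- as.matrix(read.delim(file.path(data_dir, "query_profiles.tsv")))
truth <- read.delim(file.path(data_dir, "panel_truth.tsv"))
cmap <- correlate_to_reference(queries, panel, min_shared = 50)
write.table(round(cmap$rho, 4), file.path(out, "reference_correlation.tsv"),
            sep = "\t", quote = FALSE)
acc <- mean(cmap$best_match[truth$sample] == truth$reference)
message(sprintf(
  "reference mapping: %d/%d query profiles matched to their source condition",
  round(acc * nrow(truth)), nrow(truth)))
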