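#!/usr/bin/env Rscript
# Stage 2 — normalization, detection filter, imputation, PCA QC.
#
# Reads the stage-1 peptide table, applies the log2/z rescale (every
# retained peptide row is pinned to the global mean/SD of the log2
# data), aggregates peptides to proteins by median, keeps proteins
# detected in >= 3 of 4 replicates in every design cell, imputes the
# remaining missing values by kNN (k = 10), and records a PCA of the
# batch-centered data as the separation QC.

suppressPackageStartupMessages(library(proteonet))

peptides <- read_intensity_table("results/data/peptides.tsv", scale = "raw")
design <- read_design("results/data/design.tsv")

norm <- log2_z_rescale(peptides)
cat(sprintf("normalized: global mean %.3f, global sd %.3f, %d constant rows dropped\n",
            norm$record$global_mean, norm$record$global_sd,
            norm$record$dropped_constant_rows))

proteins <- aggregate_peptides(norm$table, method = "median")
filtered <- filter_by_detection(proteins, design, min_detected = 3)
cat(sprintf("detection filter (>=3 of 4 per cell): %d kept, %d dropped\n",
            attr(filtered, "n_retained"), attr(filtered, "n_dropped")))

complete <- impute_missing(filtered, k = 10)
write_table(complete, "results/proteins.tsv")

# visualization path only: batch centering, then PCA of the samples
centered <- suppressWarnings(remove_batch_means(complete, design))
pc <- pca_scores(centered, n_components = 4)
qc <- data.frame(sample_id = rownames(pc$scores), pc$scores,
                 check.names = FALSE)
write_table(qc, "results/pca_scores.tsv")
cat(sprintf("PCA variance explained: PC1 %.1f%%, PC2 %.1f%%\n",
            100 * pc$var_explained[1], 100 * pc$var_explained[2]))
cat("protein table written to results/proteins.tsv\n")
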