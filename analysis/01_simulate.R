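#!/usr/bin/env Rscript
# Stage 1 — simulate the factorial TMT study with planted ground truth.
#
# Generates the default synthetic dataset standing in for the deposited
# fly fat-body proteomics: 2 ages x 2 drug x 2 induction x 4 replicates,
# 2,000 proteins of which 200 sit in 10 interaction-network modules, a
# log2 effect of +1 planted on module 1 for the rapamycin contrast, and
# intensity-dependent missingness. Writes the three standard input files
# plus the truth tables that later stages are scored against.

suppressPackageStartupMessages(library(proteonet))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(seed = 1L)
sim <- simulate_dataset(cfg)

write_table(sim$peptides, file.path(out, "peptides.tsv"))
write_table(as.data.frame(sim$design), file.path(out, "design.tsv"))
utils::write.table(sim$graph$edges, file.path(out, "edges.txt"),
                   sep = " ", quote = FALSE, row.names = FALSE)
ann_df <- data.frame(term_id = rep(names(sim$annotations$terms),
                                   lengths(sim$annotations$terms)),
                     gene_id = unlist(sim$annotations$terms))
utils::write.table(ann_df, file.path(out, "annotations.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE, col.names = FALSE)
write_table(data.frame(protein_id = names(sim$modules),
                       module = as.integer(sim$modules)),
            file.path(out, "modules.tsv"))
write_table(data.frame(protein_id = rownames(sim$truth$log2fc),
                       sim$truth$log2fc, check.names = FALSE),
            file.path(out, "truth_log2fc.tsv"))

cat(sprintf("simulated %d peptides / %d proteins x %d samples\n",
            nrow(sim$peptides$values), cfg$n_proteins, nrow(sim$design)))
cat(sprintf("network: %d nodes, %d edges in %d modules; %d annotation terms\n",
            length(sim$graph$nodes), nrow(sim$graph$edges), cfg$n_modules,
            length(sim$annotations$terms)))
cat(sprintf("planted: log2FC = +%g on module 1 (%d proteins) for EtOHvsRapa\n",
            cfg$effect_map[[1]]$delta, cfg$module_size))
cat("inputs written to", out, "\n")
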