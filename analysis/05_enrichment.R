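#!/usr/bin/env Rscript
# Stage 5 — Fisher term enrichment and annotation-level classification.
#
# Tests each contrast's up/down node selections for term
# over-representation against the degree-filtered, measured network
# background (one-sided Fisher, minimal node size 5), collapses to
# signed -log10 p significance scores, and applies the classification
# rules: age-related terms (p < 0.05 in the ageing contrast),
# S6K-activation-dependent vs -independent rapamycin terms (100-fold
# p-ratio rule) and S6K-inhibition-induced terms.

suppressPackageStartupMessages(library(proteonet))

graph <- read_network_edges("results/data/edges.txt", score_threshold = 899)
annotations <- read_annotations("results/data/annotations.tsv",
                                format = "two_column")
deg <- graph_degree(graph)

enr <- list()
for (nm in c("OldvsYoung_control", "EtOHvsRapa", "RUvsRURapa", "RUvsEtOH")) {
  de <- utils::read.delim(sprintf("results/de_%s.tsv", nm))
  selt <- utils::read.delim(sprintf("results/selection_%s.tsv", nm))
  sel <- list(up = selt$node[selt$direction == "up"],
              down = selt$node[selt$direction == "down"])
  background <- intersect(names(deg)[deg >= 5], de$protein_id)
  tab <- fisher_enrichment(sel, background, annotations, min_size = 5)
  enr[[nm]] <- signed_scores(tab)
  write_table(as.data.frame(enr[[nm]]), sprintf("results/enrichment_%s.tsv", nm))
  top <- enr[[nm]][order(enr[[nm]]$p), ][1, ]
  cat(sprintf("%-20s top term %s (%s, p = %.2e, signed score %+0.2f)\n",
              nm, top$term_id, top$direction, top$p, top$signed_score))
}

age <- classify_age_terms(enr$OldvsYoung_control, alpha = 0.05)
rapa <- classify_rapa_terms(enr$EtOHvsRapa, enr$RUvsRURapa, margin = 2)
inhib <- classify_s6k_inhibition_terms(enr$RUvsEtOH, threshold = 2)
write_table(age, "results/terms_age_related.tsv")
write_table(rapa, "results/terms_rapa_classes.tsv")
write_table(inhib, "results/terms_s6k_inhibition.tsv")
cat(sprintf("classified: %d age-related, %d S6K^CA-dependent + %d -independent rapamycin, %d inhibition-induced\n",
            nrow(age), sum(rapa$class == "s6kca_dependent_rapa"),
            sum(rapa$class == "s6kca_independent_rapa"), nrow(inhib)))
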