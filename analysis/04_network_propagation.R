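#!/usr/bin/env Rscript
# Stage 4 — propagate fold changes over the interaction network.
#
# Imports each contrast's log2 fold changes onto the score > 899
# interaction graph, smooths them with x_{t+1} = 0.5 W x_t + 0.5 x_0
# for 26 iterations (symmetric normalization), and selects the top and
# bottom 5% of nodes with more than four interaction partners.

suppressPackageStartupMessages(library(proteonet))

graph <- read_network_edges("results/data/edges.txt", score_threshold = 899)
op <- build_operator(graph, normalization = "symmetric",
                     weighting = "binary")
cat(sprintf("network: %d nodes, %d edges\n", length(graph$nodes),
            nrow(graph$edges)))

modules <- utils::read.delim("results/data/modules.tsv")
mod1 <- modules$protein_id[modules$module == 1]

for (nm in c("OldvsYoung_control", "EtOHvsRapa", "RUvsRURapa", "RUvsEtOH")) {
  de <- utils::read.delim(sprintf("results/de_%s.tsv", nm))
  x0 <- stats::setNames(de$log2fc, de$protein_id)
  scores <- propagate(x0, op, alpha = 0.5, iterations = 26)
  sel <- select_nodes(scores, graph, min_degree = 5, quantile = 0.05)
  write_table(data.frame(node = names(scores), score = as.vector(scores)),
              sprintf("results/propagation_%s.tsv", nm))
  write_table(data.frame(node = c(sel$up, sel$down),
                         direction = rep(c("up", "down"),
                                         c(length(sel$up), length(sel$down)))),
              sprintf("results/selection_%s.tsv", nm))
  cat(sprintf("%-20s coverage %.0f%%, %d up / %d down of %d eligible; %d/%d up from module 1\n",
              nm, 100 * attr(scores, "coverage"), length(sel$up),
              length(sel$down), sel$n_filtered,
              sum(sel$up %in% mod1), length(sel$up)))
}
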