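#!/usr/bin/env Rscript
# Stage 2: centrality table of the main connected component.
#
# Degree, normalized betweenness, closeness and raw stress, computed from
# first principles (Brandes accumulation for the path-based metrics) on the
# component written by 01_simulate.R.

library(hubnet)

net <- read_edge_list("results/network.tsv")
main <- main_component(net)
tab <- centrality_table(main)
write_centrality(tab, "results/centrality.tsv")

top <- tab[order(-tab$degree), ][1:5, ]
cat(sprintf("centrality table: %d nodes (component size %d)\n",
            nrow(tab), attr(tab, "component_size")))
cat("top 5 by degree:\n")
print(top, row.names = FALSE, digits = 3)
cat("wrote results/centrality.tsv\n")
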