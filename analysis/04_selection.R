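#!/usr/bin/env Rscript
# Stage 4: gene prioritization.
#
# Two runs of the cutoff-and-intersection cascade:
#  (a) on the synthetic main component's centrality table — hubs by the
#      mean + 2 SD degree cutoff, top-5% lists by betweenness / closeness /
#      stress, hub-bottlenecks, crucial genes, and tiers;
#  (b) the reference worked example: replaying the embedded colon
#      adenocarcinoma ranked lists through the same intersection and
#      tiering stages, which must yield 11 hub-bottlenecks and the 10
#      crucial genes with a 3 / 5 / 2 tier split.

library(hubnet)

tab <- utils::read.delim("results/centrality.tsv")
class(tab) <- c("centrality_table", "data.frame")

sel <- select_genes(tab)
print(sel)
write_ranked_lists(sel, "results/ranked_lists.tsv")
write_crucial_genes(sel, tab, "results/crucial_genes.tsv")
cat("wrote results/ranked_lists.tsv, results/crucial_genes.tsv\n\n")

cat("reference worked example:\n")
ref <- run_reference_example("results/reference")
print(ref)
stopifnot(length(ref$hub_bottlenecks) == 11L, length(ref$crucial) == 10L)
cat("wrote results/reference/ranked_lists.tsv, results/reference/crucial_genes.tsv\n")
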