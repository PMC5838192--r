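#!/usr/bin/env Rscript
# Stage 5: dense-cluster detection.
#
# MCODE-style seed-and-grow clustering of the main component (node score
# cutoff 0.2, 2-core filter, haircut on) and the overlap of the rank-1
# cluster with the hub and crucial gene lists — the presence of the
# prioritized genes inside the main cluster is what marks it as the
# disease-relevant module.

library(hubnet)

net <- read_edge_list("results/network.tsv")
main <- main_component(net)
tab <- utils::read.delim("results/centrality.tsv")
class(tab) <- c("centrality_table", "data.frame")
sel <- select_genes(tab)

cs <- mcode_cluster(main)
print(cs)
write_clusters(cs, "results/clusters.tsv")

mcl <- main_cluster(cs, hubs = sel$hubs, crucial = sel$crucial)
cat(sprintf("main cluster: %d nodes, %d edges, density %.3f\n",
            mcl$size, mcl$edge_count, mcl$density))
cat(sprintf("hubs in main cluster: %d / %d\n",
            mcl$hub_overlap$count, mcl$hub_overlap$total))
cat(sprintf("crucial genes in main cluster: %d / %d\n",
            mcl$crucial_overlap$count, mcl$crucial_overlap$total))
cat("wrote results/clusters.tsv\n")
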