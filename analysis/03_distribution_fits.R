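#!/usr/bin/env Rscript
# Stage 3: scale-free assessment.
#
# Power-law fits (log-log least squares) to the degree histogram and to the
# binned betweenness and closeness distributions of the main component. A
# negative degree exponent with a decent log-log R-squared is the
# scale-free signature expected of a preferential-attachment interactome.

library(hubnet)

tab <- utils::read.delim("results/centrality.tsv")
report <- scale_free_report(tab)
print(report)
write_power_law_report(report, "results/power_law.json")
cat("wrote results/power_law.json\n")
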