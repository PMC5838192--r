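Package: hubnet
Title: Hub-Bottleneck Gene Prioritization in Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Topological analysis of protein-protein interaction networks for
    disease-gene prioritization. Builds undirected interaction networks from
    plain or STRING-export edge lists, decomposes them into connected
    components, computes degree, betweenness, closeness and stress centrality
    from first principles on the main component, fits power-law models to
    centrality distributions to assess scale-free structure, selects hub,
    bottleneck and crucial genes by a cutoff-and-intersection cascade with a
    three-way tiering of crucial genes, and detects dense clusters with an
    MCODE-style seed-and-grow algorithm. Includes a seeded generator for
    scale-free benchmark networks with planted dense modules, and an embedded
    worked example from a colon adenocarcinoma interactome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
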