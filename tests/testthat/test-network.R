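write_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("plain edge lists are read with duplicates collapsed and self-loops dropped", {
  net <- read_edge_list(write_tmp(c("A B", "B C", "B C")))
  expect_equal(n_nodes(net), 3L)
  expect_equal(n_edges(net), 2L)

  expect_warning(net2 <- read_edge_list(write_tmp(c("A A", "A B"))),
                 "self-loop")
  expect_equal(n_nodes(net2), 2L)
  expect_equal(n_edges(net2), 1L)

  # duplicate scored edges keep the maximum score
  net3 <- read_edge_list(write_tmp(c("A B 100", "B A 900")))
  expect_equal(net3$edges$score, 900)
})

test_that("score thresholding removes edges below min_score", {
  path <- write_tmp(c("A B 150", "B C 700", "C D 900"))
  net <- read_edge_list(path, min_score = 400)
  expect_equal(n_edges(net), 2L)
  expect_true(all(net$edges$score >= 400))
  expect_equal(n_nodes(net), 4L)  # endpoints survive as isolated nodes
  expect_error(read_edge_list(write_tmp("A B"), min_score = 400), "no score")
})

test_that("malformed, empty and unknown-format inputs error clearly", {
  expect_error(read_edge_list(write_tmp(c("A B", "oops", "C D"))),
               "line 2")
  expect_error(read_edge_list(write_tmp(c("# only a comment"))), "empty")
  expect_error(read_edge_list(write_tmp("A B"), format = "xml"),
               "'arg' should be one")
  expect_error(read_edge_list(write_tmp(c("A B notanumber"))), "line 1")
  expect_error(read_edge_list(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("STRING-style TSV exports parse with doubled edges collapsed silently", {
  path <- write_tmp(c("#node1\tnode2\tcombined_score",
                      "TP53\tEGFR\t990",
                      "EGFR\tTP53\t990",
                      "TP53\tALB\t350"))
  net <- read_edge_list(path, format = "string_tsv")
  expect_equal(n_edges(net), 2L)
  expect_equal(n_nodes(net), 3L)
  net_hi <- read_edge_list(path, format = "string_tsv", min_score = 400)
  expect_equal(n_edges(net_hi), 1L)
  expect_equal(net_hi$edges$from, "EGFR")
})

test_that("components decompose with deterministic ordering and isolated nodes", {
  net <- ppi_network(edge_df(c("A", "B"), c("B", "C")), nodes = c("D", "E"))
  cc <- connected_components(net)
  expect_equal(cc$components, list(c("A", "B", "C"), "D", "E"))
  expect_equal(cc$isolated_nodes, c("D", "E"))
  expect_equal(cc$main_component, c("A", "B", "C"))

  cc4 <- connected_components(g_clique(4))
  expect_length(cc4$components, 1L)
  expect_length(cc4$isolated_nodes, 0L)

  # equal-size components ordered by lexicographic smallest member
  net2 <- ppi_network(edge_df(c("X", "A"), c("Y", "B")))
  expect_equal(connected_components(net2)$main_component, c("A", "B"))

  expect_length(connected_components(ppi_network(edge_df(character(), character())))$components, 0L)
})

test_that("components partition the node set and degrees sum to twice the edges", {
  for (s in 1:8) {
    net <- hubnet:::.with_seed(s, {
      ends <- igraph::as_edgelist(igraph::sample_gnp(15, 0.15), names = FALSE)
      ppi_network(edge_df(sprintf("N%02d", ends[, 1]), sprintf("N%02d", ends[, 2])),
                  nodes = sprintf("N%02d", 1:15))
    })
    cc <- connected_components(net)
    members <- unlist(cc$components)
    expect_equal(sort(members), net$nodes)   # union = node set, no overlap
    expect_equal(anyDuplicated(members), 0L)
    expect_equal(sum(compute_degree(net)), 2L * n_edges(net))
    expect_true(all(diff(lengths(cc$components)) <= 0))
  }
})

test_that("induced subgraphs keep internal edges, attributes, and reject unknown nodes", {
  k4 <- g_clique(4)
  sub <- induced_subgraph(k4, c("K01", "K02"))
  expect_equal(n_nodes(sub), 2L)
  expect_equal(n_edges(sub), 1L)

  expect_equal(induced_subgraph(k4, k4$nodes)$edges, k4$edges)

  p3 <- g_path(3)
  sub2 <- induced_subgraph(p3, c("A", "C"))
  expect_equal(n_edges(sub2), 0L)
  expect_equal(n_nodes(sub2), 2L)

  expect_error(induced_subgraph(k4, c("K01", "ZZ", "QQ")), "QQ, ZZ")

  net <- ppi_network(edge_df("A", "B"), nodes = "C",
                     node_attrs = data.frame(node = c("A", "C"), DS = c(1, 2)))
  sub3 <- induced_subgraph(net, c("A", "B"))
  expect_equal(sub3$node_attrs$node, "A")

  # restricting to one component yields a single component
  net2 <- ppi_network(edge_df(c("A", "B", "X"), c("B", "C", "Y")))
  cc <- connected_components(net2)
  expect_length(connected_components(induced_subgraph(net2, cc$main_component))$components, 1L)
})

test_that("write/read round-trips preserve the network", {
  net <- hubnet:::.with_seed(4, generate_network(20, 35, n_isolated = 3, seed = 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read_edge_list(path)
  back <- ppi_network(back$edges, nodes = c(back$nodes, hubnet:::.read_isolated_comment(path)))
  expect_equal(back$edges[, c("from", "to")], net$edges[, c("from", "to")])
  expect_equal(back$nodes, net$nodes)
  # a second round-trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
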