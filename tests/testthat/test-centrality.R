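test_that("degree counts incident edges on any network, isolated nodes included", {
  expect_equal(unname(compute_degree(g_clique(4))), rep(3L, 4))
  st <- compute_degree(g_star(5))
  expect_equal(st[["HUB"]], 5L)
  expect_equal(unname(st[names(st) != "HUB"]), rep(1L, 5))
  expect_equal(compute_degree(ppi_network(edge_df("A", "B"), nodes = "Z"))[["Z"]], 0L)
})

test_that("betweenness, closeness and stress match hand values on canonical graphs", {
  p3 <- g_path(3)
  expect_equal(compute_betweenness(p3), c(A = 0, B = 1, C = 0))
  expect_equal(compute_closeness(p3), c(A = 2 / 3, B = 1, C = 2 / 3))
  expect_equal(compute_stress(p3), c(A = 0, B = 1, C = 0))

  expect_equal(unname(compute_betweenness(g_clique(4))), rep(0, 4))
  expect_equal(unname(compute_stress(g_clique(4))), rep(0, 4))
  expect_equal(unname(compute_closeness(g_clique(3))), rep(1, 3))
  expect_equal(compute_closeness(g_star(6))[["HUB"]], 1)

  # C4: the A-C geodesic through B is the only geodesic interior to B
  expect_equal(compute_stress(g_cycle(4)), c(A = 1, B = 1, C = 1, D = 1))
})

test_that("Brandes betweenness and stress equal the path-enumeration oracle on seeded graphs", {
  cases <- expand.grid(n = c(6L, 8L), p = c(0.3, 0.55), seed = 1:5)
  for (i in seq_len(nrow(cases))) {
    net <- rand_connected(cases$n[i], cases$p[i], seed = 100 + i)
    o <- oracle_path_centrality(net)
    expect_named_equal(compute_betweenness(net, normalized = FALSE), o$betweenness_raw)
    expect_named_equal(compute_betweenness(net), o$betweenness)
    expect_named_equal(compute_stress(net), o$stress)
  }
})

test_that("summed raw betweenness equals the oracle's average-interior-count total", {
  for (s in 1:5) {
    net <- rand_connected(7, 0.4, seed = s)
    o <- oracle_path_centrality(net)
    expect_equal(sum(compute_betweenness(net, normalized = FALSE)),
                 sum(o$betweenness_raw), tolerance = 1e-10)
  }
})

test_that("all four metrics are invariant under node relabeling", {
  net <- rand_connected(9, 0.35, seed = 42)
  perm <- hubnet:::.with_seed(7, sample(net$nodes))
  relabel <- stats::setNames(perm, net$nodes)
  net2 <- ppi_network(edge_df(unname(relabel[net$edges$from]),
                              unname(relabel[net$edges$to])))
  for (metric in list(compute_degree, compute_betweenness,
                      compute_closeness, compute_stress)) {
    v1 <- metric(net)
    v2 <- metric(net2)
    expect_equal(unname(v2[unname(relabel[names(v1)])]), unname(v1),
                 tolerance = 1e-10)
  }
})

test_that("component-restricted metrics reject disconnected input; degree never does", {
  two <- ppi_network(edge_df(c("A", "X"), c("B", "Y")))
  expect_error(compute_betweenness(two), "connected")
  expect_error(compute_closeness(two), "connected")
  expect_error(compute_stress(two), "connected")
  expect_error(centrality_table(two), "connected")
  expect_length(compute_degree(two), 4L)
  expect_error(compute_betweenness(ppi_network(edge_df("A", "B"))), "n >= 3")
})

test_that("the centrality table bundles the per-metric values unchanged", {
  tab <- centrality_table(g_path(3))
  expect_equal(tab$node, c("A", "B", "C"))
  expect_equal(tab$degree, c(1L, 2L, 1L))
  expect_equal(tab$betweenness, c(0, 1, 0))
  expect_equal(tab$closeness, c(2 / 3, 1, 2 / 3), tolerance = 1e-12)
  expect_equal(tab$stress, c(0, 1, 0))
  expect_equal(attr(tab, "component_size"), 3L)

  k4 <- centrality_table(g_clique(4))
  expect_equal(k4$degree, rep(3L, 4))
  expect_equal(k4$betweenness, rep(0, 4))
  expect_equal(k4$closeness, rep(1, 4))

  net <- rand_connected(8, 0.4, seed = 9)
  tab8 <- centrality_table(net)
  o <- oracle_path_centrality(net)
  expect_equal(tab8$betweenness, unname(o$betweenness[tab8$node]), tolerance = 1e-10)
  expect_equal(tab8$stress, unname(o$stress[tab8$node]), tolerance = 1e-10)
  expect_equal(tab8$degree, unname(compute_degree(net)[tab8$node]))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_centrality(tab8, path)
  expect_equal(names(utils::read.delim(path)),
               c("node", "degree", "betweenness", "closeness", "stress"))
})
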