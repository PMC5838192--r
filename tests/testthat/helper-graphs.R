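# small-graph builders ------------------------------------------------------

edge_df <- function(a, b) data.frame(a = a, b = b, stringsAsFactors = FALSE)

g_path <- function(n, labels = LETTERS[seq_len(n)]) {
  ppi_network(edge_df(labels[-n], labels[-1]))
}

g_cycle <- function(n, labels = LETTERS[seq_len(n)]) {
  ppi_network(edge_df(labels, labels[c(2:n, 1)]))
}

g_clique <- function(n, labels = sprintf("K%02d", seq_len(n))) {
  p <- utils::combn(labels, 2)
  ppi_network(edge_df(p[1, ], p[2, ]))
}

g_star <- function(leaves, center = "HUB") {
  ppi_network(edge_df(rep(center, leaves), sprintf("L%02d", seq_len(leaves))))
}

# seeded random connected graph on n nodes (rejection-sampled G(n, p))
rand_connected <- function(n, p = 0.4, seed = 1) {
  hubnet:::.with_seed(seed, {
    repeat {
      g <- igraph::sample_gnp(n, p)
      if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
    }
    ends <- igraph::as_edgelist(g, names = FALSE)
    lab <- sprintf("N%02d", seq_len(n))
    ppi_network(edge_df(lab[ends[, 1]], lab[ends[, 2]]),
                nodes = lab)
  })
}

# independent oracle: enumerate every geodesic explicitly ------------------
# (BFS distance matrix + recursive path enumeration; no Brandes-style
# dependency accumulation anywhere)
oracle_path_centrality <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  ai <- match(net$edges$from, nodes)
  bi <- match(net$edges$to, nodes)
  adj <- lapply(seq_len(n), function(v) sort(c(bi[ai == v], ai[bi == v])))
  bfs <- function(s) {
    d <- rep(NA_integer_, n); d[s] <- 0L
    q <- s; head <- 1L
    while (head <= length(q)) {
      v <- q[head]; head <- head + 1L
      for (u in adj[[v]]) if (is.na(d[u])) { d[u] <- d[v] + 1L; q <- c(q, u) }
    }
    d
  }
  D <- vapply(seq_len(n), bfs, integer(n))  # D[v, s] = d(s, v)
  # every geodesic from s to t, walking back from t along distance levels
  enum <- function(s, t) {
    if (s == t) return(list(s))
    out <- list()
    for (u in adj[[t]])
      if (!is.na(D[u, s]) && D[u, s] == D[t, s] - 1L)
        out <- c(out, lapply(enum(s, u), function(p) c(p, t)))
    out
  }
  bet <- numeric(n); stress <- numeric(n)
  if (n >= 2) for (s in seq_len(n - 1L)) for (t in seq.int(s + 1L, n)) {
    paths <- enum(s, t)
    k <- length(paths)
    for (p in paths) {
      interior <- p[-c(1L, length(p))]
      if (length(interior)) {
        bet[interior] <- bet[interior] + 1 / k
        stress[interior] <- stress[interior] + 1
      }
    }
  }
  names(bet) <- names(stress) <- nodes
  list(betweenness_raw = bet,
       betweenness = if (n >= 3) bet * 2 / ((n - 1) * (n - 2)) else bet,
       stress = stress)
}

# enumerate labeled graphs on n nodes by edge bitmask; calls fn(net) for each
# connected one and returns the number visited
for_each_connected_graph <- function(n, fn) {
  lab <- sprintf("N%d", seq_len(n))
  pairs <- utils::combn(seq_len(n), 2)
  np <- ncol(pairs)
  count <- 0L
  for (mask in seq_len(2^np - 1L)) {
    sel <- bitwAnd(mask, bitwShiftL(1L, seq_len(np) - 1L)) != 0L
    if (sum(sel) < n - 1L) next  # cannot be connected
    el <- pairs[, sel, drop = FALSE]
    g <- igraph::graph_from_edgelist(t(el), directed = FALSE)
    if (igraph::vcount(g) < n || !igraph::is_connected(g)) next
    net <- ppi_network(edge_df(lab[el[1, ]], lab[el[2, ]]))
    fn(net)
    count <- count + 1L
  }
  count
}

expect_named_equal <- function(actual, expected, tol = 1e-10) {
  expect_equal(actual[sort(names(actual))],
               expected[sort(names(expected))], tolerance = tol)
}
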