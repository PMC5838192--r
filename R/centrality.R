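#' @name centrality
#' @title Centrality metrics on one connected component
#'
#' @description
#' Four classic node-centrality metrics for undirected, unweighted PPI
#' networks: degree, betweenness, closeness and stress. Betweenness and
#' stress are computed with Brandes' dependency-accumulation algorithm;
#' betweenness accumulates fractional pair-dependencies, stress accumulates
#' raw geodesic counts. All shortest paths are unweighted (edge scores are
#' ignored) and pairs are unordered, the convention under which normalized
#' betweenness and closeness lie in \[0, 1\].
#'
#' Except for degree, the metrics are defined on a single connected
#' component; pass the output of [main_component()] (disconnected input is
#' an error). Nodes are processed in sorted order so floating-point
#' accumulation is reproducible.
NULL

.assert_connected <- function(net, what, min_n = 1L) {
  n <- length(net$nodes)
  if (n < min_n)
    stop(sprintf("%s needs a component of at least %d nodes", what, min_n))
  cc <- connected_components(net)
  if (length(cc$components) != 1L)
    stop(what, " requires a single connected component (",
         length(cc$components), " found); decompose with connected_components() first")
  invisible(TRUE)
}

# one Brandes sweep from source s: BFS order, predecessor lists, path counts
.brandes_sweep <- function(adj, s, n) {
  sigma <- numeric(n); sigma[s] <- 1
  dist <- rep.int(-1L, n); dist[s] <- 0L
  preds <- vector("list", n)
  order_v <- integer(n)
  head <- 1L; tail <- 1L
  order_v[1L] <- s
  while (head <= tail) {
    v <- order_v[head]; head <- head + 1L
    dv1 <- dist[v] + 1L
    for (w in adj[[v]]) {
      if (dist[w] < 0L) {
        dist[w] <- dv1
        tail <- tail + 1L
        order_v[tail] <- w
      }
      if (dist[w] == dv1) {
        sigma[w] <- sigma[w] + sigma[v]
        preds[[w]] <- c(preds[[w]], v)
      }
    }
  }
  list(sigma = sigma, preds = preds, order = order_v[seq_len(tail)],
       dist = dist)
}

#' @describeIn centrality number of incident edges per node; defined on any
#'   network, isolated nodes get 0.
#' @param net a [ppi_network]
#' @return a named numeric (or integer) vector over `net$nodes`, in sorted
#'   node order.
#' @export
compute_degree <- function(net) {
  deg <- integer(length(net$nodes))
  names(deg) <- net$nodes
  tab <- table(c(net$edges$from, net$edges$to))
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' @describeIn centrality Brandes betweenness over unordered node pairs,
#'   endpoints excluded; `normalized = TRUE` divides by `(n-1)(n-2)/2`, the
#'   number of pairs a node can sit between.
#' @param normalized return values scaled to \[0, 1\] (requires n >= 3)
#' @export
compute_betweenness <- function(net, normalized = TRUE) {
  .assert_connected(net, "compute_betweenness")
  n <- length(net$nodes)
  if (normalized && n < 3L)
    stop("normalized betweenness needs n >= 3")
  adj <- .adjacency(net)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sw <- .brandes_sweep(adj, s, n)
    delta <- numeric(n)
    for (w in rev(sw$order)) {
      coeff <- (1 + delta[w]) / sw$sigma[w]
      for (v in sw$preds[[w]]) delta[v] <- delta[v] + sw$sigma[v] * coeff
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2  # each unordered pair accumulated from both endpoints
  if (normalized) bc <- bc * 2 / ((n - 1) * (n - 2))
  names(bc) <- net$nodes
  bc
}

#' @describeIn centrality raw count of geodesics passing through each node
#'   as an interior vertex (unit accumulation, not fractional); always an
#'   integer-valued count.
#' @export
compute_stress <- function(net) {
  .assert_connected(net, "compute_stress")
  n <- length(net$nodes)
  adj <- .adjacency(net)
  st <- numeric(n)
  for (s in seq_len(n)) {
    sw <- .brandes_sweep(adj, s, n)
    # psi[v] = number of geodesics from v to targets strictly below v in the
    # BFS dag of s; contribution of source s to stress(v) is sigma_sv * psi[v]
    psi <- numeric(n)
    for (w in rev(sw$order)) {
      for (v in sw$preds[[w]]) psi[v] <- psi[v] + 1 + psi[w]
      if (w != s) st[w] <- st[w] + sw$sigma[w] * psi[w]
    }
  }
  st <- st / 2
  names(st) <- net$nodes
  st
}

#' @describeIn centrality `(n-1) / sum_v d(u, v)` with unweighted
#'   shortest-path distance; 1 for a node adjacent to every other.
#' @export
compute_closeness <- function(net) {
  .assert_connected(net, "compute_closeness", min_n = 2L)
  n <- length(net$nodes)
  adj <- .adjacency(net)
  cc <- numeric(n)
  for (s in seq_len(n)) {
    sw <- .brandes_sweep(adj, s, n)
    cc[s] <- (n - 1) / sum(sw$dist)
  }
  names(cc) <- net$nodes
  cc
}

#' Centrality table for a connected component
#'
#' Bundles the four metrics of the [centrality] family into one table, one
#' row per node in sorted order. Values are identical to calling each
#' metric separately.
#'
#' @param net a [ppi_network] that is a single connected component with at
#'   least 3 nodes (so normalized betweenness is defined)
#' @return a data frame of class `centrality_table` with columns `node`,
#'   `degree`, `betweenness` (normalized), `closeness`, `stress`, and an
#'   attribute `component_size`.
#' @export
centrality_table <- function(net) {
  .assert_connected(net, "centrality_table", min_n = 3L)
  out <- data.frame(node = net$nodes,
                    degree = unname(compute_degree(net)),
                    betweenness = unname(compute_betweenness(net)),
                    closeness = unname(compute_closeness(net)),
                    stress = unname(compute_stress(net)),
                    stringsAsFactors = FALSE)
  attr(out, "component_size") <- length(net$nodes)
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Write a centrality table as TSV
#'
#' Columns `node`, `degree`, `betweenness`, `closeness`, `stress`.
#'
#' @param table a [centrality_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_centrality <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
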