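#' MCODE vertex weighting
#'
#' Each node is scored by the density of the highest k-core of its closed
#' neighborhood (the node plus its neighbors) multiplied by that core's k —
#' the core-clustering coefficient weighting of the MCODE algorithm. Nodes
#' whose neighborhood contains no core of order at least `k_core` (default
#' 2) get weight 0: a star center or the endpoint of an isolated edge
#' scores 0, a node inside a clique K_m scores m - 1.
#'
#' @param net a [ppi_network] (one connected component)
#' @param k_core minimum core order for a nonzero weight
#' @return named numeric vector of weights over `net$nodes`
#' @export
vertex_weights <- function(net, k_core = 2L) {
  adj <- .adjacency(net)
  n <- length(adj)
  w <- numeric(n)
  for (v in seq_len(n)) {
    nb <- c(v, adj[[v]])
    sub <- .induced_adj(adj, nb)
    core <- .coreness(sub)
    k_max <- max(core)
    if (k_max < k_core) next
    members <- which(core == k_max)
    m_edges <- sum(vapply(members,
                          function(i) sum(sub[[i]] %in% members),
                          integer(1L))) / 2L
    nc <- length(members)
    w[v] <- k_max * 2 * m_edges / (nc * (nc - 1))
  }
  names(w) <- net$nodes
  w
}

# induced adjacency (local indices 1..length(keep)) of the node set `keep`
.induced_adj <- function(adj, keep) {
  pos <- integer(length(adj))
  pos[keep] <- seq_along(keep)
  lapply(keep, function(v) {
    nb <- adj[[v]]
    pos[nb[pos[nb] > 0L]]
  })
}

# coreness by iterated minimum-degree peeling
.coreness <- function(adj) {
  n <- length(adj)
  deg <- lengths(adj)
  core <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0L
  for (i in seq_len(n)) {
    cand <- which(alive)
    v <- cand[which.min(deg[cand])]
    k <- max(k, deg[v])
    core[v] <- k
    alive[v] <- FALSE
    for (u in adj[[v]]) if (alive[u]) deg[u] <- deg[u] - 1L
  }
  core
}

#' MCODE-style density clustering
#'
#' Seed-and-grow molecular-complex detection: nodes are weighted with
#' [vertex_weights()]; the highest-weight unvisited node seeds a cluster
#' which grows breadth-first, admitting neighbors whose weight is within
#' `node_score_cutoff` of the seed weight (i.e. `weight >= seed_weight *
#' (1 - node_score_cutoff)`); grown members are marked visited so clusters
#' are disjoint. The optional haircut prunes singly-connected members
#' (iterated to a fixed point), and clusters not containing a core of order
#' `k_core` are discarded. Clusters are ranked by score = density x size,
#' descending, ties broken by size then by lexicographically smallest
#' member. All tie-breaking is deterministic.
#'
#' @param net a [ppi_network] forming a single connected component
#' @param node_score_cutoff admission band below the seed weight, in
#'   \[0, 1\] (default 0.2)
#' @param k_core minimum core order a cluster must contain (default 2)
#' @param haircut remove singly-connected cluster members (default TRUE)
#' @param max_depth maximum growth distance from the seed (default 100)
#' @return an object of class `cluster_set`: list with `clusters` (each a
#'   `cluster` record: `members`, `seed`, `size`, `edge_count`, `density`,
#'   `score`, `rank`) and `parameters`.
#' @export
mcode_cluster <- function(net, node_score_cutoff = 0.2, k_core = 2L,
                          haircut = TRUE, max_depth = 100L) {
  .assert_connected(net, "mcode_cluster")
  adj <- .adjacency(net)
  n <- length(adj)
  w <- unname(vertex_weights(net, k_core = k_core))
  visited <- rep(FALSE, n)
  clusters <- list()
  seed_order <- order(-w, net$nodes)
  for (s in seed_order) {
    if (visited[s] || w[s] <= 0) next
    threshold <- w[s] * (1 - node_score_cutoff)
    members <- .grow_cluster(adj, w, s, threshold, visited, max_depth)
    visited[members] <- TRUE
    if (haircut) members <- .haircut(adj, members)
    if (length(members) < 2L) next
    sub <- .induced_adj(adj, members)
    if (max(.coreness(sub)) < k_core) next
    e <- sum(lengths(sub)) / 2L
    sz <- length(members)
    density <- 2 * e / (sz * (sz - 1))
    clusters[[length(clusters) + 1L]] <- list(
      members = net$nodes[sort(members)],
      seed = net$nodes[s],
      size = sz, edge_count = as.integer(e),
      density = density, score = density * sz)
  }
  if (length(clusters)) {
    score <- vapply(clusters, `[[`, numeric(1L), "score")
    size <- vapply(clusters, `[[`, numeric(1L), "size")
    first <- vapply(clusters, function(cl) cl$members[1L], "")
    o <- order(-score, -size, first)
    clusters <- clusters[o]
    for (i in seq_along(clusters)) {
      clusters[[i]]$rank <- i
      class(clusters[[i]]) <- "mcode_cluster"
    }
  }
  structure(list(clusters = clusters,
                 parameters = list(node_score_cutoff = node_score_cutoff,
                                   k_core = as.integer(k_core),
                                   haircut = haircut,
                                   max_depth = as.integer(max_depth))),
            class = "cluster_set")
}

# breadth-first growth from seed s admitting weights >= threshold
.grow_cluster <- function(adj, w, s, threshold, visited, max_depth) {
  in_cl <- logical(length(adj))
  in_cl[s] <- TRUE
  depth <- integer(length(adj))
  queue <- s
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    if (depth[v] >= max_depth) next
    for (u in adj[[v]]) {
      if (!in_cl[u] && !visited[u] && w[u] >= threshold) {
        in_cl[u] <- TRUE
        depth[u] <- depth[v] + 1L
        queue <- c(queue, u)
      }
    }
  }
  which(in_cl)
}

# iteratively strip members with fewer than 2 within-cluster neighbors
.haircut <- function(adj, members) {
  repeat {
    sub <- .induced_adj(adj, members)
    keep <- lengths(sub) >= 2L
    if (all(keep) || !any(keep)) return(members[keep])
    members <- members[keep]
  }
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s)  [cutoff %.2f, k-core %d, haircut %s]\n",
              length(x$clusters), x$parameters$node_score_cutoff,
              x$parameters$k_core, x$parameters$haircut))
  for (cl in x$clusters)
    cat(sprintf("  #%d: %d nodes, %d edges, density %.3f, score %.3f\n",
                cl$rank, cl$size, cl$edge_count, cl$density, cl$score))
  invisible(x)
}

#' The top-ranked cluster, with hub/crucial overlap counts
#'
#' Returns the rank-1 cluster of a [mcode_cluster()] result and, when hub
#' and/or crucial gene lists are supplied, how many of them fall inside it
#' — the presence of prioritized genes in the main cluster is what makes
#' it the biologically central one.
#'
#' @param cs a `cluster_set`
#' @param hubs,crucial optional gene lists to intersect with the cluster
#' @return the rank-1 `mcode_cluster` record, with `hub_overlap` /
#'   `crucial_overlap` elements (count, total, members) when lists given
#' @export
main_cluster <- function(cs, hubs = NULL, crucial = NULL) {
  if (!length(cs$clusters)) stop("empty cluster set: no main cluster")
  cl <- cs$clusters[[1L]]
  overlap <- function(genes) {
    inside <- intersect(genes, cl$members)
    list(count = length(inside), total = length(genes), members = inside)
  }
  if (!is.null(hubs)) cl$hub_overlap <- overlap(hubs)
  if (!is.null(crucial)) cl$crucial_overlap <- overlap(crucial)
  cl
}

#' Write a cluster set as TSV
#'
#' Columns: `rank`, `size`, `edge_count`, `density`, `score`, `members`
#' (semicolon-joined).
#'
#' @param cs a `cluster_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_clusters <- function(cs, path) {
  rows <- lapply(cs$clusters, function(cl)
    data.frame(rank = cl$rank, size = cl$size, edge_count = cl$edge_count,
               density = cl$density, score = cl$score,
               members = paste(cl$members, collapse = ";"),
               stringsAsFactors = FALSE))
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rank = integer(), size = integer(), edge_count = integer(),
               density = numeric(), score = numeric(), members = character())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
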