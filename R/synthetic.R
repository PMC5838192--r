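# run code under a given seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

.gene_labels <- function(n, offset = 0L, width = NULL) {
  if (is.null(width)) width <- max(4L, nchar(n + offset))
  sprintf(paste0("G%0", width, "d"), offset + seq_len(n))
}

# add/remove edges until exactly `target`, preserving connectivity;
# additions are degree-preferential when `preferential`
.adjust_edge_count <- function(g, target, preferential = TRUE) {
  while (igraph::ecount(g) > target) {
    removed <- FALSE
    for (eid in sample.int(igraph::ecount(g))) {
      g2 <- igraph::delete_edges(g, eid)
      if (igraph::is_connected(g2)) { g <- g2; removed <- TRUE; break }
    }
    if (!removed) stop("cannot reduce edge count without disconnecting the graph")
  }
  n <- igraph::vcount(g)
  while (igraph::ecount(g) < target) {
    prob <- if (preferential) igraph::degree(g) + 1 else rep(1, n)
    repeat {
      v <- sample.int(n, 2L, prob = prob)
      if (!igraph::are_adjacent(g, v[1L], v[2L])) break
    }
    g <- igraph::add_edges(g, v)
  }
  g
}

# connect stray components to the largest one with single random edges
.patch_connectivity <- function(g) {
  comp <- igraph::components(g)
  while (comp$no > 1L) {
    main_id <- which.max(comp$csize)
    main_v <- which(comp$membership == main_id)
    other_v <- which(comp$membership != main_id)
    pick <- other_v[comp$membership[other_v] == comp$membership[other_v[1L]]]
    g <- igraph::add_edges(g, c(pick[sample.int(length(pick), 1L)],
                                main_v[sample.int(length(main_v), 1L)]))
    comp <- igraph::components(g)
  }
  g
}

.igraph_to_ppi <- function(g, labels, extra_nodes = character(),
                           scores = FALSE) {
  ends <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(from = labels[ends[, 1L]], to = labels[ends[, 2L]],
                      stringsAsFactors = FALSE)
  if (scores) edges$score <- round(stats::runif(nrow(edges), 400, 999))
  ppi_network(edges, nodes = c(labels, extra_nodes))
}

#' Generate a benchmark network with an exact shape
#'
#' Emits a network whose main component has exactly `n_connected` nodes and
#' `n_edges` edges, plus `n_isolated` degree-0 nodes — the shape of a
#' disease-query interactome in which part of the gene list attracts no
#' interactions. Under the default `preferential_attachment` model the
#' component is grown by scale-free preferential attachment and then
#' adjusted to the exact edge count by seeded preferential edge additions /
#' random removals, each removal checked to preserve connectivity. The
#' `erdos_renyi` model gives a homogeneous-degree control. Output is
#' bitwise reproducible for a given seed.
#'
#' @param n_connected nodes in the main component
#' @param n_edges edges in the main component; must satisfy
#'   `n_connected - 1 <= n_edges <= n_connected * (n_connected - 1) / 2`
#' @param n_isolated number of isolated nodes appended
#' @param seed integer seed; the caller's RNG state is left untouched
#' @param model `"preferential_attachment"` or `"erdos_renyi"`
#' @param scores attach uniform confidence scores on \[400, 999\]
#' @return a [ppi_network] with node labels `G0001`, `G0002`, ...
#' @examples
#' net <- generate_network(50, 120, n_isolated = 5, seed = 7)
#' connected_components(net)
#' @export
generate_network <- function(n_connected, n_edges, n_isolated = 0L, seed = 1L,
                             model = c("preferential_attachment", "erdos_renyi"),
                             scores = FALSE) {
  model <- match.arg(model)
  n_connected <- as.integer(n_connected)
  n_edges <- as.integer(n_edges)
  if (n_connected < 2L) stop("n_connected must be at least 2")
  if (n_edges < n_connected - 1L)
    stop(sprintf("infeasible: n_edges = %d is below the connectivity minimum %d for %d nodes",
                 n_edges, n_connected - 1L, n_connected))
  max_edges <- n_connected * (n_connected - 1L) / 2
  if (n_edges > max_edges)
    stop(sprintf("infeasible: n_edges = %d exceeds the maximum %d for %d nodes",
                 n_edges, max_edges, n_connected))
  .with_seed(seed, {
    g <- if (model == "preferential_attachment") {
      m <- max(1L, round(n_edges / n_connected))
      igraph::sample_pa(n_connected, m = m, directed = FALSE)
    } else {
      .patch_connectivity(igraph::sample_gnm(n_connected, min(n_edges, max_edges)))
    }
    g <- .adjust_edge_count(g, n_edges,
                            preferential = model == "preferential_attachment")
    width <- max(4L, nchar(n_connected + n_isolated))
    iso <- .gene_labels(n_isolated, offset = n_connected, width = width)
    .igraph_to_ppi(g, .gene_labels(n_connected, width = width),
                   extra_nodes = iso, scores = scores)
  })
}

#' Generate a background network with a planted dense module
#'
#' A sparse Erdos-Renyi background on `n_nodes` nodes (edge probability
#' `p_background`, patched to one connected component) with a planted
#' module of `module_size` nodes wired at `module_density` — the ground
#' truth benchmark for dense-cluster recovery. With `hub_overlap` the
#' module is dense enough that the degree-cutoff hubs of the full network
#' fall inside it, which [select_hubs()] can verify against the returned
#' truth.
#'
#' @param n_nodes background size
#' @param p_background background edge probability
#' @param module_size planted module size (<= `n_nodes`)
#' @param module_density edge probability inside the module (1 = clique)
#' @param hub_overlap logical, recorded in the ground truth: the intended
#'   hubs are the module members
#' @param seed integer seed
#' @return a list with `network` (a [ppi_network]), `module` (planted
#'   member labels) and `intended_hubs` (module labels when `hub_overlap`,
#'   else `character()`)
#' @export
generate_planted <- function(n_nodes = 200L, p_background = 0.03,
                             module_size = 20L, module_density = 1,
                             hub_overlap = FALSE, seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  module_size <- as.integer(module_size)
  if (module_size > n_nodes)
    stop(sprintf("infeasible: module_size = %d exceeds n_nodes = %d",
                 module_size, n_nodes))
  .with_seed(seed, {
    g <- igraph::sample_gnp(n_nodes, p_background)
    module <- sort(sample.int(n_nodes, module_size))
    pairs <- utils::combn(module, 2L)
    take <- stats::runif(ncol(pairs)) <= module_density
    if (any(take)) {
      new_edges <- pairs[, take, drop = FALSE]
      have <- igraph::get_edge_ids(g, as.vector(new_edges))
      new_edges <- new_edges[, have == 0L, drop = FALSE]
      if (ncol(new_edges)) g <- igraph::add_edges(g, as.vector(new_edges))
    }
    g <- .patch_connectivity(g)
    labels <- .gene_labels(n_nodes)
    list(network = .igraph_to_ppi(g, labels),
         module = labels[module],
         intended_hubs = if (hub_overlap) labels[module] else character())
  })
}

#' Reference gene tables of the colon adenocarcinoma interactome
#'
#' The embedded worked example for the selection cascade: the ranked gene
#' lists and the crucial-gene centrality table obtained from the main
#' connected component (232 nodes, 2097 edges) of a colon adenocarcinoma
#' protein-protein interaction network — 16 hubs by the mean + 2 SD degree
#' cutoff and the top-5% lists by betweenness (the bottlenecks), closeness
#' and stress. Intersecting these lists reproduces the 11 hub-bottleneck
#' and 10 crucial genes, and the crucial table's degree column drives the
#' potent/moderate/weak tiering. `DS` is the disease score the source
#' database attached to each gene (an opaque pass-through attribute).
#'
#' @return a list with `hubs` (16 symbols), `bottlenecks`, `top_cc`,
#'   `top_stress` (12 symbols each, rank order) and `crucial`, a data frame
#'   with columns `gene`, `description`, `degree`, `bc`, `cc`, `stress`,
#'   `ds`.
#' @examples
#' tabs <- coad_tables()
#' find_hub_bottlenecks(tabs$hubs, tabs$bottlenecks)
#' @export
coad_tables <- function() {
  list(
    hubs = c("TP53", "ALB", "PRDM10", "EGFR", "AKT1", "MYC", "KRAS", "HRAS",
             "SRC", "CCND1", "CDH1", "ITGA2", "CTNNB1", "ERBB2", "FOS", "TNF"),
    bottlenecks = c("TP53", "ALB", "PRDM10", "EGFR", "SRC", "MYC", "AKT1",
                    "KRAS", "CTNNB1", "CDH1", "ITGA2", "GUCY2C"),
    top_cc = c("TP53", "ALB", "PRDM10", "EGFR", "AKT1", "MYC", "SRC", "KRAS",
               "HRAS", "CDH1", "CTNNB1", "ERBB2"),
    top_stress = c("ALB", "TP53", "PRDM10", "EGFR", "SRC", "AKT1", "KRAS",
                   "MYC", "HRAS", "CTNNB1", "CDH1", "ITGA2"),
    crucial = data.frame(
      gene = c("TP53", "ALB", "PRDM10", "EGFR", "AKT1", "MYC", "KRAS",
               "SRC", "CDH1", "CTNNB1"),
      description = c(
        "tumor protein p53",
        "albumin",
        "PR domain containing 10",
        "epidermal growth factor receptor",
        "v-akt murine thymoma viral oncogene homolog 1",
        "v-myc myelocytomatosis viral oncogene homolog (avian)",
        "v-Ki-ras2 Kirsten rat sarcoma viral oncogene homolog",
        "v-src sarcoma (Schmidt-Ruppin A-2) viral oncogene homolog (avian)",
        "cadherin 1, type 1, E-cadherin (epithelial)",
        "catenin (cadherin-associated protein), beta 1, 88kDa"),
      degree = c(110L, 103L, 102L, 82L, 81L, 76L, 71L, 69L, 64L, 64L),
      bc = c(0.13, 0.12, 0.11, 0.06, 0.04, 0.04, 0.04, 0.05, 0.03, 0.03),
      cc = c(0.63, 0.62, 0.61, 0.58, 0.57, 0.56, 0.56, 0.56, 0.55, 0.55),
      stress = c(49586L, 50494L, 47678L, 27510L, 22286L, 20724L, 22076L,
                 23574L, 15662L, 16936L),
      ds = c(1.9, 0.8, 0.9, 1.0, 1.0, 1.4, 1.7, 0.6, 1.4, 1.7),
      stringsAsFactors = FALSE)
  )
}
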