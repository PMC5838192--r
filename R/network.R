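#' Construct an undirected protein-protein interaction network
#'
#' A `ppi_network` is a simple undirected graph over gene identifiers:
#' no self-loops, no duplicate edges (unordered pairs stored once), with
#' optional per-edge confidence scores (STRING combined-score scale, 0-1000)
#' and optional named numeric node attributes (e.g. a disease score `DS`).
#' Nodes may be isolated (degree 0).
#'
#' Self-loops are dropped with a warning. Duplicate edges (including the
#' reversed listing STRING exports use) are collapsed, keeping the maximum
#' score when scores are present.
#'
#' @param edges a two- or three-column data frame or matrix; columns are
#'   endpoint 1, endpoint 2 and (optionally) a numeric edge score. May have
#'   zero rows.
#' @param nodes optional character vector of node identifiers; the union of
#'   edge endpoints is always included, additional names become isolated
#'   nodes.
#' @param node_attrs optional data frame of numeric node attributes with a
#'   `node` column.
#' @return an object of class `ppi_network` with elements `nodes` (sorted
#'   character vector), `edges` (data frame `from`, `to`, `score`; `from` <
#'   `to` lexicographically) and `node_attrs`.
#' @examples
#' net <- ppi_network(data.frame(a = c("A", "B"), b = c("B", "C")))
#' net
#' @export
ppi_network <- function(edges, nodes = NULL, node_attrs = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L && nrow(edges) > 0L)
    stop("`edges` needs at least two columns")
  if (nrow(edges) == 0L) {
    ed <- data.frame(from = character(), to = character(),
                     score = numeric(), stringsAsFactors = FALSE)
  } else {
    a <- as.character(edges[[1L]])
    b <- as.character(edges[[2L]])
    score <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(NA_real_, length(a))
    loop <- a == b
    if (any(loop)) {
      warning(sprintf("dropped %d self-loop(s)", sum(loop)))
      a <- a[!loop]; b <- b[!loop]; score <- score[!loop]
    }
    from <- pmin(a, b)
    to <- pmax(a, b)
    key <- paste(from, to, sep = "\r")
    if (anyDuplicated(key)) {
      keep <- !duplicated(key)
      # collapse parallel listings, keeping the maximum score per pair
      mx <- tapply(score, key, function(s) if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE))
      score <- as.numeric(mx[key[keep]])
      from <- from[keep]; to <- to[keep]
    }
    o <- order(from, to)
    ed <- data.frame(from = from[o], to = to[o], score = score[o],
                     stringsAsFactors = FALSE)
  }
  all_nodes <- sort(unique(c(ed$from, ed$to, as.character(nodes))))
  if (!is.null(node_attrs)) {
    node_attrs <- as.data.frame(node_attrs, stringsAsFactors = FALSE)
    if (!"node" %in% names(node_attrs)) stop("`node_attrs` needs a `node` column")
    unknown <- setdiff(node_attrs$node, all_nodes)
    if (length(unknown))
      stop("node_attrs for unknown node(s): ", paste(unknown, collapse = ", "))
  }
  structure(list(nodes = all_nodes, edges = ed, node_attrs = node_attrs),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges", length(x$nodes), nrow(x$edges)))
  if (any(!is.na(x$edges$score))) cat(", scored")
  cat("\n")
  invisible(x)
}

#' Number of nodes / edges of a network
#' @param net a [ppi_network]
#' @return an integer
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

# integer adjacency list over the sorted node vector
.adjacency <- function(net) {
  n <- length(net$nodes)
  i <- match(net$edges$from, net$nodes)
  j <- match(net$edges$to, net$nodes)
  adj <- vector("list", n)
  idx <- split(c(j, i), c(i, j))
  adj[as.integer(names(idx))] <- lapply(idx, function(v) sort(unique(v)))
  empty <- vapply(adj, is.null, logical(1L))
  adj[empty] <- list(integer())
  adj
}

.as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Read an undirected edge list
#'
#' Two dialects are supported. `plain`: whitespace/tab-separated lines with
#' two or three columns (`node1 node2 [score]`), lines starting with `#`
#' ignored. `string_tsv`: a STRING-style export with a header row; the two
#' node columns are detected by a name containing `node1`/`node2` or
#' `protein1`/`protein2`, and the score column is named `combined_score`.
#' STRING exports list every edge in both orientations; the duplicate
#' listings are collapsed silently.
#'
#' @param path path to the file.
#' @param format `"plain"` or `"string_tsv"`.
#' @param min_score optional numeric; edges with score below this are removed
#'   (applied after duplicate collapsing). Requires a score column.
#' @return a [ppi_network]
#' @export
read_edge_list <- function(path, format = c("plain", "string_tsv"),
                           min_score = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format)
  if (format == "plain") {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) stop("empty edge list: ", path)
    fields <- strsplit(trimws(lines), "\\s+")
    nf <- lengths(fields)
    bad <- which(nf < 2L | nf > 3L)
    if (length(bad))
      stop(sprintf("malformed line %d in %s: expected 2-3 columns, got %d",
                   lineno[bad[1L]], path, nf[bad[1L]]))
    a <- vapply(fields, `[[`, "", 1L)
    b <- vapply(fields, `[[`, "", 2L)
    s <- rep(NA_real_, length(fields))
    has3 <- nf == 3L
    if (any(has3)) {
      raw <- vapply(fields[has3], `[[`, "", 3L)
      val <- suppressWarnings(as.numeric(raw))
      if (anyNA(val))
        stop(sprintf("malformed line %d in %s: non-numeric score '%s'",
                     lineno[has3][which(is.na(val))[1L]], path,
                     raw[which(is.na(val))[1L]]))
      s[has3] <- val
    }
    edges <- data.frame(a, b, s, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (!nrow(tab)) stop("empty edge list: ", path)
    nm <- tolower(names(tab))
    c1 <- which(grepl("node1|protein1", nm))[1L]
    c2 <- which(grepl("node2|protein2", nm))[1L]
    if (is.na(c1) || is.na(c2))
      stop("could not detect node columns (node1/node2 or protein1/protein2) in ", path)
    sc <- which(nm == "combined_score")[1L]
    edges <- data.frame(tab[[c1]], tab[[c2]],
                        if (!is.na(sc)) as.numeric(tab[[sc]]) else NA_real_,
                        stringsAsFactors = FALSE)
  }
  net <- ppi_network(edges)
  if (!is.null(min_score)) {
    if (all(is.na(net$edges$score)))
      stop("min_score given but the file has no score column")
    net$edges <- net$edges[!is.na(net$edges$score) & net$edges$score >= min_score, , drop = FALSE]
    rownames(net$edges) <- NULL
    # endpoints stay as (possibly now isolated) nodes
  }
  net
}

#' Write a network as a plain edge list
#'
#' Emits the `plain` dialect of [read_edge_list()]: `node1 node2 [score]`,
#' tab-separated, one line per edge, isolated nodes recorded in a trailing
#' comment block so a round-trip preserves the node set.
#'
#' @param net a [ppi_network]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(net, path) {
  ed <- net$edges
  scored <- any(!is.na(ed$score))
  lines <- if (scored) {
    sprintf("%s\t%s\t%s", ed$from, ed$to,
            ifelse(is.na(ed$score), "", format(ed$score, trim = TRUE)))
  } else sprintf("%s\t%s", ed$from, ed$to)
  iso <- setdiff(net$nodes, c(ed$from, ed$to))
  if (length(iso)) lines <- c(lines, paste("#isolated:", paste(iso, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

# read back the "#isolated:" block write_edge_list() appends
.read_isolated_comment <- function(path) {
  lines <- grep("^#isolated:", readLines(path, warn = FALSE), value = TRUE)
  if (!length(lines)) return(character())
  unlist(strsplit(sub("^#isolated:\\s*", "", lines), "\\s+"))
}

#' Connected components of a network
#'
#' Components are ordered by size descending, ties broken by the
#' lexicographically smallest member, so the decomposition is deterministic.
#' The first component is the main component on which all centrality
#' analysis is performed.
#'
#' @param net a [ppi_network]
#' @return an object of class `component_decomposition`: a list with
#'   `components` (list of sorted node vectors), `main_component` (the
#'   first), `isolated_nodes` (degree-0 nodes) and `sizes`.
#' @export
connected_components <- function(net) {
  if (!length(net$nodes)) {
    out <- list(components = list(), main_component = character(),
                isolated_nodes = character(), sizes = integer())
    return(structure(out, class = "component_decomposition"))
  }
  memb <- igraph::components(.as_igraph(net))$membership
  comps <- split(names(memb), memb)
  comps <- lapply(comps, function(v) sort(unname(v)))
  first <- vapply(comps, `[[`, "", 1L)
  o <- order(-lengths(comps), first)
  comps <- unname(comps[o])
  iso <- sort(unlist(comps[lengths(comps) == 1L], use.names = FALSE))
  structure(list(components = comps,
                 main_component = comps[[1L]],
                 isolated_nodes = if (is.null(iso)) character() else iso,
                 sizes = lengths(comps)),
            class = "component_decomposition")
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf("<component_decomposition> %d component(s); main %d node(s); %d isolated\n",
              length(x$components),
              if (length(x$components)) length(x$main_component) else 0L,
              length(x$isolated_nodes)))
  invisible(x)
}

#' Induced subgraph
#'
#' Restricts a network to a node subset, keeping edges with both endpoints
#' in the subset; edge scores and node attributes are carried over.
#'
#' @param net a [ppi_network]
#' @param keep character vector of node identifiers, a subset of `net$nodes`
#' @return a [ppi_network]
#' @export
induced_subgraph <- function(net, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, net$nodes)
  if (length(unknown))
    stop("unknown node(s) in `keep`: ", paste(sort(unknown), collapse = ", "))
  ed <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, , drop = FALSE]
  attrs <- net$node_attrs
  if (!is.null(attrs)) {
    attrs <- attrs[attrs$node %in% keep, , drop = FALSE]
    rownames(attrs) <- NULL
    if (!nrow(attrs)) attrs <- NULL
  }
  ppi_network(ed, nodes = keep, node_attrs = attrs)
}

#' Extract the main connected component as a network
#'
#' Convenience wrapper: [connected_components()] followed by
#' [induced_subgraph()] on the largest component.
#'
#' @param net a [ppi_network]
#' @return a [ppi_network] restricted to the main component
#' @export
main_component <- function(net) {
  induced_subgraph(net, connected_components(net)$main_component)
}
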