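#' Write the four ranked gene lists as one padded table
#'
#' Columns `R` (rank), hubs, bottlenecks, top-closeness, top-stress; the
#' shorter lists are padded with `"-"` to the length of the longest, the
#' layout used to report ranked selection lists side by side.
#'
#' @param result a `selection_result`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ranked_lists <- function(result, path) {
  cols <- list(hub_genes = result$hubs,
               bottleneck_genes = result$bottlenecks,
               top_cc_genes = result$top_cc,
               top_stress_genes = result$top_stress)
  len <- max(0L, lengths(cols))
  pad <- function(v) c(v, rep("-", len - length(v)))
  tab <- if (len > 0L) {
    cbind(data.frame(R = seq_len(len)),
          as.data.frame(lapply(cols, pad), stringsAsFactors = FALSE))
  } else {
    as.data.frame(c(list(R = integer()),
                    lapply(cols, function(v) character())))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the crucial-gene report
#'
#' One row per crucial gene, ordered by degree descending (ties broken
#' lexicographically), with its centrality values, tier, an optional
#' description and an optional disease score (`DS`); description and DS
#' are left blank when not available. A crucial gene missing from the
#' centrality table is an error naming the gene.
#'
#' @param result a `selection_result`
#' @param table a [centrality_table()] covering the crucial genes
#' @param path output path
#' @param annotations optional data frame with columns `node` and
#'   `description`
#' @param ds optional named numeric vector of disease scores
#' @return `path`, invisibly
#' @export
write_crucial_genes <- function(result, table, path, annotations = NULL,
                                ds = NULL) {
  crucial <- result$crucial
  missing <- setdiff(crucial, table$node)
  if (length(missing))
    stop("crucial gene(s) missing from centrality table: ",
         paste(missing, collapse = ", "))
  rows <- table[match(crucial, table$node), , drop = FALSE]
  o <- order(-rows$degree, rows$node)
  rows <- rows[o, , drop = FALSE]
  lookup <- function(x, key) {
    out <- rep("", nrow(rows))
    if (!is.null(x)) {
      hit <- match(rows$node, if (is.data.frame(x)) x$node else names(x))
      val <- if (is.data.frame(x)) x[[key]][hit] else unname(x[hit])
      out[!is.na(hit)] <- as.character(val[!is.na(hit)])
    }
    out
  }
  tier <- rep("", nrow(rows))
  known <- match(rows$node, names(result$tiers))
  tier[!is.na(known)] <- result$tiers[known[!is.na(known)]]
  tab <- data.frame(R = seq_len(nrow(rows)),
                    name = rows$node,
                    description = lookup(annotations, "description"),
                    degree = rows$degree,
                    BC = rows$betweenness,
                    CC = rows$closeness,
                    stress = rows$stress,
                    DS = lookup(ds, "ds"),
                    tier = tier,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.stage <- function(report, name, code) {
  t0 <- Sys.time()
  message(sprintf("[%s] ...", name))
  value <- tryCatch(code, error = function(e) {
    report$failed_stage <- name
    report$error <- conditionMessage(e)
    if (!is.null(report$out_dir))
      .write_run_report(report, file.path(report$out_dir, "run_report.json"))
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  value
}

.write_run_report <- function(report, path) {
  jsonlite::write_json(report[setdiff(names(report), "out_dir")], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(path)
}

#' Run the full interactome analysis end to end
#'
#' Stages, in order: ingest an edge list (or generate a benchmark network
#' from a generator spec) -> connected components -> centrality table of
#' the main component -> scale-free power-law report -> selection cascade
#' with tiering -> MCODE clustering -> main-cluster overlap with the hub
#' and crucial lists. Every artifact is written under `out_dir` and a run
#' report (JSON) summarizes inputs, parameters, outputs and the seed. A
#' stage error aborts the run with the stage name; the report written so
#' far is retained with a failed-stage marker.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   `input` (edge-list path) plus optional `format` / `min_score`, or
#'   `generator` (list with `n_connected`, `n_edges`, `n_isolated`,
#'   optional `model`); optional `thresholds` (`hub_sd_multiplier`,
#'   `top_fraction`, `tier_override`), `mcode` (`node_score_cutoff`,
#'   `k_core`, `haircut`, `max_depth`), `bins`, `annotations` (TSV path
#'   with `node`, `description`), `seed`, and `out_dir` (required).
#' @return the run report, invisibly (class `run_report`)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  th <- config$thresholds
  mc <- config$mcode
  p <- list(hub_sd_multiplier = th$hub_sd_multiplier %||% 2,
            top_fraction = th$top_fraction %||% 0.05,
            node_score_cutoff = mc$node_score_cutoff %||% 0.2,
            k_core = mc$k_core %||% 2L,
            haircut = mc$haircut %||% TRUE,
            max_depth = mc$max_depth %||% 100L,
            bins = config$bins %||% 20L,
            min_score = config$min_score)
  report <- list(out_dir = config$out_dir, seed = seed, parameters = p,
                 tool_version = as.character(utils::packageVersion("hubnet")),
                 outputs = list())
  out <- function(name) file.path(config$out_dir, name)

  net <- .stage(report, "ingest", {
    if (!is.null(config$input)) {
      read_edge_list(config$input, format = config$format %||% "plain",
                     min_score = config$min_score)
    } else if (!is.null(config$generator)) {
      g <- config$generator
      n <- generate_network(g$n_connected, g$n_edges,
                            n_isolated = g$n_isolated %||% 0L, seed = seed,
                            model = g$model %||% "preferential_attachment")
      write_edge_list(n, out("network.tsv"))
      report$outputs$network <- out("network.tsv")
      n
    } else stop("config needs either `input` or `generator`")
  })
  cc <- .stage(report, "components", connected_components(net))
  report$input_summary <- list(nodes = n_nodes(net), edges = n_edges(net),
                               components = length(cc$components),
                               main_component_size = length(cc$main_component),
                               isolated = length(cc$isolated_nodes))
  main <- induced_subgraph(net, cc$main_component)

  tab <- .stage(report, "centrality", {
    t <- centrality_table(main)
    write_centrality(t, out("centrality.tsv"))
    report$outputs$centrality <- out("centrality.tsv")
    t
  })
  fits <- .stage(report, "power_law", {
    r <- scale_free_report(tab, bins = p$bins)
    write_power_law_report(r, out("power_law.json"))
    report$outputs$power_law <- out("power_law.json")
    r
  })
  sel <- .stage(report, "selection", {
    s <- select_genes(tab, hub_sd_multiplier = p$hub_sd_multiplier,
                      top_fraction = p$top_fraction,
                      tier_override = th$tier_override)
    stopifnot(all(s$crucial %in% s$hub_bottlenecks),
              all(s$hub_bottlenecks %in% s$hubs))
    write_ranked_lists(s, out("ranked_lists.tsv"))
    ann <- if (!is.null(config$annotations))
      utils::read.delim(config$annotations, stringsAsFactors = FALSE)
    ds <- NULL
    if (!is.null(net$node_attrs) && "DS" %in% names(net$node_attrs))
      ds <- stats::setNames(net$node_attrs$DS, net$node_attrs$node)
    write_crucial_genes(s, tab, out("crucial_genes.tsv"),
                        annotations = ann, ds = ds)
    report$outputs$ranked_lists <- out("ranked_lists.tsv")
    report$outputs$crucial_genes <- out("crucial_genes.tsv")
    s
  })
  cs <- .stage(report, "clustering", {
    c <- mcode_cluster(main, node_score_cutoff = p$node_score_cutoff,
                       k_core = p$k_core, haircut = p$haircut,
                       max_depth = p$max_depth)
    write_clusters(c, out("clusters.tsv"))
    report$outputs$clusters <- out("clusters.tsv")
    c
  })
  report$selection <- list(n_hubs = length(sel$hubs),
                           n_bottlenecks = length(sel$bottlenecks),
                           n_hub_bottlenecks = length(sel$hub_bottlenecks),
                           n_crucial = length(sel$crucial),
                           crucial = sel$crucial,
                           tiers = as.list(sel$tiers))
  report$power_law <- lapply(unclass(fits), function(f)
    if (inherits(f, "power_law_fit")) list(metric = f$metric, a = f$a, b = f$b,
                                           r_squared = f$r_squared) else f)
  if (length(cs$clusters)) {
    mcl <- main_cluster(cs, hubs = sel$hubs, crucial = sel$crucial)
    report$main_cluster <- list(size = mcl$size, edge_count = mcl$edge_count,
                                density = mcl$density, score = mcl$score,
                                hubs_in_cluster = mcl$hub_overlap$count,
                                crucial_in_cluster = mcl$crucial_overlap$count)
  } else {
    report$main_cluster <- list(size = 0L)
  }
  .write_run_report(report, out("run_report.json"))
  report$outputs$run_report <- out("run_report.json")
  class(report) <- "run_report"
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replay the selection cascade on the embedded reference tables
#'
#' Runs the intersection and tiering stages of the cascade on the ranked
#' gene lists of [coad_tables()] (the fixture mode of the pipeline):
#' hub-bottlenecks from the hub and bottleneck lists, crucial genes from
#' the top-closeness and top-stress lists, and tiers from the crucial-gene
#' degrees. Optionally writes the ranked-lists and crucial-gene reports.
#'
#' @param out_dir optional output directory for the two TSV reports
#' @return a `selection_result`
#' @examples
#' run_reference_example()
#' @export
run_reference_example <- function(out_dir = NULL) {
  tabs <- coad_tables()
  sel <- selection_from_lists(tabs$hubs, tabs$bottlenecks, tabs$top_cc,
                              tabs$top_stress,
                              degrees = stats::setNames(tabs$crucial$degree,
                                                        tabs$crucial$gene))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ranked_lists(sel, file.path(out_dir, "ranked_lists.tsv"))
    ref <- tabs$crucial
    tab <- data.frame(node = ref$gene, degree = ref$degree,
                      betweenness = ref$bc, closeness = ref$cc,
                      stress = ref$stress, stringsAsFactors = FALSE)
    write_crucial_genes(sel, tab, file.path(out_dir, "crucial_genes.tsv"),
                        annotations = data.frame(node = ref$gene,
                                                 description = ref$description,
                                                 stringsAsFactors = FALSE),
                        ds = stats::setNames(ref$ds, ref$gene))
  }
  sel
}
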