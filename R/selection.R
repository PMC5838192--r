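#' Select hub nodes by the mean + k*SD degree cutoff
#'
#' Hubs are nodes whose degree strictly exceeds `mean(degree) +
#' multiplier * sd(degree)` over the component, with the sample standard
#' deviation (n-1 denominator). The strict inequality makes a
#' degree-regular component hub-free.
#'
#' @param table a [centrality_table()] (any data frame with `node` and
#'   `degree` columns works)
#' @param multiplier the number of standard deviations above the mean
#'   (default 2)
#' @return character vector of hub genes ordered by degree descending, ties
#'   broken lexicographically
#' @export
select_hubs <- function(table, multiplier = 2) {
  if (nrow(table) < 2L) stop("hub selection needs a component of >= 2 nodes")
  cutoff <- mean(table$degree) + multiplier * stats::sd(table$degree)
  hubs <- table[table$degree > cutoff, , drop = FALSE]
  hubs$node[order(-hubs$degree, hubs$node)]
}

#' Select the top fraction of genes by a centrality value
#'
#' The target count is `ceiling(n * fraction)`. Genes are ranked by value
#' descending (ties broken lexicographically) and the list is expanded to
#' include every gene tied with the last admitted value, so a boundary tie
#' is never silently truncated (the expansion is logged).
#'
#' @param values named numeric vector, gene -> centrality value
#' @param fraction fraction of genes to keep, in (0, 1]
#' @return character vector of selected genes, value descending
#' @export
select_top_fraction <- function(values, fraction = 0.05) {
  if (!length(values)) stop("empty value mapping")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]")
  genes <- names(values)
  if (is.null(genes)) stop("`values` must be named by gene")
  o <- order(-values, genes)
  genes <- genes[o]; values <- values[o]
  count <- ceiling(length(values) * fraction)
  threshold <- values[count]
  sel <- which(values >= threshold)
  if (length(sel) > count)
    message(sprintf("select_top_fraction: boundary tie expanded selection from %d to %d",
                    count, length(sel)))
  genes[sel]
}

#' Intersect hub and bottleneck lists
#'
#' Hub-bottleneck genes are the nodes that are simultaneously hubs (degree
#' cutoff) and bottlenecks (top fraction by betweenness). The hub
#' (degree-rank) order is preserved.
#'
#' @param hubs,bottlenecks character vectors from [select_hubs()] and
#'   [select_top_fraction()]
#' @return character vector, in hub order
#' @export
find_hub_bottlenecks <- function(hubs, bottlenecks) {
  hubs[hubs %in% bottlenecks]
}

#' Crucial genes: hub-bottlenecks also top-ranked by closeness and stress
#'
#' @param hub_bottlenecks output of [find_hub_bottlenecks()]
#' @param top_cc,top_stress top-fraction lists by closeness and stress
#' @return character vector, in hub order
#' @export
classify_crucial <- function(hub_bottlenecks, top_cc, top_stress) {
  hub_bottlenecks[hub_bottlenecks %in% top_cc & hub_bottlenecks %in% top_stress]
}

#' Tier crucial genes as potent / moderate / weak
#'
#' A documented reconstruction of the narrative three-way grouping of
#' crucial genes by degree: genes tied at the minimum degree form the
#' *weak* tier (provided at least one gene remains above them); among the
#' remaining genes, sorted by degree descending, the *potent* tier is
#' everything above the largest consecutive degree gap (first occurrence
#' scanning from the top) and the rest are *moderate*. If all degrees are
#' equal every gene is moderate; a single gene left above the weak tier is
#' potent. Fewer than 3 crucial genes cannot be tiered three ways: all are
#' assigned potent with a warning.
#'
#' @param crucial character vector of crucial genes
#' @param degrees named numeric vector of degrees covering `crucial`, or a
#'   [centrality_table()]
#' @return named character vector gene -> tier, in `crucial` order; levels
#'   `"potent"`, `"moderate"`, `"weak"`
#' @export
tier_crucial <- function(crucial, degrees) {
  if (is.data.frame(degrees))
    degrees <- stats::setNames(degrees$degree, degrees$node)
  missing <- setdiff(crucial, names(degrees))
  if (length(missing))
    stop("no degree for crucial gene(s): ", paste(missing, collapse = ", "))
  tiers <- stats::setNames(rep("moderate", length(crucial)), crucial)
  if (length(crucial) < 3L) {
    warning("fewer than 3 crucial genes; all assigned 'potent'")
    tiers[] <- "potent"
    return(tiers)
  }
  d <- degrees[crucial]
  if (length(unique(d)) == 1L) return(tiers)  # all moderate
  weak <- crucial[d == min(d)]
  tiers[weak] <- "weak"
  rest <- setdiff(crucial, weak)
  dr <- d[rest]
  o <- order(-dr, rest)
  rest <- rest[o]; dr <- dr[o]
  if (length(rest) == 1L) {
    tiers[rest] <- "potent"
  } else {
    gaps <- dr[-length(dr)] - dr[-1L]
    if (max(gaps) > 0) {
      cut <- which.max(gaps)  # first occurrence of the largest gap
      tiers[rest[seq_len(cut)]] <- "potent"
    }
  }
  tiers
}

#' Run the full gene-prioritization cascade on a centrality table
#'
#' From a main-component [centrality_table()]: hubs by the mean + k*SD
#' degree cutoff; bottleneck / top-closeness / top-stress lists as the top
#' fraction by the respective metric; hub-bottlenecks as the hub/bottleneck
#' intersection; crucial genes as hub-bottlenecks present in both the
#' top-closeness and top-stress lists; and a three-way tiering of the
#' crucial genes.
#'
#' @param table a [centrality_table()]
#' @param hub_sd_multiplier degree-cutoff multiplier (default 2)
#' @param top_fraction fraction for the centrality top lists (default 0.05)
#' @param tier_override optional named character vector gene -> tier that
#'   replaces the computed tier for the named genes
#' @return an object of class `selection_result`: list with `hubs`,
#'   `bottlenecks`, `top_cc`, `top_stress`, `hub_bottlenecks`, `crucial`,
#'   `tiers`, and the thresholds used.
#' @export
select_genes <- function(table, hub_sd_multiplier = 2, top_fraction = 0.05,
                         tier_override = NULL) {
  val <- function(col) stats::setNames(table[[col]], table$node)
  hubs <- select_hubs(table, hub_sd_multiplier)
  bottlenecks <- select_top_fraction(val("betweenness"), top_fraction)
  top_cc <- select_top_fraction(val("closeness"), top_fraction)
  top_stress <- select_top_fraction(val("stress"), top_fraction)
  .assemble_selection(hubs, bottlenecks, top_cc, top_stress,
                      degrees = val("degree"), tier_override = tier_override,
                      thresholds = list(hub_sd_multiplier = hub_sd_multiplier,
                                        top_fraction = top_fraction))
}

#' Replay the cascade's intersection stages on precomputed ranked lists
#'
#' Used when the four ranked lists (hubs, bottlenecks, top-closeness,
#' top-stress) come from elsewhere — e.g. the embedded colon adenocarcinoma
#' reference tables of [coad_tables()] — rather than from a centrality
#' table computed here.
#'
#' @param hubs,bottlenecks,top_cc,top_stress ranked gene lists
#' @param degrees optional named degree vector; tiering is skipped without it
#' @param tier_override as in [select_genes()]
#' @return a `selection_result`
#' @export
selection_from_lists <- function(hubs, bottlenecks, top_cc, top_stress,
                                 degrees = NULL, tier_override = NULL) {
  .assemble_selection(hubs, bottlenecks, top_cc, top_stress,
                      degrees = degrees, tier_override = tier_override,
                      thresholds = list())
}

.assemble_selection <- function(hubs, bottlenecks, top_cc, top_stress,
                                degrees, tier_override, thresholds) {
  hb <- find_hub_bottlenecks(hubs, bottlenecks)
  crucial <- classify_crucial(hb, top_cc, top_stress)
  tiers <- if (length(crucial) && !is.null(degrees)) {
    tier_crucial(crucial, degrees)
  } else stats::setNames(character(), character())
  if (!is.null(tier_override)) {
    known <- intersect(names(tier_override), names(tiers))
    tiers[known] <- tier_override[known]
  }
  structure(list(hubs = hubs, bottlenecks = bottlenecks, top_cc = top_cc,
                 top_stress = top_stress, hub_bottlenecks = hb,
                 crucial = crucial, tiers = tiers, thresholds = thresholds),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d hubs, %d bottlenecks, %d hub-bottlenecks, %d crucial\n",
              length(x$hubs), length(x$bottlenecks),
              length(x$hub_bottlenecks), length(x$crucial)))
  if (length(x$crucial)) {
    for (tier in c("potent", "moderate", "weak")) {
      g <- names(x$tiers)[x$tiers == tier]
      if (length(g)) cat(sprintf("  %-8s %s\n", tier, paste(g, collapse = ", ")))
    }
  }
  invisible(x)
}
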