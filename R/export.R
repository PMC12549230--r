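#' Write a results table to TSV
#'
#' Writes differential results, module assignments, hub reports and other
#' tabular results with a deterministic row order: hub reports keep their
#' ranking (descending neighborhood connectivity, ties by id); every other
#' table is sorted by its id column. An empty result yields a header-only
#' file. The output re-reads with `read.delim()`.
#'
#' @param result a data.frame (`diff_result`, `module_assignment`,
#'   `hub_report`, or plain).
#' @param path output path.
#' @export
write_results_table <- function(result, path) {
  df <- as.data.frame(result, stringsAsFactors = FALSE)
  if (!inherits(result, "hub_report") && nrow(df) > 0) {
    id_col <- intersect(c("feature_id", "gene_id", "node", "sample_id"),
                        names(df))
    if (length(id_col) > 0) df <- df[order(df[[id_col[1]]]), , drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results table to ", path, call. = FALSE)
  invisible(path)
}

#' Export an association network to GraphML or SIF
#'
#' GraphML carries all node attributes (layer, centralities, cluster, ...)
#' and the `rho` / `p` / `weight` edge attributes; SIF carries topology
#' only (`a pp b` lines, one isolated node id per line). Centrality
#' records and cluster labels, if supplied, are attached as node
#' attributes before writing.
#'
#' @param net an `association_network`.
#' @param path output path.
#' @param format `"graphml"` or `"sif"`.
#' @param centrality optional data.frame from [centrality_metrics()].
#' @param clusters optional named labels from [community_clusters()].
#' @export
export_network <- function(net, path, format = c("graphml", "sif"),
                           centrality = NULL, clusters = NULL) {
  stopifnot(inherits(net, "association_network"))
  format <- match.arg(format)
  g <- net$graph
  ids <- igraph::V(g)$name
  if (!is.null(centrality) && length(ids) > 0) {
    idx <- match(ids, centrality$node)
    g <- igraph::set_vertex_attr(g, "degree", value = centrality$degree[idx])
    g <- igraph::set_vertex_attr(g, "betweenness",
                                 value = centrality$betweenness[idx])
    g <- igraph::set_vertex_attr(
      g, "neighborhood_connectivity",
      value = centrality$neighborhood_connectivity[idx])
  }
  if (!is.null(clusters) && length(ids) > 0)
    g <- igraph::set_vertex_attr(g, "cluster",
                                 value = unname(clusters[ids]))
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    lines <- if (nrow(el) > 0) paste(el[, 1], "pp", el[, 2]) else character(0)
    isolated <- setdiff(ids, unique(c(el)))
    writeLines(c(lines, isolated), path)
  }
  invisible(path)
}
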