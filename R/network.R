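# Spearman association networks over differential host and microbial
# features, per experimental group: edge inference, global properties,
# community structure, centralities, hubs, and gene-family association
# tables.

#' Spearman correlation edges between features
#'
#' Tests every unordered feature pair with Spearman correlation (average
#' ranks for ties; p from the t-distribution approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` at all n) and keeps pairs passing both
#' thresholds. Edge weight is the `-log10` of the p-value. Constant
#' features cannot be ranked and are skipped with a log message.
#'
#' @param table a `feature_table`, typically restricted to one group's
#'   samples (>= 4) via [ft_subset()]; >= 2 features.
#' @param p_max p-value threshold (strict: `p < p_max`).
#' @param rho_min rho threshold (inclusive). In `"signed"` mode the filter
#'   is `rho >= rho_min` (positive associations only); `"absolute"` keeps
#'   `|rho| >= rho_min`.
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return data.frame with `feature_a`, `feature_b`, `rho`, `p`, `weight`.
#' @export
spearman_edges <- function(table, p_max = 0.05, rho_min = 0.5,
                           mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  n <- nrow(v)
  if (n < 4) stop("correlation needs >= 4 samples", call. = FALSE)
  if (ncol(v) < 2) stop(">= 2 features required", call. = FALSE)
  variable <- apply(v, 2, function(col) length(unique(col)) > 1)
  if (!any(variable)) stop("all features are constant", call. = FALSE)
  if (any(!variable))
    mb_log("spearman_edges: skipping %d constant feature(s)",
           sum(!variable))
  v <- v[, variable, drop = FALSE]
  ranks <- apply(v, 2, rank)  # average ranks for ties
  rho <- stats::cor(ranks)    # Pearson on ranks = Spearman
  p <- ncol(v)
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[upper.tri(rho)]
  r_clamp <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tval <- r_clamp * sqrt((n - 2) / (1 - r_clamp^2))
  pval <- 2 * stats::pt(-abs(tval), df = n - 2)
  pval[abs(r) >= 1] <- 0
  keep <- if (mode == "signed") r >= rho_min else abs(r) >= rho_min
  keep <- keep & (pval < p_max)
  pv <- pmax(pval[keep], 1e-300)  # floor so -log10 stays finite
  data.frame(feature_a = colnames(v)[pairs[keep, 1]],
             feature_b = colnames(v)[pairs[keep, 2]],
             rho = r[keep], p = pval[keep], weight = -log10(pv),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build an association network from a filtered edge list
#'
#' Constructs a simple undirected igraph graph carrying `rho`, `p` and
#' `weight` edge attributes, plus node attributes (`layer`, `taxon`,
#' `is_aars`, ...) taken from `node_meta`. Global properties (node/edge
#' count, density `2E / (N (N-1))`, average neighbors = mean degree) are
#' reported alongside.
#'
#' @param edges data.frame as returned by [spearman_edges()].
#' @param node_meta optional data.frame keyed by node id (rownames or a
#'   `node_id` column) with per-node annotation columns.
#' @param include_isolated if TRUE, every row of `node_meta` becomes a
#'   node even without edges.
#' @return object of class `association_network`: list with `graph`
#'   (igraph) and `properties`.
#' @export
build_network <- function(edges, node_meta = NULL, include_isolated = FALSE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    if (any(edges$feature_a == edges$feature_b))
      stop("self-loops are not allowed", call. = FALSE)
    key <- paste(pmin(edges$feature_a, edges$feature_b),
                 pmax(edges$feature_a, edges$feature_b))
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)]
      stop("duplicate edges for pair(s): ",
           paste(utils::head(dup, 3), collapse = "; "), call. = FALSE)
    }
  }
  if (!is.null(node_meta)) {
    node_meta <- as.data.frame(node_meta, stringsAsFactors = FALSE)
    if ("node_id" %in% names(node_meta)) {
      rownames(node_meta) <- node_meta$node_id
      node_meta$node_id <- NULL
    }
  }
  edge_nodes <- unique(c(edges$feature_a, edges$feature_b))
  nodes <- if (include_isolated && !is.null(node_meta))
    union(rownames(node_meta), edge_nodes) else edge_nodes
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(edges$feature_a, nodes),
                                    match(edges$feature_b, nodes)))
    igraph::E(g)$rho <- edges$rho
    igraph::E(g)$p <- edges$p
    igraph::E(g)$weight <- edges$weight
  }
  if (!is.null(node_meta) && length(nodes) > 0) {
    for (col in names(node_meta)) {
      vals <- node_meta[nodes, col]
      g <- igraph::set_vertex_attr(g, col, value = vals)
    }
  }
  n <- length(nodes)
  e <- nrow(edges)
  structure(list(
    graph = g,
    properties = list(n_nodes = n, n_edges = e,
                      density = if (n > 1) 2 * e / (n * (n - 1)) else 0,
                      average_neighbors = if (n > 0) 2 * e / n else 0)),
    class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  p <- x$properties
  cat(sprintf(
    "association_network: %d nodes, %d edges, density %.3f, avg neighbors %.2f\n",
    p$n_nodes, p$n_edges, p$density, p$average_neighbors))
  invisible(x)
}

#' Community clustering by greedy modularity maximization
#'
#' Partitions the network with fast-greedy modularity optimization
#' (unweighted, deterministic) and reports the modularity Q of the
#' returned partition. Disconnected components can never be merged, so
#' separable graphs yield at least one cluster per component.
#'
#' @param net an `association_network` with >= 1 edge.
#' @param seed accepted for interface stability; the greedy algorithm is
#'   deterministic and does not consume randomness.
#' @return list with `labels` (named integer vector), `n_clusters`,
#'   `modularity`.
#' @export
community_clusters <- function(net, seed = 1) {
  stopifnot(inherits(net, "association_network"))
  g <- net$graph
  if (igraph::ecount(g) < 1) stop("clustering needs >= 1 edge", call. = FALSE)
  comm <- igraph::cluster_fast_greedy(g, weights = NA)
  # choose the dendrogram cut with maximal modularity; ties (within
  # floating-point noise) resolve to the coarser partition
  best_mem <- igraph::membership(comm)
  best_q <- igraph::modularity(g, best_mem)
  best_k <- length(unique(best_mem))
  for (k in seq_len(igraph::vcount(g))) {
    mem <- tryCatch(suppressWarnings(igraph::cut_at(comm, no = k)),
                    error = function(e) NULL)
    if (is.null(mem)) next
    q <- igraph::modularity(g, mem)
    if (q > best_q + 1e-12 ||
        (q > best_q - 1e-12 && length(unique(mem)) < best_k)) {
      best_mem <- mem
      best_q <- q
      best_k <- length(unique(mem))
    }
  }
  labels <- stats::setNames(as.integer(best_mem), igraph::V(g)$name)
  list(labels = labels, n_clusters = length(unique(labels)),
       modularity = igraph::modularity(g, best_mem))
}

#' Node centralities: degree, betweenness, neighborhood connectivity
#'
#' Betweenness is unweighted shortest-path betweenness, unnormalized, each
#' unordered pair counted once. Neighborhood connectivity is the mean
#' degree of a node's neighbors (0 for isolated nodes).
#'
#' @param net an `association_network`.
#' @return data.frame with `node`, `degree`, `betweenness`,
#'   `neighborhood_connectivity`.
#' @export
centrality_metrics <- function(net) {
  stopifnot(inherits(net, "association_network"))
  g <- net$graph
  if (igraph::vcount(g) == 0)
    return(data.frame(node = character(0), degree = integer(0),
                      betweenness = numeric(0),
                      neighborhood_connectivity = numeric(0)))
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  nc <- ifelse(deg > 0, as.vector(adj %*% deg) / deg, 0)
  data.frame(node = igraph::V(g)$name, degree = as.integer(deg),
             betweenness = unname(btw),
             neighborhood_connectivity = unname(nc),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Identify hub nodes by neighborhood connectivity
#'
#' Hubs are nodes attached to well-connected nodes: among nodes with
#' degree at least `min_degree`, those whose neighborhood connectivity
#' reaches the `quantile`-quantile of the eligible nodes are flagged (ties
#' at the boundary included). The report ranks all nodes by descending
#' neighborhood connectivity, ties broken by id.
#'
#' @param records centrality data.frame from [centrality_metrics()]
#'   (non-empty).
#' @param quantile quantile of neighborhood connectivity defining "high".
#' @param min_degree minimum degree for hub eligibility.
#' @param clusters optional named cluster labels (from
#'   [community_clusters()]) to carry into the report.
#' @return data.frame of class `hub_report`, ranked, with a logical
#'   `hub` column (and `cluster` if provided).
#' @export
identify_hubs <- function(records, quantile = 0.90, min_degree = 2,
                          clusters = NULL) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) stop("empty centrality records", call. = FALSE)
  eligible <- records$degree >= min_degree
  if (any(eligible)) {
    thr <- stats::quantile(records$neighborhood_connectivity[eligible],
                           probs = quantile, names = FALSE)
    records$hub <- eligible & records$neighborhood_connectivity >= thr
  } else {
    records$hub <- FALSE
  }
  if (!is.null(clusters))
    records$cluster <- unname(clusters[records$node])
  ord <- order(-records$neighborhood_connectivity, records$node)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hub_report", "data.frame")
  out
}

#' Gene-family to host-gene association table
#'
#' Restricts the network to edges linking a flagged microbial gene-family
#' node (e.g. an aminoacyl-tRNA synthetase, `is_aars`) to a host gene,
#' annotates the host genes with GO terms, drops terms annotating at least
#' `max_term_size` genes (broad terms carry little specific signal), and
#' summarises per (source microbe, GO term): number of distinct host genes
#' and mean edge rho. This is the input shape of a chord diagram.
#'
#' @param net an `association_network` whose vertices carry `layer` (with
#'   host genes labelled `"host_gene"`), a logical family flag attribute,
#'   and `taxon` for microbial nodes (falling back to the `"gene|taxon"`
#'   id convention).
#' @param go_annotation data.frame with columns `gene_id`, `go_term`
#'   (one row per annotation; required).
#' @param family_flag name of the logical vertex attribute (default
#'   `"is_aars"`).
#' @param max_term_size terms annotating at least this many genes in the
#'   annotation table are dropped (default 100, i.e. terms with fewer than
#'   100 genes are kept).
#' @return data.frame with `microbe`, `go_term`, `n_host_genes`,
#'   `mean_rho`, sorted by microbe then term.
#' @export
extract_gene_family_associations <- function(net, go_annotation,
                                             family_flag = "is_aars",
                                             max_term_size = 100) {
  stopifnot(inherits(net, "association_network"))
  if (missing(go_annotation) || is.null(go_annotation))
    stop("go_annotation table is required", call. = FALSE)
  go_annotation <- as.data.frame(go_annotation, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "go_term") %in% names(go_annotation)))
    stop("go_annotation needs columns gene_id and go_term", call. = FALSE)
  empty <- data.frame(microbe = character(0), go_term = character(0),
                      n_host_genes = integer(0), mean_rho = numeric(0),
                      stringsAsFactors = FALSE)
  g <- net$graph
  if (igraph::ecount(g) == 0) return(empty)
  flag <- igraph::vertex_attr(g, family_flag)
  layer <- igraph::vertex_attr(g, "layer")
  if (is.null(flag) || !any(flag %in% TRUE)) return(empty)
  taxon <- igraph::vertex_attr(g, "taxon")
  if (is.null(taxon)) taxon <- rep(NA_character_, igraph::vcount(g))
  taxon <- ifelse(is.na(taxon) | taxon == "",
                  split_taxon_labels(igraph::V(g)$name), taxon)
  ends <- igraph::as_edgelist(g, names = FALSE)
  rho <- igraph::E(g)$rho
  rows <- list()
  term_size <- table(unique(go_annotation)[, "go_term"])
  for (e in seq_len(nrow(ends))) {
    a <- ends[e, 1]; b <- ends[e, 2]
    fam <- c(isTRUE(flag[a]), isTRUE(flag[b]))
    host <- c(identical(layer[a], "host_gene"), identical(layer[b], "host_gene"))
    if (fam[1] && host[2]) idx <- c(a, b)
    else if (fam[2] && host[1]) idx <- c(b, a)
    else next
    gene <- igraph::V(g)$name[idx[2]]
    terms <- go_annotation$go_term[go_annotation$gene_id == gene]
    terms <- terms[term_size[terms] < max_term_size]
    for (tm in unique(terms))
      rows[[length(rows) + 1]] <- data.frame(
        microbe = taxon[idx[1]], go_term = tm, host_gene = gene,
        rho = rho[e], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  long <- do.call(rbind, rows)
  groups <- split(long, list(long$microbe, long$go_term), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(gdf) data.frame(
    microbe = gdf$microbe[1], go_term = gdf$go_term[1],
    n_host_genes = length(unique(gdf$host_gene)),
    mean_rho = mean(gdf$rho), stringsAsFactors = FALSE)))
  out <- out[order(out$microbe, out$go_term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
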