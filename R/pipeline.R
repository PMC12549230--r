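# End-to-end orchestration: diversity -> differential abundance per layer
# -> preprocessing -> sparse CCA integrations -> per-group association
# networks with hubs. Every stochastic stage draws its seed from the
# config, so a rerun with the same inputs and config reproduces all
# outputs bit for bit.

.object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

# differential features of one layer across all reference comparisons;
# falls back to the full feature set when too few reach significance
# (small synthetic runs), logging the fallback
.select_differential <- function(table, design, ref, others, alpha,
                                 layer) {
  res <- list()
  sel <- character(0)
  for (g in others) {
    dr <- differential_features(table, design, ref, g, alpha = alpha)
    res[[paste0(ref, "_vs_", g)]] <- dr
    sel <- union(sel, dr$feature_id[dr$significant])
  }
  if (length(sel) < 3) {
    mb_log("layer %s: only %d significant feature(s); using all %d",
           layer, length(sel), length(table$feature_ids))
    sel <- table$feature_ids
  }
  list(results = res, selected = sel)
}

#' Run the full integration pipeline
#'
#' Executes, in order: alpha/beta diversity with ANOSIM on the taxon
#' table; Wilcoxon/BH differential features per layer (reference group
#' versus every other group); preprocessing (taxon-specific scaling of
#' the gene layer, sparsity filtering, log2 transform of the amplicon
#' layer); two sparse CCA integrations (taxa x host and, when a gene
#' table is given, microbial genes x host) with permutation significance
#' and leave-one-out feature extraction; and per-group Spearman
#' association networks over the differential features, with community
#' clusters, centralities and hub calls. All artifacts are written under
#' `output_dir` together with a JSON run manifest.
#'
#' @param taxa count `feature_table` of microbial taxa (16S layer).
#' @param host `feature_table` of normalized host gene expression.
#' @param design a [group_design()]; its first-sorted group label is taken
#'   as reference unless `reference` is given.
#' @param genes optional RPK `feature_table` of per-organism microbial
#'   genes (`"gene|taxon"` ids or `feature_meta$taxon`).
#' @param config a [pipeline_config()].
#' @param output_dir directory for artifacts (created if needed).
#' @param reference reference group label (default: first by sort order).
#' @param go_annotation optional data.frame (`gene_id`, `go_term`) enabling
#'   the gene-family association table on the reference-group network.
#' @param scca_k components per integration (default `min(n - 1, 10)`).
#' @return the run manifest (list, also written to `manifest.json`):
#'   config snapshot, input hashes, seed, stage timings, output paths and
#'   package version.
#' @export
run_pipeline <- function(taxa, host, design, genes = NULL,
                         config = pipeline_config(),
                         output_dir = tempfile("mbcca_run_"),
                         reference = NULL, go_annotation = NULL,
                         scca_k = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stopifnot(inherits(taxa, "feature_table"), inherits(host, "feature_table"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  groups <- sort(unique(unclass(design)))
  if (length(groups) < 2) stop(">= 2 groups required", call. = FALSE)
  ref <- if (is.null(reference)) groups[1] else reference
  if (!ref %in% groups) stop("reference group not in design", call. = FALSE)
  others <- setdiff(groups, ref)
  samples <- taxa$sample_ids
  if (!setequal(samples, host$sample_ids))
    stop("taxa and host tables must cover the same samples", call. = FALSE)
  host <- ft_subset(host, samples = samples)
  if (!is.null(genes)) genes <- ft_subset(genes, samples = samples)
  n <- length(samples)
  if (is.null(scca_k)) scca_k <- min(n - 1, 10)
  outputs <- character(0)
  timings <- list()
  out <- function(name) {
    p <- file.path(output_dir, name)
    outputs <<- c(outputs, p)
    p
  }
  clock <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- .stage(name, expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  div <- clock("diversity", {
    alpha_tab <- alpha_diversity(taxa)
    bc <- bray_curtis(taxa)
    ord <- pcoa(bc, k = min(2, n - 1))
    an <- anosim(bc, design, n_perm = config$n_permutations,
                 seed = config$seed)
    write_results_table(alpha_tab, out("alpha_diversity.tsv"))
    utils::write.table(bc$matrix, out("bray_curtis.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    utils::write.table(
      data.frame(sample_id = rownames(ord$coordinates), ord$coordinates),
      out("pcoa.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(R = an$statistic, p = an$p,
           n_permutations = an$n_permutations),
      out("anosim.json"), auto_unbox = TRUE, digits = NA)
    list(anosim = an)
  })

  genes_scaled <- if (!is.null(genes))
    clock("taxon_scale", taxon_scale(genes)) else NULL

  diff <- clock("differential", {
    layers <- list(taxa = taxa, host = host)
    if (!is.null(genes_scaled)) layers$genes <- genes_scaled
    sel <- lapply(names(layers), function(ly)
      .select_differential(layers[[ly]], design, ref, others,
                           config$alpha, ly))
    names(sel) <- names(layers)
    for (ly in names(sel))
      for (cmp in names(sel[[ly]]$results))
        write_results_table(sel[[ly]]$results[[cmp]],
                            out(sprintf("diff_%s_%s.tsv", ly, cmp)))
    sel
  })

  prep <- clock("preprocess", {
    taxa_sel <- filter_sparse_variables(
      ft_subset(taxa, features = diff$taxa$selected))
    taxa_cca <- log2_transform(taxa_sel, pseudocount = config$pseudocount)
    host_cca <- filter_sparse_variables(
      ft_subset(host, features = diff$host$selected))
    genes_cca <- if (!is.null(genes_scaled))
      filter_sparse_variables(
        ft_subset(genes_scaled, features = diff$genes$selected)) else NULL
    list(taxa = taxa_cca, host = host_cca, genes = genes_cca)
  })

  run_scca <- function(xtab, ytab, label) {
    k <- min(scca_k, length(xtab$feature_ids), length(ytab$feature_ids))
    fit <- scca(xtab, ytab, k = k,
                grid = penalty_grid(config$penalty_lo, config$penalty_hi,
                                    config$penalty_n))
    fit <- scca_significance(fit, n_perm = config$n_permutations,
                             seed = config$seed)
    fit <- scca_loocv(fit, retention = config$loocv_retention)
    utils::write.table(fit$u, out(sprintf("scca_%s_weights_x.tsv", label)),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(fit$v, out(sprintf("scca_%s_weights_y.tsv", label)),
                       sep = "\t", quote = FALSE, col.names = NA)
    jsonlite::write_json(
      list(penalty_x = fit$penalty_x, penalty_y = fit$penalty_y,
           correlations = fit$cors,
           significance = fit$significance,
           tuning = fit$tuning_table,
           robust_x = lapply(fit$loocv$components, `[[`, "robust_x"),
           robust_y = lapply(fit$loocv$components, `[[`, "robust_y")),
      out(sprintf("scca_%s.json", label)), auto_unbox = TRUE, digits = NA)
    fit
  }
  scca_taxa <- clock("scca_host_taxa",
                     run_scca(prep$host, prep$taxa, "host_taxa"))
  scca_genes <- if (!is.null(prep$genes))
    clock("scca_host_genes", run_scca(prep$host, prep$genes, "host_genes"))
  else NULL

  nets <- clock("networks", {
    feats <- list(host = diff$host$selected, taxa = diff$taxa$selected)
    if (!is.null(genes_scaled)) feats$genes <- diff$genes$selected
    layer_of <- c(stats::setNames(rep("host_gene", length(feats$host)),
                                  feats$host),
                  stats::setNames(rep("microbial_taxon", length(feats$taxa)),
                                  feats$taxa))
    if (!is.null(feats$genes))
      layer_of <- c(layer_of,
                    stats::setNames(rep("microbial_gene",
                                        length(feats$genes)), feats$genes))
    per_group <- list()
    for (g in groups) {
      gs <- design_samples(design, g)
      if (length(gs) < 4) {
        mb_log("group %s has %d sample(s); skipping network", g, length(gs))
        next
      }
      mats <- list(ft_subset(host, gs, feats$host)$values,
                   ft_subset(taxa, gs, feats$taxa)$values)
      if (!is.null(feats$genes))
        mats <- c(mats, list(ft_subset(genes_scaled, gs,
                                       feats$genes)$values))
      combined <- feature_table(do.call(cbind, mats),
                                value_kind = "normalized")
      edges <- spearman_edges(combined, p_max = config$alpha,
                              rho_min = config$rho_min)
      node_ids <- unique(c(edges$feature_a, edges$feature_b))
      nm <- data.frame(layer = unname(layer_of[node_ids]),
                       row.names = node_ids,
                       stringsAsFactors = FALSE)
      if (!is.null(genes) && !is.null(genes$feature_meta) &&
          "is_aars" %in% names(genes$feature_meta)) {
        nm$is_aars <- FALSE
        hit <- intersect(node_ids, genes$feature_ids)
        nm[hit, "is_aars"] <- as.logical(
          genes$feature_meta[hit, "is_aars"])
        nm$taxon <- NA_character_
        nm[hit, "taxon"] <-
          if ("taxon" %in% names(genes$feature_meta))
            as.character(genes$feature_meta[hit, "taxon"])
          else split_taxon_labels(hit)
      }
      net <- build_network(edges, node_meta = nm)
      cent <- centrality_metrics(net)
      clus <- if (net$properties$n_edges > 0)
        community_clusters(net, seed = config$seed) else NULL
      hubs <- if (nrow(cent) > 0)
        identify_hubs(cent, quantile = config$hub_quantile,
                      min_degree = config$hub_min_degree,
                      clusters = if (!is.null(clus)) clus$labels)
      else NULL
      export_network(net, out(sprintf("network_%s.graphml", g)),
                     "graphml", centrality = cent,
                     clusters = if (!is.null(clus)) clus$labels)
      if (!is.null(hubs))
        write_results_table(hubs, out(sprintf("hubs_%s.tsv", g)))
      jsonlite::write_json(
        c(net$properties,
          list(n_clusters = if (!is.null(clus)) clus$n_clusters else 0,
               modularity = if (!is.null(clus)) clus$modularity else NA)),
        out(sprintf("network_%s.json", g)), auto_unbox = TRUE, digits = NA)
      per_group[[g]] <- list(network = net, centrality = cent,
                             clusters = clus, hubs = hubs)
    }
    per_group
  })

  assoc <- NULL
  if (!is.null(go_annotation) && !is.null(nets[[ref]])) {
    assoc <- clock("gene_family_associations", {
      tab <- extract_gene_family_associations(nets[[ref]]$network,
                                              go_annotation)
      write_results_table(tab, out("aars_associations.tsv"))
      tab
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mbcca")),
    config = unclass(config),
    seed = config$seed,
    reference_group = ref,
    input_hashes = list(
      taxa = .object_md5(taxa), host = .object_md5(host),
      genes = if (!is.null(genes)) .object_md5(genes)),
    stage_timings_s = timings,
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(manifest,
              list(results = list(diversity = div, differential = diff,
                                  scca_host_taxa = scca_taxa,
                                  scca_host_genes = scca_genes,
                                  networks = nets, associations = assoc),
                   output_dir = output_dir)))
}
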