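#' Two-sample Wilcoxon rank-sum test
#'
#' Thin, contract-enforcing wrapper around [stats::wilcox.test()]: the
#' two-sided p-value is exact (full enumeration of rank assignments) when
#' the pooled sample size is at most 12 and there are no ties, and
#' otherwise uses the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with `statistic` (Mann-Whitney U for the first sample) and
#'   `p` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs >= 2 observations", call. = FALSE)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1)  # fully tied: no evidence either way
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && (length(x) + length(y)) <= 12
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  p <- ht$p.value
  if (!is.finite(p)) p <- 1  # zero-variance rank configuration
  list(statistic = unname(ht$statistic), p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")`:
#' `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1, returned in input
#' order. Adjusted values are never below the raw values.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Per-feature differential abundance between two groups
#'
#' Runs [wilcoxon_rank_sum()] on every feature and applies one BH family
#' across all tested features of the table (one family per comparison per
#' data layer). Direction is the sign of the group-median difference,
#' `median(group_b) - median(group_a)`: `"up"` means higher in `group_b`.
#'
#' @param table a `feature_table`.
#' @param design a [group_design()] covering the table's samples.
#' @param group_a,group_b group labels to compare (each >= 2 samples).
#' @param alpha BH-adjusted significance level.
#' @return data.frame of class `diff_result`, one row per feature:
#'   `feature_id`, `statistic`, `p`, `q`, `direction` (`"up"`, `"down"` or
#'   `NA` when the medians are equal), `significant` (q < alpha).
#' @export
differential_features <- function(table, design, group_a, group_b,
                                  alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  check_two_groups(design, group_a, group_b)
  sa <- intersect(table$sample_ids, design_samples(design, group_a))
  sb <- intersect(table$sample_ids, design_samples(design, group_b))
  if (length(sa) < 2 || length(sb) < 2)
    stop("both groups need >= 2 samples present in the table", call. = FALSE)
  va <- table$values[sa, , drop = FALSE]
  vb <- table$values[sb, , drop = FALSE]
  m <- length(table$feature_ids)
  stat <- p <- med_diff <- numeric(m)
  for (j in seq_len(m)) {
    w <- wilcoxon_rank_sum(va[, j], vb[, j])
    stat[j] <- w$statistic
    p[j] <- w$p
    med_diff[j] <- stats::median(vb[, j]) - stats::median(va[, j])
  }
  q <- bh_adjust(p)
  direction <- ifelse(med_diff > 0, "up", ifelse(med_diff < 0, "down", NA))
  out <- data.frame(feature_id = table$feature_ids, statistic = stat,
                    p = p, q = q, direction = direction,
                    significant = q < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "comparison") <- c(group_a = group_a, group_b = group_b)
  attr(out, "alpha") <- alpha
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Taxon-specific scaling of per-organism gene abundances
#'
#' Renormalizes each organism's gene abundances within each sample so that
#' expression is read relative to that organism's total transcriptional
#' activity: `scaled(g) = value(g) / sum(values of the taxon in that
#' sample) * constant`. A taxon contributing nothing to a sample yields
#' zeros there. Scaling a taxon's raw values by any per-sample factor
#' leaves the output unchanged by construction.
#'
#' @param table a `feature_table` of RPK-scale gene values; taxon labels
#'   come from `feature_meta$taxon` or, failing that, from composite
#'   `"gene|taxon"` feature ids via [split_taxon_labels()].
#' @param constant within-taxon total after scaling (default 1e6, a
#'   within-organism counts-per-million analogue).
#' @return a `feature_table` (value_kind `"normalized"`) with the taxon
#'   labels recorded in `feature_meta`.
#' @export
taxon_scale <- function(table, constant = 1e6) {
  stopifnot(inherits(table, "feature_table"))
  if (constant <= 0) stop("constant must be positive", call. = FALSE)
  taxa <- if (!is.null(table$feature_meta) &&
              "taxon" %in% names(table$feature_meta))
    as.character(table$feature_meta$taxon)
  else split_taxon_labels(table$feature_ids)
  if (anyNA(taxa) || any(taxa == ""))
    stop("every feature needs a taxon label (feature_meta$taxon or 'gene|taxon' id)",
         call. = FALSE)
  if (any(table$values < 0))
    stop("taxon_scale requires non-negative values", call. = FALSE)
  v <- table$values
  out <- v
  for (tx in unique(taxa)) {
    cols <- which(taxa == tx)
    totals <- rowSums(v[, cols, drop = FALSE])
    scale <- ifelse(totals > 0, constant / totals, 0)
    out[, cols] <- v[, cols, drop = FALSE] * scale
  }
  fm <- if (is.null(table$feature_meta))
    data.frame(taxon = taxa, row.names = table$feature_ids)
  else {
    fm <- table$feature_meta
    fm$taxon <- taxa
    fm
  }
  feature_table(out, sample_meta = table$sample_meta, feature_meta = fm,
                value_kind = "normalized")
}

#' Log2 transformation with pseudocount
#'
#' `log2(x + pseudocount)` element-wise; used to stabilise amplicon-scale
#' values that pile up near zero before canonical correlation.
#'
#' @param table a `feature_table` with non-negative values.
#' @param pseudocount positive offset (default 1, so zero maps to zero).
#' @return a `feature_table` with value_kind `"log2"`.
#' @export
log2_transform <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
  if (any(table$values < 0))
    stop("log2_transform requires non-negative values", call. = FALSE)
  feature_table(log2(table$values + pseudocount),
                sample_meta = table$sample_meta,
                feature_meta = table$feature_meta, value_kind = "log2")
}

#' Drop features observed in at most one sample
#'
#' Removes variables with a nonzero value in no more than one sample —
#' such features cannot support correlation estimates and only add noise
#' to sparse CCA. Dropped ids are logged to stderr.
#'
#' @param table a `feature_table`.
#' @return the filtered `feature_table`.
#' @export
filter_sparse_variables <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  prevalence <- colSums(table$values != 0)
  drop <- table$feature_ids[prevalence <= 1]
  if (length(drop) > 0)
    mb_log("filter_sparse_variables: dropping %d feature(s): %s",
           length(drop), paste(utils::head(drop, 10), collapse = ", "))
  keep <- setdiff(table$feature_ids, drop)
  if (length(keep) == 0) stop("no features left after sparsity filter",
                              call. = FALSE)
  ft_subset(table, features = keep)
}

#' Classify DEGs into the six two-comparison expression modules
#'
#' Given up- and down-regulated gene sets from the day-3 and day-6
#' comparisons against control, assigns each gene to one of six modules:
#' 1 = up on day 3 only, 2 = up in both comparisons, 3 = up on day 6 only,
#' 4 = down on day 3 only, 5 = down in both, 6 = down on day 6 only.
#' Genes up in one comparison and down in the other fall outside the six
#' definitions and receive the explicit label `"discordant"` so that the
#' output remains a partition of the input genes.
#'
#' @param up_day3,up_day6,down_day3,down_day6 character vectors of gene
#'   ids; the up and down sets of the same day must be disjoint.
#' @return data.frame of class `module_assignment`: `gene_id`, `module`
#'   (factor with levels `"1"`..`"6"`, `"discordant"`); each input gene
#'   appears exactly once.
#' @export
classify_deg_modules <- function(up_day3, up_day6, down_day3, down_day6) {
  up_day3 <- unique(as.character(up_day3))
  up_day6 <- unique(as.character(up_day6))
  down_day3 <- unique(as.character(down_day3))
  down_day6 <- unique(as.character(down_day6))
  clash3 <- intersect(up_day3, down_day3)
  if (length(clash3) > 0)
    stop("gene(s) both up- and down-regulated on day 3: ",
         paste(utils::head(clash3, 5), collapse = ", "), call. = FALSE)
  clash6 <- intersect(up_day6, down_day6)
  if (length(clash6) > 0)
    stop("gene(s) both up- and down-regulated on day 6: ",
         paste(utils::head(clash6, 5), collapse = ", "), call. = FALSE)
  discordant <- union(intersect(up_day3, down_day6),
                      intersect(down_day3, up_day6))
  assign_one <- function(g) {
    if (g %in% discordant) return("discordant")
    u3 <- g %in% up_day3; u6 <- g %in% up_day6
    d3 <- g %in% down_day3; d6 <- g %in% down_day6
    if (u3 && u6) "2" else if (u3) "1" else if (u6) "3"
    else if (d3 && d6) "5" else if (d3) "4" else "6"
  }
  genes <- sort(unique(c(up_day3, up_day6, down_day3, down_day6)))
  module <- vapply(genes, assign_one, character(1))
  out <- data.frame(gene_id = genes,
                    module = factor(module,
                                    levels = c(as.character(1:6), "discordant")),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("module_assignment", "data.frame")
  out
}
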