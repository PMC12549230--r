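#' Shannon diversity index
#'
#' `H = -sum p_i log(p_i)` over the strictly positive proportions of the
#' count vector. Natural log by default; `base` switches (e.g. `base = 2`
#' for bits).
#'
#' @param counts non-negative numeric vector with at least one positive
#'   entry.
#' @param base logarithm base.
#' @return the Shannon index (0 for a single-species community).
#' @export
shannon <- function(counts, base = exp(1)) {
  p <- .proportions(counts)
  -sum(p * log(p, base = base))
}

#' Simpson-family diversity indices
#'
#' With concentration `D = sum p_i^2`, the Gini-Simpson index is `1 - D`
#' and the inverse Simpson index `1 / D`.
#'
#' @param counts non-negative numeric vector with at least one positive
#'   entry.
#' @param variant `"gini_simpson"` or `"inverse_simpson"`.
#' @return the requested index.
#' @export
simpson_family <- function(counts,
                           variant = c("gini_simpson", "inverse_simpson")) {
  variant <- match.arg(variant)
  d <- sum(.proportions(counts)^2)
  if (variant == "gini_simpson") 1 - d else 1 / d
}

.proportions <- function(counts) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts) | counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("all-zero count vector", call. = FALSE)
  counts[counts > 0] / total
}

#' Chao1 richness estimator (bias-corrected)
#'
#' `S_chao1 = S_obs + F1 (F1 - 1) / (2 (F2 + 1))` where `F1` and `F2` are
#' the singleton and doubleton counts. The +1 in the denominator makes the
#' estimator well-defined when no doubletons are observed; with no
#' singletons it reduces to the observed richness.
#'
#' @param counts non-negative integer vector.
#' @return the estimated richness (>= [observed_species()]).
#' @export
chao1 <- function(counts) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts) | counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (any(counts != round(counts)))
    stop("chao1 requires integer counts (singletons/doubletons undefined otherwise)",
         call. = FALSE)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Observed species richness
#'
#' @param counts non-negative numeric vector.
#' @return number of strictly positive entries.
#' @export
observed_species <- function(counts) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts) | counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  sum(counts > 0)
}

#' Per-sample alpha-diversity table
#'
#' @param table a `feature_table` of counts.
#' @return data.frame with one row per sample: `shannon`, `gini_simpson`,
#'   `inverse_simpson`, `chao1`, `observed_species`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  is_int <- all(v == round(v))
  data.frame(
    sample_id = table$sample_ids,
    shannon = apply(v, 1, shannon),
    gini_simpson = apply(v, 1, simpson_family, variant = "gini_simpson"),
    inverse_simpson = apply(v, 1, simpson_family, variant = "inverse_simpson"),
    chao1 = if (is_int) apply(v, 1, chao1) else NA_real_,
    observed_species = apply(v, 1, observed_species),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(u, v) = sum |u_i - v_i| / sum (u_i + v_i)`. A pair of all-zero
#' samples, for which the quotient is 0/0, is defined to have distance 0.
#'
#' @param table a `feature_table` with >= 2 samples.
#' @return an object of class `distance_matrix`: list with `sample_ids` and
#'   the symmetric zero-diagonal `matrix` with entries in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  if (nrow(v) < 2) stop(">= 2 samples required", call. = FALSE)
  if (any(v < 0)) stop("Bray-Curtis requires non-negative values", call. = FALSE)
  n <- nrow(v)
  d <- matrix(0, n, n, dimnames = list(table$sample_ids, table$sample_ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- sum(v[i, ] + v[j, ])
      d[i, j] <- d[j, i] <- if (denom == 0) 0 else sum(abs(v[i, ] - v[j, ])) / denom
    }
  }
  distance_matrix(d, table$sample_ids)
}

#' Construct (and validate) a distance matrix object
#'
#' @param m symmetric numeric matrix with zero diagonal.
#' @param sample_ids ids for rows/columns (defaults to rownames).
#' @export
distance_matrix <- function(m, sample_ids = rownames(m)) {
  m <- as.matrix(m)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(m)))
  if (nrow(m) != ncol(m)) stop("distance matrix must be square", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix must be symmetric",
                                       call. = FALSE)
  if (any(abs(diag(m)) > 1e-12)) stop("diagonal must be zero", call. = FALSE)
  if (any(m < 0)) stop("distances must be non-negative", call. = FALSE)
  dimnames(m) <- list(sample_ids, sample_ids)
  structure(list(sample_ids = as.character(sample_ids), matrix = m),
            class = "distance_matrix")
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Eigen-decomposition of the double-centred `-d^2/2` matrix via
#' [stats::cmdscale()]. Coordinates are scaled by the square roots of the
#' positive eigenvalues; negative eigenvalues (possible for non-Euclidean
#' dissimilarities such as Bray-Curtis) are retained in the eigenvalue
#' report but contribute no coordinate axes.
#'
#' @param dist a `distance_matrix`.
#' @param k number of axes to return (`<= n - 1`).
#' @return list of class `ordination`: `coordinates` (n x k', where
#'   k' <= k is limited by the number of positive eigenvalues),
#'   `eigenvalues` (all n, descending), `proportion_explained` (share of the
#'   positive-eigenvalue total, one per returned axis).
#' @export
pcoa <- function(dist, k = 2) {
  stopifnot(inherits(dist, "distance_matrix"))
  n <- length(dist$sample_ids)
  if (k > n - 1) stop("k must be <= n - 1", call. = FALSE)
  if (all(dist$matrix == 0)) {
    coords <- matrix(0, n, k, dimnames = list(dist$sample_ids, paste0("Axis", seq_len(k))))
    return(structure(list(coordinates = coords,
                          eigenvalues = rep(0, n),
                          proportion_explained = rep(0, k)),
                     class = "ordination"))
  }
  fit <- stats::cmdscale(stats::as.dist(dist$matrix), k = k, eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  coords <- fit$points
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  rownames(coords) <- dist$sample_ids
  pos_total <- sum(eig[eig > 0])
  prop <- if (pos_total > 0)
    pmax(eig[seq_len(ncol(coords))], 0) / pos_total else rep(0, ncol(coords))
  structure(list(coordinates = coords, eigenvalues = eig,
                 proportion_explained = prop),
            class = "ordination")
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of between- versus within-group
#' dissimilarity: with ranks over all pairwise distances,
#' `R = (mean_between - mean_within) / (M / 2)`, `M = n (n - 1) / 2`.
#' Significance by permuting group labels; the add-one estimator
#' `p = (1 + #(R_perm >= R_obs)) / (n_perm + 1)` is used.
#'
#' @param dist a `distance_matrix`.
#' @param design a [group_design()]; >= 2 groups with >= 2 samples each
#'   among the samples present in `dist`.
#' @param n_perm number of label permutations (>= 1).
#' @param seed integer seed for the permutation draw.
#' @return list of class `anosim_result`: `statistic` (R in [-1, 1]), `p`,
#'   `n_permutations`, `seed`.
#' @export
anosim <- function(dist, design, n_perm = 999, seed = 1) {
  stopifnot(inherits(dist, "distance_matrix"))
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  ids <- dist$sample_ids
  g <- unclass(design)[ids]
  if (anyNA(g)) stop("design missing groups for some samples", call. = FALSE)
  tab <- table(g)
  if (length(tab) < 2) stop(">= 2 groups required", call. = FALSE)
  if (any(tab < 2)) stop("every group needs >= 2 samples", call. = FALSE)
  d <- dist$matrix
  n <- length(ids)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  r <- rank(d[upper.tri(d)])  # average ranks for ties
  m <- n * (n - 1) / 2
  stat_for <- function(gg) {
    within <- gg[idx[, 1]] == gg[idx[, 2]]
    (mean(r[!within]) - mean(r[within])) / (m / 2)
  }
  observed <- stat_for(g)
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm))
      if (stat_for(sample(g)) >= observed) exceed <- exceed + 1L
    structure(list(statistic = observed,
                   p = (1 + exceed) / (n_perm + 1),
                   n_permutations = as.integer(n_perm),
                   seed = as.integer(seed)),
              class = "anosim_result")
  })
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.3f, p = %.4g (%d permutations)\n",
              x$statistic, x$p, x$n_permutations))
  invisible(x)
}

#' Pairwise ANOSIM between all group pairs
#'
#' The omnibus test does not say which groups differ; this runs [anosim()]
#' on every pair of groups and reports raw and BH-adjusted p-values.
#'
#' @inheritParams anosim
#' @return data.frame with `group_a`, `group_b`, `statistic`, `p`, `q`.
#' @export
anosim_pairwise <- function(dist, design, n_perm = 999, seed = 1) {
  g <- unclass(design)[dist$sample_ids]
  groups <- sort(unique(g))
  pairs <- utils::combn(groups, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    keep <- dist$sample_ids[g %in% pairs[, i]]
    sub <- distance_matrix(dist$matrix[keep, keep, drop = FALSE], keep)
    a <- anosim(sub, design, n_perm = n_perm, seed = seed + i)
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               statistic = a$statistic, p = a$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}
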