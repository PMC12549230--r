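# Synthetic data with known ground truth. All generators are pure functions
# of their arguments including `seed`: the global RNG state is saved and
# restored around every call.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# sparse unit-norm loading matrix (p x k); equal-magnitude entries, random
# signs; supports disjoint across components while features remain.
.sparse_loadings <- function(p, k, nonzeros) {
  a <- matrix(0, p, k)
  pool <- seq_len(p)
  for (j in seq_len(k)) {
    if (length(pool) >= nonzeros) {
      supp <- sample(pool, nonzeros)
      pool <- setdiff(pool, supp)
    } else supp <- sample(seq_len(p), nonzeros)
    a[supp, j] <- sample(c(-1, 1), nonzeros, replace = TRUE) / sqrt(nonzeros)
  }
  a
}

#' Simulate paired omics tables sharing sparse latent components
#'
#' Generates two matrices `X` (n x p_x) and `Y` (n x p_y) driven by `k`
#' shared standard-normal latent score vectors through sparse unit-norm
#' loading columns, plus i.i.d. Gaussian noise:
#' `X = Z G_x A' + E_x`, `Y = Z G_y B' + E_y`. The per-component signal
#' scale `G` is chosen so that the population correlation between the true
#' projections `X a_k` and `Y b_k` equals `correlation_strengths[k]`; with
#' `noise_sd = 0` the projections are exactly collinear.
#'
#' @param n samples (>= 4).
#' @param p_x,p_y feature counts per side.
#' @param k number of latent components, `k <= min(p_x, p_y)`.
#' @param nonzeros_per_component nonzero loadings per component (>= 1);
#'   supports are drawn disjoint across components while features last.
#' @param correlation_strengths length-`k` vector in (0, 1]; values of 1
#'   require `noise_sd = 0`.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed; identical seeds give bitwise identical output.
#' @return list with `feature_table`s `x` and `y` (value_kind
#'   `"normalized"`) and `truth` (class `paired_omics_truth`) holding
#'   `loadings_x`, `loadings_y`, `latent_scores`, `planted_correlations`,
#'   `support_x`/`support_y` (feature ids per component), `noise_sd`, `seed`.
#' @export
simulate_paired_omics <- function(n, p_x, p_y, k = 1,
                                  nonzeros_per_component = 5,
                                  correlation_strengths = rep(0.9, k),
                                  noise_sd = 1, seed = 1) {
  if (n < 4) stop("n must be >= 4", call. = FALSE)
  if (k > min(p_x, p_y)) stop("k must be <= min(p_x, p_y)", call. = FALSE)
  if (nonzeros_per_component < 1) stop("nonzeros must be >= 1", call. = FALSE)
  if (length(correlation_strengths) != k)
    stop("correlation_strengths must have length k", call. = FALSE)
  if (any(correlation_strengths <= 0 | correlation_strengths > 1))
    stop("correlation strengths must lie in (0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (noise_sd > 0 && any(correlation_strengths >= 1))
    stop("strength 1 is attainable only with noise_sd = 0", call. = FALSE)
  with_seed(seed, {
    a <- .sparse_loadings(p_x, k, nonzeros_per_component)
    b <- .sparse_loadings(p_y, k, nonzeros_per_component)
    z <- matrix(stats::rnorm(n * k), n, k)
    # corr(Xa, Yb) = g^2 / (g^2 + sd^2) for symmetric scale g per side
    g <- if (noise_sd == 0) rep(1, k)
         else noise_sd * sqrt(correlation_strengths / (1 - correlation_strengths))
    x <- z %*% (t(a) * g) + noise_sd * matrix(stats::rnorm(n * p_x), n, p_x)
    y <- z %*% (t(b) * g) + noise_sd * matrix(stats::rnorm(n * p_y), n, p_y)
    sample_ids <- sprintf("S%03d", seq_len(n))
    fx <- paste0("hostgene_", seq_len(p_x))
    fy <- paste0("microbe_", seq_len(p_y))
    dimnames(x) <- list(sample_ids, fx)
    dimnames(y) <- list(sample_ids, fy)
    truth <- structure(
      list(loadings_x = a, loadings_y = b, latent_scores = z,
           planted_correlations = correlation_strengths,
           support_x = lapply(seq_len(k), function(j) fx[a[, j] != 0]),
           support_y = lapply(seq_len(k), function(j) fy[b[, j] != 0]),
           noise_sd = noise_sd, seed = seed),
      class = "paired_omics_truth")
    list(x = feature_table(x, value_kind = "normalized"),
         y = feature_table(y, value_kind = "normalized"),
         truth = truth)
  })
}

#' Simulate a grouped count table with planted fold changes
#'
#' Counts follow a log-normal/Poisson hierarchy: each feature has a
#' log-normal baseline mean, each sample draws a log-normal rate around its
#' group mean, and counts are Poisson around the rate. `n_diff` planted
#' features have their non-reference group means multiplied by
#' `2^(+/- log2_effect)` (random sign per feature); the reference group is
#' the first name of `n_per_group`.
#'
#' @param n_per_group named integer vector, group label -> sample count;
#'   every group needs >= 2 samples.
#' @param n_features total features.
#' @param n_diff number of planted differential features (<= n_features).
#' @param log2_effect absolute planted log2 fold change.
#' @param baseline_log_mean,baseline_log_sd log-scale mean/sd of feature
#'   baselines (defaults give median counts near 100).
#' @param dispersion log-scale sd of per-sample rate noise.
#' @param seed integer seed.
#' @return list with `table` (a count `feature_table` whose `sample_meta`
#'   carries `group`), `design` (a [group_design()]) and `truth` (class
#'   `count_truth`: `diff_feature_ids`, per-feature `log2_fc`, baseline
#'   parameters, `dispersion`, `seed`).
#' @export
simulate_count_table <- function(n_per_group = c(control = 5L, dss3 = 5L,
                                                 dss6 = 5L),
                                 n_features = 100, n_diff = 10,
                                 log2_effect = 2,
                                 baseline_log_mean = log(100),
                                 baseline_log_sd = 1,
                                 dispersion = 0.5, seed = 1) {
  if (is.null(names(n_per_group)) || any(names(n_per_group) == ""))
    stop("n_per_group must be a named vector", call. = FALSE)
  if (any(n_per_group < 2))
    stop("every group needs >= 2 samples", call. = FALSE)
  if (n_diff > n_features) stop("n_diff must be <= n_features", call. = FALSE)
  if (!is.finite(log2_effect)) stop("log2_effect must be finite", call. = FALSE)
  with_seed(seed, {
    groups <- rep(names(n_per_group), times = n_per_group)
    n <- length(groups)
    sample_ids <- unlist(lapply(names(n_per_group), function(g)
      sprintf("%s_%02d", g, seq_len(n_per_group[[g]]))))
    feature_ids <- sprintf("taxon_%03d", seq_len(n_features))
    diff_idx <- if (n_diff > 0) sort(sample(seq_len(n_features), n_diff))
                else integer(0)
    lfc <- numeric(n_features)
    if (n_diff > 0)
      lfc[diff_idx] <- sample(c(-1, 1), n_diff, replace = TRUE) * log2_effect
    mu <- stats::rnorm(n_features, baseline_log_mean, baseline_log_sd)
    ref <- names(n_per_group)[1]
    shift <- outer(as.numeric(groups != ref), lfc * log(2))
    log_rate <- matrix(mu, n, n_features, byrow = TRUE) + shift +
      matrix(stats::rnorm(n * n_features, 0, dispersion), n, n_features)
    counts <- matrix(stats::rpois(n * n_features, exp(log_rate)),
                     n, n_features, dimnames = list(sample_ids, feature_ids))
    design <- group_design(sample_ids, groups)
    truth <- structure(
      list(diff_feature_ids = feature_ids[diff_idx],
           log2_fc = stats::setNames(lfc, feature_ids),
           baseline_log_mean = baseline_log_mean,
           baseline_log_sd = baseline_log_sd,
           dispersion = dispersion, seed = seed),
      class = "count_truth")
    tab <- feature_table(counts,
                         sample_meta = data.frame(group = groups,
                                                  row.names = sample_ids),
                         value_kind = "count")
    list(table = tab, design = design, truth = truth)
  })
}

#' Simulate up/down DEG id sets covering the two-comparison Venn partition
#'
#' Emits disjoint synthetic gene ids populating exactly the requested
#' regions of the day-3 / day-6 up- and down-regulated Venn diagram, the
#' input shape consumed by [classify_deg_modules()].
#'
#' @param region_counts named non-negative integer vector over
#'   `up3_only`, `up_both`, `up6_only`, `down3_only`, `down_both`,
#'   `down6_only`, `discordant` (missing names default to 0; discordant
#'   genes are placed in up-day3 and down-day6).
#' @param seed integer seed (shuffles id assignment).
#' @return list of character vectors `up_day3`, `up_day6`, `down_day3`,
#'   `down_day6`.
#' @export
simulate_deg_sets <- function(region_counts, seed = 1) {
  regions <- c("up3_only", "up_both", "up6_only",
               "down3_only", "down_both", "down6_only", "discordant")
  counts <- stats::setNames(rep(0L, length(regions)), regions)
  if (length(region_counts) > 0) {
    unknown <- setdiff(names(region_counts), regions)
    if (length(unknown) > 0)
      stop("unknown regions: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    if (any(region_counts < 0)) stop("counts must be >= 0", call. = FALSE)
    counts[names(region_counts)] <- as.integer(region_counts)
  }
  total <- sum(counts)
  with_seed(seed, {
    ids <- sprintf("gene_%04d", if (total > 0) sample(9999, total) else integer(0))
    lab <- rep(regions, times = counts)
    pick <- function(r) ids[lab %in% r]
    list(up_day3   = pick(c("up3_only", "up_both", "discordant")),
         up_day6   = pick(c("up6_only", "up_both")),
         down_day3 = pick(c("down3_only", "down_both")),
         down_day6 = pick(c("down6_only", "down_both", "discordant")))
  })
}
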