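# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration, direct formula evaluation, and
# matrix dynamic programming.

# exact two-sided Wilcoxon p by full enumeration of group assignments
enum_wilcoxon_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  center <- m * n / 2
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
}

# exact two-sided Spearman p by enumeration of all rank permutations
enum_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- all_permutations(n)
  rho_all <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(ifelse(sub >= i, sub + 1, sub), nrow(sub)))))
}

# shortest-path distances and path counts from an adjacency matrix
shortest_path_counts <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n); diag(d) <- 0
  s <- diag(n)  # path counts; 1 trivial path to self
  d[a == 1] <- 1
  s[a == 1] <- 1
  reach <- a
  for (len in 2:max(2, n)) {
    reach_new <- (reach %*% a > 0) * 1
    cand <- reach_new == 1 & !is.finite(d)
    if (!any(cand)) break
    d[cand] <- len
    cnt <- s %*% a  # extends shortest paths of length len-1 by one edge
    s[cand] <- cnt[cand]
    reach <- (reach + reach_new > 0) * 1
  }
  list(d = d, sigma = s)
}

# unnormalized betweenness (each unordered pair once) by direct counting
brute_betweenness <- function(a) {
  n <- nrow(a)
  sp <- shortest_path_counts(a)
  d <- sp$d; sigma <- sp$sigma
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t])
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  b
}

brute_neighborhood_connectivity <- function(a) {
  deg <- rowSums(a)
  ifelse(deg > 0, as.vector(a %*% deg) / deg, 0)
}

# direct evaluation of Newman modularity for an unweighted partition
direct_modularity <- function(a, membership) {
  m2 <- sum(a)  # 2m
  if (m2 == 0) return(0)
  deg <- rowSums(a)
  same <- outer(membership, membership, "==")
  sum((a - outer(deg, deg) / m2) * same) / m2
}

# network object from an adjacency matrix, with dummy edge statistics
net_from_adjacency <- function(a, ids = NULL) {
  n <- nrow(a)
  if (is.null(ids)) ids <- paste0("n", seq_len(n))
  idx <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
  edges <- data.frame(feature_a = ids[idx[, 1]], feature_b = ids[idx[, 2]],
                      rho = rep(0.9, nrow(idx)), p = rep(0.01, nrow(idx)),
                      weight = rep(2, nrow(idx)),
                      stringsAsFactors = FALSE)
  meta <- data.frame(row.names = ids,
                     layer = rep("microbial_taxon", n),
                     stringsAsFactors = FALSE)
  build_network(edges, node_meta = meta, include_isolated = TRUE)
}

# small two-group table with complete between-group separation in
# distance: group A near 0, group B near a far offset
separated_distance_fixture <- function(n_per_group = 4) {
  vals <- rbind(matrix(abs(rnorm(n_per_group * 3, 5, 0.1)), n_per_group),
                matrix(abs(rnorm(n_per_group * 3, 50, 0.1)), n_per_group))
  ids <- sprintf("s%d", seq_len(2 * n_per_group))
  rownames(vals) <- ids
  colnames(vals) <- paste0("f", 1:3)
  list(dist = bray_curtis(feature_table(vals)),
       design = group_design(ids, rep(c("a", "b"), each = n_per_group)))
}
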