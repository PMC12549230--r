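test_that("alpha-diversity indices reproduce closed forms and hand cases", {
  expect_equal(shannon(c(5, 5, 5, 5)), log(4), tolerance = 1e-12)
  expect_equal(shannon(c(10, 0, 0)), 0)
  expect_equal(shannon(c(1, 2, 3)),
               -sum(c(1, 2, 3) / 6 * log(c(1, 2, 3) / 6)),
               tolerance = 1e-12)
  expect_equal(shannon(c(1, 2, 3)), 1.0114, tolerance = 1e-4)
  expect_equal(shannon(c(4, 4), base = 2), 1)
  expect_error(shannon(c(0, 0)), "all-zero")

  expect_equal(simpson_family(c(7, 0, 0), "gini_simpson"), 0)
  expect_equal(simpson_family(c(7, 0, 0), "inverse_simpson"), 1)
  expect_equal(simpson_family(rep(2, 4), "gini_simpson"), 0.75)
  expect_equal(simpson_family(rep(2, 4), "inverse_simpson"), 4)
  expect_equal(simpson_family(c(1, 2, 3), "gini_simpson"), 22 / 36)
  expect_equal(simpson_family(c(1, 2, 3), "inverse_simpson"), 36 / 14)

  # chao1: no singletons -> observed; F1=4, F2=2 on 10 species -> 12;
  # F1=3, F2=0 on 5 species -> 8 (the +1 guards the zero-doubleton case)
  expect_equal(chao1(c(5, 5, 3, 2, 2)), 5)
  expect_equal(chao1(c(1, 1, 1, 1, 2, 2, rep(5, 4))), 12)
  expect_equal(chao1(c(1, 1, 1, 5, 5)), 8)
  expect_error(chao1(c(1.5, 2)), "integer")

  expect_equal(observed_species(c(0, 0, 0)), 0)
  expect_equal(observed_species(c(1, 0, 2, 3)), 3)
  no_singletons <- c(3, 0, 2, 7)
  expect_equal(chao1(no_singletons), observed_species(no_singletons))
})

test_that("alpha indices agree with vegan on random communities", {
  skip_if_not_installed("vegan")
  set.seed(42)
  m <- matrix(rpois(60, 8), nrow = 4)
  expect_equal(apply(m, 1, shannon), unname(vegan::diversity(m, "shannon")),
               tolerance = 1e-12)
  expect_equal(apply(m, 1, simpson_family, variant = "gini_simpson"),
               unname(vegan::diversity(m, "simpson")), tolerance = 1e-12)
  expect_equal(apply(m, 1, chao1),
               unname(vegan::estimateR(m)["S.chao1", ]), tolerance = 1e-8)
})

test_that("Bray-Curtis matches hand cases, bounds, and vegan", {
  two <- function(u, v) {
    ft <- feature_table(rbind(s1 = u, s2 = v))
    bray_curtis(ft)$matrix[1, 2]
  }
  expect_equal(two(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(two(c(1, 2, 0), c(0, 0, 5)), 1)
  expect_equal(two(c(1, 2, 3), c(3, 2, 1)), 4 / 12)
  expect_equal(two(c(0, 0, 0), c(0, 0, 0)), 0)  # 0/0 pair defined as 0

  set.seed(9)
  m <- matrix(rpois(50, 6), nrow = 5,
              dimnames = list(paste0("s", 1:5), paste0("f", 1:10)))
  d <- bray_curtis(feature_table(m))$matrix
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  perm <- sample(10)
  d2 <- bray_curtis(feature_table(m[, perm]))$matrix
  expect_equal(d, d2)  # invariant to joint feature permutation
  skip_if_not_installed("vegan")
  expect_equal(d[lower.tri(d)],
               as.vector(vegan::vegdist(m, "bray")), tolerance = 1e-12)
})

test_that("PCoA preserves Euclidean configurations and orders eigenvalues", {
  pts <- c(0, 1, 3)
  d <- as.matrix(dist(pts))
  ord <- pcoa(distance_matrix(d), k = 2)
  rec <- as.matrix(dist(ord$coordinates[, 1]))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  expect_lte(sum(ord$proportion_explained), 1 + 1e-12)

  zero <- pcoa(distance_matrix(matrix(0, 4, 4)), k = 2)
  expect_true(all(zero$coordinates == 0))
  expect_error(pcoa(distance_matrix(matrix(0, 3, 3)), k = 3), "n - 1")
  expect_error(distance_matrix(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("ANOSIM reaches R = 1 under complete separation and matches vegan", {
  set.seed(31)
  fx <- separated_distance_fixture(4)
  res <- anosim(fx$dist, fx$design, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)
  expect_lte(res$p, 0.05)

  # statistic cross-check on unstructured data
  skip_if_not_installed("vegan")
  set.seed(32)
  m <- matrix(rpois(80, 10), nrow = 8,
              dimnames = list(paste0("s", 1:8), NULL))
  des <- group_design(paste0("s", 1:8), rep(c("a", "b"), each = 4))
  d <- bray_curtis(feature_table(m))
  ours <- anosim(d, des, n_perm = 9, seed = 1)$statistic
  vg <- vegan::anosim(as.dist(d$matrix), rep(c("a", "b"), each = 4),
                      permutations = 9)$statistic
  expect_equal(ours, unname(vg), tolerance = 1e-12)
})

test_that("ANOSIM R uses ranks only: invariant to monotone distance maps", {
  set.seed(33)
  m <- matrix(rpois(60, 10), nrow = 6,
              dimnames = list(paste0("s", 1:6), NULL))
  des <- group_design(paste0("s", 1:6), rep(c("a", "b"), each = 3))
  d <- bray_curtis(feature_table(m))
  r1 <- anosim(d, des, n_perm = 5, seed = 2)$statistic
  squared <- distance_matrix(d$matrix^2, d$sample_ids)
  r2 <- anosim(squared, des, n_perm = 5, seed = 2)$statistic
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("sampled permutation p agrees with exhaustive label enumeration", {
  set.seed(34)
  m <- matrix(rpois(36, 10), nrow = 6,
              dimnames = list(paste0("s", 1:6), NULL))
  ids <- paste0("s", 1:6)
  des <- group_design(ids, rep(c("a", "b"), each = 3))
  d <- bray_curtis(feature_table(m))
  # exhaustive null over all 20 assignments of 3 labels to 6 samples
  idx <- which(upper.tri(d$matrix), arr.ind = TRUE)
  r <- rank(d$matrix[upper.tri(d$matrix)])
  stat_for <- function(g) {
    within <- g[idx[, 1]] == g[idx[, 2]]
    (mean(r[!within]) - mean(r[within])) / (length(r) / 2)
  }
  obs <- stat_for(rep(c("a", "b"), each = 3))
  combos <- utils::combn(6, 3)
  null <- apply(combos, 2, function(s) {
    g <- rep("b", 6); g[s] <- "a"; stat_for(g)
  })
  p_exact <- mean(null >= obs - 1e-12)
  p_sampled <- anosim(d, des, n_perm = 4999, seed = 3)$p
  expect_lt(abs(p_sampled - p_exact), 0.03)
})

test_that("pairwise ANOSIM reports raw and BH-adjusted p per group pair", {
  set.seed(35)
  fx <- separated_distance_fixture(4)
  des3 <- group_design(c(names(unclass(fx$design)), paste0("t", 1:4)),
                       c(unclass(fx$design), rep("c", 4)))
  vals <- rbind(matrix(abs(rnorm(12, 5, 0.1)), 4),
                matrix(abs(rnorm(12, 50, 0.1)), 4),
                matrix(abs(rnorm(12, 20, 0.1)), 4))
  rownames(vals) <- names(unclass(des3))
  d <- bray_curtis(feature_table(vals))
  pw <- anosim_pairwise(d, des3, n_perm = 39, seed = 1)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$q >= pw$p))
})
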