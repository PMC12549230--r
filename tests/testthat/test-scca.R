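test_that("soft thresholding matches its closed form", {
  expect_equal(soft_threshold(c(3, -2, 0.5), 0), c(3, -2, 0.5))
  expect_equal(soft_threshold(0.5, 1), 0)
  expect_equal(soft_threshold(c(3, -2, 0.5), 1), c(2, -1, 0))
  expect_error(soft_threshold(1, -0.1), "delta")
})

test_that("L1 projection honours its budget and limiting cases", {
  set.seed(61)
  w <- rnorm(10)
  # c = sqrt(p): constraint inactive by Cauchy-Schwarz
  expect_equal(l1_project(w, sqrt(10)), w / sqrt(sum(w^2)), tolerance = 1e-12)
  # c = 1: single surviving coordinate, ties to the lowest index
  u <- l1_project(c(2, -3, 1), 1)
  expect_equal(u, c(0, -1, 0))
  u_tie <- l1_project(c(2, -2, 1), 1)
  expect_equal(u_tie, c(1, 0, 0))
  expect_error(l1_project(rep(0, 4), 1.5), "zero vector")

  # grid-scan oracle: achieved L1 agrees with a fine brute-force scan
  for (rep in 1:20) {
    w <- rnorm(sample(5:40, 1))
    cc <- runif(1, 1, sqrt(length(w)))
    got <- l1_project(w, cc)
    expect_equal(sum(got^2), 1, tolerance = 1e-9)
    expect_lte(sum(abs(got)), cc + 1e-6)
    l1_of <- function(d) {
      s <- soft_threshold(w, d)
      if (all(s == 0)) return(1)
      sum(abs(s)) / sqrt(sum(s^2))
    }
    # two-stage scan: coarse bracket, then fine refinement
    deltas <- seq(0, max(abs(w)), length.out = 2000)
    i <- which(vapply(deltas, l1_of, numeric(1)) <= cc)[1]
    fine <- seq(deltas[max(1, i - 1)], deltas[i], length.out = 2000)
    best <- fine[which(vapply(fine, l1_of, numeric(1)) <= cc)[1]]
    expect_equal(sum(abs(got)), l1_of(best), tolerance = 1e-4)
  }
})

test_that("rank-1 PMD reduces to the leading singular triplet without sparsity", {
  set.seed(62)
  z <- matrix(rnorm(30 * 20), 30, 20)
  fit <- pmd_rank1(z, sqrt(30), sqrt(20), tol = 1e-10)
  sv <- svd(z, nu = 1, nv = 1)
  expect_equal(fit$d, sv$d[1], tolerance = 1e-6)
  expect_gte(abs(sum(fit$u * sv$u[, 1])), 1 - 1e-6)
  expect_gte(abs(sum(fit$v * sv$v[, 1])), 1 - 1e-6)
  # sign-convention invariance
  expect_equal(pmd_rank1(-z, sqrt(30), sqrt(20))$d, fit$d, tolerance = 1e-8)
})

test_that("rank-1 PMD recovers a planted sparse factor exactly", {
  set.seed(63)
  a <- numeric(40); a[c(3, 11, 25)] <- c(1, -1, 1) / sqrt(3)
  b <- numeric(50); b[c(2, 9)] <- c(1, 1) / sqrt(2)
  z <- 5 * tcrossprod(a, b)
  fit <- pmd_rank1(z, sum(abs(a)) + 1e-3, sum(abs(b)) + 1e-3)
  expect_gte(abs(sum(fit$u * a)), 1 - 1e-6)
  expect_gte(abs(sum(fit$v * b)), 1 - 1e-6)
  expect_error(pmd_rank1(matrix(0, 3, 3), 1, 1), "nonzero")
})

test_that("penalty grid spans the stated endpoints with uniform spacing", {
  g <- penalty_grid()
  expect_length(g, 20)
  expect_equal(g[1], 0.02)
  expect_equal(g[20], 0.5)
  expect_equal(unique(round(diff(g), 12)), round((0.5 - 0.02) / 19, 12))
  expect_error(penalty_grid(0.3, 0.3), "degenerate")
  expect_error(penalty_grid(0.1, 0.5, 1), "n must be")
})

test_that("noiseless planted data yields a perfect first component", {
  sim <- simulate_paired_omics(30, 25, 20, k = 1,
                               nonzeros_per_component = 4,
                               correlation_strengths = 1, noise_sd = 0,
                               seed = 64)
  # off-support features are exactly zero and are dropped as zero-variance
  # columns; penalty 1 keeps the full (standardized) support
  fit <- scca(sim$x, sim$y, k = 1, penalty = 1)
  expect_equal(abs(fit$cors[1]), 1, tolerance = 1e-6)
  expect_setequal(rownames(fit$u)[fit$u[, 1] != 0], sim$truth$support_x[[1]])
  expect_setequal(rownames(fit$v)[fit$v[, 1] != 0], sim$truth$support_y[[1]])
})

test_that("full-penalty fit reproduces the truncated SVD with zeroed deflation", {
  set.seed(65)
  x <- matrix(rnorm(25 * 12), 25, 12)
  y <- matrix(rnorm(25 * 15), 25, 15)
  fit <- scca(x, y, k = 3, penalty = 1, tol = 1e-10, max_iter = 5000)
  z <- crossprod(scale(x), scale(y))
  sv <- svd(z)
  expect_equal(fit$d, sv$d[1:3], tolerance = 1e-6)
  # deflation: extracted directions annihilate the deflated matrix
  z_defl <- z
  for (j in 1:3) {
    z_defl <- z_defl - fit$d[j] * tcrossprod(fit$u[, j], fit$v[, j])
    expect_lt(abs(crossprod(fit$u[, j], z_defl %*% fit$v[, j])), 1e-8)
  }
  # unit norms and L1 budgets hold for every component
  for (j in 1:3) {
    expect_equal(sum(fit$u[, j]^2), 1, tolerance = 1e-8)
    expect_lte(sum(abs(fit$u[, j])), fit$c_x + 1e-6)
    expect_lte(sum(abs(fit$v[, j])), fit$c_y + 1e-6)
  }
})

test_that("sparsity is monotone in the penalty on noiseless rank-1 data", {
  sim <- simulate_paired_omics(40, 30, 30, k = 1,
                               nonzeros_per_component = 6,
                               correlation_strengths = 1, noise_sd = 0,
                               seed = 66)
  nnz <- vapply(c(0.1, 0.2, 0.35, 0.5, 0.75, 1), function(f) {
    fit <- scca(sim$x, sim$y, k = 1, penalty = f)
    sum(fit$u != 0) + sum(fit$v != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) >= 0))
})

test_that("independent matrices give an unremarkable first correlation", {
  set.seed(67)
  x <- matrix(rnorm(100 * 15), 100, 15)
  y <- matrix(rnorm(100 * 15), 100, 15)
  fit <- scca(x, y, k = 1, penalty = 0.5)
  fit <- scca_significance(fit, n_perm = 99, seed = 1)
  expect_gt(fit$significance$p[1], 0.05)
})

test_that("tuning covers the grid, beats the endpoints, breaks ties low", {
  sim <- simulate_paired_omics(20, 15, 15, k = 1,
                               nonzeros_per_component = 3,
                               correlation_strengths = 0.9, noise_sd = 1,
                               seed = 68)
  grid <- c(0.02, 0.1, 0.25, 0.5)
  tuned <- scca_tune(sim$x, sim$y, k = 1, grid = grid)
  expect_equal(nrow(tuned$tuning_table), length(grid))
  tab <- tuned$tuning_table
  best_score <- tab$mean_cv_cor[tab$penalty == tuned$best_penalty]
  expect_gte(best_score, tab$mean_cv_cor[1] - 1e-12)
  expect_gte(best_score, tab$mean_cv_cor[nrow(tab)] - 1e-12)

  # noiseless: every penalty achieves held-out correlation 1 -> lowest wins
  clean <- simulate_paired_omics(12, 8, 8, k = 1,
                                 nonzeros_per_component = 2,
                                 correlation_strengths = 1, noise_sd = 0,
                                 seed = 69)
  tie <- scca_tune(clean$x, clean$y, k = 1, grid = c(0.4, 0.7, 1))
  expect_equal(tie$best_penalty, 0.4)
  expect_error(scca_tune(sim$x, sim$y, k = 1, grid = numeric(0)), "empty")
})

test_that("saturated planted signal attains the minimum permutation p", {
  sim <- simulate_paired_omics(100, 20, 20, k = 1,
                               nonzeros_per_component = 4,
                               correlation_strengths = 0.9, noise_sd = 1,
                               seed = 70)
  fit <- scca(sim$x, sim$y, k = 1, penalty = 0.4)
  fit <- scca_significance(fit, n_perm = 199, seed = 2)
  expect_equal(fit$significance$p[1], 1 / 200)
  expect_true(all(fit$significance$q >= fit$significance$p))
})

test_that("permutation p-values are super-uniform on null data", {
  set.seed(71)
  pvals <- replicate(400, {
    x <- matrix(rnorm(16 * 8), 16, 8)
    y <- matrix(rnorm(16 * 8), 16, 8)
    fit <- scca(x, y, k = 1, penalty = 0.5)
    scca_significance(fit, n_perm = 39,
                      seed = sample.int(1e6, 1))$significance$p[1]
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  # add-one estimator is slightly conservative; super-uniformity suffices
  expect_gte(mean(pvals <= 0.05), 0)
  expect_lte(mean(pvals <= 0.05), 0.08)
  expect_gt(ks$p.value, 1e-4)
})

test_that("LOOCV keeps planted features and discards noise features", {
  clean <- simulate_paired_omics(20, 12, 12, k = 1,
                                 nonzeros_per_component = 3,
                                 correlation_strengths = 1, noise_sd = 0,
                                 seed = 72)
  fit <- scca(clean$x, clean$y, k = 1, penalty = 1)
  fit <- scca_loocv(fit, retention = 1)
  comp <- fit$loocv$components[[1]]
  expect_setequal(comp$robust_x, clean$truth$support_x[[1]])
  expect_setequal(comp$robust_y, clean$truth$support_y[[1]])
  expect_true(all(comp$robust_x %in% comp$selected_x))

  # with noise, planted features should recur across nearly all refits
  # while pure-noise features recur rarely
  noisy <- simulate_paired_omics(100, 30, 30, k = 1,
                                 nonzeros_per_component = 5,
                                 correlation_strengths = 0.9, noise_sd = 1,
                                 seed = 73)
  # budget sized to the planted support: c = sqrt(5) means penalty
  # fraction sqrt(5)/sqrt(30)
  nf <- scca(noisy$x, noisy$y, k = 1, penalty = sqrt(5 / 30))
  nf <- scca_loocv(nf, retention = 0.9)
  planted <- noisy$truth$support_x[[1]]
  rate <- nf$loocv$count_x[, 1] / nf$loocv$n_refits
  expect_gte(mean(rate[planted]), 0.9)
  expect_lte(mean(rate[setdiff(rownames(nf$u), planted)]), 0.1)
  expect_error(scca_loocv(nf, retention = 1.2), "retention")
})

test_that("scca model methods expose weights, scores and summaries", {
  sim <- simulate_paired_omics(25, 10, 12, k = 2,
                               nonzeros_per_component = 3,
                               correlation_strengths = c(0.9, 0.8),
                               seed = 74)
  fit <- scca(sim$x, sim$y, k = 2, penalty = 0.6)
  cf <- coef(fit)
  expect_equal(dim(cf$x), c(10, 2))
  sc <- predict(fit)
  expect_equal(dim(sc$x), c(25, 2))
  expect_equal(cor(sc$x[, 1], sc$y[, 1]), fit$cors[1], tolerance = 1e-12)
  new_sc <- predict(fit, newx = sim$x$values[1:3, , drop = FALSE])
  expect_equal(new_sc$x, sc$x[1:3, ], tolerance = 1e-12)
  expect_output(print(fit), "Sparse CCA")
  expect_output(print(summary(fit)), "component")
  expect_error(scca(sim$x$values[1:10, ], sim$y$values[1:9, ], k = 1,
                    penalty = 0.5), "sample")
})
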