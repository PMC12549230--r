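# Inference on a fitted sparse CCA model: penalty tuning, permutation
# significance, and leave-one-out feature robustness.

# greedy matching of refit components to reference components by maximal
# |cosine| of the concatenated (u, v) weight vectors; returns, per
# reference component, the matched refit index and the aligning sign
.match_components <- function(u_ref, v_ref, u_new, v_new) {
  k <- ncol(u_ref)
  ref <- rbind(u_ref, v_ref)
  new <- rbind(u_new, v_new)
  cosine <- crossprod(ref, new) /
    outer(sqrt(colSums(ref^2)), sqrt(colSums(new^2)))
  cosine[!is.finite(cosine)] <- 0
  idx <- integer(k)
  sgn <- numeric(k)
  free <- rep(TRUE, k)
  for (j in seq_len(k)) {
    cand <- abs(cosine[j, ])
    cand[!free] <- -Inf
    pick <- which.max(cand)
    idx[j] <- pick
    sgn[j] <- if (cosine[j, pick] >= 0) 1 else -1
    free[pick] <- FALSE
  }
  list(index = idx, sign = sgn)
}

#' Tune the sCCA penalty fraction by leave-one-out cross-validation
#'
#' For every grid value (applied to both sides), each sample is held out
#' in turn, the model is refit on the remaining samples, and the held-out
#' sample's canonical scores are computed with the refit weights (after
#' aligning each refit's components to the full-data fit by maximal
#' |cosine|, so sign flips and order swaps across refits cannot cancel).
#' The tuning score is the mean over components of the correlation between
#' the held-out x- and y-scores across all samples; the argmax wins, ties
#' going to the smallest penalty. Cross-validated rather than in-sample
#' correlation is used because the in-sample canonical correlation is
#' non-decreasing in the penalty fraction and would trivially select the
#' largest grid value.
#'
#' @param x,y matrices or `feature_table`s on shared samples (n >= 4).
#' @param k components per fit.
#' @param grid penalty fractions to evaluate (non-empty).
#' @param tol,max_iter passed to the PMD core.
#' @return list with `best_penalty` and `tuning_table` (data.frame
#'   `penalty`, `mean_cv_cor`, one row per grid value).
#' @export
scca_tune <- function(x, y, k = 2, grid = penalty_grid(),
                      tol = 1e-6, max_iter = 1000) {
  xm <- .as_matrix(x)
  ym <- .as_matrix(y)
  if (length(grid) == 0) stop("empty penalty grid", call. = FALSE)
  n <- nrow(xm)
  if (n < 4) stop("tuning needs >= 4 samples", call. = FALSE)
  scores <- vapply(grid, function(f) {
    full <- tryCatch(scca(xm, ym, k = k, penalty = f, tol = tol,
                          max_iter = max_iter), error = function(e) NULL)
    if (is.null(full)) return(NA_real_)
    hx <- hy <- matrix(NA_real_, n, k)
    for (i in seq_len(n)) {
      fit_i <- tryCatch(scca(xm[-i, , drop = FALSE], ym[-i, , drop = FALSE],
                             k = k, penalty = f, tol = tol,
                             max_iter = max_iter),
                        error = function(e) NULL)
      if (is.null(fit_i)) next
      mm <- .match_components(
        full$u[fit_i$x_std$features, , drop = FALSE],
        full$v[fit_i$y_std$features, , drop = FALSE],
        fit_i$u, fit_i$v)
      sc <- predict(fit_i, newx = xm[i, , drop = FALSE],
                    newy = ym[i, , drop = FALSE])
      hx[i, ] <- sc$x[1, mm$index] * mm$sign
      hy[i, ] <- sc$y[1, mm$index] * mm$sign
    }
    comp_cor <- vapply(seq_len(k), function(j) {
      ok <- stats::complete.cases(hx[, j], hy[, j])
      if (sum(ok) < 3) return(NA_real_)
      suppressWarnings(stats::cor(hx[ok, j], hy[ok, j]))
    }, numeric(1))
    mean(comp_cor, na.rm = TRUE)
  }, numeric(1))
  tab <- data.frame(penalty = grid, mean_cv_cor = scores)
  usable <- which(is.finite(scores))
  if (length(usable) == 0) stop("tuning failed on every grid value",
                                call. = FALSE)
  best <- usable[scores[usable] >= max(scores[usable]) - 1e-12]
  list(best_penalty = grid[min(best)], tuning_table = tab)
}

#' Permutation significance of sCCA components
#'
#' Builds the null by permuting the sample order of the y-side matrix and
#' refitting all `k` components with the fitted penalties; the
#' per-component raw p-value is the add-one estimator
#' `(1 + #(null cor >= observed cor)) / (n_perm + 1)`, compared
#' component-wise by position in the estimation sequence. Raw p-values are
#' BH-adjusted across the `k` components.
#'
#' @param object a fitted [scca()] model.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutation draw.
#' @return `object`, with `$significance` set to a data.frame
#'   (`component`, `cor`, `p`, `q`).
#' @export
scca_significance <- function(object, n_perm = 999, seed = 1) {
  stopifnot(inherits(object, "scca"))
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  xs <- object$x_std$values
  ys <- object$y_std$values
  n <- nrow(xs)
  exceed <- integer(object$k)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      null <- .scca_core(xs, ys[sample(n), , drop = FALSE], object$k,
                         object$c_x, object$c_y, object$tol,
                         object$max_iter)
      exceed <- exceed + as.integer(null$cors >= object$cors)
    }
  })
  p <- (1 + exceed) / (n_perm + 1)
  object$significance <- data.frame(component = seq_len(object$k),
                                    cor = object$cors, p = p,
                                    q = bh_adjust(p))
  object
}

#' Leave-one-out robust feature extraction for sCCA components
#'
#' Refits the model with each sample left out, aligns every refit's
#' components to the full fit by maximal |cosine| of the weight vectors,
#' and calls a feature robust for a component if its weight is nonzero in
#' at least `retention` of the n refits (and in the full fit).
#'
#' @param object a fitted [scca()] model on >= 3 samples.
#' @param retention required fraction of refits, in (0, 1] (default 1:
#'   present in every refit).
#' @return `object`, with `$loocv` set: per component, `selected_x` /
#'   `selected_y` (nonzero-weight ids of the full fit), `robust_x` /
#'   `robust_y` (ids passing the retention rule; always a subset of
#'   selected), plus the per-feature retention counts.
#' @export
scca_loocv <- function(object, retention = 1.0) {
  stopifnot(inherits(object, "scca"))
  if (retention <= 0 || retention > 1)
    stop("retention must be in (0, 1]", call. = FALSE)
  xs <- object$x_std$values
  ys <- object$y_std$values
  n <- nrow(xs)
  if (n < 3) stop("leave-one-out extraction needs >= 3 samples",
                  call. = FALSE)
  k <- object$k
  fx <- rownames(object$u)
  fy <- rownames(object$v)
  count_x <- matrix(0L, length(fx), k, dimnames = list(fx, NULL))
  count_y <- matrix(0L, length(fy), k, dimnames = list(fy, NULL))
  for (i in seq_len(n)) {
    # refit on the already-standardized training rows; re-centering the
    # n-1 rows is part of the refit
    sub <- scca(xs[-i, , drop = FALSE], ys[-i, , drop = FALSE], k = k,
                penalty_x = object$penalty_x, penalty_y = object$penalty_y,
                tol = object$tol, max_iter = object$max_iter)
    mm <- .match_components(object$u[sub$x_std$features, , drop = FALSE],
                            object$v[sub$y_std$features, , drop = FALSE],
                            sub$u, sub$v)
    for (j in seq_len(k)) {
      nz_x <- rownames(sub$u)[sub$u[, mm$index[j]] != 0]
      nz_y <- rownames(sub$v)[sub$v[, mm$index[j]] != 0]
      count_x[nz_x, j] <- count_x[nz_x, j] + 1L
      count_y[nz_y, j] <- count_y[nz_y, j] + 1L
    }
  }
  need <- retention * n - 1e-9
  per_comp <- lapply(seq_len(k), function(j) {
    sel_x <- fx[object$u[, j] != 0]
    sel_y <- fy[object$v[, j] != 0]
    list(selected_x = sel_x, selected_y = sel_y,
         robust_x = intersect(sel_x, fx[count_x[, j] >= need]),
         robust_y = intersect(sel_y, fy[count_y[, j] >= need]))
  })
  object$loocv <- list(components = per_comp, retention = retention,
                       count_x = count_x, count_y = count_y, n_refits = n)
  object
}
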