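#' Soft-thresholding operator
#'
#' `S(w, delta)_i = sign(w_i) max(|w_i| - delta, 0)`, the proximal operator
#' of the L1 penalty that shrinks small weights to exactly zero.
#'
#' @param w numeric vector.
#' @param delta threshold, >= 0.
#' @return shrunken vector of the same length.
#' @export
soft_threshold <- function(w, delta) {
  if (length(delta) != 1 || !is.finite(delta) || delta < 0)
    stop("delta must be a single non-negative number", call. = FALSE)
  sign(w) * pmax(abs(w) - delta, 0)
}

#' Project a vector onto the unit L2 sphere intersected with an L1 ball
#'
#' Finds the smallest `delta >= 0` such that the L2-normalized
#' soft-thresholded vector `S(w, delta) / ||S(w, delta)||_2` has L1 norm at
#' most `c`, by bisection. This is the per-side subproblem of the
#' penalized matrix decomposition. For `c >= sqrt(p)` the constraint is
#' inactive (Cauchy-Schwarz) and plain normalization is returned; at the
#' other extreme `c = 1` forces a single nonzero coordinate (the
#' largest-magnitude one, ties broken by lowest index).
#'
#' @param w nonzero numeric vector.
#' @param c L1 budget, `1 <= c <= sqrt(length(w))`.
#' @param tol L1 slack tolerance.
#' @return unit-L2 vector with `sum(abs(.)) <= c + tol`.
#' @export
l1_project <- function(w, c, tol = 1e-6) {
  p <- length(w)
  if (all(w == 0)) stop("cannot project the zero vector", call. = FALSE)
  if (c < 1 - 1e-12 || c > sqrt(p) + 1e-12)
    stop("c must lie in [1, sqrt(length(w))]", call. = FALSE)
  u <- w / sqrt(sum(w^2))
  if (sum(abs(u)) <= c + tol) return(u)
  if (abs(c - 1) < 1e-12) {
    # limit of the L1 ball at unit L2: a single coordinate survives
    i <- which.max(abs(w))
    out <- numeric(p)
    out[i] <- sign(w[i])
    return(out)
  }
  lo <- 0
  hi <- max(abs(w))
  for (iter in 1:60) {
    delta <- (lo + hi) / 2
    s <- soft_threshold(w, delta)
    if (all(s == 0)) { hi <- delta; next }
    if (sum(abs(s)) / sqrt(sum(s^2)) > c) lo <- delta else hi <- delta
  }
  s <- soft_threshold(w, hi)
  if (all(s == 0)) {  # fall back to the single-coordinate limit
    i <- which.max(abs(w))
    s[i] <- sign(w[i])
  }
  s / sqrt(sum(s^2))
}

#' Rank-1 penalized matrix decomposition
#'
#' Alternating soft-thresholded power iteration on a cross-product matrix
#' `Z`: starting from the leading right singular vector,
#' `u <- l1_project(Z v, c_x)` and `v <- l1_project(Z' u, c_y)` until the
#' largest coordinate change falls below `tol`. Returns the penalized
#' singular triplet; `d = u' Z v >= 0` by construction, and the sign
#' convention makes the largest-magnitude entry of `u` positive.
#'
#' @param z numeric matrix (p_x x p_y), finite and nonzero.
#' @param c_x,c_y L1 budgets for `u` and `v`.
#' @param tol convergence tolerance on the iterates.
#' @param max_iter iteration cap; non-convergence is reported via the
#'   `converged` flag (and a warning) with the last iterate returned.
#' @return list `u`, `v` (unit L2), `d` (>= 0), `iterations`, `converged`.
#' @export
pmd_rank1 <- function(z, c_x, c_y, tol = 1e-6, max_iter = 1000) {
  if (!all(is.finite(z))) stop("z must be finite", call. = FALSE)
  if (all(z == 0)) stop("z must be nonzero", call. = FALSE)
  sv <- svd(z, nu = 1, nv = 1)
  v <- sv$v[, 1]
  u <- l1_project(drop(z %*% v), c_x)
  converged <- FALSE
  iter <- 0
  d_old <- drop(crossprod(u, z %*% v))
  while (iter < max_iter) {
    iter <- iter + 1
    v_new <- l1_project(drop(crossprod(z, u)), c_y)
    u_new <- l1_project(drop(z %*% v_new), c_x)
    delta <- max(max(abs(u_new - u)), max(abs(v_new - v)))
    u <- u_new
    v <- v_new
    d_new <- drop(crossprod(u, z %*% v))
    # stop on stable iterates, or on a stable objective (iterates can
    # oscillate between equal-objective solutions on near-tied data)
    if (delta < tol || abs(d_new - d_old) < tol * max(1, abs(d_new))) {
      converged <- TRUE
      break
    }
    d_old <- d_new
  }
  if (!converged)
    warning("pmd_rank1 did not converge in ", max_iter, " iterations")
  i <- which.max(abs(u))
  if (u[i] < 0) { u <- -u; v <- -v }
  list(u = u, v = v, d = drop(crossprod(u, z %*% v)),
       iterations = iter, converged = converged)
}

#' Equally spaced sCCA penalty grid
#'
#' @param lo,hi grid endpoints, `0 < lo < hi <= 1`.
#' @param n number of values (>= 2), equally spaced, endpoints included.
#' @return numeric vector of length `n`.
#' @export
penalty_grid <- function(lo = 0.02, hi = 0.5, n = 20) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (!(lo > 0 && hi <= 1)) stop("grid must lie in (0, 1]", call. = FALSE)
  if (lo >= hi) stop("degenerate grid: lo must be < hi", call. = FALSE)
  seq(lo, hi, length.out = n)
}

# columns standardized to mean 0 / sd 1; zero-variance columns dropped
.standardize <- function(m, what = "matrix") {
  ctr <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  keep <- which(sdv > 0)
  if (length(keep) < ncol(m))
    mb_log("%s: dropping %d zero-variance column(s)", what,
           ncol(m) - length(keep))
  if (length(keep) == 0) stop("all columns have zero variance", call. = FALSE)
  list(values = scale(m[, keep, drop = FALSE], center = ctr[keep],
                      scale = sdv[keep]),
       center = ctr[keep], scale = sdv[keep],
       features = colnames(m)[keep])
}

# K penalized components of Z = X'Y with deflation; xs, ys standardized
.scca_core <- function(xs, ys, k, c_x, c_y, tol = 1e-6, max_iter = 1000) {
  z <- crossprod(xs, ys)
  p_x <- ncol(xs); p_y <- ncol(ys)
  u <- matrix(0, p_x, k); v <- matrix(0, p_y, k)
  d <- cors <- numeric(k)
  converged <- logical(k)
  for (j in seq_len(k)) {
    fit <- pmd_rank1(z, c_x, c_y, tol = tol, max_iter = max_iter)
    u[, j] <- fit$u; v[, j] <- fit$v; d[j] <- fit$d
    converged[j] <- fit$converged
    cors[j] <- stats::cor(drop(xs %*% fit$u), drop(ys %*% fit$v))
    z <- z - fit$d * tcrossprod(fit$u, fit$v)
  }
  list(u = u, v = v, d = d, cors = cors, converged = converged)
}

.as_matrix <- function(x) {
  if (inherits(x, "feature_table")) x$values else as.matrix(x)
}

#' Sparse canonical correlation analysis
#'
#' Fits `k` sparse canonical components between two data matrices observed
#' on the same samples, via rank-1 penalized matrix decomposition of the
#' standardized cross-product `Z = X'Y` with deflation. Sparsity is
#' controlled by a penalty fraction `f` in (0, 1] per side, setting the L1
#' budget `c = f sqrt(p)`; at `f = 1` the fit coincides with the truncated
#' SVD of `Z` (classical diagonal-covariance CCA), and smaller fractions
#' zero out weights. When `penalty` is `NULL` a shared fraction is tuned
#' on a grid by leave-one-out cross-validated correlation (see
#' [scca_tune()]).
#'
#' @param x,y `feature_table`s or numeric matrices on the same samples, in
#'   the same row order (checked via rownames when available). Columns are
#'   standardized internally; zero-variance columns are dropped with a log
#'   message.
#' @param k number of components, `>= 1` and at most the smaller feature
#'   count.
#' @param penalty shared penalty fraction in (0, 1], or `NULL` to tune.
#' @param penalty_x,penalty_y per-side overrides of `penalty`.
#' @param grid penalty grid used when tuning (default
#'   `penalty_grid(0.02, 0.5, 20)`).
#' @param tol,max_iter convergence control passed to [pmd_rank1()].
#' @return an object of class `scca`: weight matrices `u` (p_x x k) and
#'   `v` with feature rownames, penalized singular values `d`, in-sample
#'   canonical correlations `cors`, the penalties used, the tuning table
#'   (if tuned), and the standardization recipe needed by [predict.scca()].
#' @seealso [scca_significance()], [scca_loocv()], [scca_tune()]
#' @examples
#' sim <- simulate_paired_omics(n = 40, p_x = 20, p_y = 25, k = 1,
#'                              nonzeros_per_component = 4,
#'                              correlation_strengths = 0.9, seed = 3)
#' fit <- scca(sim$x, sim$y, k = 1, penalty = 0.3)
#' fit$cors
#' @export
scca <- function(x, y, k = 2, penalty = NULL,
                 penalty_x = penalty, penalty_y = penalty,
                 grid = penalty_grid(), tol = 1e-6, max_iter = 1000) {
  xm <- .as_matrix(x)
  ym <- .as_matrix(y)
  if (nrow(xm) != nrow(ym))
    stop("x and y must share the sample set", call. = FALSE)
  if (!is.null(rownames(xm)) && !is.null(rownames(ym)) &&
      !identical(rownames(xm), rownames(ym)))
    stop("x and y sample ids disagree (same set and order required)",
         call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  tuning <- NULL
  if (is.null(penalty_x) || is.null(penalty_y)) {
    tuned <- scca_tune(xm, ym, k = k, grid = grid, tol = tol,
                       max_iter = max_iter)
    penalty_x <- penalty_y <- tuned$best_penalty
    tuning <- tuned$tuning_table
  }
  for (f in c(penalty_x, penalty_y))
    if (f <= 0 || f > 1) stop("penalty fractions must lie in (0, 1]",
                              call. = FALSE)
  sx <- .standardize(xm, "x")
  sy <- .standardize(ym, "y")
  if (k > min(ncol(sx$values), ncol(sy$values)))
    stop("k exceeds the number of usable features", call. = FALSE)
  c_x <- max(1, penalty_x * sqrt(ncol(sx$values)))
  c_y <- max(1, penalty_y * sqrt(ncol(sy$values)))
  core <- .scca_core(sx$values, sy$values, k, c_x, c_y, tol, max_iter)
  rownames(core$u) <- sx$features
  rownames(core$v) <- sy$features
  colnames(core$u) <- colnames(core$v) <- paste0("comp", seq_len(k))
  structure(
    list(u = core$u, v = core$v, d = core$d, cors = core$cors,
         k = k, penalty_x = penalty_x, penalty_y = penalty_y,
         c_x = c_x, c_y = c_y, tuning_table = tuning,
         converged = core$converged,
         x_std = sx, y_std = sy, tol = tol, max_iter = max_iter,
         significance = NULL, loocv = NULL, call = match.call()),
    class = "scca")
}

#' @export
print.scca <- function(x, ...) {
  cat(sprintf("Sparse CCA: %d component(s), penalty (%.3g, %.3g)\n",
              x$k, x$penalty_x, x$penalty_y))
  cat("canonical correlations:",
      paste(sprintf("%.3f", x$cors), collapse = ", "), "\n")
  nz <- sprintf("%d/%d", colSums(x$u != 0) + colSums(x$v != 0),
                nrow(x$u) + nrow(x$v))
  cat("nonzero weights per component:", paste(nz, collapse = ", "), "\n")
  if (!is.null(x$significance))
    cat("significant components (q < 0.05):",
        sum(x$significance$q < 0.05), "of", x$k, "\n")
  invisible(x)
}

#' @export
summary.scca <- function(object, ...) {
  tab <- data.frame(
    component = seq_len(object$k),
    correlation = object$cors,
    d = object$d,
    nonzero_x = colSums(object$u != 0),
    nonzero_y = colSums(object$v != 0))
  if (!is.null(object$significance)) {
    tab$p <- object$significance$p
    tab$q <- object$significance$q
  }
  structure(list(table = tab, penalty_x = object$penalty_x,
                 penalty_y = object$penalty_y,
                 tuned = !is.null(object$tuning_table)),
            class = "summary.scca")
}

#' @export
print.summary.scca <- function(x, ...) {
  cat(sprintf("Sparse CCA fit (penalty %.3g/%.3g%s)\n", x$penalty_x,
              x$penalty_y, if (x$tuned) ", tuned by LOOCV" else ""))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Extract sCCA weight vectors
#'
#' @param object an `scca` fit.
#' @param side `"x"`, `"y"` or `"both"`.
#' @param ... unused.
#' @return a weight matrix (features x components), or a list of both.
#' @export
coef.scca <- function(object, side = c("both", "x", "y"), ...) {
  side <- match.arg(side)
  switch(side, x = object$u, y = object$v,
         both = list(x = object$u, y = object$v))
}

#' Project (new) samples onto fitted canonical components
#'
#' Applies the training standardization to `newx`/`newy` and returns the
#' canonical scores. With no new data, returns the training scores.
#'
#' @param object an `scca` fit.
#' @param newx,newy matrices or `feature_table`s carrying (at least) the
#'   features used in the fit.
#' @param ... unused.
#' @return list with score matrices `x` and/or `y` (samples x components).
#' @export
predict.scca <- function(object, newx = NULL, newy = NULL, ...) {
  project <- function(m, std, w) {
    m <- .as_matrix(m)
    missing <- setdiff(std$features, colnames(m))
    if (length(missing) > 0)
      stop("new data lacks fitted features: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    ms <- scale(m[, std$features, drop = FALSE], center = std$center,
                scale = std$scale)
    ms %*% w
  }
  out <- list()
  out$x <- if (is.null(newx)) object$x_std$values %*% object$u
           else project(newx, object$x_std, object$u)
  out$y <- if (is.null(newy)) object$y_std$values %*% object$v
           else project(newy, object$y_std, object$v)
  out
}

#' Plot an sCCA fit
#'
#' Bar plot of the canonical correlations (filled where the component is
#' significant, if [scca_significance()] has been run); when a tuning
#' table is present, the cross-validated tuning curve is drawn alongside.
#'
#' @param x an `scca` fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.scca <- function(x, ...) {
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  if (!is.null(x$tuning_table)) graphics::par(mfrow = c(1, 2))
  sig <- if (!is.null(x$significance)) x$significance$q < 0.05
         else rep(NA, x$k)
  cols <- ifelse(is.na(sig), "grey40", ifelse(sig, "firebrick", "grey70"))
  graphics::barplot(x$cors, names.arg = seq_len(x$k), col = cols,
                    xlab = "component", ylab = "canonical correlation", ...)
  if (!is.null(x$tuning_table)) {
    graphics::plot(x$tuning_table$penalty, x$tuning_table$mean_cv_cor,
                   type = "b", xlab = "penalty fraction",
                   ylab = "mean LOOCV correlation")
    graphics::abline(v = x$penalty_x, lty = 2)
  }
  invisible(x)
}
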