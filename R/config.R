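#' Pipeline configuration
#'
#' Bundles every tunable threshold of the pipeline in one validated object.
#' Defaults mirror the analysis conventions the pipeline implements: a 0.05
#' significance level throughout, a Spearman edge filter of rho >= 0.5, and
#' an sCCA penalty grid of 20 equally spaced fractions from 0.02 to 0.5.
#'
#' @param alpha significance level for BH-adjusted p-values, in (0, 1).
#' @param rho_min minimum Spearman rho for network edges.
#' @param penalty_lo,penalty_hi,penalty_n sCCA penalty-fraction grid:
#'   `penalty_n` equally spaced values from `penalty_lo` to `penalty_hi`
#'   inclusive; requires `0 < lo < hi <= 1` and `n >= 2`.
#' @param n_permutations permutations for ANOSIM and sCCA significance.
#' @param seed integer RNG seed recorded with every stochastic stage.
#' @param pseudocount added before log2 transformation.
#' @param hub_quantile neighborhood-connectivity quantile defining hubs.
#' @param hub_min_degree minimum degree for hub eligibility.
#' @param loocv_retention fraction of leave-one-out refits in which a
#'   feature's weight must be nonzero to be called robust, in (0, 1].
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05, rho_min = 0.5,
                            penalty_lo = 0.02, penalty_hi = 0.5,
                            penalty_n = 20L, n_permutations = 999L,
                            seed = 1L, pseudocount = 1,
                            hub_quantile = 0.90, hub_min_degree = 2L,
                            loocv_retention = 1.0) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)", call. = FALSE)
  if (!is.numeric(rho_min) || rho_min < 0 || rho_min > 1)
    stop("rho_min must be in [0, 1]", call. = FALSE)
  if (!(penalty_lo > 0 && penalty_lo <= penalty_hi && penalty_hi <= 1))
    stop("penalty grid requires 0 < lo <= hi <= 1", call. = FALSE)
  if (penalty_n < 2) stop("penalty_n must be >= 2", call. = FALSE)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
    stop("seed must be a single integer", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
  if (hub_quantile < 0 || hub_quantile > 1)
    stop("hub_quantile must be in [0, 1]", call. = FALSE)
  if (loocv_retention <= 0 || loocv_retention > 1)
    stop("loocv_retention must be in (0, 1]", call. = FALSE)
  structure(list(alpha = alpha, rho_min = rho_min,
                 penalty_lo = penalty_lo, penalty_hi = penalty_hi,
                 penalty_n = as.integer(penalty_n),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), pseudocount = pseudocount,
                 hub_quantile = hub_quantile,
                 hub_min_degree = as.integer(hub_min_degree),
                 loocv_retention = loocv_retention),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read / write pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns a validated `pipeline_config`; unknown
#'   keys raise an error so typos cannot silently fall back to defaults.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

#' @param config a `pipeline_config`.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# stderr logging; silenced via options(mbcca.quiet = TRUE)
mb_log <- function(fmt, ...) {
  if (isTRUE(getOption("mbcca.quiet", FALSE))) return(invisible(NULL))
  message(sprintf(paste0("[mbcca] ", fmt), ...))
}
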