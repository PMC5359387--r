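#' Pipeline configuration
#'
#' Collects every tunable parameter of the coexpression-clustering
#' pipeline in one validated object. The defaults are the analysis
#' constants used throughout: intensities below 100 are treated as
#' unexpressed, edges require Pearson r >= 0.9, MCL runs at inflation
#' 2.2 with expansion power 2, clusters need at least five members, a
#' tissue call requires fivefold enrichment of the cluster mean, and
#' enrichment significance is Bonferroni-corrected at alpha = 0.05.
#'
#' @param intensity_threshold minimum natural-scale intensity a feature
#'   must reach in at least one condition to be retained (default 100).
#' @param corr_cutoff Pearson correlation cutoff in (0, 1] for graph
#'   edges; the comparison is inclusive (default 0.9).
#' @param inflation MCL inflation exponent, must exceed 1; larger values
#'   give finer clusters (default 2.2).
#' @param expansion_power MCL expansion power (number of transition-matrix
#'   self-multiplications per iteration), integer >= 2 (default 2).
#' @param min_cluster_size smallest reported cluster, integer >= 1
#'   (default 5).
#' @param fold_threshold fold change of cluster mean expression required
#'   to call a condition specific (default 5).
#' @param alpha Bonferroni-corrected significance level for enrichment
#'   (default 0.05).
#' @param prune_threshold MCL entries below this are zeroed after each
#'   iteration, then columns renormalized (default 1e-5).
#' @param convergence_tol MCL stops when the largest elementwise change
#'   over one iteration falls below this (default 1e-8).
#' @param max_iterations MCL iteration cap; exceeding it is an error
#'   carrying iteration diagnostics (default 200).
#' @param rng_seed optional integer seed recorded for provenance.
#' @param filter_before_averaging apply the low-intensity filter to raw
#'   replicate columns instead of averaged condition columns. Off by
#'   default: the filter speaks of low *average* expression, so the
#'   averaged columns are the primary reading; the flag exists for
#'   sensitivity analysis.
#' @param specificity_reference how the "other tissues" level is
#'   summarized in the fold-change rule: `"mean"` (default) compares a
#'   condition against the mean of the remaining condition means,
#'   `"max"` against their maximum.
#' @return an object of class `coexp_config` (a validated named list).
#' @examples
#' coexp_config()
#' coexp_config(corr_cutoff = 0.8, inflation = 3)
#' @export
coexp_config <- function(intensity_threshold = 100,
                         corr_cutoff = 0.9,
                         inflation = 2.2,
                         expansion_power = 2L,
                         min_cluster_size = 5L,
                         fold_threshold = 5,
                         alpha = 0.05,
                         prune_threshold = 1e-5,
                         convergence_tol = 1e-8,
                         max_iterations = 200L,
                         rng_seed = NULL,
                         filter_before_averaging = FALSE,
                         specificity_reference = c("mean", "max")) {
  specificity_reference <- match.arg(specificity_reference)
  cfg <- list(
    intensity_threshold = as.numeric(intensity_threshold),
    corr_cutoff = as.numeric(corr_cutoff),
    inflation = as.numeric(inflation),
    expansion_power = as.integer(expansion_power),
    min_cluster_size = as.integer(min_cluster_size),
    fold_threshold = as.numeric(fold_threshold),
    alpha = as.numeric(alpha),
    prune_threshold = as.numeric(prune_threshold),
    convergence_tol = as.numeric(convergence_tol),
    max_iterations = as.integer(max_iterations),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
    filter_before_averaging = isTRUE(filter_before_averaging),
    specificity_reference = specificity_reference
  )
  class(cfg) <- "coexp_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  num <- c("intensity_threshold", "corr_cutoff", "inflation",
           "fold_threshold", "alpha", "prune_threshold",
           "convergence_tol")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      config_error(sprintf("'%s' must be a single finite positive number", f))
  }
  if (cfg$corr_cutoff > 1)
    config_error("'corr_cutoff' must lie in (0, 1]")
  if (cfg$inflation <= 1)
    config_error("'inflation' must exceed 1 (granularity contract)")
  if (cfg$expansion_power < 2)
    config_error("'expansion_power' must be an integer >= 2")
  if (cfg$min_cluster_size < 1)
    config_error("'min_cluster_size' must be an integer >= 1")
  if (cfg$max_iterations < 1)
    config_error("'max_iterations' must be an integer >= 1")
  if (cfg$alpha > 1)
    config_error("'alpha' must lie in (0, 1]")
  invisible(cfg)
}

#' @export
print.coexp_config <- function(x, ...) {
  cat("Coexpression pipeline configuration\n")
  cat(sprintf("  intensity filter : >= %g\n", x$intensity_threshold))
  cat(sprintf("  correlation edge : r >= %g\n", x$corr_cutoff))
  cat(sprintf("  MCL              : inflation %g, expansion %d, prune %g,\n",
              x$inflation, x$expansion_power, x$prune_threshold))
  cat(sprintf("                     tol %g, max %d iterations\n",
              x$convergence_tol, x$max_iterations))
  cat(sprintf("  min cluster size : %d\n", x$min_cluster_size))
  cat(sprintf("  specificity      : %g-fold vs %s of other conditions\n",
              x$fold_threshold, x$specificity_reference))
  cat(sprintf("  enrichment alpha : %g (Bonferroni)\n", x$alpha))
  invisible(x)
}

# Build a coexp_config from a plain named list (e.g. parsed YAML/JSON),
# ignoring keys that are not configuration fields.
config_from_list <- function(lst) {
  known <- names(formals(coexp_config))
  do.call(coexp_config, lst[intersect(names(lst), known)])
}
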