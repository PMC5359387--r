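#' Fit a coexpression clustering to an expression matrix
#'
#' The central entry point: runs replicate averaging (when metadata is
#' supplied), low-intensity filtering, all-pairs Pearson correlation,
#' threshold-graph construction, Markov clustering, minimum-size
#' filtering with size-ordered cluster naming, and tissue-specificity
#' calling, all under one [coexp_config()].
#'
#' @param expr numeric matrix, features x samples (or features x
#'   conditions if already averaged).
#' @param metadata optional sample metadata (`sample_id`,
#'   `experiment_group`, `condition_id`); when given, replicate columns
#'   are averaged per condition first.
#' @param config a [coexp_config()].
#' @return object of class `coexp_fit` with components `config`,
#'   `averaged` (condition-level matrix), `filtered` (post-filter
#'   matrix), `graph` (`coexp_graph`), `components`, `raw` (`mcl_raw`),
#'   `clusters` (`cluster_set`), `specificity` (named list of
#'   `specificity_call`s), and `counts` (stage bookkeeping).
#' @examples
#' sim <- generate_dataset(synth_params(n_modules = 2, module_size = 8,
#'                                      n_conditions = 4, n_background = 20),
#'                         seed = 42)
#' fit <- coexp_cluster(sim$expr, sim$metadata)
#' fit
#' @export
coexp_cluster <- function(expr, metadata = NULL, config = coexp_config()) {
  validate_config(config)
  validate_expression_matrix(expr)
  n_in <- nrow(expr)
  if (config$filter_before_averaging)
    expr <- filter_low_expression(expr, config$intensity_threshold)
  averaged <- if (is.null(metadata)) expr else average_replicates(expr, metadata)
  filtered <- if (config$filter_before_averaging) averaged
              else filter_low_expression(averaged, config$intensity_threshold)
  corr <- pearson_matrix(filtered)
  graph <- build_graph(corr, config$corr_cutoff)
  comps <- connected_components(graph)
  raw <- mcl(graph, config)
  clusters <- extract_clusters(raw, config$min_cluster_size)
  specificity <- lapply(names(clusters$clusters), function(cid)
    tissue_specificity(filtered, clusters$clusters[[cid]],
                       fold_threshold = config$fold_threshold,
                       reference = config$specificity_reference,
                       cluster_id = cid))
  names(specificity) <- names(clusters$clusters)
  counts <- list(features_in = n_in,
                 features_after_filter = nrow(filtered),
                 nodes = length(graph$nodes),
                 edges = nrow(graph$edges),
                 components = length(comps),
                 clusters = length(clusters$clusters),
                 clustered = sum(lengths(clusters$clusters)),
                 unclustered = length(clusters$unclustered))
  out <- list(config = config, averaged = averaged, filtered = filtered,
              graph = graph, components = comps, raw = raw,
              clusters = clusters, specificity = specificity,
              counts = counts)
  class(out) <- "coexp_fit"
  out
}

#' @export
print.coexp_fit <- function(x, ...) {
  ct <- x$counts
  cat("Coexpression clustering fit\n")
  cat(sprintf("  %d features in, %d past intensity filter (>= %g)\n",
              ct$features_in, ct$features_after_filter,
              x$config$intensity_threshold))
  cat(sprintf("  graph: %d nodes, %d edges (r >= %g), %d components\n",
              ct$nodes, ct$edges, x$config$corr_cutoff, ct$components))
  cat(sprintf("  MCL (inflation %g): %d clusters of >= %d members, %d genes unclustered\n",
              x$config$inflation, ct$clusters, x$config$min_cluster_size,
              ct$unclustered))
  invisible(x)
}

#' @export
summary.coexp_fit <- function(object, ...) {
  cs <- object$clusters
  df <- data.frame(
    cluster_id = names(cs$clusters),
    size = as.integer(lengths(cs$clusters)),
    specific_for = vapply(names(cs$clusters), function(cid) {
      called <- object$specificity[[cid]]$called
      if (length(called)) paste(called, collapse = ",") else ""
    }, character(1)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(list(table = df, counts = object$counts,
                 config = object$config),
            class = "summary.coexp_fit")
}

#' @export
print.summary.coexp_fit <- function(x, ...) {
  cat("Coexpression clustering summary\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("unclustered: %d of %d graph nodes\n",
              x$counts$unclustered, x$counts$nodes))
  invisible(x)
}

#' Plot a coexpression clustering fit
#'
#' Two base-graphics panels: cluster sizes (largest first) and the mean
#' expression profile of the largest clusters across conditions.
#'
#' @param x a `coexp_fit`.
#' @param top number of clusters to profile (default 6).
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.coexp_fit <- function(x, top = 6, ...) {
  cs <- x$clusters$clusters
  if (!length(cs)) {
    warning("nothing to plot: no clusters")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(old))
  graphics::barplot(lengths(cs), names.arg = names(cs), las = 2,
                    ylab = "genes", main = "Cluster sizes", ...)
  top <- min(top, length(cs))
  prof <- t(vapply(cs[seq_len(top)], function(m)
    colMeans(x$filtered[m, , drop = FALSE]), numeric(ncol(x$filtered))))
  graphics::matplot(t(prof), type = "l", lty = 1, lwd = 2, xaxt = "n",
                    ylab = "mean intensity", xlab = "",
                    main = "Mean cluster profiles")
  graphics::axis(1, at = seq_len(ncol(x$filtered)),
                 labels = colnames(x$filtered), las = 2)
  graphics::legend("topright", legend = rownames(prof), lty = 1, lwd = 2,
                   col = seq_len(top), cex = 0.7, bty = "n")
  invisible(x)
}

#' Run the full pipeline from a config file
#'
#' Reads a YAML (or JSON) configuration naming the input files and any
#' parameter overrides, executes ingest, averaging, filtering,
#' correlation, graph construction, MCL, cluster extraction,
#' specificity calling and (when annotations are configured) scoring
#' and enrichment, writes every stage output under `out_dir`, and
#' returns a run manifest. Reruns with identical config and inputs
#' produce identical outputs.
#'
#' Config keys: `expression` (TSV path, required), `metadata` (TSV
#' path, optional), `annotations` (long TSV, optional), `gene_sets`
#' (GMT, optional), `out_dir` (default `"."`), plus any [coexp_config()]
#' parameter.
#'
#' @param config_path path to the YAML/JSON config file.
#' @param out_dir overrides the config's `out_dir` when non-NULL.
#' @return the run manifest (list, also written as `manifest.json`),
#'   invisibly; component `fit` of the attribute carries the
#'   `coexp_fit`.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  raw_cfg <- yaml::read_yaml(config_path)
  cfg <- config_from_list(raw_cfg)
  if (is.null(raw_cfg$expression))
    config_error("config must name an 'expression' TSV")
  out_dir <- out_dir %||% raw_cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(raw_cfg$metadata)) {
    inp <- read_expression_matrix(raw_cfg$expression, raw_cfg$metadata)
    fit <- coexp_cluster(inp$expr, inp$metadata, cfg)
  } else {
    expr <- read_expression_matrix(raw_cfg$expression)
    fit <- coexp_cluster(expr, NULL, cfg)
  }
  paths <- list(
    clusters = file.path(out_dir, "clusters.tsv"),
    cluster_sizes = file.path(out_dir, "cluster_sizes.tsv"),
    edges = file.path(out_dir, "edges.tsv"),
    graphml = file.path(out_dir, "graph.graphml"),
    specificity = file.path(out_dir, "specificity.tsv"),
    manifest = file.path(out_dir, "manifest.json"))
  write_clusters(fit$clusters, paths$clusters, paths$cluster_sizes)
  write_edge_list(fit$graph, paths$edges)
  write_graphml(fit$graph, paths$graphml)
  spec_df <- do.call(rbind, lapply(fit$specificity, function(s)
    data.frame(cluster_id = s$cluster_id,
               called_conditions = paste(s$called, collapse = ","),
               stringsAsFactors = FALSE)))
  utils::write.table(spec_df %||%
                       data.frame(cluster_id = character(0),
                                  called_conditions = character(0)),
                     paths$specificity, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(raw_cfg$annotations)) {
    ann <- read_annotation_table(raw_cfg$annotations,
                                 universe = fit$graph$nodes)
    paths$scores <- file.path(out_dir, "annotation_scores.tsv")
    utils::write.table(score_clusters(fit$clusters, ann), paths$scores,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(raw_cfg$gene_sets)) {
    sets <- read_gmt(raw_cfg$gene_sets)
    bg <- fit$graph$nodes
    enr <- do.call(rbind, lapply(names(fit$clusters$clusters), function(cid)
      enrich_cluster(fit$clusters$clusters[[cid]], sets, bg,
                     alpha = cfg$alpha, cluster_id = cid)))
    paths$enrichment <- file.path(out_dir, "enrichment.tsv")
    utils::write.table(enr, paths$enrichment, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  manifest <- list(
    config = raw_cfg,
    parameters = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
    inputs = list(expression = unname(tools::md5sum(raw_cfg$expression)),
                  metadata = if (!is.null(raw_cfg$metadata))
                    unname(tools::md5sum(raw_cfg$metadata))),
    counts = fit$counts,
    outputs = lapply(paths, normalizePath, mustWork = FALSE),
    elapsed_seconds = proc.time()[["elapsed"]] - t0,
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  stopifnot(all(file.exists(unlist(paths))))
  attr(manifest, "fit") <- fit
  invisible(manifest)
}
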