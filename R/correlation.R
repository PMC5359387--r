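#' All-pairs Pearson correlation of feature profiles
#'
#' Computes the feature-by-feature Pearson product-moment correlation of
#' expression profiles across condition columns. Rows are standardized
#' once and the correlation block is accumulated by chunked cross
#' products, so peak memory beyond the result itself is proportional to
#' `chunk_size * nrow` rather than `nrow^2` intermediates.
#'
#' Features with zero variance across conditions have no defined
#' correlation; they are excluded from the result with a warning and
#' recorded in the `"excluded"` attribute.
#'
#' @param expr numeric matrix, features x conditions, with at least 3
#'   condition columns.
#' @param chunk_size number of feature rows per cross-product block.
#' @return symmetric correlation matrix with unit diagonal and values in
#'   `[-1, 1]`; attribute `excluded` lists zero-variance feature ids.
#' @export
pearson_matrix <- function(expr, chunk_size = 1024L) {
  validate_expression_matrix(expr)
  m <- ncol(expr)
  if (m < 3)
    format_error("Pearson correlation requires >= 3 condition columns")
  mu <- rowMeans(expr)
  cen <- expr - mu
  ss <- sqrt(rowSums(cen^2))
  zero <- ss == 0
  excluded <- rownames(expr)[zero]
  if (any(zero)) {
    warning(sprintf("%d zero-variance feature(s) excluded from correlation",
                    sum(zero)))
    cen <- cen[!zero, , drop = FALSE]
    ss <- ss[!zero]
  }
  n <- nrow(cen)
  z <- cen / ss
  r <- matrix(NA_real_, n, n, dimnames = list(rownames(cen), rownames(cen)))
  starts <- seq(1L, max(n, 1L), by = chunk_size)
  if (n > 0) {
    for (s in starts) {
      e <- min(s + chunk_size - 1L, n)
      r[s:e, ] <- tcrossprod(z[s:e, , drop = FALSE], z)
    }
    r[r > 1] <- 1
    r[r < -1] <- -1
    diag(r) <- 1
  }
  attr(r, "excluded") <- excluded
  r
}

#' Build the thresholded coexpression graph
#'
#' An undirected weighted graph whose nodes are the features of the
#' correlation matrix and whose edges connect pairs with r at or above
#' the cutoff (inclusive). Isolated nodes (no passing edge) stay in the
#' node set and are reported separately.
#'
#' @param corr symmetric correlation matrix with unit diagonal, e.g.
#'   from [pearson_matrix()].
#' @param corr_cutoff correlation cutoff in (0, 1].
#' @return object of class `coexp_graph`: list with `nodes`, `edges`
#'   (data frame `from`, `to`, `weight`), `cutoff`, `isolated`, and
#'   `excluded` (zero-variance features carried over from `corr`).
#' @export
build_graph <- function(corr, corr_cutoff = 0.9) {
  if (!is.numeric(corr_cutoff) || length(corr_cutoff) != 1 ||
      corr_cutoff <= 0 || corr_cutoff > 1)
    config_error("'corr_cutoff' must lie in (0, 1]")
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    format_error("'corr' must be a square correlation matrix")
  if (nrow(corr) > 0) {
    if (max(abs(corr - t(corr))) > 1e-12)
      format_error("'corr' must be symmetric")
    if (max(abs(diag(corr) - 1)) > 1e-12)
      format_error("'corr' must have unit diagonal")
  }
  ids <- rownames(corr)
  hit <- which(upper.tri(corr) & corr >= corr_cutoff, arr.ind = TRUE)
  edges <- data.frame(from = ids[hit[, 1]],
                      to = ids[hit[, 2]],
                      weight = corr[hit],
                      stringsAsFactors = FALSE)
  isolated <- setdiff(ids, unique(c(edges$from, edges$to)))
  g <- list(nodes = ids, edges = edges, cutoff = corr_cutoff,
            isolated = isolated,
            excluded = attr(corr, "excluded") %||% character(0))
  class(g) <- "coexp_graph"
  g
}

#' @export
print.coexp_graph <- function(x, ...) {
  cat(sprintf("Coexpression graph: %d nodes, %d edges (r >= %g), %d isolated\n",
              length(x$nodes), nrow(x$edges), x$cutoff, length(x$isolated)))
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = data.frame(name = graph$nodes))
}

#' Connected components of the coexpression graph
#'
#' Partitions the non-isolated nodes into connected components, ordered
#' by decreasing size (ties broken by the lexicographically smallest
#' member id, so the ordering is reproducible). Isolated nodes are not
#' components; together with the components they cover the node set.
#'
#' @param graph a `coexp_graph`.
#' @return list of character vectors of member ids, largest first, with
#'   attribute `isolated`.
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "coexp_graph"))
  connected <- setdiff(graph$nodes, graph$isolated)
  if (!length(connected)) {
    out <- list()
    attr(out, "isolated") <- graph$isolated
    return(out)
  }
  ig <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                      vertices = data.frame(name = connected))
  memb <- igraph::components(ig)$membership
  comps <- split(names(memb), memb)
  comps <- lapply(comps, function(v) sort(v))
  ord <- order(-lengths(comps), vapply(comps, `[`, character(1), 1))
  comps <- unname(comps[ord])
  attr(comps, "isolated") <- graph$isolated
  comps
}

#' Export the edge list as TSV
#'
#' Writes `feature_a<TAB>feature_b<TAB>r` with r formatted to 6
#' decimals.
#'
#' @param graph a `coexp_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "coexp_graph"))
  df <- data.frame(feature_a = graph$edges$from,
                   feature_b = graph$edges$to,
                   r = sprintf("%.6f", graph$edges$weight),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the graph as GraphML
#'
#' Edge weights are stored in the standard `weight` edge attribute.
#'
#' @param graph a `coexp_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "coexp_graph"))
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}
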