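#' Column-stochastic transition matrix of a weighted graph
#'
#' Builds the Markov transition matrix underlying MCL: entry (i, j) is
#' proportional to the edge weight w(i, j), with self-loops added before
#' column normalization. The default self-loop policy gives every node a
#' loop equal to its maximum incident edge weight, the usual damping of
#' the random walk's periodicity on weighted graphs (isolated nodes get
#' a unit loop). Policy `"unit"` adds a loop of 1 to every node;
#' `"none"` adds no loops and errors if any node then has zero total
#' weight.
#'
#' @param graph a `coexp_graph`, or a non-negative symmetric numeric
#'   matrix with dimnames, treated as the weighted adjacency matrix.
#' @param self_loop one of `"max"`, `"unit"`, `"none"`.
#' @return dense column-stochastic matrix (columns sum to 1 within
#'   1e-12).
#' @export
stochastic_matrix <- function(graph, self_loop = c("max", "unit", "none")) {
  self_loop <- match.arg(self_loop)
  W <- if (inherits(graph, "coexp_graph")) adjacency_matrix(graph) else graph
  if (!is.matrix(W) || nrow(W) != ncol(W) || nrow(W) == 0)
    format_error("need a non-empty square adjacency matrix or coexp_graph")
  if (any(W < 0)) format_error("edge weights must be non-negative")
  diag(W) <- switch(self_loop,
    max = {
      offdiag_max <- apply(`diag<-`(W, 0), 2, max)
      ifelse(offdiag_max > 0, offdiag_max, 1)
    },
    unit = diag(W) + 1,
    none = diag(W)
  )
  cs <- colSums(W)
  if (any(cs == 0))
    format_error("node(s) with zero total weight and no self-loop")
  sweep(W, 2, cs, "/")
}

adjacency_matrix <- function(graph) {
  n <- length(graph$nodes)
  W <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, graph$nodes)
    j <- match(graph$edges$to, graph$nodes)
    W[cbind(i, j)] <- graph$edges$weight
    W[cbind(j, i)] <- graph$edges$weight
  }
  W
}

#' MCL inflation operator
#'
#' Raises every entry of a column-stochastic matrix to the inflation
#' power and renormalizes each column to sum 1. Inflation must exceed 1;
#' it is the granularity control of MCL.
#'
#' @param m column-stochastic matrix.
#' @param inflation exponent > 1.
#' @return column-stochastic matrix of the same shape.
#' @export
inflate <- function(m, inflation) {
  if (!is.numeric(inflation) || length(inflation) != 1 || inflation <= 1)
    config_error("'inflation' must be a single number > 1")
  m <- m^inflation
  sweep(m, 2, colSums(m), "/")
}

# One dense MCL run on an adjacency matrix block. Returns the converged
# flow matrix plus iteration diagnostics.
mcl_dense <- function(W, cfg) {
  M <- stochastic_matrix(W, self_loop = "max")
  deltas <- numeric(0)
  for (it in seq_len(cfg$max_iterations)) {
    prev <- M
    # expansion: matrix self-multiplication to the expansion power
    E <- M
    for (k in seq_len(cfg$expansion_power - 1L)) E <- E %*% M
    M <- inflate(E, cfg$inflation)
    # prune tiny flow, then restore column stochasticity
    M[M < cfg$prune_threshold] <- 0
    M <- sweep(M, 2, colSums(M), "/")
    delta <- max(abs(M - prev))
    deltas[it] <- delta
    if (delta < cfg$convergence_tol)
      return(list(M = M, iterations = it, deltas = deltas, converged = TRUE))
  }
  stop(errorCondition(
    sprintf("MCL did not converge in %d iterations (last delta %.3g)",
            cfg$max_iterations, deltas[length(deltas)]),
    class = c("coexnet_mcl_error", "error"),
    iterations = cfg$max_iterations, deltas = deltas))
}

# Read attractor systems off a converged flow matrix. Attractors are
# nodes with positive self-flow; each attractor row's support is a
# system; systems sharing an attractor are merged. Non-attractor nodes
# may still sit in several merged systems; that overlap is resolved
# later by extract_clusters().
interpret_attractors <- function(M) {
  ids <- colnames(M)
  att <- which(diag(M) > 0)
  if (!length(att)) return(list(ids))  # degenerate; treat block as one system
  supports <- lapply(att, function(i) which(M[i, ] > 0))
  # merge systems whose attractor sets overlap (union-find over systems)
  parent <- seq_along(supports)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  att_sets <- lapply(supports, function(s) intersect(s, att))
  for (a in seq_along(supports)) {
    for (b in seq_len(a - 1L)) {
      if (length(intersect(att_sets[[a]], att_sets[[b]])))
        parent[find(a)] <- find(b)
    }
  }
  roots <- vapply(seq_along(supports), find, integer(1))
  merged <- lapply(split(seq_along(supports), roots), function(sys)
    sort(unique(unlist(supports[sys]))))
  lapply(unname(merged), function(ix) ids[ix])
}

#' Markov clustering of a coexpression graph
#'
#' Runs the Markov Cluster algorithm: the edge-weighted transition
#' matrix (self-loops at each node's maximum incident weight) is
#' alternately expanded (matrix powering) and inflated (elementwise
#' powering plus column renormalization), with entries below the prune
#' threshold zeroed, until the largest elementwise change falls below
#' the convergence tolerance. Clusters are the supports of attractor
#' rows of the converged flow matrix. Each connected component is
#' processed independently, which is equivalent to running on the whole
#' (block-diagonal) graph; isolated nodes become singleton systems.
#'
#' @param graph a `coexp_graph`.
#' @param config a [coexp_config()]; `inflation`, `expansion_power`,
#'   `prune_threshold`, `convergence_tol` and `max_iterations` are used.
#' @return object of class `mcl_raw`: list with `systems` (list of
#'   member-id vectors, possibly overlapping until resolved by
#'   [extract_clusters()]), `iterations` (per-component data frame) and
#'   the parameters used.
#' @seealso [extract_clusters()]
#' @export
mcl <- function(graph, config = coexp_config()) {
  stopifnot(inherits(graph, "coexp_graph"))
  validate_config(config)
  comps <- connected_components(graph)
  adj <- adjacency_matrix(graph)
  systems <- list()
  iters <- data.frame(component = integer(0), size = integer(0),
                      iterations = integer(0))
  for (ci in seq_along(comps)) {
    members <- comps[[ci]]
    W <- adj[members, members, drop = FALSE]
    fit <- mcl_dense(W, config)
    systems <- c(systems, interpret_attractors(fit$M))
    iters <- rbind(iters, data.frame(component = ci, size = length(members),
                                     iterations = fit$iterations))
  }
  systems <- c(systems, lapply(attr(comps, "isolated"), function(x) x))
  out <- list(systems = systems, iterations = iters,
              nodes = graph$nodes,
              inflation = config$inflation, cutoff = graph$cutoff,
              min_cluster_size = config$min_cluster_size)
  class(out) <- "mcl_raw"
  out
}

#' @export
print.mcl_raw <- function(x, ...) {
  cat(sprintf("MCL raw clustering: %d systems over %d nodes (inflation %g)\n",
              length(x$systems), length(x$nodes), x$inflation))
  invisible(x)
}

#' Resolve, filter and name MCL clusters
#'
#' Turns the raw attractor systems into a disjoint, size-ordered,
#' named cluster set. A node claimed by several systems is assigned to
#' the larger one, ties going to the system whose lexicographically
#' smallest member id sorts first (deterministic, seed-free). Systems
#' smaller than `min_cluster_size` after resolution are dropped and
#' their members reported as unclustered. Survivors are sorted by
#' decreasing size (same tie-break) and named `Cluster001`,
#' `Cluster002`, ... largest first.
#'
#' @param raw an `mcl_raw` object from [mcl()].
#' @param min_cluster_size smallest retained cluster (default from the
#'   run's configuration).
#' @return object of class `cluster_set`: list with `clusters` (named
#'   list of member-id vectors), `unclustered` (character vector) and
#'   `provenance` (inflation, cutoff, min_cluster_size).
#' @export
extract_clusters <- function(raw, min_cluster_size = raw$min_cluster_size) {
  stopifnot(inherits(raw, "mcl_raw"))
  if (min_cluster_size < 1) config_error("'min_cluster_size' must be >= 1")
  systems <- lapply(raw$systems, function(v) sort(unique(v)))
  # resolve overlapping membership: larger system wins, then the system
  # with the lexicographically smallest member id
  if (length(systems)) {
    first_id <- vapply(systems, `[`, character(1), 1)
    rank <- order(-lengths(systems), first_id)
    prio <- integer(length(systems)); prio[rank] <- seq_along(systems)
    assigned <- character(0)
    for (s in order(prio)) {
      systems[[s]] <- setdiff(systems[[s]], assigned)
      assigned <- c(assigned, systems[[s]])
    }
  }
  sizes <- lengths(systems)
  keep <- sizes >= min_cluster_size & sizes > 0
  unclustered <- sort(unique(unlist(systems[!keep])))
  systems <- systems[keep]
  if (length(systems)) {
    first_id <- vapply(systems, `[`, character(1), 1)
    systems <- systems[order(-lengths(systems), first_id)]
    names(systems) <- sprintf("Cluster%03d", seq_along(systems))
  } else {
    names(systems) <- character(0)
  }
  out <- list(clusters = systems, unclustered = unclustered,
              provenance = list(inflation = raw$inflation,
                                cutoff = raw$cutoff,
                                min_cluster_size = min_cluster_size))
  class(out) <- "cluster_set"
  out
}

#' @export
print.cluster_set <- function(x, ...) {
  sz <- lengths(x$clusters)
  cat(sprintf("Cluster set: %d clusters (sizes %s), %d unclustered nodes\n",
              length(sz),
              if (length(sz)) paste(range(sz)[2:1], collapse = " down to ")
              else "-",
              length(x$unclustered)))
  if (length(sz)) {
    show <- utils::head(sz, 10)
    cat(paste(sprintf("  %s: %d members", names(show), show), collapse = "\n"),
        "\n")
    if (length(sz) > 10) cat(sprintf("  ... and %d more\n", length(sz) - 10))
  }
  invisible(x)
}

#' Cluster membership as a data frame
#'
#' @param x a `cluster_set`.
#' @return data frame with `feature_id` and `cluster_id` (`NA` for
#'   unclustered features).
#' @export
membership_table <- function(x) {
  stopifnot(inherits(x, "cluster_set"))
  df <- data.frame(
    feature_id = c(unlist(x$clusters, use.names = FALSE), x$unclustered),
    cluster_id = c(rep(names(x$clusters), lengths(x$clusters)),
                   rep(NA_character_, length(x$unclustered))),
    stringsAsFactors = FALSE)
  df[order(df$feature_id), , drop = FALSE]
}

#' Write cluster membership and size summaries as TSV
#'
#' Produces `feature_id<TAB>cluster_id` (unclustered nodes with
#' cluster_id `NA`) and, for the summary file, `cluster_id<TAB>size`.
#'
#' @param x a `cluster_set`.
#' @param path membership output path.
#' @param summary_path optional size-summary output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(x, path, summary_path = NULL) {
  df <- membership_table(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (!is.null(summary_path)) {
    utils::write.table(
      data.frame(cluster_id = names(x$clusters), size = lengths(x$clusters)),
      summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
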