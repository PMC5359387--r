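# Independent reference implementations used as oracles. Deliberately
# written as plain loops, separate from the package code paths.

# Pearson r from the product-moment formula, one pair at a time.
ref_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# Edge set by O(n^2) loop: recompute every pairwise r and threshold it.
ref_edge_set <- function(expr, cutoff) {
  ids <- rownames(expr)
  out <- character(0)
  for (i in seq_len(nrow(expr) - 1)) {
    for (j in (i + 1):nrow(expr)) {
      r <- ref_pearson(expr[i, ], expr[j, ])
      if (r >= cutoff)
        out <- c(out, paste(sort(c(ids[i], ids[j])), collapse = "|"))
    }
  }
  sort(out)
}

edge_key <- function(graph) {
  if (!nrow(graph$edges)) return(character(0))
  sort(apply(graph$edges[c("from", "to")], 1, function(e)
    paste(sort(e), collapse = "|")))
}

# Union-find connected components over an edge list.
ref_components <- function(nodes, from, to) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(from)) {
    ra <- find(from[k]); rb <- find(to[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  comps <- split(nodes, roots)
  comps <- lapply(comps, sort)
  comps <- comps[vapply(comps, function(cc)
    any(cc %in% c(from, to)), logical(1))]
  unname(comps[order(-lengths(comps), vapply(comps, `[`, character(1), 1))])
}

# Reference dense MCL: same algorithm contract, independent straight-line
# coding (explicit column loops, repeat-until loop, its own attractor
# resolution). Returns the resolved partition as a list of id vectors,
# singletons included.
ref_mcl_partition <- function(W, inflation = 2.2, expansion = 2,
                              prune = 1e-5, tol = 1e-8, max_iter = 200) {
  n <- nrow(W)
  ids <- rownames(W)
  A <- W
  for (j in seq_len(n)) {
    inc <- A[, j]
    inc[j] <- 0
    A[j, j] <- if (max(inc) > 0) max(inc) else 1
  }
  M <- A
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  it <- 0
  repeat {
    it <- it + 1
    old <- M
    P <- M
    for (k in seq_len(expansion - 1)) P <- P %*% M
    Q <- P^inflation
    for (j in seq_len(n)) Q[, j] <- Q[, j] / sum(Q[, j])
    Q[Q < prune] <- 0
    for (j in seq_len(n)) Q[, j] <- Q[, j] / sum(Q[, j])
    M <- Q
    if (max(abs(M - old)) < tol || it >= max_iter) break
  }
  stopifnot(it < max_iter)
  att <- which(diag(M) > 0)
  if (!length(att)) return(list(sort(ids)))
  systems <- lapply(att, function(i) which(M[i, ] > 0))
  # merge systems sharing an attractor node
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (a in seq_along(systems)) {
      if (is.null(systems[[a]])) next
      for (b in seq_along(systems)) {
        if (b <= a || is.null(systems[[b]])) next
        if (length(intersect(intersect(systems[[a]], att),
                             intersect(systems[[b]], att)))) {
          systems[[a]] <- sort(union(systems[[a]], systems[[b]]))
          systems[[b]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  systems <- Filter(Negate(is.null), systems)
  systems <- lapply(systems, function(s) sort(ids[s]))
  # resolve residual overlap: larger system first, then lexicographic
  ord <- order(-lengths(systems), vapply(systems, `[`, character(1), 1))
  taken <- character(0)
  out <- list()
  for (s in ord) {
    mem <- setdiff(systems[[s]], taken)
    if (length(mem)) {
      out[[length(out) + 1]] <- mem
      taken <- c(taken, mem)
    }
  }
  for (x in setdiff(ids, taken)) out[[length(out) + 1]] <- x
  out
}

# canonical form of a partition (list of member vectors) for comparison
canon_partition <- function(parts) {
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, character(1), 1))]
}

# membership of a cluster_set as a partition over given nodes
fit_partition <- function(cs, min_size = 1) {
  parts <- unname(cs$clusters)
  parts <- c(parts, as.list(cs$unclustered))
  canon_partition(parts)
}

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# C(N, n) draws.
ref_hyper_upper <- function(N, K, n, k) {
  marked <- c(rep(TRUE, K), rep(FALSE, N - K))
  draws <- utils::combn(N, n)
  hits <- 0
  for (c_i in seq_len(ncol(draws)))
    if (sum(marked[draws[, c_i]]) >= k) hits <- hits + 1
  hits / ncol(draws)
}

# random weighted graph as a coexp_graph (weights in correlation range)
rand_graph <- function(n, p_edge, seed, wmin = 0.9, wmax = 1) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  from <- character(0); to <- character(0); w <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) {
        from <- c(from, ids[i]); to <- c(to, ids[j])
        w <- c(w, stats::runif(1, wmin, wmax))
      }
    }
  }
  g <- list(nodes = ids,
            edges = data.frame(from = from, to = to, weight = w,
                               stringsAsFactors = FALSE),
            cutoff = wmin,
            isolated = setdiff(ids, c(from, to)),
            excluded = character(0))
  class(g) <- "coexp_graph"
  g
}

# graph made of vertex-disjoint cliques, with optional extra bridges
clique_graph <- function(sizes, bridges = NULL, weight = 1) {
  ids <- character(0); from <- character(0); to <- character(0)
  offset <- 0
  for (s in sizes) {
    mem <- sprintf("v%02d", offset + seq_len(s))
    ids <- c(ids, mem)
    if (s > 1) {
      pairs <- utils::combn(mem, 2)
      from <- c(from, pairs[1, ]); to <- c(to, pairs[2, ])
    }
    offset <- offset + s
  }
  if (!is.null(bridges)) {
    from <- c(from, bridges[, 1]); to <- c(to, bridges[, 2])
  }
  g <- list(nodes = ids,
            edges = data.frame(from = from, to = to,
                               weight = rep(weight, length(from)),
                               stringsAsFactors = FALSE),
            cutoff = 0.9,
            isolated = setdiff(ids, c(from, to)),
            excluded = character(0))
  class(g) <- "coexp_graph"
  g
}

cluster_lookup_acc <- function(cs) {
  stats::setNames(rep(names(cs$clusters), lengths(cs$clusters)),
                  unlist(cs$clusters, use.names = FALSE))
}

# recovered-vs-truth labels for a synthetic dataset fit
truth_labels <- function(truth) {
  stats::setNames(truth$module, truth$gene_id)
}

fit_labels <- function(fit, gene_ids) {
  mt <- membership_table(fit$clusters)
  lab <- stats::setNames(mt$cluster_id, mt$feature_id)[gene_ids]
  lab[is.na(lab)] <- "unclustered"
  lab
}

run_synth_fit <- function(sim, config = coexp_config()) {
  suppressWarnings(coexp_cluster(sim$expr, sim$metadata, config))
}
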