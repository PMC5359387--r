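test_that("stochastic_matrix normalizes columns with the documented self-loop policies", {
  # single edge A-B, weight 1, unit self-loops -> each column (0.5, 0.5)
  W <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  M <- stochastic_matrix(W, self_loop = "unit")
  expect_equal(unname(M), matrix(0.5, 2, 2))
  # same under "max": max incident weight is also 1
  expect_equal(stochastic_matrix(W, self_loop = "max"), M)

  # star K1,3 with unit weights: hub column is (0.25, 0.25, 0.25, 0.25)
  ids <- c("hub", "l1", "l2", "l3")
  S <- matrix(0, 4, 4, dimnames = list(ids, ids))
  S["hub", c("l1", "l2", "l3")] <- 1
  S[c("l1", "l2", "l3"), "hub"] <- 1
  Ms <- stochastic_matrix(S, self_loop = "unit")
  expect_equal(unname(Ms[, "hub"]), rep(0.25, 4))

  # normalization contract on random weighted graphs
  for (seed in 1:3) {
    g <- rand_graph(25, 0.15, seed)
    M <- stochastic_matrix(g)
    expect_lte(max(abs(colSums(M) - 1)), 1e-12)
    expect_true(all(M >= 0))
  }

  # zero-weight node without self-loop errors
  Z <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(stochastic_matrix(Z, self_loop = "none"), "zero total weight")
})

test_that("inflation raises entries to a power and renormalizes", {
  m <- matrix(c(0.5, 0.5), 2, 1)
  expect_equal(inflate(m, 2.2), m)  # symmetric fixed point
  m2 <- matrix(c(0.8, 0.2), 2, 1)
  expect_equal(inflate(m2, 2), matrix(c(0.64, 0.04) / 0.68, 2, 1))
  expect_error(inflate(m, 1), "> 1")
  expect_error(inflate(m, 0.5), "> 1")

  # naive elementwise-power-then-normalize loop oracle
  set.seed(41)
  col <- stats::runif(10)
  col <- col / sum(col)
  got <- inflate(matrix(col, ncol = 1), 2.2)
  pow <- numeric(10)
  for (i in 1:10) pow[i] <- col[i]^2.2
  expect_equal(as.numeric(got), pow / sum(pow), tolerance = 1e-12)
})

test_that("MCL separates disconnected cliques and keeps single cliques whole", {
  cfg <- coexp_config()
  g <- clique_graph(c(4, 4))
  cs <- extract_clusters(mcl(g, cfg), min_cluster_size = 1)
  expect_length(cs$clusters, 2)
  expect_identical(sort(unname(lengths(cs$clusters))), c(4L, 4L))
  expect_setequal(unlist(cs$clusters), g$nodes)

  g6 <- clique_graph(c(6))
  cs6 <- extract_clusters(mcl(g6, cfg), min_cluster_size = 1)
  expect_length(cs6$clusters, 1)
  expect_identical(sort(cs6$clusters[[1]]), sort(g6$nodes))
})

test_that("MCL splits two 4-cliques joined by a bridge, matching the dense reference", {
  bridge <- matrix(c("v01", "v05"), 1, 2)
  g <- clique_graph(c(4, 4), bridges = bridge)
  cfg <- coexp_config()
  cs <- extract_clusters(mcl(g, cfg), min_cluster_size = 1)
  expect_length(cs$clusters, 2)
  expect_identical(unname(lengths(cs$clusters)), c(4L, 4L))

  W <- matrix(0, 8, 8, dimnames = list(g$nodes, g$nodes))
  W[cbind(g$edges$from, g$edges$to)] <- g$edges$weight
  W[cbind(g$edges$to, g$edges$from)] <- g$edges$weight
  ref <- ref_mcl_partition(W, inflation = cfg$inflation)
  expect_identical(fit_partition(cs), canon_partition(ref))
})

test_that("columns stay stochastic through expansion, inflation and pruning", {
  cfg <- coexp_config()
  g <- rand_graph(30, 0.12, 7)
  M <- stochastic_matrix(g)
  for (it in 1:12) {
    M <- M %*% M
    expect_lte(max(abs(colSums(M) - 1)), 1e-10)
    M <- inflate(M, cfg$inflation)
    expect_lte(max(abs(colSums(M) - 1)), 1e-10)
    M[M < cfg$prune_threshold] <- 0
    M <- sweep(M, 2, colSums(M), "/")
    expect_lte(max(abs(colSums(M) - 1)), 1e-10)
  }
})

test_that("MCL partitions match the independent dense reference on random graphs", {
  cfg <- coexp_config()
  for (seed in c(2, 5, 9, 12, 21)) {
    n <- 20 + (seed %% 4) * 10  # 20..50 nodes
    g <- rand_graph(n, 0.12, seed)
    cs <- extract_clusters(mcl(g, cfg), min_cluster_size = 1)
    W <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
    if (nrow(g$edges)) {
      W[cbind(g$edges$from, g$edges$to)] <- g$edges$weight
      W[cbind(g$edges$to, g$edges$from)] <- g$edges$weight
    }
    conn <- setdiff(g$nodes, g$isolated)
    ref <- ref_mcl_partition(W[conn, conn, drop = FALSE],
                             inflation = cfg$inflation)
    ref <- c(ref, as.list(g$isolated))
    expect_identical(fit_partition(cs), canon_partition(ref),
                     info = sprintf("seed %d", seed))
  }
})

test_that("node relabeling permutes clusters but preserves sizes", {
  cfg <- coexp_config()
  g <- rand_graph(30, 0.15, 3)
  cs <- extract_clusters(mcl(g, cfg), min_cluster_size = 1)
  # relabel by reversing ids
  relab <- stats::setNames(rev(g$nodes), g$nodes)
  g2 <- g
  g2$nodes <- unname(relab[g$nodes])
  g2$edges$from <- unname(relab[g$edges$from])
  g2$edges$to <- unname(relab[g$edges$to])
  g2$isolated <- unname(relab[g$isolated])
  cs2 <- extract_clusters(mcl(g2, cfg), min_cluster_size = 1)
  expect_identical(sort(unname(lengths(cs$clusters))),
                   sort(unname(lengths(cs2$clusters))))
  # structure is preserved: translating the original partition gives the new one
  translated <- canon_partition(lapply(unname(cs$clusters),
                                       function(v) unname(relab[v])))
  expect_identical(fit_partition(cs2), translated)
})

test_that("running per connected component equals running on the whole graph", {
  cfg <- coexp_config()
  g <- clique_graph(c(5, 4, 3))
  whole <- extract_clusters(mcl(g, cfg), min_cluster_size = 1)
  parts <- list()
  for (comp in connected_components(g)) {
    sub <- g
    keep <- g$edges$from %in% comp & g$edges$to %in% comp
    sub$nodes <- comp
    sub$edges <- g$edges[keep, , drop = FALSE]
    sub$isolated <- character(0)
    parts <- c(parts, unname(extract_clusters(mcl(sub, cfg),
                                              min_cluster_size = 1)$clusters))
  }
  expect_identical(fit_partition(whole), canon_partition(parts))
})

test_that("higher inflation does not merge clusters found at lower inflation", {
  g <- clique_graph(c(5, 5, 4), bridges = rbind(c("v01", "v06"),
                                                c("v06", "v11")))
  low <- extract_clusters(mcl(g, coexp_config(inflation = 1.6)),
                          min_cluster_size = 1)
  high <- extract_clusters(mcl(g, coexp_config(inflation = 3)),
                           min_cluster_size = 1)
  # each high-inflation cluster sits inside one low-inflation cluster
  lookup_low <- stats::setNames(rep(names(low$clusters),
                                    lengths(low$clusters)),
                                unlist(low$clusters))
  for (cl in high$clusters) {
    hosts <- unique(lookup_low[cl])
    hosts <- hosts[!is.na(hosts)]
    expect_lte(length(hosts), 1)
  }
})

test_that("cluster extraction drops small systems, orders by size and names deterministically", {
  raw <- structure(list(
    systems = list(sprintf("j%02d", 1:10), sprintf("a%02d", 1:7),
                   sprintf("b%02d", 1:7), sprintf("z%02d", 1:4)),
    iterations = data.frame(), nodes = character(0),
    inflation = 2.2, cutoff = 0.9, min_cluster_size = 5L),
    class = "mcl_raw")
  cs <- extract_clusters(raw, 5)
  expect_identical(names(cs$clusters), c("Cluster001", "Cluster002", "Cluster003"))
  expect_identical(lengths(cs$clusters),
                   c(Cluster001 = 10L, Cluster002 = 7L, Cluster003 = 7L))
  # size tie broken by lexicographically smallest member
  expect_identical(cs$clusters$Cluster002[1], "a01")
  expect_identical(cs$unclustered, sprintf("z%02d", 1:4))

  # all systems below the minimum: empty set, everything unclustered
  cs_empty <- extract_clusters(raw, 20)
  expect_length(cs_empty$clusters, 0)
  expect_length(cs_empty$unclustered, 28)

  # overlapping membership goes to the larger system
  raw$systems <- list(c("a", "b", "c", "d", "x"), c("x", "y", "z"))
  cs_ov <- extract_clusters(raw, 1)
  expect_identical(cs_ov$clusters$Cluster001, c("a", "b", "c", "d", "x"))
  expect_identical(cs_ov$clusters$Cluster002, c("y", "z"))
  mt <- membership_table(cs_ov)
  expect_false(anyDuplicated(mt$feature_id) > 0)
})

test_that("non-convergence raises an error carrying iteration diagnostics", {
  # bridged cliques need several iterations; a bare clique is a fixed point
  g <- clique_graph(c(4, 4), bridges = matrix(c("v01", "v05"), 1, 2))
  err <- tryCatch(mcl(g, coexp_config(max_iterations = 2)),
                  error = identity)
  expect_s3_class(err, "coexnet_mcl_error")
  expect_identical(err$iterations, 2L)
  expect_length(err$deltas, 2)
})

test_that("cluster TSV output lists members and sizes, with NA for unclustered", {
  g <- clique_graph(c(5, 3))
  cs <- extract_clusters(mcl(g, coexp_config()), 5)
  f <- tempfile(); fs <- tempfile()
  write_clusters(cs, f, fs)
  mem <- utils::read.delim(f)
  expect_identical(sum(is.na(mem$cluster_id)), 3L)
  expect_identical(sum(mem$cluster_id == "Cluster001", na.rm = TRUE), 5L)
  sz <- utils::read.delim(fs)
  expect_identical(sz$size, 5L)
})
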