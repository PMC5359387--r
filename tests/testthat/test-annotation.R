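toy_matrix <- function(vals, conds = sprintf("t%d", seq_len(ncol(vals)))) {
  dimnames(vals) <- list(sprintf("g%d", seq_len(nrow(vals))), conds)
  vals
}

test_that("tissue specificity is called at the inclusive fold boundary", {
  # cluster mean 500 in tissue A, 100 in each of the others: exactly 5x
  x <- toy_matrix(matrix(c(500, 100, 100, 100), 1, 4),
                  conds = c("A", "B", "C", "D"))
  call <- tissue_specificity(x, "g1", fold_threshold = 5)
  expect_identical(call$called, "A")

  # just under the boundary: no call
  x2 <- toy_matrix(matrix(c(499, 100, 100, 100), 1, 4),
                   conds = c("A", "B", "C", "D"))
  expect_length(tissue_specificity(x2, "g1", 5)$called, 0)

  # flat profile: fold 1 everywhere, never called at 5x
  flat <- toy_matrix(matrix(200, 2, 4))
  expect_length(tissue_specificity(flat, c("g1", "g2"), 5)$called, 0)

  # zero reference with positive numerator counts as a call
  z <- toy_matrix(matrix(c(10, 0, 0, 0), 1, 4))
  expect_identical(tissue_specificity(z, "g1", 5)$called, "t1")

  expect_error(tissue_specificity(flat, character(0)), "no members")
})

test_that("specificity of random clusters matches a per-condition loop oracle", {
  set.seed(19)
  for (rep in 1:5) {
    x <- toy_matrix(matrix(stats::rexp(8 * 6, 1 / 300), 8, 6))
    members <- sample(rownames(x), 4)
    fold <- sample(c(1, 2, 5), 1)
    got <- tissue_specificity(x, members, fold)$called
    means <- colMeans(x[members, ])
    manual <- character(0)
    for (ci in seq_along(means)) {
      others <- mean(means[-ci])
      if (means[ci] >= fold * others) manual <- c(manual, names(means)[ci])
    }
    expect_identical(got, manual)
  }
})

test_that("raising the fold threshold never adds specificity calls", {
  set.seed(29)
  x <- toy_matrix(matrix(stats::rexp(10 * 5, 1 / 200), 10, 5))
  prev <- tissue_specificity(x, rownames(x)[1:5], 1)$called
  for (fold in c(2, 3, 5, 8)) {
    cur <- tissue_specificity(x, rownames(x)[1:5], fold)$called
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("the max-reference variant compares against the largest other condition", {
  x <- toy_matrix(matrix(c(500, 250, 10, 10), 1, 4))
  # vs mean of others (90): 500 >= 5*90 -> called
  expect_identical(tissue_specificity(x, "g1", 5, reference = "mean")$called, "t1")
  # vs max of others (250): 500 < 1250 -> not called
  expect_length(tissue_specificity(x, "g1", 5, reference = "max")$called, 0)
})

test_that("annotation scores reproduce published per-cluster values from their counts", {
  tab <- published_go_counts()
  expect_identical(nrow(tab), 26L)
  expect_true(all(tab$n0 + tab$n1 + tab$n2 + tab$n3 == tab$n_genes))
  for (i in seq_len(nrow(tab))) {
    built <- annotations_from_counts(tab$n0[i], tab$n1[i], tab$n2[i], tab$n3[i])
    s <- annotation_score(built$genes, built$annotations, tab$cluster_id[i])
    expect_identical(unname(s$counts),
                     c(tab$n0[i], tab$n1[i], tab$n2[i], tab$n3[i]))
    expect_equal(s$score_rounded, tab$score[i], tolerance = 0,
                 info = tab$cluster_id[i])
  }
})

test_that("annotation score is permutation invariant, bounded, and handles absent genes", {
  built <- annotations_from_counts(2, 3, 4, 5)
  s1 <- annotation_score(built$genes, built$annotations)
  set.seed(3)
  s2 <- annotation_score(sample(built$genes), built$annotations)
  expect_equal(s1$score, s2$score)
  expect_gte(s1$score, 0); expect_lte(s1$score, 3)

  # score 3 iff every gene annotated in all three namespaces
  all3 <- annotations_from_counts(0, 0, 0, 6)
  expect_equal(annotation_score(all3$genes, all3$annotations)$score, 3)

  # duplicates collapse to unique genes
  dup <- annotation_score(rep(built$genes, 2), built$annotations)
  expect_identical(dup$n_genes, 14L)

  # absent genes are n0 and messaged
  expect_message(
    s3 <- annotation_score(c(built$genes, "ghost1"), built$annotations),
    "absent")
  expect_identical(unname(s3$counts["n0"]), 3L)
})

test_that("score_clusters mirrors the published table layout and collapses probes", {
  cs <- structure(list(
    clusters = list(Cluster001 = c("p1", "p2", "p3"), Cluster002 = c("p4", "p5")),
    unclustered = character(0),
    provenance = list()), class = "cluster_set")
  ann <- annotation_table(c("gA", "gB", "gC"),
                          has_bp = c(TRUE, TRUE, FALSE),
                          has_mf = c(TRUE, FALSE, FALSE),
                          has_cc = c(TRUE, TRUE, FALSE))
  probe_map <- c(p1 = "gA", p2 = "gA", p3 = "gB", p4 = "gC", p5 = "gB")
  out <- score_clusters(cs, ann, probe_to_gene = probe_map)
  # Cluster001 -> unique genes gA (3 namespaces), gB (2)
  expect_identical(out$n_genes, c(2L, 2L))
  expect_equal(out$score[1], 2.50)
  expect_equal(out$score[2], 1.00)  # gC (0) and gB (2)
  expect_identical(out$pct0, c(0, 50))
})

test_that("hypergeometric enrichment p-values match exhaustive enumeration", {
  # N=10, K=5, n=2, k=2 -> C(5,2)/C(10,2) = 10/45
  bg <- sprintf("g%02d", 1:10)
  term <- list(T1 = bg[1:5])
  res <- enrich_cluster(bg[1:2], term, bg, alpha = 0.05)
  expect_equal(res$p_raw, 10 / 45, tolerance = 1e-12)
  expect_equal(res$p_raw, ref_hyper_upper(10, 5, 2, 2), tolerance = 1e-12)

  # random small instances against the combinatorial oracle
  set.seed(47)
  for (rep in 1:10) {
    N <- sample(6:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    bgx <- sprintf("x%02d", 1:N)
    cluster <- sample(bgx, n)
    marked <- sample(bgx, K)
    k <- length(intersect(cluster, marked))
    if (k == 0) next
    res <- enrich_cluster(cluster, list(tm = marked), bgx)
    expect_equal(res$p_raw, ref_hyper_upper(N, K, n, k), tolerance = 1e-12,
                 info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
  }
})

test_that("Bonferroni correction, significance calls and ordering follow the contract", {
  bg <- sprintf("g%02d", 1:20)
  terms <- list(strong = bg[1:5], weak = c(bg[1], bg[10:14]),
                everything = bg, untouched = bg[16:20])
  res <- enrich_cluster(bg[1:5], terms, bg, alpha = 0.05)
  # only terms overlapping the cluster are tested
  expect_setequal(res$term, c("strong", "weak", "everything"))
  expect_identical(res$p_bonferroni, pmin(1, res$p_raw * 3))
  expect_identical(res$significant, res$p_bonferroni <= 0.05)
  expect_true(all(diff(res$p_bonferroni) >= 0))
  # a term annotating the whole background is never significant
  expect_equal(res$p_raw[res$term == "everything"], 1)
  expect_false(res$significant[res$term == "everything"])
  # hand computation: strong has k=5,K=5,n=5,N=20
  p_hand <- 1 / choose(20, 5)
  expect_equal(res$p_raw[res$term == "strong"], p_hand, tolerance = 1e-12)
  expect_true(res$significant[res$term == "strong"])

  expect_error(enrich_cluster(bg, terms, bg[1:5]), "smaller")
  expect_error(enrich_cluster(c(bg[1], "alien"), terms, bg), "subset")
})

test_that("guilt-by-association transfers labels only to unannotated members", {
  ann <- annotation_table(c("known1", "known2"),
                          has_bp = TRUE, has_mf = TRUE, has_cc = TRUE)
  members <- c("known1", "known2", "dark1", "dark2", "dark3")
  spec <- structure(list(cluster_id = "Cluster001", called = "brain",
                         fold_threshold = 5, reference = "mean"),
                    class = "specificity_call")
  enr <- data.frame(term = c("synapse", "ribosome"),
                    significant = c(TRUE, FALSE))
  out <- transfer_annotations(members, spec, enr, ann, "Cluster001")
  expect_identical(sort(unique(out$gene_id)), c("dark1", "dark2", "dark3"))
  expect_setequal(unique(out$label), c("brain", "synapse"))
  expect_identical(nrow(out), 6L)  # 3 genes x 2 labels
  expect_true(all(out$prediction))

  # nothing to transfer when there is no call and no significant term
  spec0 <- structure(list(called = character(0)), class = "specificity_call")
  enr0 <- data.frame(term = character(0), significant = logical(0))
  expect_identical(nrow(transfer_annotations(members, spec0, enr0, ann)), 0L)
})
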