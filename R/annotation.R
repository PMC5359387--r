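#' Construct a gene annotation table
#'
#' Per-gene presence/absence flags for the three Gene Ontology
#' namespaces (biological process, molecular function, cellular
#' component). A gene scores 1 for a namespace as soon as it has at
#' least one term there, no matter how minimal.
#'
#' @param gene_id character vector of unique gene ids.
#' @param has_bp,has_mf,has_cc logical vectors.
#' @param term_sets optional named list (`bp`, `mf`, `cc`) of per-gene
#'   term-id lists; when supplied, each flag must agree with whether the
#'   gene's term set is non-empty.
#' @return data frame of class `annotation_table`.
#' @export
annotation_table <- function(gene_id, has_bp, has_mf, has_cc,
                             term_sets = NULL) {
  if (anyDuplicated(gene_id)) format_error("duplicate gene ids")
  df <- data.frame(gene_id = as.character(gene_id),
                   has_bp = as.logical(has_bp),
                   has_mf = as.logical(has_mf),
                   has_cc = as.logical(has_cc),
                   stringsAsFactors = FALSE)
  if (anyNA(df)) format_error("annotation flags must be TRUE/FALSE")
  if (!is.null(term_sets)) {
    for (ns in c("bp", "mf", "cc")) {
      sets <- term_sets[[ns]]
      flag <- df[[paste0("has_", ns)]]
      nonempty <- df$gene_id %in% names(sets)[lengths(sets) > 0]
      if (!identical(flag, nonempty))
        format_error(sprintf("has_%s flags disagree with term_sets$%s", ns, ns))
    }
    attr(df, "term_sets") <- term_sets
  }
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Read gene annotations from a long TSV
#'
#' Input format: `gene_id<TAB>namespace<TAB>term_id`, one term per row,
#' where namespace is one of `bp`, `mf`, `cc` (GO biological process,
#' molecular function, cellular component). Genes listed in `universe`
#' but absent from the file get all-FALSE flags.
#'
#' @param path TSV path.
#' @param universe optional character vector of gene ids to include even
#'   if unannotated.
#' @return an [annotation_table()] with term sets attached.
#' @export
read_annotation_table <- function(path, universe = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_id", "namespace", "term_id")
  if (!all(need %in% colnames(df)))
    format_error("annotation TSV must have columns gene_id, namespace, term_id")
  bad <- setdiff(unique(df$namespace), c("bp", "mf", "cc"))
  if (length(bad))
    format_error(sprintf("unknown namespace(s): %s", paste(bad, collapse = ", ")))
  genes <- sort(unique(c(df$gene_id, universe)))
  term_sets <- lapply(c(bp = "bp", mf = "mf", cc = "cc"), function(ns) {
    sub <- df[df$namespace == ns, , drop = FALSE]
    split(sub$term_id, factor(sub$gene_id, levels = unique(sub$gene_id)))
  })
  annotation_table(
    genes,
    has_bp = genes %in% names(term_sets$bp),
    has_mf = genes %in% names(term_sets$mf),
    has_cc = genes %in% names(term_sets$cc),
    term_sets = term_sets)
}

#' Read gene sets in GMT format
#'
#' One term per line: `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT path.
#' @return named list mapping term id to a character vector of member
#'   genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      format_error("GMT line needs term, description and >= 1 gene")
    unique(parts[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(out))) format_error("duplicate term ids in GMT")
  out
}

#' Call tissue-specific expression for a cluster
#'
#' A cluster is specific for a condition when the average expression of
#' its genes there is at least `fold_threshold` times the level in the
#' other conditions (default fivefold, inclusive at the boundary). The
#' cluster profile is the per-condition mean over member features; the
#' "other tissues" level is by default the mean of the remaining
#' condition means (`reference = "max"` compares against their maximum
#' instead). A zero reference with positive expression counts as a
#' call.
#'
#' @param expr numeric matrix, features x conditions (averaged).
#' @param members character vector of cluster member feature ids.
#' @param fold_threshold required fold change (default 5).
#' @param reference `"mean"` (default) or `"max"` of the other
#'   conditions' means.
#' @param cluster_id optional id carried into the result.
#' @return object of class `specificity_call`: list with `cluster_id`,
#'   `means` (named per-condition cluster means), `called` (character
#'   vector of called conditions), `fold_threshold`, `reference`.
#' @export
tissue_specificity <- function(expr, members, fold_threshold = 5,
                               reference = c("mean", "max"),
                               cluster_id = NA_character_) {
  reference <- match.arg(reference)
  validate_expression_matrix(expr)
  if (!length(members)) format_error("cluster has no members")
  missing <- setdiff(members, rownames(expr))
  if (length(missing))
    format_error(sprintf("cluster member(s) not in matrix: %s",
                         paste(missing, collapse = ", ")))
  means <- colMeans(expr[members, , drop = FALSE])
  called <- vapply(seq_along(means), function(i) {
    ref <- switch(reference, mean = mean(means[-i]), max = max(means[-i]))
    if (ref == 0) means[i] > 0 else means[i] >= fold_threshold * ref
  }, logical(1))
  out <- list(cluster_id = cluster_id, means = means,
              called = names(means)[called],
              fold_threshold = fold_threshold, reference = reference)
  class(out) <- "specificity_call"
  out
}

#' @export
print.specificity_call <- function(x, ...) {
  cat(sprintf("Specificity call%s: %s (>= %g-fold vs %s of others)\n",
              if (is.na(x$cluster_id)) "" else paste0(" for ", x$cluster_id),
              if (length(x$called)) paste(x$called, collapse = ", ")
              else "none",
              x$fold_threshold, x$reference))
  invisible(x)
}

#' Weighted GO-annotation completeness score of a cluster
#'
#' Each gene scores 0 or 1 per GO namespace for presence of at least one
#' term, giving a per-gene score of 0-3; the cluster score is the mean
#' over its unique genes (maximum 3 when every gene is annotated in all
#' three namespaces). Counts `n0`..`n3` of genes with 0-3 annotated
#' namespaces are returned alongside the exact score and the score
#' rounded to 2 decimals, half away from zero. Genes absent from the
#' annotation table count as unannotated (`n0`) and are reported via a
#' message.
#'
#' @param cluster_genes character vector of gene ids (duplicates are
#'   collapsed).
#' @param annotations an [annotation_table()].
#' @param cluster_id optional id carried into the result.
#' @return object of class `annotation_score`: list with `cluster_id`,
#'   `n_genes`, `counts` (named n0..n3), `score` (exact), and
#'   `score_rounded`.
#' @export
annotation_score <- function(cluster_genes, annotations,
                             cluster_id = NA_character_) {
  stopifnot(inherits(annotations, "annotation_table"))
  genes <- unique(as.character(cluster_genes))
  if (!length(genes)) format_error("cluster has no genes")
  idx <- match(genes, annotations$gene_id)
  absent <- genes[is.na(idx)]
  if (length(absent))
    message(sprintf("%d gene(s) absent from annotation table, scored 0: %s",
                    length(absent),
                    paste(utils::head(absent, 5), collapse = ", ")))
  per_gene <- ifelse(is.na(idx), 0L,
                     annotations$has_bp[idx] + annotations$has_mf[idx] +
                       annotations$has_cc[idx])
  counts <- vapply(0:3, function(k) sum(per_gene == k), integer(1))
  names(counts) <- paste0("n", 0:3)
  score <- sum((0:3) * counts) / length(genes)
  out <- list(cluster_id = cluster_id, n_genes = length(genes),
              counts = counts, score = score,
              score_rounded = round_half_away(score, 2))
  class(out) <- "annotation_score"
  out
}

#' @export
print.annotation_score <- function(x, ...) {
  cat(sprintf(
    "Annotation score%s: %.2f (N=%d; N0..N3 = %s)\n",
    if (is.na(x$cluster_id)) "" else paste0(" for ", x$cluster_id),
    x$score_rounded, x$n_genes, paste(x$counts, collapse = "/")))
  invisible(x)
}

#' Table of annotation scores for a cluster set
#'
#' One row per cluster: counts of genes with 0-3 annotated namespaces,
#' the corresponding percentages (rounded, half away from zero), and the
#' weighted score.
#'
#' @param cluster_set a `cluster_set`.
#' @param annotations an [annotation_table()].
#' @param probe_to_gene optional named character vector mapping feature
#'   (probe) ids to gene ids; clusters are collapsed to unique genes
#'   before scoring. Features without a mapping are dropped.
#' @return data frame with columns `cluster_id`, `n0`..`n3`, `n_genes`,
#'   `score`, `pct0`..`pct3`.
#' @export
score_clusters <- function(cluster_set, annotations, probe_to_gene = NULL) {
  stopifnot(inherits(cluster_set, "cluster_set"))
  rows <- lapply(names(cluster_set$clusters), function(cid) {
    genes <- cluster_set$clusters[[cid]]
    if (!is.null(probe_to_gene)) {
      genes <- probe_to_gene[genes]
      genes <- genes[!is.na(genes)]
    }
    s <- suppressMessages(annotation_score(genes, annotations, cid))
    pct <- round_half_away(100 * s$counts / s$n_genes, 0)
    data.frame(cluster_id = cid, t(s$counts), n_genes = s$n_genes,
               score = s$score_rounded,
               pct0 = pct[1], pct1 = pct[2], pct2 = pct[3], pct3 = pct[4],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Hypergeometric term enrichment of a cluster with Bonferroni control
#'
#' For each term with at least one cluster member, the raw p value is
#' the one-sided (over-representation) upper-tail hypergeometric
#' probability P(X >= k) of observing k term members when drawing the
#' cluster (size n) from the background (size N) containing K term
#' members. Bonferroni correction multiplies by the number of terms
#' tested for this cluster, capped at 1; significance is called at
#' `p_bonferroni <= alpha`.
#'
#' @param cluster_genes character vector, must be a subset of
#'   `background`.
#' @param term_annotations named list term -> member genes (e.g. from
#'   [read_gmt()]), or a data frame with columns `gene_id` and `term`.
#' @param background character vector of background gene ids.
#' @param alpha significance level after correction (default 0.05).
#' @param cluster_id optional id carried into the result.
#' @return data frame of class `enrichment_result`, sorted by ascending
#'   `p_bonferroni`, with columns `cluster_id`, `term`, `k`, `n`, `K`,
#'   `N`, `p_raw`, `p_bonferroni`, `significant`.
#' @export
enrich_cluster <- function(cluster_genes, term_annotations, background,
                           alpha = 0.05, cluster_id = NA_character_) {
  cluster_genes <- unique(as.character(cluster_genes))
  background <- unique(as.character(background))
  if (length(background) < length(cluster_genes))
    format_error("background is smaller than the cluster")
  if (!all(cluster_genes %in% background))
    format_error("cluster genes must be a subset of the background")
  if (is.data.frame(term_annotations)) {
    if (!all(c("gene_id", "term") %in% colnames(term_annotations)))
      format_error("term annotation data frame needs gene_id and term columns")
    term_annotations <- split(term_annotations$gene_id, term_annotations$term)
  }
  N <- length(background)
  n <- length(cluster_genes)
  rows <- lapply(names(term_annotations), function(tm) {
    tg <- intersect(unique(term_annotations[[tm]]), background)
    k <- length(intersect(tg, cluster_genes))
    if (k == 0) return(NULL)
    K <- length(tg)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(cluster_id = cluster_id, term = tm, k = k, n = n, K = K,
               N = N, p_raw = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(0), term = character(0),
               k = integer(0), n = integer(0), K = integer(0), N = integer(0),
               p_raw = numeric(0), stringsAsFactors = FALSE)
  n_tested <- nrow(out)
  out$p_bonferroni <- pmin(1, out$p_raw * n_tested)
  out$significant <- out$p_bonferroni <= alpha
  out <- out[order(out$p_bonferroni, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Guilt-by-association label transfer to unannotated genes
#'
#' Cluster members without any GO-namespace annotation inherit, as
#' explicitly flagged *predictions*, the cluster's called conditions
#' and its significantly enriched terms. The annotation table itself is
#' never modified.
#'
#' @param members character vector of cluster member gene ids.
#' @param specificity a `specificity_call` for the cluster (or NULL).
#' @param enrichments an `enrichment_result` for the cluster (or NULL).
#' @param annotations an [annotation_table()].
#' @param cluster_id optional id carried into the result.
#' @return data frame with columns `gene_id`, `cluster_id`, `label`,
#'   `source` (`"tissue_specificity"` or `"enrichment"`), `prediction`
#'   (always TRUE); zero rows when there is nothing to transfer.
#' @export
transfer_annotations <- function(members, specificity = NULL,
                                 enrichments = NULL, annotations,
                                 cluster_id = NA_character_) {
  stopifnot(inherits(annotations, "annotation_table"))
  members <- unique(as.character(members))
  idx <- match(members, annotations$gene_id)
  n_ns <- ifelse(is.na(idx), 0L,
                 annotations$has_bp[idx] + annotations$has_mf[idx] +
                   annotations$has_cc[idx])
  targets <- members[n_ns == 0]
  labels <- character(0); src <- character(0)
  if (!is.null(specificity) && length(specificity$called)) {
    labels <- c(labels, specificity$called)
    src <- c(src, rep("tissue_specificity", length(specificity$called)))
  }
  if (!is.null(enrichments)) {
    sig <- enrichments$term[enrichments$significant]
    labels <- c(labels, sig)
    src <- c(src, rep("enrichment", length(sig)))
  }
  if (!length(targets) || !length(labels)) {
    return(data.frame(gene_id = character(0), cluster_id = character(0),
                      label = character(0), source = character(0),
                      prediction = logical(0), stringsAsFactors = FALSE))
  }
  data.frame(gene_id = rep(targets, each = length(labels)),
             cluster_id = cluster_id,
             label = rep(labels, times = length(targets)),
             source = rep(src, times = length(targets)),
             prediction = TRUE, stringsAsFactors = FALSE)
}
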