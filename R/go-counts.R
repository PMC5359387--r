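#' Published GO-annotation counts for 26 mouse coexpression clusters
#'
#' A reference table of per-cluster counts of genes with 0, 1, 2 or 3
#' annotated GO namespaces, from a published MCL clustering of a mouse
#' multi-tissue microarray atlas, together with the weighted annotation
#' score as printed there (2 decimals). Used to validate
#' [annotation_score()] against independently computed values.
#'
#' @return data frame with columns `cluster_id`, `description`,
#'   `n0`..`n3`, `n_genes`, `score`.
#' @examples
#' counts <- published_go_counts()
#' head(counts)
#' @export
published_go_counts <- function() {
  path <- system.file("extdata", "cluster_go_counts.tsv", package = "coexnet",
                      mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Rebuild an annotation table realizing given namespace counts
#'
#' Constructs a minimal gene set and [annotation_table()] such that
#' exactly `n0` genes have no annotated namespace, `n1` one, `n2` two
#' and `n3` all three — the smallest synthetic input on which
#' [annotation_score()] must reproduce a published score.
#'
#' @param n0,n1,n2,n3 non-negative gene counts.
#' @param prefix gene-id prefix.
#' @return list with `genes` (character vector, length n0+n1+n2+n3) and
#'   `annotations` (an [annotation_table()]).
#' @export
annotations_from_counts <- function(n0, n1, n2, n3, prefix = "g") {
  n <- n0 + n1 + n2 + n3
  genes <- sprintf("%s%04d", prefix, seq_len(n))
  k <- rep(0:3, c(n0, n1, n2, n3))
  list(genes = genes,
       annotations = annotation_table(genes,
                                      has_bp = k >= 1,
                                      has_mf = k >= 2,
                                      has_cc = k >= 3))
}
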