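#' Read an expression matrix (and optional sample metadata)
#'
#' Expression tables are tab-separated, UTF-8, with a header line
#' `feature_id<TAB>sample1<TAB>...` and one feature per row; values are
#' natural-scale (unlogged) normalized intensities. Metadata tables are
#' TSV with columns `sample_id`, `experiment_group`, `condition_id`,
#' mapping every sample column to a replicate set and a tissue/cell-type
#' label.
#'
#' @param path path to the expression TSV.
#' @param metadata_path optional path to the sample-metadata TSV; when
#'   given, every sample column must be covered by the metadata.
#' @return with `metadata_path`, a list with elements `expr` (numeric
#'   matrix, features x samples) and `metadata` (data frame); otherwise
#'   just the matrix.
#' @seealso [write_expression_matrix()], [average_replicates()]
#' @export
read_expression_matrix <- function(path, metadata_path = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2)
    format_error("expression table needs a feature_id column and >= 1 sample")
  feats <- raw[[1]]
  if (anyDuplicated(feats))
    format_error(sprintf("duplicate feature id(s): %s",
                         paste(unique(feats[duplicated(feats)]), collapse = ", ")))
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples))
    format_error(sprintf("duplicate sample id(s) in header: %s",
                         paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(feats, samples))
  if (anyNA(vals))
    format_error("non-numeric or missing expression cell(s); dense numeric values are required")
  validate_expression_matrix(vals)
  if (is.null(metadata_path)) return(vals)
  md <- read_sample_metadata(metadata_path)
  missing <- setdiff(samples, md$sample_id)
  if (length(missing))
    format_error(sprintf("sample(s) missing from metadata: %s",
                         paste(missing, collapse = ", ")))
  list(expr = vals, metadata = md[match(samples, md$sample_id), , drop = FALSE])
}

#' Read a sample-metadata table
#'
#' @param path TSV with columns `sample_id`, `experiment_group`,
#'   `condition_id`.
#' @return data frame with those three character columns.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "experiment_group", "condition_id")
  if (!all(need %in% colnames(md)))
    format_error(sprintf("metadata must have columns %s",
                         paste(need, collapse = ", ")))
  if (anyDuplicated(md$sample_id))
    format_error("duplicate sample_id in metadata")
  md[need]
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: numbers are written with full
#' precision (up to 17 significant digits) so that a write/read
#' round-trip reproduces the matrix exactly.
#'
#' @param x numeric matrix with feature row names and sample/condition
#'   column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  df <- data.frame(feature_id = rownames(x),
                   format(x, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    format_error("expression data must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    format_error("expression matrix needs feature row names and sample column names")
  if (anyDuplicated(rownames(x))) format_error("duplicate feature ids")
  if (anyDuplicated(colnames(x))) format_error("duplicate sample/condition ids")
  if (!all(is.finite(x))) format_error("expression values must be finite")
  if (any(x < 0)) format_error("expression values must be >= 0 (natural scale)")
  invisible(x)
}

#' Average replicate samples into condition columns
#'
#' Collapses the sample columns of an expression matrix to one column
#' per condition (tissue/cell type), each cell being the unweighted
#' arithmetic mean of that feature's replicate samples. Condition
#' labels are matched exactly and case-sensitively. Feature order is
#' preserved; condition columns appear in order of first appearance in
#' the metadata.
#'
#' @param expr numeric matrix, features x samples.
#' @param metadata data frame with `sample_id` and `condition_id`
#'   covering every column of `expr`.
#' @return numeric matrix, features x conditions.
#' @export
average_replicates <- function(expr, metadata) {
  validate_expression_matrix(expr)
  idx <- match(colnames(expr), metadata$sample_id)
  if (anyNA(idx))
    format_error("every sample column must appear in the metadata")
  cond <- metadata$condition_id[idx]
  conds <- unique(metadata$condition_id[order(match(metadata$sample_id, colnames(expr)))])
  conds <- conds[!is.na(conds)]
  if (!length(conds)) format_error("no conditions found in metadata")
  out <- vapply(conds, function(cc) {
    cols <- which(cond == cc)
    if (!length(cols)) format_error(sprintf("condition '%s' has zero samples", cc))
    rowMeans(expr[, cols, drop = FALSE])
  }, numeric(nrow(expr)))
  out <- matrix(out, nrow = nrow(expr),
                dimnames = list(rownames(expr), conds))
  out
}

#' Remove features that never reach an expression threshold
#'
#' Retains exactly the features whose maximum intensity across columns
#' is at least `threshold` (the boundary is inclusive: a feature whose
#' maximum equals the threshold stays). Column set and relative feature
#' order are unchanged. An empty result is legal and only warned about.
#'
#' @param expr numeric matrix, features x conditions (normally the
#'   averaged matrix; see `filter_before_averaging` in [coexp_config()]).
#' @param threshold minimum intensity, default 100.
#' @return the filtered matrix.
#' @export
filter_low_expression <- function(expr, threshold = 100) {
  validate_expression_matrix(expr)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    config_error("'threshold' must be a single positive number")
  keep <- apply(expr, 1, max) >= threshold
  if (!any(keep))
    warning("no feature reaches the intensity threshold; result is empty")
  expr[keep, , drop = FALSE]
}
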