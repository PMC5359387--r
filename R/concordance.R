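#' Map gene ids into a target dataset's id space
#'
#' One-to-many mappings are collapsed deterministically to the
#' lexicographically first target id (a message reports how many were
#' collapsed). Genes without a target id are returned separately and
#' excluded from concordance denominators.
#'
#' @param genes character vector of source ids.
#' @param id_map data frame with columns `source_id`, `target_id`, or a
#'   named character vector (names = source ids).
#' @return list with `mapped` (named character vector source -> target)
#'   and `unmapped` (character vector).
#' @export
map_ids <- function(genes, id_map) {
  genes <- as.character(genes)
  if (is.data.frame(id_map)) {
    if (!all(c("source_id", "target_id") %in% colnames(id_map)))
      format_error("id_map needs source_id and target_id columns")
    id_map <- id_map[order(id_map$source_id, id_map$target_id), , drop = FALSE]
    dup <- duplicated(id_map$source_id)
    if (any(dup))
      message(sprintf(
        "%d one-to-many id mapping(s) collapsed to lexicographically first target",
        length(unique(id_map$source_id[dup]))))
    id_map <- stats::setNames(id_map$target_id[!dup], id_map$source_id[!dup])
  }
  hit <- genes %in% names(id_map)
  list(mapped = stats::setNames(unname(id_map[genes[hit]]), genes[hit]),
       unmapped = genes[!hit])
}

#' Read a two-column id mapping TSV
#'
#' @param path TSV with columns `source_id`, `target_id`.
#' @return data frame with those columns.
#' @export
read_id_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("source_id", "target_id") %in% colnames(df)))
    format_error("id map TSV must have columns source_id, target_id")
  df
}

cluster_lookup <- function(cs) {
  stats::setNames(rep(names(cs$clusters), lengths(cs$clusters)),
                  unlist(cs$clusters, use.names = FALSE))
}

#' Cross-dataset cluster concordance
#'
#' For every source cluster, the distribution of its mappable members
#' over the clusters of a target clustering, with an explicit
#' `unclustered` bin so fractions always sum to 1. Denominators count
#' mappable genes only; genes the id map cannot translate are tallied
#' but excluded. The best match is the non-`unclustered` bin with the
#' largest fraction.
#'
#' @param source,target `cluster_set` objects.
#' @param id_map optional mapping accepted by [map_ids()]; NULL means
#'   the two datasets share ids (identity map).
#' @param source_calls,target_calls optional named lists of
#'   `specificity_call`s (one per cluster of the respective clustering);
#'   when both are given, each source cluster additionally gets
#'   `call_match`: the fraction of its mappable genes lying in target
#'   clusters that share at least one called condition with it.
#' @return object of class `concordance_report`: list with `bins` (data
#'   frame source_cluster, target_bin, count, fraction) and `summary`
#'   (data frame source_cluster, n_members, n_mappable, best_match,
#'   best_fraction).
#' @export
cluster_concordance <- function(source, target, id_map = NULL,
                                source_calls = NULL, target_calls = NULL) {
  stopifnot(inherits(source, "cluster_set"), inherits(target, "cluster_set"))
  tl <- cluster_lookup(target)
  bins <- list(); summ <- list()
  for (cid in names(source$clusters)) {
    members <- source$clusters[[cid]]
    if (is.null(id_map)) {
      mapped <- stats::setNames(members, members); unmapped <- character(0)
    } else {
      mm <- map_ids(members, id_map)
      mapped <- mm$mapped; unmapped <- mm$unmapped
    }
    n_map <- length(mapped)
    if (n_map == 0) {
      summ[[cid]] <- data.frame(source_cluster = cid,
                                n_members = length(members), n_mappable = 0L,
                                best_match = NA_character_,
                                best_fraction = NA_real_,
                                stringsAsFactors = FALSE)
      next
    }
    bin <- tl[mapped]
    bin[is.na(bin)] <- "unclustered"
    tab <- table(bin)
    df <- data.frame(source_cluster = cid, target_bin = names(tab),
                     count = as.integer(tab),
                     fraction = as.numeric(tab) / n_map,
                     stringsAsFactors = FALSE)
    bins[[cid]] <- df[order(-df$fraction, df$target_bin), , drop = FALSE]
    real <- df[df$target_bin != "unclustered", , drop = FALSE]
    best <- if (nrow(real)) real[order(-real$fraction, real$target_bin), ][1, ]
            else data.frame(target_bin = NA_character_, fraction = NA_real_)
    summ[[cid]] <- data.frame(source_cluster = cid,
                              n_members = length(members),
                              n_mappable = n_map,
                              best_match = best$target_bin,
                              best_fraction = best$fraction,
                              stringsAsFactors = FALSE)
  }
  out <- list(
    bins = if (length(bins)) do.call(rbind, c(bins, list(make.row.names = FALSE)))
           else data.frame(source_cluster = character(0),
                           target_bin = character(0), count = integer(0),
                           fraction = numeric(0)),
    summary = do.call(rbind, c(summ, list(make.row.names = FALSE))))
  if (!is.null(source_calls) && !is.null(target_calls)) {
    tcalls <- lapply(target_calls, function(s) s$called)
    scalls <- lapply(source_calls, function(s) s$called)
    out$summary$call_match <- vapply(out$summary$source_cluster, function(cid) {
      b <- out$bins[out$bins$source_cluster == cid &
                      out$bins$target_bin != "unclustered", , drop = FALSE]
      if (!nrow(b)) return(NA_real_)
      sum(b$fraction[vapply(b$target_bin, function(tb)
        length(intersect(tcalls[[tb]] %||% character(0),
                         scalls[[cid]] %||% character(0))) > 0, logical(1))])
    }, numeric(1))
  }
  class(out) <- "concordance_report"
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Cluster concordance report\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Dispersal of one cluster over another clustering
#'
#' Specialization of [cluster_concordance()] for a single cluster in a
#' same-dataset comparison (identity map): the sorted fractions of its
#' members over the target clusters (plus `unclustered`) and the
#' natural-log Shannon entropy of that distribution. An intact cluster
#' has one bin of fraction 1 and entropy 0; a cluster split evenly over
#' two bins has entropy log(2).
#'
#' @param members character vector of cluster member ids.
#' @param target a `cluster_set` from the comparison dataset.
#' @return object of class `dispersal`: list with `fractions` (named,
#'   sorted decreasing), `entropy`, `n`.
#' @export
dispersal <- function(members, target) {
  stopifnot(inherits(target, "cluster_set"))
  members <- unique(as.character(members))
  if (!length(members)) format_error("no members to disperse")
  bin <- cluster_lookup(target)[members]
  bin[is.na(bin)] <- "unclustered"
  tab <- table(bin)
  p <- as.numeric(tab) / length(members)
  names(p) <- names(tab)
  p <- sort(p, decreasing = TRUE)
  out <- list(fractions = p, entropy = -sum(p * log(p)), n = length(members))
  class(out) <- "dispersal"
  out
}

#' @export
print.dispersal <- function(x, ...) {
  cat(sprintf("Dispersal over %d bins, entropy %.4f nats\n",
              length(x$fractions), x$entropy))
  print(round(x$fractions, 4))
  invisible(x)
}

#' Write a concordance report as TSV
#'
#' One row per (source cluster, target bin).
#'
#' @param report a `concordance_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(report, path) {
  stopifnot(inherits(report, "concordance_report"))
  utils::write.table(report$bins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
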