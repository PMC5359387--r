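#' Parameters for the synthetic expression generator
#'
#' The default design emulates a multi-tissue microarray atlas at desk
#' scale: 6 planted modules of 30 genes, each switched on in one of 8
#' conditions measured in 3 replicates, on-intensity 1000 versus
#' off-intensity 100 with 10% multiplicative (lognormal) noise, plus
#' 200 background genes whose intensities are drawn independently per
#' condition (so their pairwise correlations concentrate near 0).
#'
#' @param n_modules number of planted modules.
#' @param module_size genes per module.
#' @param n_conditions number of conditions (tissue/cell types); must be
#'   at least `n_modules` so each module gets its own designated
#'   condition.
#' @param replicates replicate samples per condition.
#' @param mu_on natural-scale intensity of a module gene in its
#'   designated condition.
#' @param mu_off intensity elsewhere.
#' @param sigma standard deviation of the lognormal noise applied both
#'   at the condition level and per replicate.
#' @param n_background number of uncorrelated background genes.
#' @param bg_meanlog,bg_sdlog lognormal parameters of the per-gene
#'   *baseline* intensity of background genes (drawn once per gene;
#'   defaults centre baselines near 300 with a realistic spread across
#'   genes). Condition-level values are the baseline times the same
#'   multiplicative noise `sigma` as the rest of the design, so the
#'   baseline spread never enters any correlation (Pearson r is
#'   invariant to per-gene scaling) and background correlations
#'   concentrate near 0, below the edge cutoff.
#' @param n_low number of genes planted below the intensity filter
#'   (default 0).
#' @param mu_low intensity of the low genes in every condition.
#' @return a validated list of class `synth_params`.
#' @export
synth_params <- function(n_modules = 6L, module_size = 30L,
                         n_conditions = 8L, replicates = 3L,
                         mu_on = 1000, mu_off = 100, sigma = 0.1,
                         n_background = 200L,
                         bg_meanlog = log(300), bg_sdlog = 0.5,
                         n_low = 0L, mu_low = 50) {
  p <- list(n_modules = as.integer(n_modules),
            module_size = as.integer(module_size),
            n_conditions = as.integer(n_conditions),
            replicates = as.integer(replicates),
            mu_on = as.numeric(mu_on), mu_off = as.numeric(mu_off),
            sigma = as.numeric(sigma),
            n_background = as.integer(n_background),
            bg_meanlog = as.numeric(bg_meanlog),
            bg_sdlog = as.numeric(bg_sdlog),
            n_low = as.integer(n_low), mu_low = as.numeric(mu_low))
  if (p$n_modules < 1 || p$module_size < 1)
    config_error("need at least one module with at least one gene")
  if (p$n_conditions < p$n_modules)
    config_error("need at least as many conditions as modules")
  if (p$replicates < 1) config_error("'replicates' must be >= 1")
  if (p$mu_on <= 0 || p$mu_off <= 0) config_error("intensities must be positive")
  if (p$sigma < 0 || p$bg_sdlog < 0) config_error("noise sd must be >= 0")
  if (p$n_background < 0) config_error("'n_background' must be >= 0")
  if (p$n_low < 0) config_error("'n_low' must be >= 0")
  if (p$mu_low <= 0) config_error("'mu_low' must be positive")
  class(p) <- "synth_params"
  p
}

#' Generate a synthetic expression dataset with planted modules
#'
#' Module gene intensities are `mu_on * exp(N(0, sigma))` in the
#' module's designated condition and `mu_off * exp(N(0, sigma))`
#' elsewhere, drawn once per (gene, condition); replicate samples are
#' further independent lognormal draws around the condition value.
#' Background genes get a per-gene lognormal baseline (`bg_meanlog`,
#' `bg_sdlog`) and independent `sigma`-scale noise per condition, so
#' they are uncorrelated with everything.
#' Output is bitwise-deterministic given `params` and `seed`.
#'
#' @param params a [synth_params()].
#' @param seed integer seed.
#' @return list with `expr` (genes x samples matrix), `metadata` (sample
#'   metadata data frame), `truth` (class `synth_truth`: data frame
#'   `gene_id`, `module`, `designated_condition` with the parameters and
#'   seed as attributes), and `conditions`.
#' @export
generate_dataset <- function(params = synth_params(), seed = 1L) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(as.integer(seed))
  p <- params
  n_mod_genes <- p$n_modules * p$module_size
  n_genes <- n_mod_genes + p$n_background + p$n_low
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  conds <- sprintf("tissue%02d", seq_len(p$n_conditions))
  module <- c(rep(sprintf("module%d", seq_len(p$n_modules)),
                  each = p$module_size),
              rep("background", p$n_background),
              rep("low", p$n_low))
  designated <- rep(NA_character_, n_genes)
  designated[seq_len(n_mod_genes)] <-
    rep(conds[seq_len(p$n_modules)], each = p$module_size)
  # condition-level expectations
  cond_val <- matrix(NA_real_, n_genes, p$n_conditions,
                     dimnames = list(gene_ids, conds))
  if (n_mod_genes) {
    base <- matrix(p$mu_off, n_mod_genes, p$n_conditions)
    base[cbind(seq_len(n_mod_genes),
               match(designated[seq_len(n_mod_genes)], conds))] <- p$mu_on
    noise <- matrix(exp(stats::rnorm(n_mod_genes * p$n_conditions, 0, p$sigma)),
                    n_mod_genes, p$n_conditions)
    cond_val[seq_len(n_mod_genes), ] <- base * noise
  }
  if (p$n_background) {
    baseline <- exp(stats::rnorm(p$n_background, p$bg_meanlog, p$bg_sdlog))
    cond_val[n_mod_genes + seq_len(p$n_background), ] <- baseline *
      matrix(exp(stats::rnorm(p$n_background * p$n_conditions, 0, p$sigma)),
             p$n_background, p$n_conditions)
  }
  if (p$n_low) {
    cond_val[n_mod_genes + p$n_background + seq_len(p$n_low), ] <-
      p$mu_low * exp(stats::rnorm(p$n_low * p$n_conditions, 0, p$sigma))
  }
  # replicate samples around the condition values
  sample_ids <- as.vector(vapply(conds, function(cc)
    sprintf("%s_r%d", cc, seq_len(p$replicates)), character(p$replicates)))
  expr <- matrix(NA_real_, n_genes, length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (ci in seq_along(conds)) {
    for (ri in seq_len(p$replicates)) {
      col <- (ci - 1L) * p$replicates + ri
      expr[, col] <- cond_val[, ci] *
        exp(stats::rnorm(n_genes, 0, p$sigma))
    }
  }
  metadata <- data.frame(
    sample_id = sample_ids,
    experiment_group = rep(sprintf("exp_%s", conds), each = p$replicates),
    condition_id = rep(conds, each = p$replicates),
    stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gene_ids, module = module,
                      designated_condition = designated,
                      stringsAsFactors = FALSE)
  attr(truth, "params") <- params
  attr(truth, "seed") <- as.integer(seed)
  class(truth) <- c("synth_truth", "data.frame")
  list(expr = expr, metadata = metadata, truth = truth, conditions = conds)
}

#' Generate random per-gene GO-namespace annotations
#'
#' Each namespace flag is an independent Bernoulli draw, so the expected
#' per-gene (and cluster) score is `rates["bp"] + rates["mf"] +
#' rates["cc"]`.
#'
#' @param genes character vector of gene ids.
#' @param rates numeric vector of length 3 (`bp`, `mf`, `cc`), values in
#'   `[0, 1]`.
#' @param seed integer seed.
#' @return an [annotation_table()].
#' @export
generate_annotations <- function(genes, rates = c(bp = 0.8, mf = 0.7, cc = 0.8),
                                 seed = 1L) {
  if (length(rates) != 3 || any(rates < 0) || any(rates > 1))
    config_error("'rates' must be 3 probabilities in [0, 1]")
  set.seed(as.integer(seed))
  n <- length(genes)
  annotation_table(genes,
                   has_bp = stats::runif(n) < rates[[1]],
                   has_mf = stats::runif(n) < rates[[2]],
                   has_cc = stats::runif(n) < rates[[3]])
}

#' Generate a pair of datasets for replication analysis
#'
#' Both datasets carry the same gene ids. For a fraction
#' `overlap_fraction` of each module's genes the module structure is
#' shared; the remaining module genes become background in the second
#' dataset (their correlation with the module is destroyed). The id map
#' is the identity with a fraction `dropout_fraction` of genes removed,
#' emulating genes that cannot be found in the other dataset's
#' annotation.
#'
#' @param params a [synth_params()].
#' @param overlap_fraction fraction of module genes keeping their module
#'   in the target dataset, in `[0, 1]`.
#' @param dropout_fraction fraction of gene ids removed from the id map,
#'   in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `source`, `target` (each as returned by
#'   [generate_dataset()]) and `id_map` (data frame `source_id`,
#'   `target_id`).
#' @export
generate_replication_pair <- function(params = synth_params(),
                                      overlap_fraction = 1,
                                      dropout_fraction = 0, seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction > 1 ||
      dropout_fraction < 0 || dropout_fraction > 1)
    config_error("fractions must lie in [0, 1]")
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  src <- generate_dataset(params, sub_seeds[1])
  tgt <- generate_dataset(params, sub_seeds[2])
  # demote the non-overlapping module genes to background in the target
  set.seed(sub_seeds[3])
  p <- params
  demoted <- character(0)
  for (m in sprintf("module%d", seq_len(p$n_modules))) {
    genes <- src$truth$gene_id[src$truth$module == m]
    n_keep <- round(overlap_fraction * length(genes))
    if (n_keep < length(genes))
      demoted <- c(demoted, sample(genes, length(genes) - n_keep))
  }
  if (length(demoted)) {
    idx <- match(demoted, rownames(tgt$expr))
    n_cond <- p$n_conditions
    baseline <- exp(stats::rnorm(length(idx), p$bg_meanlog, p$bg_sdlog))
    bg_cond <- baseline *
      matrix(exp(stats::rnorm(length(idx) * n_cond, 0, p$sigma)),
             length(idx), n_cond)
    for (ci in seq_len(n_cond)) {
      for (ri in seq_len(p$replicates)) {
        col <- (ci - 1L) * p$replicates + ri
        tgt$expr[idx, col] <- bg_cond[, ci] *
          exp(stats::rnorm(length(idx), 0, p$sigma))
      }
    }
    tgt$truth$module[match(demoted, tgt$truth$gene_id)] <- "background"
    tgt$truth$designated_condition[match(demoted, tgt$truth$gene_id)] <- NA
  }
  ids <- src$truth$gene_id
  n_drop <- round(dropout_fraction * length(ids))
  dropped <- if (n_drop) sample(ids, n_drop) else character(0)
  keep <- setdiff(ids, dropped)
  id_map <- data.frame(source_id = keep, target_id = keep,
                       stringsAsFactors = FALSE)
  list(source = src, target = tgt, id_map = id_map, dropped = dropped)
}

#' Destroy the within-module correlation of one planted module
#'
#' Each gene of the module independently has its condition profile
#' permuted (replicate columns move with their condition), which
#' preserves the gene's intensity distribution but breaks its
#' correlation with the rest of the module. All other genes are
#' untouched. Deterministic given the seed; a drawn identity permutation
#' leaves that gene unchanged.
#'
#' @param dataset a list as returned by [generate_dataset()].
#' @param module_id module to perturb, e.g. `"module1"`.
#' @param seed integer seed.
#' @return the dataset with a perturbed `expr` matrix (truth is carried
#'   over unchanged, since the perturbation is the point of comparison).
#' @export
perturb_module <- function(dataset, module_id, seed = 1L) {
  truth <- dataset$truth
  genes <- truth$gene_id[truth$module == module_id]
  if (!length(genes))
    format_error(sprintf("unknown module id '%s'", module_id))
  set.seed(as.integer(seed))
  conds <- dataset$conditions
  col_of <- lapply(conds, function(cc)
    which(dataset$metadata$condition_id[
      match(colnames(dataset$expr), dataset$metadata$sample_id)] == cc))
  expr <- dataset$expr
  for (g in genes) {
    perm <- sample(length(conds))
    new_row <- expr[g, ]
    for (ci in seq_along(conds))
      new_row[col_of[[ci]]] <- expr[g, col_of[[perm[ci]]]]
    expr[g, ] <- new_row
  }
  dataset$expr <- expr
  dataset$perturbed_module <- module_id
  dataset
}
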