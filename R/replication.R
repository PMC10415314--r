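#' Replication policy
#'
#' How a selected CpG-transcript pair counts as replicated in a second
#' (validation or external) dataset: at a nominal level, at a
#' Bonferroni-corrected level `alpha / m`, or at relation-specific strict
#' genome-wide thresholds, optionally also requiring the effect direction
#' to match the discovery stage.
#'
#' @param mode `"nominal"`, `"bonferroni"` or `"strict"`.
#' @param alpha base level (default 0.05; used by nominal and bonferroni).
#' @param m number of pairs tested (bonferroni divisor).
#' @param strict_cis,strict_trans strict thresholds per relation
#'   (defaults 1e-7 / 1e-14).
#' @param require_sign_match require matching effect direction (default
#'   TRUE).
#' @return `replication_policy` list.
#' @export
replication_policy <- function(mode = c("nominal", "bonferroni", "strict"),
                               alpha = 0.05, m = NULL,
                               strict_cis = 1e-7, strict_trans = 1e-14,
                               require_sign_match = TRUE) {
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (mode == "bonferroni") {
    if (is.null(m) || m < 1) stop("bonferroni mode needs m >= 1")
  }
  structure(list(mode = mode, alpha = alpha, m = m,
                 strict_cis = strict_cis, strict_trans = strict_trans,
                 require_sign_match = require_sign_match),
            class = "replication_policy")
}

policy_threshold <- function(policy, relation) {
  switch(policy$mode,
         nominal = policy$alpha,
         bonferroni = policy$alpha / policy$m,
         strict = ifelse(relation == "cis", policy$strict_cis,
                         policy$strict_trans))
}

#' Split a dataset into discovery and validation subsets
#'
#' Partitions the samples (e.g. by methylation platform) and subsets every
#' matrix, the covariate table and all traits consistently. Both groups must
#' be non-empty and the labels must cover every sample.
#'
#' @param dataset an `eqtm_dataset`.
#' @param sample_labels named character vector mapping every sample ID to
#'   `"discovery"` or `"validation"`.
#' @return list with `discovery` and `validation` datasets.
#' @export
split_discovery_validation <- function(dataset, sample_labels) {
  stopifnot(inherits(dataset, "eqtm_dataset"))
  samples <- colnames(dataset$methylation)
  if (!all(samples %in% names(sample_labels)))
    stop("labels must cover all samples")
  lab <- sample_labels[samples]
  if (!all(lab %in% c("discovery", "validation")))
    stop("labels must be 'discovery' or 'validation'")
  if (!any(lab == "discovery") || !any(lab == "validation"))
    stop("both groups must be non-empty")
  subset_ds <- function(keep) {
    ds <- dataset
    ds$methylation <- dataset$methylation[, keep, drop = FALSE]
    ds$counts <- dataset$counts[, keep, drop = FALSE]
    ds$genotypes <- dataset$genotypes[, keep, drop = FALSE]
    ds$covariates <- dataset$covariates[keep, , drop = FALSE]
    ds$traits <- lapply(dataset$traits, function(tr) tr[keep])
    ds$config$n_samples <- sum(keep)
    ds
  }
  list(discovery = subset_ds(lab == "discovery"),
       validation = subset_ds(lab == "validation"))
}

#' Top lead CpG-eGene pairs by significance
#'
#' Ranks the catalog's eGenes by the p-value of their lead CpG pair
#' (ascending; ties broken as in [lead_cpgs()]) and returns at most `n`.
#'
#' @param catalog an `eqtm_catalog`.
#' @param n maximum pairs to return (default 1000).
#' @param relation optionally restrict to `"cis"` or `"trans"` pairs before
#'   ranking.
#' @return data.frame `gene_id`, `cpg_id`, `p_value`, `relation`, ordered.
#' @export
top_pairs <- function(catalog, n = 1000, relation = NULL) {
  cat2 <- catalog
  if (!is.null(relation))
    cat2$pairs <- cat2$pairs[cat2$pairs$relation %in% relation, ,
                             drop = FALSE]
  lead <- lead_cpgs(cat2)
  lead <- lead[order(lead$p_value), , drop = FALSE]
  utils::head(lead, n)
}

#' Replication report for selected pairs
#'
#' Looks up each selected discovery pair in the validation statistics and
#' applies the policy: replicated means validation p at or below the policy
#' threshold and, if required, the same effect direction as in discovery.
#' Pairs missing from the validation statistics (e.g. filtered features)
#' are counted as unavailable and excluded from the rate denominator; the
#' rate over all selected pairs is also reported.
#'
#' @param selected data.frame with `cpg_id`, `gene_id`, `beta`, `p_value`,
#'   `relation` from the discovery stage (e.g. retained catalog pairs).
#' @param validation data.frame of validation statistics with `cpg_id`,
#'   `gene_id`, `beta`, `p_value`.
#' @param policy a [replication_policy()].
#' @return `replication_report`: list with per-pair `records` and a
#'   `summary` (n selected / evaluated / unavailable / replicated, rate and
#'   rate over selected, per relation and overall).
#' @export
replication_report <- function(selected, validation, policy) {
  stopifnot(inherits(policy, "replication_policy"))
  need <- c("cpg_id", "gene_id", "beta", "p_value", "relation")
  if (!all(need %in% names(selected)))
    stop("selected pairs need columns: ", paste(need, collapse = ", "))
  key <- function(d) paste(d$cpg_id, d$gene_id, sep = "\r")
  idx <- match(key(selected), key(validation))
  available <- !is.na(idx)
  thr <- policy_threshold(policy, selected$relation)
  val_p <- validation$p_value[idx]
  val_beta <- validation$beta[idx]
  sign_match <- sign(val_beta) == sign(selected$beta)
  replicated <- available & val_p <= thr &
    (!policy$require_sign_match | sign_match)
  replicated[!available] <- FALSE
  records <- data.frame(
    cpg_id = selected$cpg_id, gene_id = selected$gene_id,
    relation = selected$relation,
    discovery_beta = selected$beta, discovery_p = selected$p_value,
    validation_beta = val_beta, validation_p = val_p,
    threshold = thr, available = available,
    sign_match = ifelse(available, sign_match, NA),
    replicated = replicated, stringsAsFactors = FALSE)
  summarize <- function(rec) {
    n_sel <- nrow(rec); n_av <- sum(rec$available)
    n_rep <- sum(rec$replicated)
    data.frame(n_selected = n_sel, n_evaluated = n_av,
               n_unavailable = n_sel - n_av, n_replicated = n_rep,
               rate = if (n_av > 0) n_rep / n_av else NA_real_,
               rate_of_selected = if (n_sel > 0) n_rep / n_sel else NA_real_)
  }
  groups <- split(records, records$relation)
  summary <- cbind(relation = c(names(groups), "all"),
                   do.call(rbind, c(unname(lapply(groups, summarize)),
                                    list(summarize(records)))))
  rownames(summary) <- NULL
  structure(list(records = records, summary = summary, policy = policy),
            class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("replication_report [%s]\n", x$policy$mode))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
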