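#' One-sided Fisher-exact set enrichment
#'
#' Tests a query feature set for over-representation in each annotation set
#' over a fixed universe. The one-sided p-value is the exact hypergeometric
#' upper tail `P(X >= a)` for the observed 2x2 table
#' (a = query-and-set, b = query-not-set, c = set-not-query, d = neither);
#' the sample odds ratio `ad / bc` is reported with an infinite sentinel
#' when `bc = 0`. Benjamini-Hochberg q-values are added across sets.
#' Query features outside the universe are dropped with a warning.
#'
#' @param query character vector of feature IDs.
#' @param sets named list of character vectors (each a subset of the
#'   universe).
#' @param universe character vector of all eligible feature IDs.
#' @return data.frame with `set_name`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p_one_sided`, `q_bh`.
#' @export
fisher_set_enrichment <- function(query, sets, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query feature(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  nq <- length(query)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    K <- length(s)
    a <- length(intersect(query, s))
    b <- nq - a
    c_ <- K - a
    d <- N - a - b - c_
    # hypergeometric upper tail P(X >= a)
    p <- stats::phyper(a - 1, K, N - K, nq, lower.tail = FALSE)
    or <- if (b * c_ == 0) {
      if (a * d == 0) NaN else Inf
    } else (a * d) / (b * c_)
    data.frame(set_name = nm, a = a, b = b, c = c_, d = d,
               odds_ratio = or,
               p_one_sided = min(max(p, .Machine$double.xmin), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_bh <- bh_fdr(out$p_one_sided)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (monotone, capped at 1), via
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Genomic-feature enrichment of a CpG set
#'
#' One Fisher test per genomic-feature flag (island, shore, DHS, gene body,
#' ...) comparing the query CpGs against the universe of tested CpGs, with
#' BH adjustment across the features.
#'
#' @param cpg_query character vector of CpG IDs.
#' @param annotations `feature_annotation` whose `cpgs` table carries 0/1
#'   feature columns.
#' @param feature_names features to test; default all in the annotation.
#' @param universe CpG universe; default all annotated CpGs.
#' @return data.frame as [fisher_set_enrichment()].
#' @export
feature_enrichment <- function(cpg_query, annotations,
                               feature_names = NULL, universe = NULL) {
  cpgs <- annotations$cpgs
  if (is.null(feature_names)) feature_names <- annotations$feature_names
  missing_f <- setdiff(feature_names, names(cpgs))
  if (length(missing_f) > 0)
    stop("unknown feature name(s): ", paste(missing_f, collapse = ", "))
  if (is.null(universe)) universe <- cpgs$cpg_id
  sets <- lapply(feature_names, function(f)
    cpgs$cpg_id[cpgs[[f]] == 1])
  names(sets) <- feature_names
  fisher_set_enrichment(cpg_query, sets, universe)
}

#' Read a two-column set file into a named list
#'
#' Reads a TSV with columns `set_name` and `feature_id` (e.g. a local
#' GWAS-catalog gene-trait table or a pathway membership table) into the
#' list-of-sets form [fisher_set_enrichment()] consumes.
#'
#' @param path TSV file with a header.
#' @return named list of character vectors.
#' @export
read_annotation_sets <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("set_name", "feature_id") %in% names(d)))
    stop("file needs columns set_name and feature_id")
  split(d$feature_id, d$set_name)
}
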