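# Degrees of freedom convention used throughout the scan: expression is
# regressed on methylation + q covariate columns + intercept, so
# df = n - q - 2. The blockwise path projects the covariates (plus
# intercept) out of both matrices once and tests the partial correlation
# with the same df, which reproduces the per-pair fit exactly
# (Frisch-Waugh-Lovell).

P_FLOOR <- .Machine$double.xmin

#' CpG-to-gene distance and cis/trans relation
#'
#' Distance is measured from the CpG position to the gene's strand-aware
#' transcription start site. Pairs on the same chromosome at most 1 Mb apart
#' (inclusive) are cis; all others — including every inter-chromosomal pair,
#' which gets an infinite distance sentinel — are trans.
#'
#' @param cpg one-row data.frame or list with `chrom` and `position`.
#' @param gene one-row data.frame or list with `chrom` and `tss`.
#' @param cis_window cis boundary in bp, inclusive; default 1e6.
#' @return list with `distance_bp` and `relation` (`"cis"` or `"trans"`).
#' @export
pair_distance <- function(cpg, gene, cis_window = 1e6) {
  if (is.na(cpg$chrom) || is.na(gene$chrom))
    stop("unknown chromosome label")
  if (cpg$chrom != gene$chrom)
    return(list(distance_bp = Inf, relation = "trans"))
  d <- abs(cpg$position - gene$tss)
  list(distance_bp = d,
       relation = if (d <= cis_window) "cis" else "trans")
}

#' Single CpG-transcript association
#'
#' Ordinary least squares of (residualized) expression on (residualized)
#' methylation, adjusting for the covariate design. Returns the methylation
#' coefficient with its standard error, t statistic and two-sided p-value on
#' `n - q - 2` degrees of freedom (q = covariate columns beyond the
#' intercept).
#'
#' @param meth_row numeric vector of methylation values per sample.
#' @param expr_row numeric vector of expression values per sample.
#' @param covariates data.frame, design matrix, or `NULL`.
#' @return list with `beta_hat`, `se`, `t_stat`, `p_value`, `df`.
#' @export
assoc_single <- function(meth_row, expr_row, covariates = NULL) {
  n <- length(meth_row)
  if (length(expr_row) != n) stop("row lengths differ")
  if (stats::sd(meth_row) == 0) stop("constant methylation row")
  X <- if (is.null(covariates)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else if (is.matrix(covariates)) covariates
    else covariate_design(covariates, names(meth_row))
  q <- ncol(X) - 1L
  df <- n - q - 2L
  if (df <= 0) stop("not enough samples for the covariate design")
  fit <- stats::lm.fit(cbind(meth = meth_row, X), expr_row)
  beta <- fit$coefficients[["meth"]]
  rss <- sum(fit$residuals^2)
  XtX_inv <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank),
                                drop = FALSE])
  # position of the methylation column after pivoting
  pos <- match(1L, fit$qr$pivot)
  se <- sqrt(rss / df * XtX_inv[pos, pos])
  t_stat <- beta / se
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  list(beta_hat = beta, se = se, t_stat = t_stat,
       p_value = max(p, P_FLOOR), df = df,
       p_floored = p < P_FLOOR)
}

#' Single association conditional on a SNP dosage
#'
#' [assoc_single()] with the SNP dosage appended to the covariate design:
#' the methylation term is tested with one fewer residual degree of freedom.
#' Used to ask whether a CpG-transcript association survives conditioning on
#' a nearby variant.
#'
#' @inheritParams assoc_single
#' @param snp_dosage numeric vector of genotype dosages per sample.
#' @return as [assoc_single()].
#' @export
conditional_assoc <- function(meth_row, expr_row, snp_dosage,
                              covariates = NULL) {
  if (stats::sd(snp_dosage) == 0) stop("constant SNP dosage")
  if (abs(stats::cor(meth_row, snp_dosage)) >= 1 - 1e-12)
    stop("SNP dosage collinear with methylation; term not identifiable")
  n <- length(meth_row)
  X <- if (is.null(covariates)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else if (is.matrix(covariates)) covariates
    else covariate_design(covariates, names(meth_row))
  assoc_single(meth_row, expr_row, cbind(X, snp = snp_dosage))
}

#' Genomic inflation factor
#'
#' lambda = median observed 1-df chi-square statistic divided by the null
#' chi-square median (0.4549364...). Values near 1 indicate calibrated
#' p-values; values above 1 indicate inflation.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return lambda (positive scalar).
#' @export
genomic_inflation <- function(p_values) {
  if (length(p_values) == 0) stop("no p-values")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Genome-wide blockwise eQTM scan
#'
#' Tests every CpG x transcript pair: the covariate design (with intercept)
#' is projected out of both matrices once, cross-correlations are computed
#' in CpG blocks, and each correlation is converted to the identical OLS
#' t test that [assoc_single()] performs (`t = r sqrt(df) / sqrt(1 - r^2)`,
#' `df = n - q - 2`). Pairs are classified cis/trans by [pair_distance()]
#' and retained at the relation-specific significance threshold. Inflation
#' diagnostics (lambda, QQ points) are computed on ALL tested pairs.
#' Zero-variance features are excluded before testing and listed in the
#' diagnostics.
#'
#' @param meth methylation matrix (features x samples), typically
#'   residualized and winsorized betas.
#' @param expr expression matrix (features x samples), typically residualized
#'   log2 expression.
#' @param covariates data.frame or design matrix, or `NULL`.
#' @param annotations `feature_annotation` covering all features (see
#'   [build_genome_layout()]).
#' @param cis_alpha retain cis pairs at p <= cis_alpha (default 1e-7).
#' @param trans_alpha retain trans pairs at p <= trans_alpha (default 1e-14).
#' @param cis_window cis boundary in bp (default 1e6, inclusive).
#' @param block_size CpGs per block (default 512).
#' @param keep_all retain every tested pair regardless of significance
#'   (catalog flagged unfiltered); default FALSE.
#' @param qq_points number of QQ points to keep in the diagnostics.
#' @return list with `catalog` (an `eqtm_catalog`: data.frame of retained
#'   `pairs`, thresholds, `lead` index) and `diagnostics` (`lambda_gc`,
#'   `n_tests`, `qq`, `excluded`, `direction_counts`).
#' @export
scan_all_pairs <- function(meth, expr, covariates = NULL, annotations,
                           cis_alpha = 1e-7, trans_alpha = 1e-14,
                           cis_window = 1e6, block_size = 512L,
                           keep_all = FALSE, qq_points = 200L) {
  M <- as_values(meth)
  E <- as_values(expr)
  check_same_samples(M, E, "methylation and expression")
  if (block_size < 1) stop("block_size must be at least 1")
  n <- ncol(M)

  cpgs <- annotations$cpgs
  genes <- annotations$genes
  if (!all(rownames(M) %in% cpgs$cpg_id))
    stop("annotations do not cover all CpGs")
  if (!all(rownames(E) %in% genes$gene_id))
    stop("annotations do not cover all genes")

  excluded <- c(rownames(M)[apply(M, 1, stats::sd) == 0],
                rownames(E)[apply(E, 1, stats::sd) == 0])
  M <- M[!(rownames(M) %in% excluded), , drop = FALSE]
  E <- E[!(rownames(E) %in% excluded), , drop = FALSE]
  if (nrow(M) == 0 || nrow(E) == 0)
    stop("no testable features after excluding zero-variance rows")

  X <- if (is.null(covariates)) {
    matrix(1, n, 1)
  } else if (is.matrix(covariates)) covariates
    else covariate_design(covariates, colnames(M))
  q <- ncol(X) - 1L
  df <- n - q - 2L
  if (df <= 0) stop("not enough samples for the covariate design")
  qr_x <- qr(X)
  Mr <- t(qr.resid(qr_x, t(M)))
  Er <- t(qr.resid(qr_x, t(E)))
  ss_m <- rowSums(Mr^2)
  ss_e <- rowSums(Er^2)

  cpg_idx <- match(rownames(M), cpgs$cpg_id)
  gene_idx <- match(rownames(E), genes$gene_id)
  gene_chrom <- genes$chrom[gene_idx]
  gene_tss <- genes$tss[gene_idx]

  all_p <- numeric(0)
  retained <- vector("list", ceiling(nrow(M) / block_size))
  bi <- 0L
  for (start in seq(1L, nrow(M), by = block_size)) {
    bi <- bi + 1L
    rows <- start:min(start + block_size - 1L, nrow(M))
    r <- (Mr[rows, , drop = FALSE] %*% t(Er)) /
      sqrt(outer(ss_m[rows], ss_e))
    r <- pmin(pmax(r, -1), 1)
    t_stat <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
    p <- pmax(p, P_FLOOR)
    all_p <- c(all_p, as.numeric(p))

    d <- abs(outer(cpgs$position[cpg_idx[rows]], gene_tss, "-"))
    same <- outer(cpgs$chrom[cpg_idx[rows]], gene_chrom, "==")
    d[!same] <- Inf
    is_cis <- d <= cis_window
    keep <- if (keep_all) p <= 1
            else (is_cis & p <= cis_alpha) | (!is_cis & p <= trans_alpha)
    if (any(keep)) {
      w <- which(keep, arr.ind = TRUE)
      beta <- r[keep] * sqrt(ss_e[w[, 2]] / ss_m[rows][w[, 1]])
      retained[[bi]] <- data.frame(
        cpg_id = rownames(M)[rows][w[, 1]],
        gene_id = rownames(E)[w[, 2]],
        beta = beta,
        se = beta / t_stat[keep],
        t_stat = t_stat[keep],
        p_value = p[keep],
        distance_bp = d[keep],
        relation = ifelse(is_cis[keep], "cis", "trans"),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, retained[!vapply(retained, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- data.frame(cpg_id = character(), gene_id = character(),
                        beta = numeric(), se = numeric(), t_stat = numeric(),
                        p_value = numeric(), distance_bp = numeric(),
                        relation = character(), stringsAsFactors = FALSE)
  pairs$direction <- sign(pairs$beta)

  catalog <- structure(
    list(pairs = pairs, cis_alpha = cis_alpha, trans_alpha = trans_alpha,
         filtered = !keep_all, lead = NULL),
    class = "eqtm_catalog")
  if (nrow(pairs) > 0) catalog$lead <- lead_cpgs(catalog)

  m <- length(all_p)
  qq_idx <- unique(round(seq(1, m, length.out = min(qq_points, m))))
  sp <- sort(all_p)
  diagnostics <- list(
    lambda_gc = genomic_inflation(all_p),
    n_tests = m,
    qq = data.frame(expected = -log10(qq_idx / (m + 1)),
                    observed = -log10(sp[qq_idx])),
    excluded = excluded,
    direction_counts = c(positive = sum(pairs$beta > 0),
                         negative = sum(pairs$beta < 0)))
  list(catalog = catalog, diagnostics = diagnostics)
}

#' @export
print.eqtm_catalog <- function(x, ...) {
  cat(sprintf(paste0("eqtm_catalog: %d pairs (%d cis, %d trans)%s; ",
                     "thresholds cis %.3g / trans %.3g\n"),
              nrow(x$pairs), sum(x$pairs$relation == "cis"),
              sum(x$pairs$relation == "trans"),
              if (x$filtered) "" else " [unfiltered]",
              x$cis_alpha, x$trans_alpha))
  invisible(x)
}

#' Lead CpG per eGene
#'
#' For every eGene in the catalog, the CpG with the smallest association
#' p-value. Exact p ties are broken by smaller distance, then lexicographic
#' CpG ID.
#'
#' @param catalog an `eqtm_catalog` with at least one pair.
#' @return data.frame with `gene_id`, `cpg_id`, `p_value`, `relation`.
#' @export
lead_cpgs <- function(catalog) {
  pairs <- catalog$pairs
  if (is.null(pairs) || nrow(pairs) == 0) stop("catalog is empty")
  ord <- order(pairs$gene_id, pairs$p_value, pairs$distance_bp, pairs$cpg_id)
  pairs <- pairs[ord, ]
  lead <- pairs[!duplicated(pairs$gene_id),
                c("gene_id", "cpg_id", "p_value", "relation")]
  rownames(lead) <- NULL
  lead
}
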