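#' Transcriptome-wide association scan
#'
#' Per-gene least squares of a quantitative trait on expression plus the
#' covariate design, with optional trait-specific extra adjustments (e.g.
#' BMI and lipid-medication use for a log-triglycerides trait) appended to
#' the design.
#'
#' @param expr expression matrix (genes x samples), typically residualized
#'   log2 expression.
#' @param trait numeric per-sample trait vector (same sample order).
#' @param covariates data.frame or design matrix, or `NULL`.
#' @param extra_adjustments optional data.frame of additional per-sample
#'   columns appended to the design.
#' @return data.frame `gene_id`, `beta`, `se`, `t_stat`, `p_value`, sorted
#'   as the input genes.
#' @export
twas_scan <- function(expr, trait, covariates = NULL,
                      extra_adjustments = NULL) {
  E <- as_values(expr)
  n <- ncol(E)
  if (length(trait) != n) stop("trait length must match sample count")
  if (stats::sd(trait) == 0) stop("constant trait")
  X <- if (is.null(covariates)) {
    matrix(1, n, 1, dimnames = list(colnames(E), "(Intercept)"))
  } else if (is.matrix(covariates)) covariates
    else covariate_design(covariates, colnames(E))
  if (!is.null(extra_adjustments)) {
    extra <- stats::model.matrix(~ . - 1, data = as.data.frame(
      extra_adjustments))
    X <- cbind(X, extra)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("adjustment design is rank deficient")
  tr_r <- qr.resid(qr_x, trait)
  Er <- t(qr.resid(qr_x, t(E)))
  df <- n - (ncol(X) - 1L) - 2L
  if (df <= 0) stop("not enough samples for the adjustment design")
  ss_e <- rowSums(Er^2)
  ss_t <- sum(tr_r^2)
  cov_et <- as.numeric(Er %*% tr_r)
  beta <- cov_et / ss_e
  r <- cov_et / sqrt(ss_e * ss_t)
  r <- pmin(pmax(r, -1), 1)
  t_stat <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  se <- beta / t_stat
  se[!is.finite(se)] <- sqrt(ss_t / df / ss_e)[!is.finite(se)]
  data.frame(gene_id = rownames(E), beta = beta, se = se, t_stat = t_stat,
             p_value = pmax(2 * stats::pt(abs(t_stat), df,
                                          lower.tail = FALSE), P_FLOOR),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Epigenome-wide association scan
#'
#' Per-CpG analogue of [twas_scan()]: the trait regressed on each CpG's
#' methylation plus the covariate design. Used to derive trait-associated
#' CpG sets for triplet selection.
#'
#' @param meth methylation matrix (CpGs x samples).
#' @inheritParams twas_scan
#' @return data.frame `cpg_id`, `beta`, `se`, `t_stat`, `p_value`.
#' @export
ewas_scan <- function(meth, trait, covariates = NULL,
                      extra_adjustments = NULL) {
  out <- twas_scan(meth, trait, covariates, extra_adjustments)
  names(out)[1] <- "cpg_id"
  out
}

#' Align trait-associated CpGs, transcripts and cis pairs into triplets
#'
#' A candidate CpG -> expression -> trait triplet (c, g, t) is emitted iff
#' (c, t) is an EWAS hit, (g, t) is a TWAS hit, and (c, g) is a significant
#' cis eQTM pair in the catalog. Trans-only pairs never form triplets.
#'
#' @param ewas_hits data.frame with `cpg_id`, `trait_id`.
#' @param twas_hits data.frame with `gene_id`, `trait_id`.
#' @param catalog an `eqtm_catalog`; only its cis pairs are used.
#' @return data.frame `cpg_id`, `gene_id`, `trait_id` (zero rows if no
#'   alignment).
#' @export
select_triplets <- function(ewas_hits, twas_hits, catalog) {
  cis <- catalog$pairs[catalog$pairs$relation == "cis",
                       c("cpg_id", "gene_id")]
  out <- merge(merge(ewas_hits[, c("cpg_id", "trait_id")], cis,
                     by = "cpg_id"),
               twas_hits[, c("gene_id", "trait_id")],
               by = c("gene_id", "trait_id"))
  out <- unique(out[, c("cpg_id", "gene_id", "trait_id")])
  out <- out[order(out$trait_id, out$cpg_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Causal mediation of a CpG -> expression -> trait pathway
#'
#' Linear-model mediation without exposure-mediator interaction. Two fits:
#' the mediator model `expression ~ methylation + covariates` (coefficient
#' a) and the outcome model `trait ~ methylation + expression + covariates`
#' (direct effect c', mediator effect b). Point estimates are the analytic
#' ACME = a*b, ADE = c', total = a*b + c' (the identity holds exactly).
#' Uncertainty comes from quasi-Bayesian simulation: `n_sims` draws of a
#' from its asymptotic normal and of (c', b) from their joint asymptotic
#' normal, recombined per draw; percentile intervals and two-sided
#' simulation p-values are reported. The proportion mediated is summarized
#' by the median over draws of `a*b / (a*b + c')` (robust to near-zero
#' totals); the point ratio is also reported, flagged when outside (0, 1)
#' (opposite-sign direct and mediated effects).
#'
#' @param meth_row per-sample methylation (exposure).
#' @param expr_row per-sample expression (mediator).
#' @param trait per-sample outcome.
#' @param covariates data.frame or design matrix, or `NULL`.
#' @param n_sims quasi-Bayesian draws (default 1000).
#' @param seed integer seed for the draws.
#' @param conf_level interval level (default 0.95).
#' @return `mediation_result`: point estimates, CIs and p-values for ACME,
#'   ADE and total effect, both proportion-mediated summaries, the model
#'   coefficients (a, b, c'), `n_sims`, `seed`, and a `scale` flag
#'   (`"per_unit_beta"`).
#' @export
mediate_triplet <- function(meth_row, expr_row, trait, covariates = NULL,
                            n_sims = 1000, seed = 1L, conf_level = 0.95) {
  n <- length(meth_row)
  if (length(expr_row) != n || length(trait) != n)
    stop("meth, expr and trait must have equal length")
  if (stats::sd(expr_row) == 0) stop("zero-variance mediator")
  if (stats::sd(meth_row) == 0) stop("zero-variance exposure")
  X <- if (is.null(covariates)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else if (is.matrix(covariates)) covariates
    else covariate_design(covariates, names(meth_row))
  if (n <= ncol(X) + 3) stop("not enough samples for the mediation models")

  fit_ols <- function(D, y) {
    qr_d <- qr(D)
    if (qr_d$rank < ncol(D)) stop("mediation design is rank deficient")
    coefs <- qr.coef(qr_d, y)
    res <- qr.resid(qr_d, y)
    df <- n - ncol(D)
    sigma2 <- sum(res^2) / df
    # chol2inv on the pivoted R; map back to original column order
    vc <- chol2inv(qr.R(qr_d)) * sigma2
    piv <- qr_d$pivot
    vc_full <- matrix(NA_real_, ncol(D), ncol(D))
    vc_full[piv, piv] <- vc
    list(coef = coefs, vcov = vc_full)
  }

  Dm <- cbind(meth = meth_row, X)
  med_fit <- fit_ols(Dm, expr_row)
  a_hat <- med_fit$coef[["meth"]]
  a_se2 <- med_fit$vcov[1, 1]

  Do <- cbind(meth = meth_row, expr = expr_row, X)
  out_fit <- fit_ols(Do, trait)
  c_hat <- out_fit$coef[["meth"]]
  b_hat <- out_fit$coef[["expr"]]
  v_cb <- out_fit$vcov[1:2, 1:2]

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  a_draw <- stats::rnorm(n_sims, a_hat, sqrt(a_se2))
  cb_draw <- MASS::mvrnorm(n_sims, c(c_hat, b_hat), v_cb)
  acme_draw <- a_draw * cb_draw[, 2]
  ade_draw <- cb_draw[, 1]
  total_draw <- acme_draw + ade_draw
  prop_draw <- acme_draw / total_draw

  qs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  sim_p <- function(x) min(2 * min(mean(x > 0), mean(x < 0)) +
                             mean(x == 0), 1)
  pack <- function(point, draws) list(
    estimate = point,
    sim_estimate = mean(draws),
    ci = unname(stats::quantile(draws, qs)),
    p = sim_p(draws))

  acme <- a_hat * b_hat
  ade <- c_hat
  total <- acme + ade
  prop_point <- if (abs(total) > 0) acme / total else NA_real_
  structure(list(
    acme = pack(acme, acme_draw),
    ade = pack(ade, ade_draw),
    total = pack(total, total_draw),
    proportion_mediated = list(
      estimate = stats::median(prop_draw),
      point_ratio = prop_point,
      outside_unit = !is.na(prop_point) &&
        (prop_point < 0 || prop_point > 1),
      ci = unname(stats::quantile(prop_draw, qs))),
    coefficients = c(a = a_hat, b = b_hat, c_prime = c_hat),
    conf_level = conf_level, n_sims = n_sims, seed = seed,
    scale = "per_unit_beta"), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  fmt <- function(nm, q) cat(sprintf(
    "  %-18s %8.4f  [%.4f, %.4f]  p = %.3g\n", nm, q$estimate,
    q$ci[1], q$ci[2], q$p))
  cat(sprintf("mediation_result (scale: %s, %d sims)\n", x$scale, x$n_sims))
  fmt("ACME", x$acme); fmt("ADE", x$ade); fmt("total", x$total)
  cat(sprintf("  %-18s %8.4f  [%.4f, %.4f]%s\n", "prop. mediated",
              x$proportion_mediated$estimate,
              x$proportion_mediated$ci[1], x$proportion_mediated$ci[2],
              if (isTRUE(x$proportion_mediated$outside_unit))
                "  [outside (0,1)]" else ""))
  invisible(x)
}

#' Rescale mediation effects to a 10% methylation increase
#'
#' Methylation betas are proportions, so per-unit-beta effects correspond
#' to a 0-to-1 sweep; dividing by ten expresses them per 10% increase in
#' methylation. Effects and interval bounds are divided by 10; the
#' proportion mediated is scale-free and unchanged. Re-applying to an
#' already rescaled result is an error.
#'
#' @param result a `mediation_result` on the per-unit-beta scale.
#' @return the rescaled `mediation_result` (scale `"per_10pct"`).
#' @export
rescale_per_10pct <- function(result) {
  stopifnot(inherits(result, "mediation_result"))
  if (result$scale == "per_10pct")
    stop("result is already on the per-10% scale")
  for (nm in c("acme", "ade", "total")) {
    result[[nm]]$estimate <- result[[nm]]$estimate / 10
    result[[nm]]$sim_estimate <- result[[nm]]$sim_estimate / 10
    result[[nm]]$ci <- result[[nm]]$ci / 10
  }
  result$coefficients[c("a", "c_prime")] <-
    result$coefficients[c("a", "c_prime")] / 10
  result$scale <- "per_10pct"
  result
}
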