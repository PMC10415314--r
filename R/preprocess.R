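#' TMM normalization factors
#'
#' Between-sample normalization factors for RNA-seq count libraries by the
#' trimmed mean of M-values (TMM) method: the reference sample is the one
#' whose upper-quartile/library-size ratio is closest to the mean of those
#' ratios; per-gene M (log-ratio of library-size-scaled proportions) and A
#' values are computed on genes expressed in both samples, doubly trimmed
#' (30% on M, 5% on A by default), and the factor is 2 to the
#' precision-weighted mean of the retained M values, with weights the inverse
#' asymptotic binomial variances. Factors are rescaled to unit geometric
#' mean. The computation is delegated to \code{edgeR::calcNormFactors}.
#'
#' @param counts count matrix (features x samples) or `omics_matrix` with
#'   layer `"count"`; at least two samples, none all-zero.
#' @param trim_m fraction of M values trimmed from each tail (default 0.30).
#' @param trim_a fraction of A values trimmed from each tail (default 0.05).
#' @return named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  x <- as_values(counts, "count")
  if (ncol(x) < 2) stop("TMM needs at least two samples")
  if (any(colSums(x) == 0)) stop("all-zero sample(s): ",
                                 paste(colnames(x)[colSums(x) == 0],
                                       collapse = ", "))
  f <- edgeR::calcNormFactors(x, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  stats::setNames(as.numeric(f), colnames(x))
}

#' Normalized log2 expression
#'
#' Converts counts to log2 counts-per-million on TMM-adjusted library sizes:
#' \code{log2(count / (libsize * factor) * scale + 1)}. Adding one unit
#' before the log keeps zero counts at exactly zero.
#'
#' @param counts count matrix (features x samples).
#' @param factors per-sample normalization factors from [tmm_factors()] (all
#'   positive, same samples).
#' @param scale per-how-many scaling of the normalized proportion; default
#'   `1e6` (counts per million). Recorded in the result's `"scale"` attribute.
#' @return `omics_matrix` with layer `"log_expression"`.
#' @export
normalize_expression <- function(counts, factors, scale = 1e6) {
  x <- as_values(counts, "count")
  if (!all(colnames(x) %in% names(factors)))
    stop("factors must cover every sample")
  factors <- factors[colnames(x)]
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("normalization factors must be positive and finite")
  eff_lib <- colSums(x) * factors
  out <- log2(sweep(x, 2, eff_lib, "/") * scale + 1)
  out <- omics_matrix(out, "log_expression")
  attr(out, "scale") <- scale
  out
}

#' Residualize features on a covariate design
#'
#' Replaces each feature row with its least-squares residuals on the
#' covariate design (with intercept). Residual rows are orthogonal to every
#' design column; applying the operation twice is a no-op (projection
#' idempotence).
#'
#' @param matrix feature x sample matrix (any layer).
#' @param covariates data.frame of per-sample covariates (see
#'   [covariate_design()]), or a pre-built numeric design matrix.
#' @return `omics_matrix` with layer `"residual"`.
#' @export
residualize <- function(matrix, covariates) {
  x <- as_values(matrix)
  X <- if (is.matrix(covariates)) covariates
       else covariate_design(covariates, colnames(x))
  if (nrow(X) != ncol(x)) stop("design rows must equal the number of samples")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("covariate design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  res <- t(qr.resid(qr_x, t(x)))
  dimnames(res) <- dimnames(x)
  omics_matrix(res, "residual")
}

#' Winsorize feature rows at mean +/- k standard deviations
#'
#' Single-pass clipping: per row, the mean and sample SD (denominator n-1)
#' are computed once on the original values and every value is clipped to
#' `[mean - k*SD, mean + k*SD]`. Because the bounds come from the pre-clip
#' row, re-applying the operation can clip further; idempotence is not
#' guaranteed. Zero-variance rows are returned unchanged.
#'
#' @param matrix feature x sample matrix.
#' @param k bound multiplier, k > 0; default 3.
#' @return matrix of the same shape and layer with clipped rows.
#' @export
winsorize_rows <- function(matrix, k = 3) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) stop("`k` must be > 0")
  x <- as_values(matrix)
  mu <- rowMeans(x)
  sd_ <- apply(x, 1, stats::sd)
  lo <- mu - k * sd_
  hi <- mu + k * sd_
  keep <- sd_ == 0  # constant rows pass through untouched
  out <- pmin(pmax(x, lo), hi)
  out[keep, ] <- x[keep, ]
  dimnames(out) <- dimnames(x)
  ly <- attr(matrix, "layer")
  if (!is.null(ly)) out <- omics_matrix(out, ly) else out
}

#' Sample-space principal components
#'
#' Principal components of the samples computed by singular value
#' decomposition of the feature-centered matrix (each feature row centered
#' at zero). Component i's variance fraction is sigma_i^2 / sum(sigma_j^2)
#' over all components.
#'
#' @param matrix feature x sample matrix.
#' @param k number of components to return, `1 <= k <= min(features, samples)`.
#' @return list with `scores` (samples x k) and `variance_fraction`
#'   (length k, non-increasing).
#' @export
principal_components <- function(matrix, k) {
  x <- as_values(matrix)
  if (!is.numeric(k) || length(k) != 1 || k <= 0 || k != round(k))
    stop("`k` must be a positive integer")
  if (k > min(dim(x)))
    stop("`k` exceeds min(features, samples)")
  xc <- x - rowMeans(x)
  sv <- svd(t(xc), nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(colnames(x), paste0("PC", seq_len(k)))
  list(scores = scores,
       variance_fraction = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}
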