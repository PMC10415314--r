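#' Build a full-rank model design from a covariate table
#'
#' Expands a per-sample covariate table into a numeric design matrix with an
#' intercept. Character and factor columns are expanded to treatment-contrast
#' indicators; numeric columns are passed through. The design is checked for
#' full column rank and the collinear columns are named in the error if it is
#' not.
#'
#' @param covariates data.frame of per-sample covariates with sample IDs as
#'   row names (age, sex, cell counts/fractions, batch, technical PCs, ...),
#'   or `NULL` for an intercept-only design.
#' @param sample_ids sample IDs the design must cover, in order. Defaults to
#'   the table's row names.
#' @return numeric matrix, samples x columns, first column the intercept.
#' @export
covariate_design <- function(covariates, sample_ids = NULL) {
  if (is.null(covariates)) {
    if (is.null(sample_ids)) stop("need sample_ids for an intercept-only design")
    return(matrix(1, length(sample_ids), 1,
                  dimnames = list(sample_ids, "(Intercept)")))
  }
  if (!is.data.frame(covariates))
    stop("`covariates` must be a data.frame")
  if (is.null(sample_ids)) sample_ids <- rownames(covariates)
  if (!all(sample_ids %in% rownames(covariates)))
    stop("covariate table does not cover all samples")
  covariates <- covariates[sample_ids, , drop = FALSE]
  covariates[] <- lapply(covariates, function(col) {
    if (is.character(col) || is.logical(col)) factor(col) else col
  })
  X <- stats::model.matrix(~ ., data = covariates)
  rownames(X) <- sample_ids
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("covariate design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  X
}
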