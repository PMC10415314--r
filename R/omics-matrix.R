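#' Feature-by-sample omics matrix
#'
#' A thin wrapper around a numeric matrix (features in rows, samples in
#' columns) carrying a `layer` tag that records what the values are:
#' methylation beta values, raw counts, log2 expression, or residuals.
#' Layer-specific invariants are enforced at construction: betas must lie
#' strictly in (0, 1), counts must be non-negative integers.
#'
#' @param values numeric matrix, features x samples, with unique row and
#'   column names (feature IDs and sample IDs).
#' @param layer one of `"beta"`, `"count"`, `"log_expression"`, `"residual"`.
#' @return an `omics_matrix`: the input matrix with a `layer` attribute.
#' @examples
#' m <- matrix(runif(6), 2, 3,
#'             dimnames = list(c("cg1", "cg2"), paste0("s", 1:3)))
#' om <- omics_matrix(m, "beta")
#' omics_layer(om)
#' @export
omics_matrix <- function(values,
                         layer = c("beta", "count", "log_expression",
                                   "residual")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature IDs")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs")
  if (anyNA(values)) stop("missing values are not supported")
  if (layer == "beta" && (any(values <= 0) || any(values >= 1)))
    stop("layer 'beta' requires values strictly in (0, 1)")
  if (layer == "count" &&
      (any(values < 0) || any(values != round(values))))
    stop("layer 'count' requires non-negative integer values")
  structure(values, layer = layer, class = c("omics_matrix", class(values)))
}

#' @rdname omics_matrix
#' @param x an `omics_matrix` (or plain matrix, for which `NULL` is returned).
#' @export
omics_layer <- function(x) attr(x, "layer")

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples\n",
              omics_layer(x), nrow(x), ncol(x)))
  invisible(x)
}

#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "layer") <- attr(x, "layer")
    class(out) <- class(x)
  }
  out
}

# Accept either an omics_matrix or a plain named numeric matrix; check the
# layer when one is declared.
as_values <- function(x, expect_layer = NULL, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", arg))
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(sprintf("`%s` must have row and column names", arg))
  ly <- attr(x, "layer")
  if (!is.null(expect_layer) && !is.null(ly) && !(ly %in% expect_layer))
    stop(sprintf("`%s` has layer '%s', expected %s", arg, ly,
                 paste(expect_layer, collapse = "/")))
  unclass_matrix(x)
}

unclass_matrix <- function(x) {
  attr(x, "layer") <- NULL
  if (inherits(x, "omics_matrix"))
    class(x) <- setdiff(class(x), "omics_matrix")
  x
}

check_same_samples <- function(a, b, what = "matrices") {
  if (!identical(colnames(a), colnames(b)))
    stop(sprintf("%s must share the same sample IDs in the same order", what))
  invisible(TRUE)
}
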