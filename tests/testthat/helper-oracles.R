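# Independent oracles used across the suite. These deliberately do not call
# the package's own code paths.

# Step-by-step trimmed-mean-of-M-values recipe: reference = sample whose
# upper-quartile/library-size ratio is closest to the mean of those ratios;
# per-gene M and A on genes observed in both samples; double trim by rank
# (trim_m on M, trim_a on A); factor = 2^(precision-weighted mean of kept M)
# with inverse asymptotic binomial variances as weights; rescale to unit
# geometric mean.
tmm_oracle <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(obs) {
    yo <- counts[, obs]; yr <- counts[, ref]
    no <- lib[obs]; nr <- lib[ref]
    keep <- yo > 0 & yr > 0
    yo <- yo[keep]; yr <- yr[keep]
    M <- log2((yo / no) / (yr / nr))
    A <- 0.5 * log2((yo / no) * (yr / nr))
    v <- (no - yo) / (no * yo) + (nr - yr) / (nr * yr)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    k <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f <- sum(M[k] / v[k]) / sum(1 / v[k])
    if (!is.finite(f) || abs(f) < 1e-6) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# per-row OLS residuals via explicit normal equations
residual_oracle <- function(y, X) {
  as.numeric(y - X %*% solve(crossprod(X), crossprod(X, y)))
}

# exhaustive one-sided hypergeometric upper tail P(overlap >= a) for a 2x2
# table with fixed margins, by enumeration over all possible overlaps
fisher_upper_oracle <- function(a, set_size, query_size, universe_size) {
  ks <- max(0, query_size + set_size - universe_size):min(set_size,
                                                          query_size)
  w <- choose(set_size, ks) * choose(universe_size - set_size,
                                     query_size - ks)
  sum(w[ks >= a]) / sum(w)
}

# Benjamini-Hochberg step-up by the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# full-design OLS for one CpG-transcript pair: expression on methylation,
# covariates and intercept, coefficient table from lm()
pair_ols_oracle <- function(meth, expr, X) {
  d <- data.frame(e = expr, m = meth)
  fit <- if (is.null(X)) stats::lm(e ~ m, data = d)
         else stats::lm(e ~ m + X[, -1, drop = FALSE], data = d)
  co <- summary(fit)$coefficients["m", ]
  list(beta = unname(co[1]), se = unname(co[2]), p = unname(co[4]))
}

make_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

rand_omics <- function(nf, ns, prefix = "f", seed = 1) {
  set.seed(seed)
  matrix(rnorm(nf * ns), nf, ns,
         dimnames = list(make_ids(prefix, nf), make_ids("s", ns)))
}
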