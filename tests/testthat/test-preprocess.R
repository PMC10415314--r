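count_fixture <- function(nf = 10, ns = 3, seed = 3, mu = 100, size = 5) {
  set.seed(seed)
  omics_matrix(matrix(rnbinom(nf * ns, mu = mu, size = size), nf, ns,
                      dimnames = list(make_ids("g", nf), make_ids("s", ns))),
               "count")
}

test_that("TMM factors: symmetry, library-size absorption, oracle", {
  k <- count_fixture()
  col1 <- unclass(k)[, 1]
  twin <- omics_matrix(cbind(s001 = col1, s002 = col1), "count")
  expect_equal(unname(tmm_factors(twin)), c(1, 1))

  # doubling one column is pure library-size change: all M values are 0
  dbl <- omics_matrix(cbind(s001 = col1, s002 = 2L * col1), "count")
  expect_equal(unname(tmm_factors(dbl)), c(1, 1))

  expect_equal(tmm_factors(k), tmm_oracle(k), tolerance = 1e-12)
  set.seed(11)
  big <- count_fixture(nf = 300, ns = 5, seed = 11, mu = 200, size = 2)
  expect_equal(tmm_factors(big), tmm_oracle(big), tolerance = 1e-12)
  # non-default trims follow the same recipe
  expect_equal(tmm_factors(big, trim_m = 0.2, trim_a = 0.1),
               tmm_oracle(big, trim_m = 0.2, trim_a = 0.1),
               tolerance = 1e-12)
})

test_that("TMM rejects degenerate input", {
  k <- count_fixture()
  expect_error(tmm_factors(k[, 1, drop = FALSE]), "two samples")
  z <- k; z[, 2] <- 0L
  expect_error(tmm_factors(omics_matrix(unclass(z), "count")), "all-zero")
})

test_that("log2 CPM normalization follows the closed form", {
  k <- count_fixture(nf = 8, ns = 4, seed = 5)
  f <- tmm_factors(k)
  le <- normalize_expression(k, f)
  expect_equal(omics_layer(le), "log_expression")
  # zero counts map to exactly zero
  k0 <- k; k0[1, 1] <- 0L
  k0 <- omics_matrix(unclass(k0), "count")
  expect_identical(as.numeric(normalize_expression(k0,
                                                   tmm_factors(k0))[1, 1]),
                   0)
  # direct formula
  eff <- colSums(k) * f[colnames(k)]
  manual <- log2(sweep(unclass(k), 2, eff, "/") * 1e6 + 1)
  expect_equal(unclass(le), manual, tolerance = 1e-12,
               ignore_attr = TRUE)
  # monotone in the raw count within a sample
  expect_equal(order(le[, 2]), order(k[, 2]))
  expect_error(normalize_expression(k, -f), "positive")
})

test_that("TMM scale invariance carries to normalized expression", {
  # proportional columns: every M value is exactly 0, so scaling one
  # sample leaves factors at (1, 1) and log-expression unchanged
  col1 <- unclass(count_fixture(nf = 50, ns = 1, seed = 7, mu = 150))[, 1]
  k <- omics_matrix(cbind(s001 = col1, s002 = col1), "count")
  k3 <- omics_matrix(cbind(s001 = col1, s002 = 3L * col1), "count")
  a <- normalize_expression(k, tmm_factors(k))
  b <- normalize_expression(k3, tmm_factors(k3))
  expect_lt(max(abs(a[, 2] - b[, 2])), 1e-6)
  # in general the precision weights depend on the raw counts, so the
  # invariance under scaling one sample is approximate
  k4 <- count_fixture(nf = 50, ns = 4, seed = 7, mu = 150)
  k5 <- k4; k5[, 3] <- 3L * k5[, 3]
  k5 <- omics_matrix(unclass(k5), "count")
  a4 <- normalize_expression(k4, tmm_factors(k4))
  b4 <- normalize_expression(k5, tmm_factors(k5))
  expect_lt(max(abs(a4[, 3] - b4[, 3])), 0.02)
})

test_that("residualize matches per-row OLS and is an idempotent projection", {
  set.seed(21)
  y <- rand_omics(20, 30, "f", seed = 21)
  covars <- data.frame(age = rnorm(30), sex = rbinom(30, 1, 0.5),
                       batch = sample(c("a", "b", "c"), 30, TRUE),
                       row.names = colnames(y))
  r <- residualize(y, covars)
  X <- covariate_design(covars)
  for (i in c(1, 7, 20))
    expect_equal(as.numeric(r[i, ]), residual_oracle(y[i, ], X),
                 tolerance = 1e-10)
  # orthogonal to every design column
  expect_lt(max(abs(unclass(r) %*% X)) / max(abs(y)), 1e-8)
  # projection idempotence
  r2 <- residualize(r, covars)
  expect_lt(max(abs(r2 - r)), 1e-8)
})

test_that("residualize handles special designs", {
  set.seed(22)
  n <- 24
  covars <- data.frame(x = rnorm(n), row.names = make_ids("s", n))
  # feature equal to a covariate column -> residual ~ 0
  y <- matrix(covars$x, 1, n,
              dimnames = list("f1", rownames(covars)))
  expect_lt(max(abs(residualize(y, covars))), 1e-10)
  # centered feature orthogonal to the covariate -> unchanged up to centering
  v <- residual_oracle(rnorm(n), cbind(1, covars$x))
  y2 <- matrix(v + 5, 1, n, dimnames = dimnames(y))
  expect_equal(as.numeric(residualize(y2, covars)), v, tolerance = 1e-10)
  # rank-deficient design names the collinear column
  bad <- data.frame(a = rnorm(n), b = 0, row.names = rownames(covars))
  bad$b <- 2 * bad$a
  expect_error(residualize(y, bad), "collinear.*b")
})

test_that("winsorization clips to pre-clip mean +/- k SD, single pass", {
  x <- c(rep(c(1, 2, 3), 10), 50)  # lone outlier beyond 3 SD
  n <- length(x)
  m <- matrix(x, 1, n, dimnames = list("f1", make_ids("s", n)))
  w <- winsorize_rows(m, k = 3)
  bound <- mean(x) + 3 * sd(x)
  expect_lt(bound, 50)
  expect_equal(as.numeric(w[1, n]), bound)
  expect_equal(w[1, -n], m[1, -n])
  # constant row unchanged
  cm <- matrix(4, 1, n, dimnames = dimnames(m))
  expect_equal(winsorize_rows(cm), cm, ignore_attr = TRUE)
  # row already inside the bounds unchanged
  tame <- matrix(rep(c(-1, 0, 1), length.out = n), 1, n,
                 dimnames = dimnames(m))
  expect_equal(winsorize_rows(tame), tame, ignore_attr = TRUE)
  expect_error(winsorize_rows(m, k = 0), "k")
})

test_that("winsorize bound property holds across random rows", {
  set.seed(31)
  y <- rand_omics(40, 25, "f", seed = 31)
  y[cbind(sample(40, 10, TRUE), sample(25, 10, TRUE))] <-
    rnorm(10, 0, 20)  # inject outliers
  w <- winsorize_rows(y, k = 3)
  mu <- rowMeans(y); s <- apply(y, 1, sd)
  expect_true(all(abs(w - mu) <= 3 * s + 1e-12))
})

test_that("principal components reproduce an eigendecomposition", {
  set.seed(41)
  y <- rand_omics(30, 10, "f", seed = 41)
  pc <- principal_components(y, 5)
  expect_true(all(diff(pc$variance_fraction) <= 1e-12))
  expect_true(all(pc$variance_fraction >= 0 & pc$variance_fraction <= 1))
  full <- principal_components(y, 10)
  expect_equal(sum(full$variance_fraction), 1, tolerance = 1e-10)
  # eigen oracle on the sample covariance of the centered data (up to sign)
  yc <- y - rowMeans(y)
  ev <- eigen(crossprod(yc))
  for (j in 1:5) {
    ref <- ev$vectors[, j] * sqrt(ev$values[j])
    agree <- min(max(abs(pc$scores[, j] - ref)),
                 max(abs(pc$scores[, j] + ref)))
    expect_lt(agree, 1e-8)
  }
  # rank-1 matrix: first component carries all variance
  r1 <- outer(rnorm(8), rnorm(6))
  dimnames(r1) <- list(make_ids("f", 8), make_ids("s", 6))
  expect_equal(principal_components(r1, 1)$variance_fraction, 1,
               tolerance = 1e-10)
  expect_error(principal_components(y, 0), "positive")
  expect_error(principal_components(y, 99), "exceeds")
})

test_that("PCs of residualized data are orthogonal to the design", {
  set.seed(43)
  y <- rand_omics(50, 20, "f", seed = 43)
  covars <- data.frame(a = rnorm(20), b = rbinom(20, 1, 0.4),
                       row.names = colnames(y))
  r <- residualize(y, covars)
  pc <- principal_components(r, 4)
  X <- covariate_design(covars)
  Xc <- sweep(X[, -1, drop = FALSE], 2, colMeans(X[, -1, drop = FALSE]))
  expect_lt(max(abs(crossprod(pc$scores, Xc))) /
              max(abs(pc$scores)), 1e-8)
})
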