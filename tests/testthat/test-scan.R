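tiny_annotation <- function() {
  cpgs <- data.frame(cpg_id = c("cg1", "cg2", "cg3"),
                     chrom = c("chr1", "chr1", "chr2"),
                     position = c(500000L, 1600000L, 100L),
                     stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 500000L,
                      end = 530000L, strand = "+", biotype = "pc",
                      tss = 500000L, stringsAsFactors = FALSE)
  structure(list(cpgs = cpgs, genes = genes), class = "feature_annotation")
}

test_that("cis/trans classification is TSS-anchored with an inclusive 1 Mb boundary", {
  ann <- tiny_annotation()
  at_tss <- pair_distance(ann$cpgs[1, ], ann$genes[1, ])
  expect_equal(at_tss$distance_bp, 0)
  expect_equal(at_tss$relation, "cis")

  exactly <- pair_distance(list(chrom = "chr1", position = 1500000),
                           ann$genes[1, ])
  expect_equal(exactly$distance_bp, 1e6)
  expect_equal(exactly$relation, "cis")
  over <- pair_distance(list(chrom = "chr1", position = 1500001),
                        ann$genes[1, ])
  expect_equal(over$relation, "trans")

  inter <- pair_distance(ann$cpgs[3, ], ann$genes[1, ])
  expect_equal(inter$distance_bp, Inf)
  expect_equal(inter$relation, "trans")
  expect_error(pair_distance(list(chrom = NA, position = 1), ann$genes[1, ]),
               "chromosome")

  # minus-strand TSS sits at the gene end
  gm <- ann$genes[1, ]; gm$strand <- "-"; gm$tss <- gm$end
  expect_equal(pair_distance(list(chrom = "chr1", position = 530000),
                             gm)$distance_bp, 0)
})

test_that("single-pair association matches the full lm() fit", {
  set.seed(51)
  n <- 60
  X <- covariate_design(data.frame(
    a = rnorm(n), b = rnorm(n), c = rbinom(n, 1, 0.5),
    d = rnorm(n), e = rnorm(n), row.names = make_ids("s", n)))
  meth <- rnorm(n)
  expr <- 0.5 * meth + X[, 2] + rnorm(n)
  got <- assoc_single(meth, expr, X)
  ora <- pair_ols_oracle(meth, expr, X)
  expect_equal(got$beta_hat, ora$beta, tolerance = 1e-10)
  expect_equal(got$se, ora$se, tolerance = 1e-10)
  expect_equal(got$p_value, ora$p, tolerance = 1e-10)
  expect_equal(got$df, n - 5 - 2)
  expect_equal(got$t_stat, got$beta_hat / got$se)

  # perfect fit: slope one, p at the floor
  perf <- assoc_single(meth, meth)
  expect_equal(perf$beta_hat, 1, tolerance = 1e-12)
  expect_true(perf$p_floored)
  expect_error(assoc_single(rep(1, n), expr, X), "constant")
})

test_that("null single-pair p-values are uniform", {
  set.seed(52)
  p <- replicate(1000, {
    m <- rnorm(100); e <- rnorm(100)
    assoc_single(m, e)$p_value
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("blockwise scan equals the per-pair oracle on every pair", {
  cfg <- simulation_config(n_samples = 50, n_cpgs = 40, n_genes = 12,
                           n_snps = 10, n_cis_effects = 4,
                           n_trans_effects = 2, n_mediation_triplets = 1,
                           n_coloc_shared = 1, n_coloc_distinct = 1,
                           seed = 53)
  ds <- simulate_dataset(cfg)
  le <- normalize_expression(ds$counts, tmm_factors(ds$counts))
  covars <- ds$covariates[, c("age", "sex", "wbc", "batch")]
  sc <- scan_all_pairs(ds$methylation, le, covars, ds$annotations,
                       keep_all = TRUE, block_size = 7)
  expect_equal(nrow(sc$catalog$pairs), 40 * 12)
  X <- covariate_design(covars, colnames(le))
  idx <- seq(1, 480, by = 37)
  for (i in idx) {
    pr <- sc$catalog$pairs[i, ]
    o <- pair_ols_oracle(as.numeric(ds$methylation[pr$cpg_id, ]),
                         as.numeric(le[pr$gene_id, ]), X)
    expect_equal(pr$beta, o$beta, tolerance = 1e-8)
    expect_equal(pr$se, o$se, tolerance = 1e-8)
    expect_equal(pr$p_value, o$p, tolerance = 1e-8)
  }
  # direction counts partition the retained pairs
  dc <- sc$diagnostics$direction_counts
  expect_equal(sum(dc), nrow(sc$catalog$pairs))
})

test_that("scan retains planted effects and respects thresholds", {
  cfg <- simulation_config(n_samples = 300, n_cpgs = 60, n_genes = 25,
                           n_snps = 10, n_cis_effects = 6,
                           n_trans_effects = 0, cis_effect_r2 = 0.2,
                           n_mediation_triplets = 1, n_coloc_shared = 1,
                           n_coloc_distinct = 1, seed = 54)
  ds <- simulate_dataset(cfg)
  le <- normalize_expression(ds$counts, tmm_factors(ds$counts))
  covars <- ds$covariates[, c("age", "sex", "batch")]
  mr <- winsorize_rows(residualize(ds$methylation, covars))
  er <- residualize(le, covars)
  sc <- scan_all_pairs(mr, er, covars, ds$annotations)
  truth <- ds$truth$planted_pairs
  key <- paste(sc$catalog$pairs$cpg_id, sc$catalog$pairs$gene_id)
  hit <- paste(truth$cpg_id, truth$gene_id) %in% key
  expect_gte(mean(hit), 5 / 6)
  # sign concordance for the detected planted pairs
  det <- merge(truth, sc$catalog$pairs, by = c("cpg_id", "gene_id"))
  expect_true(all(sign(det$effect) == sign(det$beta)))
  expect_true(all(sc$catalog$pairs$p_value <=
                    ifelse(sc$catalog$pairs$relation == "cis",
                           sc$catalog$cis_alpha, sc$catalog$trans_alpha)))
})

test_that("zero-variance features are excluded and reported", {
  set.seed(55)
  ann <- structure(list(
    cpgs = data.frame(cpg_id = make_ids("cg", 5), chrom = "chr1",
                      position = seq(1e5, 5e5, length.out = 5)),
    genes = data.frame(gene_id = make_ids("g", 3), chrom = "chr1",
                       start = 1:3 * 1e5, end = 1:3 * 1e5 + 1e4,
                       strand = "+", biotype = "pc", tss = 1:3 * 1e5)),
    class = "feature_annotation")
  m <- rand_omics(5, 30, "cg", seed = 55)
  rownames(m) <- make_ids("cg", 5)
  m[2, ] <- 0.5
  e <- rand_omics(3, 30, "g", seed = 56)
  rownames(e) <- make_ids("g", 3)
  sc <- scan_all_pairs(m, e, NULL, ann, keep_all = TRUE)
  expect_equal(sc$diagnostics$excluded, "cg002")
  expect_equal(sc$diagnostics$n_tests, 4 * 3)
})

test_that("lead CpG selection minimizes p with distance and ID tie-breaks", {
  pairs <- data.frame(
    cpg_id = c("cgB", "cgA", "cgC", "cgD"),
    gene_id = c("g1", "g1", "g2", "g2"),
    beta = 1, se = 1, t_stat = 1,
    p_value = c(1e-12, 1e-9, 1e-5, 1e-5),
    distance_bp = c(100, 50, 200, 70),
    relation = "cis", stringsAsFactors = FALSE)
  cat <- structure(list(pairs = pairs, cis_alpha = 1e-4, trans_alpha = 1e-14,
                        filtered = TRUE), class = "eqtm_catalog")
  lead <- lead_cpgs(cat)
  expect_equal(lead$cpg_id[lead$gene_id == "g1"], "cgB")   # smaller p wins
  expect_equal(lead$cpg_id[lead$gene_id == "g2"], "cgD")   # tie -> nearer
  one <- cat; one$pairs <- pairs[1, ]
  expect_equal(lead_cpgs(one)$cpg_id, "cgB")
  # exact tie at equal distance -> lexicographic
  pairs2 <- pairs; pairs2$p_value <- 1e-5; pairs2$distance_bp <- 70
  cat$pairs <- pairs2
  expect_equal(lead_cpgs(cat)$cpg_id, c("cgA", "cgC"))
  empty <- cat; empty$pairs <- pairs[0, ]
  expect_error(lead_cpgs(empty), "empty")
})

test_that("genomic inflation factor behaves per definition", {
  expect_equal(genomic_inflation(rep(0.5, 7)), 1)
  set.seed(57)
  expect_true(abs(genomic_inflation(runif(1e5)) - 1) < 0.02)
  # chi-square statistics inflated by 1.2 give lambda about 1.2
  x <- rchisq(2e5, 1) * 1.2
  p <- pchisq(x, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p), 1.2, tolerance = 0.02)
  expect_error(genomic_inflation(numeric(0)), "no p-values")
  expect_error(genomic_inflation(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("conditioning on a SNP behaves as an extra covariate", {
  set.seed(58)
  n <- 200
  snp <- rbinom(n, 2, 0.3)
  # orthogonal SNP leaves the estimate essentially unchanged
  m <- rnorm(n); e <- 0.4 * m + rnorm(n)
  snp_o <- residual_oracle(snp, cbind(1, m, e))  # orthogonalized snp
  un <- assoc_single(m, e)
  cond <- conditional_assoc(m, e, snp_o)
  expect_equal(cond$beta_hat, un$beta_hat, tolerance = 1e-8)
  expect_equal(cond$df, un$df - 1)
  expect_error(conditional_assoc(snp, e, 2 * snp), "collinear")
  expect_error(conditional_assoc(m, e, rep(1, n)), "constant")
  # shared-cause attenuation: SNP drives both layers
  m2 <- 0.8 * snp + rnorm(n, 0, 0.5)
  e2 <- 0.8 * snp + rnorm(n, 0, 0.5)
  expect_gt(conditional_assoc(m2, e2, snp)$p_value,
            assoc_single(m2, e2)$p_value)
})
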