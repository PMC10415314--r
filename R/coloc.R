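# Approximate-Bayes-factor colocalization of two summary-statistic sets
# over a shared SNP window. All hypothesis sums are kept in log space.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Wakefield approximate log Bayes factor for one SNP
#'
#' For an estimate `beta` with standard error `se` and a normal effect
#' prior with standard deviation `prior_sd`: with `z = beta/se`,
#' `V = se^2`, `W = prior_sd^2` and shrinkage `r = W/(V+W)`, the log ABF
#' (alternative vs null) is `0.5*log(1-r) + z^2*r/2`. A zero prior SD gives
#' log ABF = 0 (no evidence either way).
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), > 0.
#' @param prior_sd prior effect SD (default 0.15, the standard
#'   quantitative-trait choice).
#' @return log approximate Bayes factor(s).
#' @export
wakefield_log_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) stop("standard errors must be positive")
  if (any(prior_sd < 0)) stop("prior_sd must be non-negative")
  z <- beta / se
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  0.5 * log(1 - r) + z^2 * r / 2
}

#' Harmonize two summary-statistic sets onto shared SNPs
#'
#' Intersects on SNP ID. Where the second set's effect/other alleles are
#' swapped relative to the first, its effect sign is flipped; SNPs whose
#' alleles cannot be reconciled at all are dropped and reported.
#'
#' @param s1,s2 `summary_stats` data.frames (snp_id, ea, oa, beta, se, ...).
#' @return list with aligned `s1`, `s2` (same SNP order) and `dropped`
#'   (IDs with irreconcilable alleles).
#' @export
harmonize_stats <- function(s1, s2) {
  shared <- intersect(s1$snp_id, s2$snp_id)
  if (length(shared) == 0) stop("no shared SNPs between the two sets")
  a <- s1[match(shared, s1$snp_id), , drop = FALSE]
  b <- s2[match(shared, s2$snp_id), , drop = FALSE]
  same <- a$ea == b$ea & a$oa == b$oa
  swapped <- a$ea == b$oa & a$oa == b$ea
  bad <- !(same | swapped)
  b$beta[swapped] <- -b$beta[swapped]
  b$ea[swapped] <- a$ea[swapped]
  b$oa[swapped] <- a$oa[swapped]
  if (any(bad)) {
    a2 <- a[!bad, , drop = FALSE]
    b2 <- b[!bad, , drop = FALSE]
    if (nrow(a2) == 0) stop("no SNPs left after dropping irreconcilable alleles")
  } else {
    a2 <- a; b2 <- b
  }
  rownames(a2) <- rownames(b2) <- NULL
  list(s1 = a2, s2 = b2, dropped = a$snp_id[bad])
}

#' Colocalization posteriors from approximate Bayes factors
#'
#' Enumerates the five hypotheses over the shared SNPs — H0 no association,
#' H1/H2 association with one trait only, H3 two distinct causal variants,
#' H4 one shared causal variant — weighting per-SNP ABFs by the prior
#' probabilities that a SNP is causal for trait 1 (`p1`), trait 2 (`p2`) or
#' both (`p12`). The H3 cross-sum is computed as
#' (sum1)(sum2) - sum(products) in log space for stability.
#'
#' @param s1,s2 summary statistics; harmonized internally via
#'   [harmonize_stats()] (pass `harmonized = TRUE` to skip).
#' @param p1,p2,p12 per-SNP priors (defaults 1e-4, 1e-4, 1e-5).
#' @param prior_sd effect prior SD for [wakefield_log_abf()].
#' @param harmonized set TRUE if inputs are already aligned SNP-for-SNP.
#' @return `coloc_result`: posterior vector `pp` (PP0..PP4, sums to 1),
#'   `n_snps`, `priors`, per-SNP log-ABF table and per-SNP H4 weights.
#' @export
coloc_abf <- function(s1, s2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd = 0.15, harmonized = FALSE) {
  if (!harmonized) {
    h <- harmonize_stats(s1, s2)
    s1 <- h$s1; s2 <- h$s2
  }
  if (nrow(s1) != nrow(s2)) stop("harmonized inputs must align")
  if (nrow(s1) == 1) warning("colocalization on a single shared SNP")
  l1 <- wakefield_log_abf(s1$beta, s1$se, prior_sd)
  l2 <- wakefield_log_abf(s2$beta, s2$se, prior_sd)
  if (any(!is.finite(l1)) || any(!is.finite(l2)))
    stop("non-finite log Bayes factors")
  lsum1 <- logsumexp(l1)
  lsum2 <- logsumexp(l2)
  lsum12 <- logsumexp(l1 + l2)
  lh <- c(
    h0 = 0,
    h1 = log(p1) + lsum1,
    h2 = log(p2) + lsum2,
    h3 = log(p1) + log(p2) + logdiffexp(lsum1 + lsum2, lsum12),
    h4 = log(p12) + lsum12)
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP", 0:4)
  snp_h4 <- exp(l1 + l2 - lsum12)
  structure(list(
    pp = pp, n_snps = nrow(s1),
    priors = c(p1 = p1, p2 = p2, p12 = p12, prior_sd = prior_sd),
    snps = data.frame(snp_id = s1$snp_id, log_abf1 = l1, log_abf2 = l2,
                      h4_weight = snp_h4, stringsAsFactors = FALSE)),
    class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result over %d SNPs\n", x$n_snps))
  print(round(x$pp, 4))
  invisible(x)
}

#' Triplet colocalization: mQTL vs eQTL and mQTL vs GWAS
#'
#' Runs [coloc_abf()] twice — methylation against expression summary
#' statistics, and methylation against the trait GWAS — and flags the
#' triplet as consistent with a single shared regulatory variant when both
#' H4 posteriors reach the threshold (inclusive; default 0.8).
#'
#' @param mqtl,eqtl,gwas `summary_stats` sets sharing SNPs pairwise.
#' @param p1,p2,p12,prior_sd priors passed to [coloc_abf()].
#' @param h4_threshold consistency threshold on PP4 (default 0.8).
#' @return list with `mqtl_eqtl` and `mqtl_gwas` `coloc_result`s, the
#'   shared-SNP counts, and `consistent`.
#' @export
coloc_triplet <- function(mqtl, eqtl, gwas, p1 = 1e-4, p2 = 1e-4,
                          p12 = 1e-5, prior_sd = 0.15, h4_threshold = 0.8) {
  me <- coloc_abf(mqtl, eqtl, p1, p2, p12, prior_sd)
  mg <- coloc_abf(mqtl, gwas, p1, p2, p12, prior_sd)
  list(mqtl_eqtl = me, mqtl_gwas = mg,
       n_snps = c(mqtl_eqtl = me$n_snps, mqtl_gwas = mg$n_snps),
       consistent = unname(me$pp["PP4"] >= h4_threshold &
                           mg$pp["PP4"] >= h4_threshold))
}

#' Simulate one colocalization locus
#'
#' Generates Hardy-Weinberg genotypes for `n_snps` independent SNPs and two
#' quantitative molecular traits, each driven by a causal SNP explaining
#' `causal_r2` of its variance — the same SNP when `shared`, two different
#' SNPs otherwise — then returns the two per-SNP summary-statistic sets.
#' Used to calibrate the posterior machinery against known locus
#' architecture.
#'
#' @param n_samples individuals (default 500).
#' @param n_snps SNPs in the window (default 200).
#' @param shared single shared causal variant (TRUE) or two distinct ones.
#' @param causal_r2 variance fraction explained by the causal SNP
#'   (default 0.1, about |z| = 7.5 at n = 500).
#' @param null_trait2 make the second trait pure noise (for H1/H2 checks).
#' @param seed integer seed.
#' @return list with `s1`, `s2` (`summary_stats`) and the causal SNP IDs.
#' @export
simulate_coloc_locus <- function(n_samples = 500, n_snps = 200,
                                 shared = TRUE, causal_r2 = 0.1,
                                 null_trait2 = FALSE, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  maf <- stats::runif(n_snps, 0.05, 0.5)
  G <- t(vapply(maf, function(p) stats::rbinom(n_samples, 2L, p),
                integer(n_samples)))
  rownames(G) <- sprintf("rs%04d", seq_len(n_snps))
  colnames(G) <- sprintf("s%04d", seq_len(n_samples))
  ann <- data.frame(snp_id = rownames(G), chrom = "chr1",
                    position = seq_len(n_snps) * 1000L,
                    ea = "A", oa = "G", stringsAsFactors = FALSE)
  causal1 <- sample.int(n_snps, 1)
  causal2 <- if (shared) causal1 else sample(setdiff(seq_len(n_snps),
                                                     causal1), 1)
  eff <- function(idx) {
    g <- G[idx, ]
    sqrt(causal_r2 / (1 - causal_r2)) / stats::sd(g) * (g - mean(g))
  }
  y1 <- eff(causal1) + stats::rnorm(n_samples)
  y2 <- if (null_trait2) stats::rnorm(n_samples)
        else eff(causal2) + stats::rnorm(n_samples)
  s1 <- single_snp_stats(G, y1, ann)
  s2 <- single_snp_stats(G, y2, ann)
  class(s1) <- class(s2) <- c("summary_stats", "data.frame")
  list(s1 = s1, s2 = s2,
       causal = c(trait1 = rownames(G)[causal1],
                  trait2 = rownames(G)[causal2]))
}
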