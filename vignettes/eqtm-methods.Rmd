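---
title: "Methods: genome-wide eQTM mapping, mediation and colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide eQTM mapping, mediation and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtmr)
```

# The problem

Expression quantitative trait methylation (eQTM) analysis asks, for every
CpG site and every gene transcript measured in the same individuals,
whether DNA methylation at the CpG is associated with the transcript's
expression. In whole blood this produces a resource of CpG–transcript
pairs that can then be interrogated jointly with trait association results:
does a trait-associated CpG act on the trait *through* the expression of
its paired gene (mediation), and are the methylation, expression and trait
signals at a locus driven by one shared genetic variant (colocalization)?

`eqtmr` implements this pipeline end to end and ships a synthetic
multi-omics generator with a machine-readable registry of planted effects,
so every stage can be validated against known ground truth.

# The association model

For CpG $c$ and transcript $g$ over $n$ individuals, the scan fits

$$ e_g = \alpha + \beta \, m_c + \Gamma' Z + \varepsilon $$

where $e_g$ is residualized log2 expression, $m_c$ is the residualized
(and winsorized) methylation beta value, and $Z$ holds the adjustment
covariates — age, sex, white blood cell count, blood cell fractions,
platelet count, and principal components of both omics layers. The test of
$\beta$ is an ordinary $t$ test with $n - q - 2$ degrees of freedom, where
$q$ is the number of covariate columns beyond the intercept.

Testing every pair naively refits this model hundreds of millions of
times. `scan_all_pairs()` instead projects the covariate design out of
both matrices once (by the Frisch–Waugh–Lovell theorem the methylation
coefficient is unchanged), computes cross-correlations of the residuals in
feature blocks, and converts each correlation to the identical $t$
statistic via $t = r\sqrt{df}/\sqrt{1-r^2}$. The per-pair fit and the
blockwise path agree to floating-point accuracy; the test suite asserts
agreement with `lm()` at $10^{-8}$ relative error on every pair of a
50-sample instance. Degrees of freedom use the full-model convention
($n - q - 2$) in both paths, so they are exactly interchangeable.

Pairs are classified **cis** when CpG and the gene's strand-aware
transcription start site lie on the same chromosome at most 1 Mb apart
(inclusive at exactly 1,000,000 bp), and **trans** otherwise;
inter-chromosomal pairs are trans with an infinite distance sentinel. The
TSS anchors both classifications — the gene-boundary alternative for trans
pairs differs only for CpGs within a gene-length of the 1 Mb boundary and
is not used. Defaults retain cis pairs at $p \le 10^{-7}$ and trans pairs
at $p \le 10^{-14}$; both thresholds are parameters. Two-sided p-values
below the double-precision floor are stored at the floor and flagged. The
genomic inflation factor $\lambda$ — the median observed 1-df $\chi^2$
over the null median 0.4549 — and QQ points are computed on *all* tested
pairs, never only the retained ones.

Per eGene, the **lead CpG** is the one with the smallest p-value; exact
ties break by smaller distance, then lexicographic CpG ID, so lead
selection is deterministic.

# Preprocessing

* **TMM normalization** (`tmm_factors()`, via edgeR): between-sample count
  normalization by the trimmed mean of M-values, default trims 0.30 on M
  and 0.05 on A, factors rescaled to unit geometric mean. The suite checks
  the implementation against an independent step-by-step transcription of
  the published recipe.
* **log2 expression** (`normalize_expression()`):
  $\log_2(\mathrm{CPM} + 1)$ on TMM-adjusted library sizes; adding one
  unit keeps zero counts at exactly zero. The per-million scale is a
  recorded parameter.
* **Residualization** (`residualize()`): per-feature least-squares
  residuals on a covariate design (batch, chip row/column, technical PCs,
  ...). The design is checked for full rank, naming collinear columns; the
  operation is an orthogonal projection, hence idempotent and with
  residuals orthogonal to every design column.
* **Winsorization** (`winsorize_rows()`): per CpG, values are clipped at
  mean $\pm$ 3 SD. The bounds are computed **once** on the pre-clip row
  (single pass); re-application can clip further, and that is intentional —
  the simplest reading of the procedure. Zero-variance rows pass through.
* **Principal components** (`principal_components()`): sample-space PCs of
  the feature-centered matrix by SVD, with variance fractions
  $\sigma_i^2/\sum_j \sigma_j^2$. Conventional adjustment uses 10
  methylation PCs and 5 expression PCs; a separate, smaller count (default
  4) can be regressed out of the betas before winsorization. Both counts
  are parameters; no automatic search over PC counts is performed.

Array-chemistry normalization (dasen/NOOB), probe QC from raw intensities
and cell-type deconvolution are out of scope: the package takes QC'd betas
and estimated cell fractions as inputs.

# Validation and replication

`split_discovery_validation()` partitions samples (e.g. by array
platform) consistently across every matrix, the covariate table and the
traits. `top_pairs()` ranks eGenes by lead-pair p-value (the "top 1000"
selection). `replication_report()` applies a `replication_policy()`:
nominal ($p \le \alpha$), Bonferroni ($p \le \alpha/m$) or strict
relation-specific genome-wide thresholds, with sign concordance required
by default. Pairs absent from the validation statistics are counted
"unavailable" and leave the denominator, mirroring how external cohorts
report "n of N pairs available after QC"; the rate over all selected
pairs is also reported. Under a true null with sign matching, the
expected rate is $\alpha/2$ — the suite checks this within binomial
error.

# Enrichment

`fisher_set_enrichment()` computes the exact one-sided hypergeometric
upper tail $P(X \ge a)$ for over-representation of a query feature set in
each annotation set over a fixed universe — equal to the one-sided
Fisher exact test — plus the sample odds ratio ($\infty$ sentinel when
$bc = 0$) and Benjamini–Hochberg q-values (`bh_fdr()`, delegating to
`p.adjust`). The universe defaults to all features tested in the scan and
is configurable, since enrichment conclusions depend on it.
`feature_enrichment()` applies the same machinery across a CpG
genomic-feature vocabulary (17 flags by default: island, shores, shelves,
open sea, promoter context, gene body, DHS, enhancer, TFBS, ...).
Trait and pathway catalogs are supplied as local two-column tables
(`read_annotation_sets()`), not live queries, so analyses are versioned
and offline.

# Mediation

For a candidate CpG $\to$ expression $\to$ trait triplet (selected by
`select_triplets()` as the alignment of EWAS hits, TWAS hits and
significant **cis** pairs), `mediate_triplet()` fits two linear models
without exposure–mediator interaction:

$$ M = a\,X + \dots, \qquad Y = c'X + b\,M + \dots $$

Point estimates are analytic: ACME $= ab$, ADE $= c'$, total $= ab + c'$,
so total $=$ ADE $+$ ACME holds exactly. Uncertainty comes from
quasi-Bayesian simulation: $a$ is drawn from its asymptotic normal and
$(c', b)$ jointly from theirs, the three quantities are recombined per
draw, and percentile intervals and two-sided simulation p-values are
reported. The proportion mediated is summarized as the median over draws
of $ab/(ab + c')$, which is robust when some draws have near-zero totals;
the point ratio is also reported and flagged when outside $(0,1)$
(opposite-sign direct and mediated effects). Everything is deterministic
given (data, seed, `n_sims`). `rescale_per_10pct()` divides the effects by
ten to express them per 10% methylation increase — betas are proportions,
so a unit change is the full 0-to-1 sweep — with a scale flag preventing
double application; the proportion mediated is scale-free. Trait-specific
adjustments (log-transforming triglycerides, BMI, medication indicators)
are the caller's responsibility via the trait vector and
`extra_adjustments`; the mediation models reuse the TWAS covariate set by
default.

# Colocalization

`coloc_abf()` scores five hypotheses for two summary-statistic sets over a
shared SNP window: no association (H0), one trait only (H1/H2), two
distinct causal variants (H3), one shared variant (H4). Per SNP, the
Wakefield approximate log Bayes factor is
$\tfrac12\log(1-r) + z^2 r/2$ with $r = W/(V+W)$, $V = \mathrm{se}^2$,
$W$ the prior effect variance (SD 0.15 for quantitative traits).
Hypothesis sums use log-sum-exp throughout; the H3 cross-sum is
$(\sum_1)(\sum_2) - \sum(\text{products})$ in log space, so results stay
finite for $|z|$ up to 40. Priors default to the conventional
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ and are exposed.
`harmonize_stats()` aligns panels on shared SNPs, flipping the effect sign
where the allele pair is swapped and dropping irreconcilable SNPs.
`coloc_triplet()` runs mQTL–eQTL and mQTL–GWAS comparisons and flags a
triplet consistent when both $PP_4 \ge 0.8$ (inclusive). When only
p-values are available, $|z|$ can be recovered from them, but the
sign-free mode and MAF/n-based prior scaling are not implemented — betas
and standard errors are required.

# The synthetic generator

`simulate_dataset()` emulates the *structure* of cohort multi-omics data,
not any specific cohort:

* **Methylation**: logistic transform of a latent Gaussian. Per-CpG means
  are drawn from a two-component mixture ($\pm 1.5$, SD 0.5 on the latent
  scale) to mimic the U-shaped marginal distribution of beta values;
  additive batch (SD 0.15), chip-row and chip-column (SD 0.1) effects and
  N(0, 0.8) noise are added, plus planted mQTL effects. Betas are clipped
  to $(10^{-6}, 1-10^{-6})$.
* **Expression**: negative binomial counts with common dispersion
  (default 0.2), per-gene log-baselines N(log 200, 0.7), log-normal
  library sizes (SD 0.3), and planted effects on the log-mean.
* **Effect sizes** are specified as variance fractions. A planted
  CpG→expression effect targeting $r^2$ is sized as
  $\sqrt{r^2/(1-r^2)\cdot v}/\mathrm{sd}(\beta_c)$ where $v$ sums the
  biological log-scale noise (SD 0.3), the dispersion and the Poisson
  term $1/\mu_g$ — i.e. the calibration anticipates the
  negative-binomial measurement variance so the realized $r^2$ on
  log-CPM data tracks the nominal value (empirically within about 15%).
* **Genotypes**: allele frequencies Uniform(0.05, 0.5), Hardy–Weinberg
  dosages, SNPs independent except that shared-colocalization loci reuse
  one causal SNP for both the mQTL and eQTL effect. No LD structure
  beyond that is simulated.
* **Traits**: for each planted mediation triplet,
  $Y = c'\beta_c + b\,M + \text{covariate effects} + N(0,1)$ where $M$ is
  the mediator gene's **latent** log-expression carrying $a\beta_c$. Using
  the latent value keeps the registry's $(a, b, c')$ exact generative
  coefficients with $ab/(ab+c') $ the exact proportion mediated
  (defaults $a = 0.5, b = 1, c' = 0.5$, proportion 0.5); on observed
  counts, NB measurement noise attenuates the estimated $b$ slightly, as
  it would in real data.
* **Covariates**: age N(60, 10), sex Bernoulli(0.5), five Dirichlet cell
  fractions, white-cell and platelet counts, categorical batch.
* **Determinism**: one global seed drives named sub-streams (layout,
  genotypes, methylation, expression, traits, covariates), so the same
  configuration reproduces bit-identical datasets and stages can be
  regenerated independently.

What the generator does **not** emulate: probe chemistry and array
normalization artifacts, LD blocks, gene–gene co-expression networks,
population structure, related individuals, or count outliers beyond the
NB. Passing tests therefore demonstrate correctness of the statistical
machinery under a clean generative model, not robustness to every
real-data pathology.

# Numerical and design choices

* Degrees-of-freedom convention: $n - q - 2$ with $q$ the covariate
  columns beyond the intercept, consistent between the blockwise and
  per-pair paths.
* Correlations are clipped to $[-1, 1]$ before the $t$ conversion;
  zero-variance features are excluded from testing and listed in the
  diagnostics rather than producing NaN statistics.
* p-value floor: `.Machine$double.xmin`, with a flag.
* Winsorization is single-pass by decision (bounds from the pre-clip
  row); it is not idempotent and the suite does not pretend otherwise.
* TMM scale-invariance under scaling one sample is exact only when the
  scaled column is proportional to the reference (all M-values zero);
  in general the precision weights depend on raw counts and the
  invariance holds to about $10^{-2}$ — the tests assert both regimes.
* Fisher p-values are exact hypergeometric tails (no continuity
  correction); zero-overlap queries give the boundary value 1.
* Mediation intervals are percentile intervals of the quasi-Bayesian
  draws; the simulation p-value is the doubled tail fraction, capped
  at 1.
* Problem sizes in the test suite and acceptance script (e.g. 20 null
  seeds of 10,000 tests; 500 mediation datasets of n = 500; 200
  colocalization loci of 200 SNPs) were chosen so the full validation
  runs in minutes on one CPU while keeping binomial error small relative
  to each acceptance band.

# Known limitations

Single-mediator, linear, no-interaction mediation only; no sensitivity
analysis for unmeasured confounding. Single-causal-variant
colocalization without LD. No transcript-isoform testing and no LD-aware
clumping of neighboring CpGs. The per-module shell entry points of a
larger deployment are intentionally not shipped: the exported functions
and `scripts/acceptance.R` are the interface.
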