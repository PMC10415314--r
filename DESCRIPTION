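Package: eqtmr
Title: Genome-Wide Expression Quantitative Trait Methylation (eQTM) Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A whole-blood eQTM analysis toolkit: covariate-residualized
    blockwise association scanning between CpG methylation and gene
    expression with cis/trans classification and genomic-inflation
    diagnostics; TMM count normalization and methylation preprocessing
    (residualization, winsorization, principal components); internal
    validation and external replication accounting with Bonferroni and
    sign-concordance policies; one-sided Fisher-exact set and
    genomic-feature enrichment with Benjamini-Hochberg control;
    transcriptome-wide association scans and causal mediation
    (ACME/ADE/proportion mediated via quasi-Bayesian simulation); and
    approximate-Bayes-factor colocalization over shared SNP windows.
    Includes a synthetic multi-omics generator with a machine-readable
    registry of planted effects for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
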