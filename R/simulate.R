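# Synthetic multi-omics generator. One global seed drives named
# sub-streams (layout, genotypes, methylation, expression, traits,
# covariates) so each stage is independently reproducible.

stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  expr
}

#' Configuration for the synthetic multi-omics dataset
#'
#' Collects all knobs of the generator with validation. Counts, effect
#' sizes (as variance fractions), mediation structure, colocalization loci,
#' batch structure, count dispersion and library-size spread are all
#' explicit so every planted effect is recoverable from the returned truth
#' registry.
#'
#' @param n_samples,n_cpgs,n_genes,n_snps,n_chromosomes feature counts.
#' @param chrom_length_bp chromosome length in bp; must exceed 2 Mb so both
#'   cis and trans geometry can exist.
#' @param n_cis_effects,n_trans_effects numbers of planted CpG-transcript
#'   effects within / beyond the 1 Mb cis window.
#' @param cis_effect_r2,trans_effect_r2 target fraction of log-expression
#'   variance explained by a planted effect, in (0, 1).
#' @param n_mediation_triplets planted CpG -> expression -> trait pathways.
#' @param mediation_prop true proportion mediated for planted triplets.
#' @param n_coloc_shared,n_coloc_distinct loci where the mQTL and eQTL
#'   causal variant is the same SNP / two different SNPs.
#' @param qtl_r2 fraction of molecular-feature variance explained by a
#'   planted QTL (sizes mQTL and eQTL effects; default 0.1).
#' @param batch_levels number of batch levels (also used for chip row and
#'   column effects on methylation).
#' @param dispersion negative-binomial dispersion shared by all genes.
#' @param lib_size_log_sd SD of log library size across samples.
#' @param seed global integer seed.
#' @return validated `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 500, n_cpgs = 1000, n_genes = 200,
                              n_snps = 200, n_chromosomes = 2,
                              chrom_length_bp = 5e7,
                              n_cis_effects = 50, n_trans_effects = 10,
                              cis_effect_r2 = 0.15, trans_effect_r2 = 0.15,
                              n_mediation_triplets = 5, mediation_prop = 0.5,
                              n_coloc_shared = 5, n_coloc_distinct = 5,
                              qtl_r2 = 0.1,
                              batch_levels = 3, dispersion = 0.2,
                              lib_size_log_sd = 0.3, seed = 1L) {
  cfg <- list(n_samples = n_samples, n_cpgs = n_cpgs, n_genes = n_genes,
              n_snps = n_snps, n_chromosomes = n_chromosomes,
              chrom_length_bp = chrom_length_bp,
              n_cis_effects = n_cis_effects,
              n_trans_effects = n_trans_effects,
              cis_effect_r2 = cis_effect_r2,
              trans_effect_r2 = trans_effect_r2,
              n_mediation_triplets = n_mediation_triplets,
              mediation_prop = mediation_prop,
              n_coloc_shared = n_coloc_shared,
              n_coloc_distinct = n_coloc_distinct,
              qtl_r2 = qtl_r2,
              batch_levels = batch_levels, dispersion = dispersion,
              lib_size_log_sd = lib_size_log_sd, seed = seed)
  counts <- cfg[c("n_samples", "n_cpgs", "n_genes", "n_snps",
                  "n_chromosomes", "n_cis_effects", "n_trans_effects",
                  "n_mediation_triplets", "n_coloc_shared",
                  "n_coloc_distinct", "batch_levels")]
  if (any(!vapply(cfg, function(v) length(v) == 1 && is.finite(v),
                  logical(1))))
    stop("all configuration values must be finite scalars")
  if (any(unlist(counts) < 0) ||
      any(unlist(counts) != round(unlist(counts))))
    stop("counts must be non-negative integers")
  fr <- unlist(cfg[c("cis_effect_r2", "trans_effect_r2", "mediation_prop",
                     "qtl_r2")])
  if (any(fr <= 0 | fr >= 1))
    stop("variance fractions must be in (0, 1)")
  if (cfg$chrom_length_bp <= 2e6)
    stop("chrom_length_bp must exceed 2 Mb for cis and trans geometry")
  if (cfg$dispersion <= 0 || cfg$lib_size_log_sd <= 0)
    stop("dispersion and lib_size_log_sd must be positive")
  if (n_trans_effects > 0 && n_chromosomes < 2 &&
      chrom_length_bp <= 2e6 + 2)
    stop("chromosome too short to place a trans pair")
  structure(cfg, class = "simulation_config")
}

# default 17-term genomic-feature vocabulary with prevalences roughly in
# array-annotation proportions
default_feature_vocabulary <- function() {
  c(island = 0.30, n_shore = 0.12, s_shore = 0.12, n_shelf = 0.05,
    s_shelf = 0.05, open_sea = 0.36, promoter = 0.20, tss200 = 0.10,
    tss1500 = 0.12, utr5 = 0.08, utr3 = 0.06, first_exon = 0.07,
    gene_body = 0.35, intergenic = 0.25, dhs = 0.15, enhancer = 0.10,
    tfbs = 0.12)
}

#' Genome layout for the synthetic dataset
#'
#' Places CpGs, gene TSSs (with strand) and SNPs on `n_chromosomes`
#' chromosomes so that every planted cis pair is within 1 Mb of its gene's
#' TSS and every planted trans pair is farther than 1 Mb away or
#' inter-chromosomal. Each CpG carries binary flags for a configurable
#' genomic-feature vocabulary (default 17 features: island/shore/shelf,
#' promoter and gene-body context, DHS, enhancer, TFBS, ...).
#'
#' @param config a [simulation_config()].
#' @param feature_vocabulary named numeric vector of feature prevalences.
#' @return `feature_annotation`: list of data.frames `cpgs`
#'   (cpg_id, chrom, position, one 0/1 column per feature), `genes`
#'   (gene_id, chrom, start, end, strand, biotype, tss), `snps`
#'   (snp_id, chrom, position, ea, oa), plus the planted pair/QTL placement
#'   in `placement`.
#' @export
build_genome_layout <- function(config,
                                feature_vocabulary =
                                  default_feature_vocabulary()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  if (cfg$n_cis_effects + cfg$n_trans_effects > 0 &&
      (cfg$n_cpgs < cfg$n_cis_effects + cfg$n_trans_effects ||
       cfg$n_genes < 1))
    stop("not enough CpGs/genes for the requested planted effects")
  with_stream(cfg$seed, "layout", {
    L <- cfg$chrom_length_bp
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))

    gene_chrom <- sample(chroms, cfg$n_genes, replace = TRUE)
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    gene_len <- pmin(round(stats::rlnorm(cfg$n_genes, log(3e4), 0.8)), 5e5)
    gene_start <- sample.int(L - max(gene_len) - 1L, cfg$n_genes,
                             replace = TRUE)
    genes <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(cfg$n_genes)),
      chrom = gene_chrom, start = gene_start,
      end = gene_start + gene_len, strand = strand,
      biotype = "protein_coding",
      stringsAsFactors = FALSE)
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)

    cpg_chrom <- sample(chroms, cfg$n_cpgs, replace = TRUE)
    cpg_pos <- sample.int(L, cfg$n_cpgs, replace = TRUE)

    # planted cis: move the CpG inside the gene's 1 Mb TSS window
    n_plant <- cfg$n_cis_effects + cfg$n_trans_effects
    plant_cpg <- if (n_plant > 0) sample.int(cfg$n_cpgs, n_plant) else integer(0)
    plant_gene <- if (n_plant > 0)
      sample.int(cfg$n_genes, n_plant, replace = cfg$n_genes < n_plant)
      else integer(0)
    if (cfg$n_cis_effects > 0) {
      ci <- seq_len(cfg$n_cis_effects)
      g <- plant_gene[ci]
      off <- sample.int(2e6 + 1L, cfg$n_cis_effects, replace = TRUE) - 1e6 - 1L
      pos <- pmin(pmax(genes$tss[g] + off, 1L), L)
      cpg_chrom[plant_cpg[ci]] <- genes$chrom[g]
      cpg_pos[plant_cpg[ci]] <- pos
    }
    if (cfg$n_trans_effects > 0) {
      ti <- cfg$n_cis_effects + seq_len(cfg$n_trans_effects)
      g <- plant_gene[ti]
      if (cfg$n_chromosomes >= 2) {
        other <- vapply(genes$chrom[g], function(ch)
          sample(setdiff(chroms, ch), 1), character(1))
        cpg_chrom[plant_cpg[ti]] <- other
        cpg_pos[plant_cpg[ti]] <- sample.int(L, cfg$n_trans_effects,
                                             replace = TRUE)
      } else {
        if (L <= 2e6 + 2) stop("chromosome too short to place a trans pair")
        cpg_chrom[plant_cpg[ti]] <- genes$chrom[g]
        far <- function(tss) {
          lo <- tss - 1e6; hi <- tss + 1e6
          ok <- c(if (lo > 1) seq(1, lo - 1) else NULL,
                  if (hi < L) seq(hi + 1, L) else NULL)
          sample(ok, 1)
        }
        cpg_pos[plant_cpg[ti]] <- vapply(genes$tss[g], far, numeric(1))
      }
    }

    flags <- vapply(feature_vocabulary, function(pr)
      stats::rbinom(cfg$n_cpgs, 1L, pr), integer(cfg$n_cpgs))
    if (cfg$n_cpgs == 1) flags <- matrix(flags, nrow = 1,
                                         dimnames = list(NULL,
                                           names(feature_vocabulary)))
    cpgs <- data.frame(
      cpg_id = sprintf("cg%07d", seq_len(cfg$n_cpgs)),
      chrom = cpg_chrom, position = cpg_pos,
      stringsAsFactors = FALSE)
    cpgs <- cbind(cpgs, as.data.frame(flags))

    alleles <- c("A", "C", "G", "T")
    ea <- sample(alleles, cfg$n_snps, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), character(1))
    snps <- data.frame(
      snp_id = sprintf("rs%06d", seq_len(cfg$n_snps)),
      chrom = sample(chroms, cfg$n_snps, replace = TRUE),
      position = sample.int(L, cfg$n_snps, replace = TRUE),
      ea = ea, oa = unname(oa),
      stringsAsFactors = FALSE)

    placement <- if (n_plant > 0) data.frame(
      cpg_id = cpgs$cpg_id[plant_cpg],
      gene_id = genes$gene_id[plant_gene],
      relation = rep(c("cis", "trans"),
                     c(cfg$n_cis_effects, cfg$n_trans_effects)),
      stringsAsFactors = FALSE)
    else data.frame(cpg_id = character(), gene_id = character(),
                    relation = character(), stringsAsFactors = FALSE)

    structure(list(cpgs = cpgs, genes = genes, snps = snps,
                   feature_names = names(feature_vocabulary),
                   placement = placement),
              class = "feature_annotation")
  })
}

#' Simulate the full synthetic multi-omics dataset
#'
#' Methylation betas arise from a logistic transform of a latent Gaussian
#' with per-CpG bimodal means (mimicking the U-shaped beta distribution)
#' plus additive batch, chip-row and chip-column effects, planted mQTL
#' effects and noise. Counts are negative binomial with log-mean = per-gene
#' baseline + planted CpG effects + eQTL effects + log library size
#' (log-normal). Traits are built as
#' `trait = c' * beta + b * latent log-expression + covariate effects + noise`
#' with the latent log-expression carrying `a * beta`, so the truth registry
#' stores the exact generative a, b, c' and proportion mediated
#' `a*b / (a*b + c')`. Planted associations are sized on the variance-
#' fraction scale requested in the config, accounting for the
#' negative-binomial measurement variance so the realized r2 on log-CPM
#' data tracks the nominal value.
#'
#' @param config a [simulation_config()].
#' @return `eqtm_dataset`: list with `methylation`, `counts`, `genotypes`
#'   (omics-style matrices), `covariates` (data.frame), `traits` (named list
#'   of per-sample vectors), `annotations`, `truth` (registry of planted
#'   pairs/triplets/QTLs/coloc loci) and the `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  ann <- build_genome_layout(cfg)
  samples <- sprintf("s%04d", seq_len(cfg$n_samples))
  n <- cfg$n_samples

  covars <- with_stream(cfg$seed, "covariates", {
    cf <- matrix(stats::rgamma(n * 5, shape = c(10, 5, 3, 2, 1)), n, 5,
                 byrow = TRUE)
    cf <- cf / rowSums(cf)
    colnames(cf) <- paste0("cellfrac_", c("neu", "lym", "mono", "eos", "bas"))
    data.frame(age = stats::rnorm(n, 60, 10),
               sex = stats::rbinom(n, 1, 0.5),
               wbc = stats::rnorm(n, 6, 1.5),
               platelet = stats::rnorm(n, 250, 50),
               cf,
               batch = sample(paste0("b", seq_len(max(cfg$batch_levels, 1))),
                              n, replace = TRUE),
               row.names = samples, stringsAsFactors = FALSE)
  })

  G <- with_stream(cfg$seed, "genotypes", {
    maf <- stats::runif(cfg$n_snps, 0.05, 0.5)
    g <- vapply(maf, function(p) stats::rbinom(n, 2L, p), integer(n))
    g <- t(g)
    dimnames(g) <- list(ann$snps$snp_id, samples)
    attr(g, "maf") <- stats::setNames(maf, ann$snps$snp_id)
    g
  })

  # coloc loci and planted QTL assignments
  qtl <- with_stream(cfg$seed, "qtl", {
    n_loci <- cfg$n_coloc_shared + cfg$n_coloc_distinct
    qtl_rows <- list()
    loci <- list()
    if (n_loci > 0) {
      need <- cfg$n_coloc_shared + 2 * cfg$n_coloc_distinct
      if (cfg$n_snps < need || cfg$n_cpgs < n_loci || cfg$n_genes < n_loci)
        stop("not enough SNPs/CpGs/genes for the requested coloc loci")
      snp_pool <- sample(ann$snps$snp_id, need)
      cpg_pool <- sample(ann$cpgs$cpg_id, n_loci)
      gene_pool <- sample(ann$genes$gene_id, n_loci)
      k <- 0
      for (i in seq_len(n_loci)) {
        shared <- i <= cfg$n_coloc_shared
        s1 <- snp_pool[k + 1]
        s2 <- if (shared) s1 else snp_pool[k + 2]
        k <- k + if (shared) 1 else 2
        qtl_rows[[length(qtl_rows) + 1]] <-
          data.frame(snp_id = s1, target = cpg_pool[i], type = "mqtl",
                     stringsAsFactors = FALSE)
        qtl_rows[[length(qtl_rows) + 1]] <-
          data.frame(snp_id = s2, target = gene_pool[i], type = "eqtl",
                     stringsAsFactors = FALSE)
        loci[[i]] <- data.frame(
          locus_id = sprintf("locus%02d", i),
          cpg_id = cpg_pool[i], gene_id = gene_pool[i],
          mqtl_snp = s1, eqtl_snp = s2,
          kind = if (shared) "shared" else "distinct",
          stringsAsFactors = FALSE)
      }
    }
    list(qtl = if (length(qtl_rows)) do.call(rbind, qtl_rows) else
           data.frame(snp_id = character(), target = character(),
                      type = character(), stringsAsFactors = FALSE),
         loci = if (length(loci)) do.call(rbind, loci) else
           data.frame(locus_id = character(), cpg_id = character(),
                      gene_id = character(), mqtl_snp = character(),
                      eqtl_snp = character(), kind = character(),
                      stringsAsFactors = FALSE))
  })

  # --- methylation: latent Gaussian -> logistic ---
  meth_sd <- 0.8  # latent-scale residual noise per CpG
  meth <- with_stream(cfg$seed, "methylation", {
    mu <- ifelse(stats::rbinom(cfg$n_cpgs, 1, 0.5) == 1,
                 stats::rnorm(cfg$n_cpgs, 1.5, 0.5),
                 stats::rnorm(cfg$n_cpgs, -1.5, 0.5))
    nb <- max(cfg$batch_levels, 1)
    batch_eff <- stats::rnorm(nb, 0, 0.15)
    names(batch_eff) <- paste0("b", seq_len(nb))
    chip_row <- sample(seq_len(6), n, replace = TRUE)
    chip_col <- sample(seq_len(2), n, replace = TRUE)
    row_eff <- stats::rnorm(6, 0, 0.1)
    col_eff <- stats::rnorm(2, 0, 0.1)
    z <- matrix(stats::rnorm(cfg$n_cpgs * n, 0, meth_sd), cfg$n_cpgs, n)
    z <- z + mu
    z <- sweep(z, 2, batch_eff[covars$batch] + row_eff[chip_row] +
                     col_eff[chip_col], "+")
    mq <- qtl$qtl[qtl$qtl$type == "mqtl", ]
    qtl_eff <- numeric(0)
    if (nrow(mq) > 0) {
      for (i in seq_len(nrow(mq))) {
        ci <- match(mq$target[i], ann$cpgs$cpg_id)
        dos <- G[mq$snp_id[i], ]
        sg <- stats::sd(dos)
        if (sg == 0) sg <- 1
        eff <- sqrt(cfg$qtl_r2 / (1 - cfg$qtl_r2)) * meth_sd / sg
        z[ci, ] <- z[ci, ] + eff * (dos - mean(dos))
        qtl_eff <- c(qtl_eff, eff)
      }
    }
    b <- stats::plogis(z)
    b <- pmin(pmax(b, 1e-6), 1 - 1e-6)
    dimnames(b) <- list(ann$cpgs$cpg_id, samples)
    attr(b, "chip_row") <- chip_row
    attr(b, "chip_col") <- chip_col
    attr(b, "mqtl_eff") <- qtl_eff
    b
  })

  # --- planted CpG -> expression effects ---
  placement <- ann$placement
  n_med <- cfg$n_mediation_triplets
  med <- NULL
  if (n_med > 0) {
    # mediator pairs are additional cis-style pairs using distinct CpGs/genes
    used_c <- placement$cpg_id
    used_g <- placement$gene_id
    free_c <- setdiff(ann$cpgs$cpg_id, used_c)
    free_g <- setdiff(ann$genes$gene_id, used_g)
    if (length(free_c) < n_med || length(free_g) < n_med)
      stop("not enough free CpGs/genes for mediation triplets")
    med <- with_stream(cfg$seed, "mediation-pick", {
      data.frame(cpg_id = sample(free_c, n_med),
                 gene_id = sample(free_g, n_med),
                 trait_id = sprintf("trait%02d", seq_len(n_med)),
                 stringsAsFactors = FALSE)
    })
  }

  expr_bio_sd <- 0.3  # natural-log biological noise beyond planted effects
  expr <- with_stream(cfg$seed, "expression", {
    base <- stats::rnorm(cfg$n_genes, log(200), 0.7)
    log_mu <- matrix(base, cfg$n_genes, n)
    log_mu <- log_mu + matrix(stats::rnorm(cfg$n_genes * n, 0, expr_bio_sd),
                              cfg$n_genes, n)
    lib <- exp(stats::rnorm(n, 0, cfg$lib_size_log_sd))

    # noise variance on the log scale incl. NB measurement component
    noise_var <- function(gi) expr_bio_sd^2 + cfg$dispersion +
      1 / exp(base[gi])

    pair_rows <- list()
    if (nrow(placement) > 0) {
      r2 <- rep(c(cfg$cis_effect_r2, cfg$trans_effect_r2),
                c(cfg$n_cis_effects, cfg$n_trans_effects))
      for (i in seq_len(nrow(placement))) {
        ci <- match(placement$cpg_id[i], ann$cpgs$cpg_id)
        gi <- match(placement$gene_id[i], ann$genes$gene_id)
        bvec <- meth[ci, ]
        sb <- stats::sd(bvec)
        eff <- sample(c(-1, 1), 1) *
          sqrt(r2[i] / (1 - r2[i]) * noise_var(gi)) / sb
        log_mu[gi, ] <- log_mu[gi, ] + eff * (bvec - mean(bvec))
        pair_rows[[i]] <- data.frame(
          cpg_id = placement$cpg_id[i], gene_id = placement$gene_id[i],
          effect = eff, relation = placement$relation[i],
          stringsAsFactors = FALSE)
      }
    }

    # mediator-gene effect a sized from the mediation proportion
    med_a <- numeric(0)
    if (!is.null(med)) {
      p <- cfg$mediation_prop
      c_prime <- 0.5
      b_eff <- 1.0
      a_eff <- p / (1 - p) * c_prime / b_eff
      for (i in seq_len(nrow(med))) {
        ci <- match(med$cpg_id[i], ann$cpgs$cpg_id)
        gi <- match(med$gene_id[i], ann$genes$gene_id)
        bvec <- meth[ci, ]
        log_mu[gi, ] <- log_mu[gi, ] + a_eff * (bvec - mean(bvec))
      }
      med_a <- rep(a_eff, nrow(med))
    }

    # eQTL effects
    eq <- qtl$qtl[qtl$qtl$type == "eqtl", ]
    eqtl_eff <- numeric(0)
    if (nrow(eq) > 0) {
      for (i in seq_len(nrow(eq))) {
        gi <- match(eq$target[i], ann$genes$gene_id)
        dos <- G[eq$snp_id[i], ]
        sg <- stats::sd(dos); if (sg == 0) sg <- 1
        eff <- sqrt(cfg$qtl_r2 / (1 - cfg$qtl_r2) * noise_var(gi)) / sg
        log_mu[gi, ] <- log_mu[gi, ] + eff * (dos - mean(dos))
        eqtl_eff <- c(eqtl_eff, eff)
      }
    }

    mu <- exp(sweep(log_mu, 2, log(lib), "+"))
    k <- matrix(stats::rnbinom(cfg$n_genes * n, mu = mu,
                               size = 1 / cfg$dispersion),
                cfg$n_genes, n)
    dimnames(k) <- list(ann$genes$gene_id, samples)
    list(counts = k, log_mu = log_mu, lib = lib,
         pairs = if (length(pair_rows)) do.call(rbind, pair_rows) else
           data.frame(cpg_id = character(), gene_id = character(),
                      effect = numeric(), relation = character(),
                      stringsAsFactors = FALSE),
         med_a = med_a, eqtl_eff = eqtl_eff)
  })

  traits <- list()
  triplets <- data.frame(cpg_id = character(), gene_id = character(),
                         trait_id = character(), a = numeric(),
                         b = numeric(), c_prime = numeric(),
                         prop_mediated = numeric(), stringsAsFactors = FALSE)
  if (!is.null(med)) {
    p <- cfg$mediation_prop
    c_prime <- 0.5; b_eff <- 1.0
    a_eff <- p / (1 - p) * c_prime / b_eff
    traits <- with_stream(cfg$seed, "traits", {
      out <- list()
      for (i in seq_len(nrow(med))) {
        ci <- match(med$cpg_id[i], ann$cpgs$cpg_id)
        gi <- match(med$gene_id[i], ann$genes$gene_id)
        bvec <- meth[ci, ]
        m_latent <- expr$log_mu[gi, ]  # carries a_eff * beta
        y <- c_prime * bvec + b_eff * m_latent +
          0.01 * covars$age + 0.2 * covars$sex + stats::rnorm(n, 0, 1)
        out[[med$trait_id[i]]] <- stats::setNames(y, samples)
      }
      out
    })
    triplets <- data.frame(cpg_id = med$cpg_id, gene_id = med$gene_id,
                           trait_id = med$trait_id,
                           a = a_eff, b = b_eff, c_prime = c_prime,
                           prop_mediated = a_eff * b_eff /
                             (a_eff * b_eff + c_prime),
                           stringsAsFactors = FALSE)
  }

  meth_m <- meth
  attr(meth_m, "chip_row") <- NULL; attr(meth_m, "chip_col") <- NULL
  attr(meth_m, "mqtl_eff") <- NULL
  truth <- list(
    planted_pairs = expr$pairs,
    planted_triplets = triplets,
    planted_coloc_loci = qtl$loci,
    planted_qtl = cbind(qtl$qtl,
                        effect = c(attr(meth, "mqtl_eff"), expr$eqtl_eff)[
                          order(c(which(qtl$qtl$type == "mqtl"),
                                  which(qtl$qtl$type == "eqtl")))]))
  covars$chip_row <- factor(attr(meth, "chip_row"))
  covars$chip_col <- factor(attr(meth, "chip_col"))

  structure(list(
    methylation = omics_matrix(meth_m, "beta"),
    counts = omics_matrix(expr$counts, "count"),
    genotypes = G,
    covariates = covars,
    traits = traits,
    annotations = ann,
    truth = truth,
    config = cfg), class = "eqtm_dataset")
}

#' @export
print.eqtm_dataset <- function(x, ...) {
  cat(sprintf(paste0("eqtm_dataset: %d samples, %d CpGs, %d genes, %d SNPs; ",
                     "%d planted pairs, %d triplets, %d coloc loci\n"),
              x$config$n_samples, x$config$n_cpgs, x$config$n_genes,
              x$config$n_snps, nrow(x$truth$planted_pairs),
              nrow(x$truth$planted_triplets),
              nrow(x$truth$planted_coloc_loci)))
  invisible(x)
}

# per-SNP least squares of a response on dosage
single_snp_stats <- function(G, y, snps_ann, n_label = length(y)) {
  mono <- apply(G, 1, function(g) stats::sd(g) == 0)
  if (all(mono)) stop("no polymorphic SNPs in region")
  G <- G[!mono, , drop = FALSE]
  res <- t(apply(G, 1, function(g) {
    f <- stats::lm.fit(cbind(1, g), y)
    rss <- sum(f$residuals^2)
    df <- length(y) - 2
    sxx <- sum((g - mean(g))^2)
    se <- sqrt(rss / df / sxx)
    b <- unname(f$coefficients[2])
    c(beta = b, se = se,
      p = 2 * stats::pt(abs(b / se), df, lower.tail = FALSE))
  }))
  idx <- match(rownames(G), snps_ann$snp_id)
  maf <- rowMeans(G) / 2
  maf <- pmin(maf, 1 - maf)
  out <- data.frame(snp_id = rownames(G),
                    chrom = snps_ann$chrom[idx],
                    position = snps_ann$position[idx],
                    ea = snps_ann$ea[idx], oa = snps_ann$oa[idx],
                    beta = res[, "beta"], se = res[, "se"], p = res[, "p"],
                    maf = maf, n = n_label,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-SNP GWAS summary statistics for a synthetic trait
#'
#' Single-SNP least-squares regressions of a trait on genotype dosage over
#' the SNPs in a genomic region, yielding effect estimate, standard error,
#' p-value, allele frequency and sample size per SNP. Monomorphic SNPs are
#' excluded; an error is raised if none remain.
#'
#' @param dataset an `eqtm_dataset`.
#' @param trait_id name of a trait in `dataset$traits`.
#' @param chrom,start,end region; defaults cover the whole genome.
#' @return `summary_stats` data.frame (snp_id, chrom, position, ea, oa,
#'   beta, se, p, maf, n) with a `label` attribute.
#' @export
simulate_gwas_summary <- function(dataset, trait_id, chrom = NULL,
                                  start = 0, end = Inf) {
  stopifnot(inherits(dataset, "eqtm_dataset"))
  if (!trait_id %in% names(dataset$traits))
    stop("unknown trait: ", trait_id)
  snps <- dataset$annotations$snps
  keep <- (is.null(chrom) | snps$chrom %in% chrom) &
    snps$position >= start & snps$position <= end
  if (!any(keep)) stop("region contains no SNPs")
  G <- dataset$genotypes[snps$snp_id[keep], , drop = FALSE]
  out <- single_snp_stats(G, dataset$traits[[trait_id]], snps)
  attr(out, "label") <- paste0("gwas:", trait_id)
  class(out) <- c("summary_stats", class(out))
  out
}

#' Per-SNP QTL summary statistics for a molecular feature
#'
#' Single-SNP regressions of a molecular feature (a CpG's methylation beta
#' or a gene's log2 expression) on genotype dosage — the synthetic analogue
#' of cis-mQTL / cis-eQTL summary statistics used by the colocalization
#' stage.
#'
#' @param dataset an `eqtm_dataset`.
#' @param feature_id a CpG or gene ID.
#' @param type `"mqtl"` (methylation) or `"eqtl"` (log2(count + 1)
#'   expression).
#' @param snp_ids SNPs to test; default all.
#' @return `summary_stats` data.frame as [simulate_gwas_summary()].
#' @export
qtl_summary_stats <- function(dataset, feature_id, type = c("mqtl", "eqtl"),
                              snp_ids = NULL) {
  stopifnot(inherits(dataset, "eqtm_dataset"))
  type <- match.arg(type)
  y <- if (type == "mqtl") {
    if (!feature_id %in% rownames(dataset$methylation))
      stop("unknown CpG: ", feature_id)
    as.numeric(dataset$methylation[feature_id, ])
  } else {
    if (!feature_id %in% rownames(dataset$counts))
      stop("unknown gene: ", feature_id)
    log2(as.numeric(dataset$counts[feature_id, ]) + 1)
  }
  snps <- dataset$annotations$snps
  if (is.null(snp_ids)) snp_ids <- snps$snp_id
  G <- dataset$genotypes[snp_ids, , drop = FALSE]
  out <- single_snp_stats(G, y, snps)
  attr(out, "label") <- paste0(type, ":", feature_id)
  class(out) <- c("summary_stats", class(out))
  out
}
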