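#' Simulation configuration
#'
#' Builds and validates the configuration object driving the synthetic cohort,
#' genotype and annotation generators. Defaults emulate the marginal structure
#' of a Korean population-based women's cohort aged 40-69: age-at-menarche
#' (AAM) category frequencies, covariate scales, and a planted early-menarche
#' effect on serum triglycerides (TG).
#'
#' @param n_subjects number of women to simulate (>= 2).
#' @param n_snps number of biallelic SNPs (>= 1).
#' @param maf_range length-2 numeric, minor allele frequency bounds in
#'   (0, 0.5]; per-SNP MAF is drawn uniformly between them.
#' @param aam_category_probs probabilities of the six AAM categories
#'   \{<=12, 13, 14, 15, 16, >=17\}; must sum to 1 within 1e-9. Defaults are
#'   the cohort's observed category frequencies (77, 269, 531, 669, 689,
#'   945)/3180.
#' @param tg_baseline_mean baseline TG mean (mg/dl).
#' @param tg_baseline_sd TG residual standard deviation (mg/dl).
#' @param early_menarche_tg_effect additive TG shift (mg/dl) for women with
#'   AAM <= 12; default 37.83.
#' @param planted_snps `NULL` or a data.frame with columns `snp_index`,
#'   `beta_main`, `beta_int` giving per-SNP additive main and interaction
#'   effects on TG (trait scale, mg/dl per allele).
#' @param enriched_pathway_id identifier of the pathway that must contain all
#'   genes harbouring planted SNPs, or `NULL`.
#' @param missing_genotype_rate probability in [0, 1) that a genotype call is
#'   missing.
#' @param seed integer seed; all generators derive documented substreams from
#'   it (cohort: seed, genotypes: seed + 1, missingness: seed + 2,
#'   annotation: seed + 3).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 2000L,
                       n_snps = 1000L,
                       maf_range = c(0.05, 0.5),
                       aam_category_probs = c(77, 269, 531, 669, 689, 945) / 3180,
                       tg_baseline_mean = 130,
                       tg_baseline_sd = 80,
                       early_menarche_tg_effect = 37.83,
                       planted_snps = NULL,
                       enriched_pathway_id = NULL,
                       missing_genotype_rate = 0,
                       seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stop("n_subjects must be >= 2", call. = FALSE)
  if (!is.numeric(n_snps) || n_snps < 1)
    stop("n_snps must be >= 1", call. = FALSE)
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an ordered pair within (0, 0.5]", call. = FALSE)
  if (length(aam_category_probs) != 6 || any(aam_category_probs < 0) ||
      abs(sum(aam_category_probs) - 1) > 1e-9)
    stop("aam_category_probs must be 6 non-negative values summing to 1",
         call. = FALSE)
  if (missing_genotype_rate < 0 || missing_genotype_rate >= 1)
    stop("missing_genotype_rate must be in [0, 1)", call. = FALSE)
  if (!is.null(planted_snps)) {
    planted_snps <- as.data.frame(planted_snps)
    need <- c("snp_index", "beta_main", "beta_int")
    if (!all(need %in% names(planted_snps)))
      stop("planted_snps needs columns snp_index, beta_main, beta_int",
           call. = FALSE)
    if (any(planted_snps$snp_index < 1 | planted_snps$snp_index > n_snps))
      stop("planted snp_index out of range 1..n_snps", call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    aam_category_probs = as.numeric(aam_category_probs),
    tg_baseline_mean = tg_baseline_mean,
    tg_baseline_sd = tg_baseline_sd,
    early_menarche_tg_effect = early_menarche_tg_effect,
    planted_snps = planted_snps,
    enriched_pathway_id = enriched_pathway_id,
    missing_genotype_rate = missing_genotype_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# truncated normal via rejection; fine for the mild truncations used here
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Simulate a phenotyped women's cohort
#'
#' Draws one row per woman: integer age at menarche (AAM) by category
#' (uniform over each category's years: the <=12 bin covers \{11, 12\}, the
#' >=17 bin \{17, 18\}), enrolment age ~ Normal(56.07, 8.88) truncated to
#' [40, 69], socioeconomic covariates with the cohort's marginal frequencies,
#' and the five metabolic-syndrome component traits. TG is
#' `tg_baseline_mean + early_menarche_tg_effect * 1[AAM <= 12] + noise`;
#' all other component traits are drawn independently of AAM.
#'
#' @param config a [sim_config()] object.
#' @return a data.frame (one row per woman) with columns `subject_id`, `aam`,
#'   `sbp`, `dbp`, `fg`, `fi`, `wc`, `tg`, `hdl`, `antihypertensive_med`,
#'   `antidiabetic_med`, `age`, `area`, `income`, `education`, `crp`,
#'   `smoking`, `alcohol`, `obs_score`. `income` and `education` are ordinal
#'   integer codes 0/1/2 (low to high); `area` is "rural"/"urban".
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects

  cat_idx <- sample.int(6L, n, replace = TRUE, prob = config$aam_category_probs)
  aam <- integer(n)
  aam[cat_idx == 1L] <- sample(11:12, sum(cat_idx == 1L), replace = TRUE)
  for (k in 2:5) aam[cat_idx == k] <- 11L + k
  aam[cat_idx == 6L] <- sample(17:18, sum(cat_idx == 6L), replace = TRUE)
  early <- as.numeric(aam <= 12)

  age <- rnorm_trunc(n, 56.07, 8.88, 40, 69)
  area <- sample(c("rural", "urban"), n, replace = TRUE,
                 prob = c(1699, 1481) / 3180)
  income <- sample(0:2, n, replace = TRUE, prob = c(0.402, 0.227, 0.371))
  education <- sample(0:2, n, replace = TRUE, prob = c(0.17, 0.50, 0.33))
  # CRP lognormal with mean 1.41, sd 1.30 mg/dl
  cv2 <- (1.30 / 1.41)^2
  sdlog <- sqrt(log(1 + cv2))
  crp <- stats::rlnorm(n, meanlog = log(1.41) - sdlog^2 / 2, sdlog = sdlog)
  smoking <- stats::rbinom(n, 1L, 0.018)
  alcohol <- stats::rbinom(n, 1L, 0.25) * stats::rexp(n, rate = 1 / 5.76)
  obs_score <- rnorm_trunc(n, 9.10, 2.51, 0, Inf)

  sbp <- rnorm_trunc(n, 121, 17, 70, 240)
  dbp <- rnorm_trunc(n, 75, 10, 40, 150)
  fg <- rnorm_trunc(n, 93, 18, 50, 400)
  fi <- rnorm_trunc(n, 7.4, 3.5, 0.5, 60)
  wc <- rnorm_trunc(n, 79.9, 8.7, 50, 140)
  hdl <- rnorm_trunc(n, 45, 10, 15, 120)
  # exactly additive-Gaussian (no truncation): keeps planted effects and the
  # scan's null calibration exact; a small fraction of draws may be <= 0
  tg <- config$tg_baseline_mean + config$early_menarche_tg_effect * early +
    stats::rnorm(n, 0, config$tg_baseline_sd)

  data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    aam = aam, sbp = sbp, dbp = dbp, fg = fg, fi = fi, wc = wc, tg = tg,
    hdl = hdl,
    antihypertensive_med = stats::rbinom(n, 1L, 0.10),
    antidiabetic_med = stats::rbinom(n, 1L, 0.04),
    age = age, area = area, income = income, education = education,
    crp = crp, smoking = smoking, alcohol = alcohol, obs_score = obs_score,
    stringsAsFactors = FALSE
  )
}

#' Simulate a genotype matrix under Hardy-Weinberg equilibrium
#'
#' Per SNP, draws a MAF uniformly within `config$maf_range` and additive
#' dosages ~ Binomial(2, MAF); missing calls are planted independently at
#' `config$missing_genotype_rate` (substream seed + 2). SNPs are laid out on
#' a regular grid over chromosomes 1-22 (5 kb spacing).
#'
#' @param config a [sim_config()] object.
#' @return an object of class `genotype_matrix`: list with `dosages`
#'   (n_subjects x n_snps integer matrix, NA = missing), `snps` (data.frame
#'   `snp_id`, `chrom`, `pos`, `ref`, `alt`, `maf`) and `samples`. The `maf`
#'   column is the empirical ALT-allele frequency folded to [0, 0.5],
#'   computed from non-missing calls.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  m <- config$n_snps

  set.seed(config$seed + 1L)
  maf_true <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  dos <- matrix(stats::rbinom(n * m, 2L, rep(maf_true, each = n)),
                nrow = n, ncol = m)

  if (config$missing_genotype_rate > 0) {
    set.seed(config$seed + 2L)
    miss <- matrix(stats::runif(n * m) < config$missing_genotype_rate, n, m)
    dos[miss] <- NA_integer_
  }

  per_chr <- ceiling(m / 22)
  chrom <- as.character(rep(1:22, each = per_chr)[seq_len(m)])
  pos <- (sequence(rle(chrom)$lengths)) * 5000L
  af <- colMeans(dos, na.rm = TRUE) / 2
  structure(list(
    dosages = dos,
    snps = data.frame(
      snp_id = sprintf("snp%06d", seq_len(m)),
      chrom = chrom, pos = pos, ref = "A", alt = "G",
      maf = pmin(af, 1 - af),
      stringsAsFactors = FALSE
    ),
    samples = sprintf("S%05d", seq_len(n))
  ), class = "genotype_matrix")
}

#' Plant per-SNP main and gene-environment interaction effects on TG
#'
#' For each planted SNP adds `beta_main * G + beta_int * G * E` to the `tg`
#' column, where `G` is the additive dosage (missing calls contribute 0) and
#' `E` the early-menarche indicator (AAM <= 12). The input cohort is not
#' modified.
#'
#' @param cohort data.frame from [simulate_cohort()].
#' @param genotypes a `genotype_matrix`.
#' @param config a [sim_config()] whose `planted_snps` describes the effects.
#' @return a new cohort data.frame with modified `tg`.
#' @export
plant_gxe_effects <- function(cohort, genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  ps <- config$planted_snps
  if (is.null(ps) || nrow(ps) == 0) return(cohort)
  if (any(ps$snp_index < 1 | ps$snp_index > ncol(genotypes$dosages)))
    stop("planted snp_index out of range", call. = FALSE)
  out <- cohort
  e <- as.numeric(out$aam <= 12)
  for (i in seq_len(nrow(ps))) {
    g <- genotypes$dosages[, ps$snp_index[i]]
    g[is.na(g)] <- 0
    out$tg <- out$tg + ps$beta_main[i] * g + ps$beta_int[i] * g * e
  }
  out
}

#' Simulate a gene/pathway annotation over the simulated SNP grid
#'
#' Tiles genes over consecutive SNP positions (so every gene contains at
#' least one SNP) and groups genes into pathways whose sizes lie within
#' [20, 200]. If `config$enriched_pathway_id` is set, that pathway contains
#' every gene harbouring a planted SNP (padded with unplanted genes up to the
#' minimum size).
#'
#' @param genotypes a `genotype_matrix`.
#' @param config a [sim_config()].
#' @param snps_per_gene number of consecutive SNPs spanned by each gene.
#' @param pathway_size target number of genes per (non-enriched) pathway.
#' @return an `annotation_bundle`: list with `gene_intervals` (data.frame
#'   `gene_id`, `chrom`, `start`, `end`, 1-based inclusive), `pathways`
#'   (named list of gene-id vectors) and `descriptions` (named character).
#' @export
simulate_annotation <- function(genotypes, config, snps_per_gene = 5L,
                                pathway_size = 30L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  snps <- genotypes$snps
  m <- nrow(snps)

  # block consecutive SNPs within a chromosome into genes
  block <- integer(m)
  nb <- 0L
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    b <- (seq_along(idx) - 1L) %/% snps_per_gene
    block[idx] <- nb + b + 1L
    nb <- nb + max(b) + 1L
  }
  n_genes <- nb
  if (n_genes < 20L)
    stop("too few SNPs to place at least one pathway-sized gene set",
         call. = FALSE)
  gene_id <- sprintf("GENE%05d", seq_len(n_genes))
  gene_intervals <- data.frame(
    gene_id = gene_id,
    chrom = tapply(snps$chrom, block, `[`, 1L),
    start = as.integer(tapply(snps$pos, block, min)),
    end = as.integer(tapply(snps$pos, block, max)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  snp_gene <- block  # gene index of each SNP

  pathways <- list()
  used <- rep(FALSE, n_genes)
  if (!is.null(config$enriched_pathway_id)) {
    planted <- if (is.null(config$planted_snps)) integer(0) else
      config$planted_snps$snp_index
    pg <- sort(unique(snp_gene[planted]))
    if (length(pg) > 200L)
      stop("planted SNPs span more than 200 genes; cannot build a valid ",
           "enriched pathway", call. = FALSE)
    pad <- max(0L, max(20L, pathway_size) - length(pg))
    free <- setdiff(seq_len(n_genes), pg)
    if (length(free) < pad)
      stop("not enough genes to pad the enriched pathway", call. = FALSE)
    members <- c(pg, sample(free, pad))
    pathways[[config$enriched_pathway_id]] <- gene_id[sort(members)]
    used[members] <- TRUE
  }
  free <- which(!used)
  free <- sample(free)  # shuffle before chunking
  n_extra <- length(free) %/% pathway_size
  for (k in seq_len(n_extra)) {
    members <- free[((k - 1L) * pathway_size + 1L):(k * pathway_size)]
    pathways[[sprintf("PW%04d", k)]] <- gene_id[sort(members)]
  }
  if (length(pathways) == 0L)
    stop("cannot place any pathway of the requested size", call. = FALSE)
  descriptions <- stats::setNames(
    paste("synthetic pathway", names(pathways)), names(pathways))
  structure(list(gene_intervals = gene_intervals, pathways = pathways,
                 descriptions = descriptions),
            class = "annotation_bundle")
}
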