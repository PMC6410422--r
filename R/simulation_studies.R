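# Reusable simulation studies: null calibration of the scan, planted-effect
# coverage, enrichment power, and null pathway calibration. These drive both
# the package's validation tests and the reproduction script.

#' Null calibration study for the interaction scan
#'
#' Simulates a cohort and genotypes with no planted SNP effects, runs the
#' full scan, and reports the empirical type-I error of the 1-df interaction
#' test together with the genomic-control inflation factors of the 1-df and
#' 2-df statistics.
#'
#' @param n_subjects,n_snps simulation size (defaults 2000 x 5000).
#' @param maf_range MAF bounds for the simulated SNPs.
#' @param alpha nominal level for the type-I error estimate.
#' @param seed integer seed.
#' @return list: `type1` (proportion of p_int < alpha), `lambda_int`,
#'   `lambda_joint`, `p_int` (vector), `n_snps`.
#' @export
null_scan_calibration <- function(n_subjects = 2000L, n_snps = 5000L,
                                  maf_range = c(0.05, 0.5), alpha = 0.05,
                                  seed = 1L) {
  cfg <- sim_config(n_subjects = n_subjects, n_snps = n_snps,
                    maf_range = maf_range, seed = seed)
  cohort <- phenotype_cohort(simulate_cohort(cfg))
  gm <- simulate_genotypes(cfg)
  sc <- run_scan(cohort, gm, scan_config())
  p <- sc$results$p_int
  list(type1 = mean(p < alpha, na.rm = TRUE),
       lambda_int = sc$lambda_int_raw, lambda_joint = sc$lambda_joint_raw,
       p_int = p, n_snps = n_snps)
}

#' Confidence-interval coverage of a planted interaction effect
#'
#' Replicated single-SNP simulation: each replicate plants `beta_int` at one
#' SNP (MAF `maf`), fits the interaction model at that SNP with the default
#' covariates, and checks whether the Wald 95% CI covers the truth.
#'
#' @param n_reps number of replicates (default 50).
#' @param n_subjects cohort size per replicate (default 2000).
#' @param maf minor allele frequency of the planted SNP (default 0.3).
#' @param beta_int planted interaction effect, mg/dl per allele among
#'   early-menarche women (default 20).
#' @param beta_main planted main effect (default 0).
#' @param base_seed replicate r uses seed `base_seed + 10 * r`.
#' @return list: `coverage` (fraction of CIs covering `beta_int`),
#'   `estimates` (data.frame of per-replicate beta_int, se, covered).
#' @export
beta_int_coverage <- function(n_reps = 50L, n_subjects = 2000L, maf = 0.3,
                              beta_int = 20, beta_main = 0, base_seed = 1L) {
  rows <- lapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(
      n_subjects = n_subjects, n_snps = 1L, maf_range = c(maf, maf),
      planted_snps = data.frame(snp_index = 1L, beta_main = beta_main,
                                beta_int = beta_int),
      seed = base_seed + 10L * r)
    gm <- simulate_genotypes(cfg)
    cohort <- phenotype_cohort(
      plant_gxe_effects(simulate_cohort(cfg), gm, cfg))
    fit <- fit_gxe_snp(cohort$tg, gm$dosages[, 1], cohort$early,
                       prepare_covariates(cohort), family = "linear")
    data.frame(beta_int = fit$beta_int, se_int = fit$se_int,
               covered = abs(fit$beta_int - beta_int) <=
                 1.959964 * fit$se_int)
  })
  est <- do.call(rbind, rows)
  list(coverage = mean(est$covered), estimates = est)
}

#' Design interaction effect for a target single-SNP z-score
#'
#' Closed-form OLS standard-error approximation for the interaction
#' coefficient of a binary exposure with prevalence `p_exposed`:
#' `se ~ sigma * sqrt((1/(n p) + 1/(n (1 - p))) / (2 maf (1 - maf)))`;
#' returns `z_target * se`, i.e. the planted effect whose expected z-score
#' is `z_target` when the SNP is the only planted signal.
#'
#' @param z_target design z-score.
#' @param n_subjects cohort size.
#' @param maf minor allele frequency.
#' @param sigma trait residual SD (mg/dl).
#' @param p_exposed exposure prevalence (default: the early-menarche
#'   frequency 77/3180).
#' @return the design `beta_int`.
#' @export
design_beta_int <- function(z_target, n_subjects, maf = 0.3, sigma = 80,
                            p_exposed = 77 / 3180) {
  v <- 2 * maf * (1 - maf)
  se <- sigma * sqrt((1 / (n_subjects * p_exposed) +
                        1 / (n_subjects * (1 - p_exposed))) / v)
  z_target * se
}

#' Power of the pathway analysis to detect a planted enriched pathway
#'
#' Each replicate simulates a cohort and `n_snps` SNPs, plants interaction
#' effects of per-SNP design z-score `z_target` (see [design_beta_int()]) at
#' 30 SNPs lying in 30 distinct genes of one pathway, runs the full scan
#' (including its genomic-control inverse-normal path, which these planted
#' effects trigger) and the permutation enrichment test, and records whether
#' the enriched pathway attains FDR q < `q_cut`.
#'
#' @param n_reps replicates (default 20).
#' @param n_subjects cohort size per replicate (default 6000; chosen by
#'   pilot power analysis for ~90% design power).
#' @param n_snps SNPs per replicate (default 2000).
#' @param n_planted planted SNPs (default 30).
#' @param maf MAF of all SNPs (default 0.3).
#' @param z_target per-SNP design z (default 5).
#' @param k_perm permutations (default 1000).
#' @param q_cut success threshold on FDR q (default 0.05).
#' @param base_seed replicate r uses seed `base_seed + 10 * r`.
#' @return list: `power` (success fraction), `q_values`, `beta_int` used.
#' @export
enrichment_power_study <- function(n_reps = 20L, n_subjects = 6000L,
                                   n_snps = 2000L, n_planted = 30L,
                                   maf = 0.3, z_target = 5, k_perm = 1000L,
                                   q_cut = 0.05, base_seed = 1L) {
  beta <- design_beta_int(z_target, n_subjects, maf = maf)
  snps_per_gene <- 5L
  planted_idx <- snps_per_gene * (seq_len(n_planted) - 1L) + 3L
  qs <- vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(
      n_subjects = n_subjects, n_snps = n_snps,
      maf_range = c(maf, maf),
      planted_snps = data.frame(snp_index = planted_idx, beta_main = 0,
                                beta_int = beta),
      enriched_pathway_id = "ENRICHED", seed = base_seed + 10L * r)
    gm <- simulate_genotypes(cfg)
    cohort <- phenotype_cohort(
      plant_gxe_effects(simulate_cohort(cfg), gm, cfg))
    ann <- simulate_annotation(gm, cfg, snps_per_gene = snps_per_gene)
    sc <- run_scan(cohort, gm, scan_config())
    res <- run_pathway_analysis(sc$results, gm$snps, ann$gene_intervals,
                                ann$pathways, k_perm = k_perm,
                                seed = cfg$seed)
    res$fdr_q[res$pathway_id == "ENRICHED"]
  }, numeric(1))
  list(power = mean(qs < q_cut), q_values = qs, beta_int = beta)
}

#' Null calibration of pathway nominal p-values
#'
#' One null scan (no planted effects); gene scores are computed and
#' `n_sets` random gene sets of size `set_size` are tested by permutation.
#' Under the null the nominal p-values should be uniform.
#'
#' @param n_subjects,n_snps simulation size.
#' @param n_sets number of random gene sets (default 100).
#' @param set_size genes per set (default 25).
#' @param k_perm permutations per set (default 500).
#' @param seed integer seed.
#' @return list: `p_nominal` (vector), `ks_p` (KS test p-value against
#'   Uniform(0,1)).
#' @export
null_pathway_calibration <- function(n_subjects = 1000L, n_snps = 2000L,
                                     n_sets = 100L, set_size = 25L,
                                     k_perm = 500L, seed = 1L) {
  cfg <- sim_config(n_subjects = n_subjects, n_snps = n_snps,
                    maf_range = c(0.1, 0.5), seed = seed)
  cohort <- phenotype_cohort(simulate_cohort(cfg))
  gm <- simulate_genotypes(cfg)
  ann <- simulate_annotation(gm, cfg)
  sc <- run_scan(cohort, gm, scan_config())
  mapping <- map_snps_to_genes(gm$snps, ann$gene_intervals)
  scores <- gene_scores(mapping,
                        stats::setNames(sc$results$p_int,
                                        sc$results$snp_id))
  set.seed(seed + 4L)
  sets <- lapply(seq_len(n_sets), function(i)
    sample(names(scores), set_size))
  names(sets) <- sprintf("NULLSET%04d", seq_len(n_sets))
  res <- permutation_test(sets, scores, k_perm = k_perm, seed = seed + 5L,
                          sig_threshold = 0.001)
  ks <- suppressWarnings(stats::ks.test(res$p_nominal, "punif"))
  list(p_nominal = res$p_nominal, ks_p = ks$p.value)
}

#' Marginal null calibration over replicate cohorts
#'
#' The single-cohort type-I error and inflation factor of a rare-exposure
#' interaction scan are highly variable across cohorts: all SNPs share the
#' exposed subgroup's residuals, so conditional on one cohort the
#' genome-wide lambda has relative sd about sqrt(2 / n_exposed) even when
#' the test is exactly calibrated. This study averages the empirical type-I
#' error and lambda over independent replicate cohorts, estimating the
#' marginal (unconditional) calibration.
#'
#' @param n_reps replicate cohorts (default 10).
#' @param n_subjects,n_snps per-replicate simulation size.
#' @param alpha nominal level.
#' @param base_seed replicate r uses seed `base_seed + 10 * r`.
#' @return list: `type1_mean`, `lambda_int_mean`, `lambda_joint_mean`, and
#'   the per-replicate vectors `type1`, `lambda_int`, `lambda_joint`.
#' @export
null_scan_marginal <- function(n_reps = 10L, n_subjects = 2000L,
                               n_snps = 500L, alpha = 0.05,
                               base_seed = 1L) {
  reps <- lapply(seq_len(n_reps), function(r)
    null_scan_calibration(n_subjects = n_subjects, n_snps = n_snps,
                          alpha = alpha, seed = base_seed + 10L * r))
  type1 <- vapply(reps, `[[`, numeric(1), "type1")
  l1 <- vapply(reps, `[[`, numeric(1), "lambda_int")
  l2 <- vapply(reps, `[[`, numeric(1), "lambda_joint")
  list(type1_mean = mean(type1), lambda_int_mean = mean(l1),
       lambda_joint_mean = mean(l2), type1 = type1, lambda_int = l1,
       lambda_joint = l2)
}
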