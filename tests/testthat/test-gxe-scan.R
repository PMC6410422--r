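test_that("QC removes SNPs by missingness and by the inclusive MAF bound", {
  # 6 SNPs x 200 subjects: construct dosage columns with known properties
  n <- 200L
  mk <- function(af) rbinom(n, 2, af)
  set.seed(12)
  dos <- cbind(
    rep(c(0L, 1L), n / 2),              # MAF 0.25, kept
    c(rep(NA_integer_, 2), mk(0.3)[-(1:2)]),  # 1% missing > 0.5%, removed
    rep(c(0L, 0L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L), n / 10), # MAF 0.2 kept
    rep(rep(0:1, c(9, 1)), n / 10),     # MAF exactly 0.05, removed
    mk(0.4),                            # kept
    rep(0L, n)                          # monomorphic MAF 0, removed
  )
  gm <- structure(list(
    dosages = dos,
    snps = data.frame(snp_id = paste0("s", 1:6), chrom = "1",
                      pos = 1:6 * 1000L, ref = "A", alt = "G",
                      maf = NA, stringsAsFactors = FALSE),
    samples = sprintf("S%05d", 1:n)), class = "genotype_matrix")
  qc <- qc_filter(gm)
  expect_equal(qc$genotypes$snps$snp_id, c("s1", "s3", "s5"))
  expect_equal(unname(qc$report["removed_missing"]), 1L)
  expect_equal(unname(qc$report["removed_maf"]), 2L)
  expect_equal(unname(qc$report["n_kept"]), 3L)
  # all removed -> error
  gm0 <- gm; gm0$dosages <- dos[, 6, drop = FALSE]
  gm0$snps <- gm$snps[6, ]
  expect_error(qc_filter(gm0), "all SNPs removed")
})

test_that("constructed fixture with 10 low-MAF SNPs loses exactly those 10", {
  cfg <- sim_config(n_subjects = 2000L, n_snps = 1000L,
                    maf_range = c(0.15, 0.5), seed = 44L)
  gm <- simulate_genotypes(cfg)
  low <- seq(10, 100, by = 10)
  set.seed(45)
  for (j in low) gm$dosages[, j] <- rbinom(2000, 2, 0.01)
  qc <- qc_filter(gm)
  expect_equal(unname(qc$report["removed_maf"]), 10L)
  expect_false(any(gm$snps$snp_id[low] %in% qc$genotypes$snps$snp_id))
})

test_that("linear interaction fit matches the normal-equations oracle to 1e-8", {
  set.seed(99)
  n <- 50
  g <- rbinom(n, 2, 0.3)
  e <- rbinom(n, 1, 0.3)
  cov1 <- rnorm(n); cov2 <- rnorm(n)
  y <- 1 + 0.5 * e + 0.8 * g + 0.5 * g * e + 0.3 * cov1 + rnorm(n)
  covmat <- cbind(c1 = cov1, c2 = cov2)
  fit <- fit_gxe_snp(y, g, e, covmat, family = "linear")
  X <- cbind(1, e, g, g * e, cov1, cov2)
  beta <- solve(crossprod(X), crossprod(X, y))
  V <- solve(crossprod(X)) *
    sum((y - X %*% beta)^2) / (n - ncol(X))
  expect_equal(fit$beta_main, unname(beta[3, 1]), tolerance = 1e-8)
  expect_equal(fit$beta_int, unname(beta[4, 1]), tolerance = 1e-8)
  expect_equal(fit$se_main, sqrt(V[3, 3]), tolerance = 1e-8)
  expect_equal(fit$se_int, sqrt(V[4, 4]), tolerance = 1e-8)
  expect_equal(fit$cov_main_int, V[3, 4], tolerance = 1e-8)
  expect_equal(fit$n_used, n)
})

test_that("degenerate designs are flagged rather than fit", {
  set.seed(100)
  n <- 60
  g <- rbinom(n, 2, 0.4)
  y <- rnorm(n)
  expect_equal(fit_gxe_snp(y, g, rep(0, n))$flag, "constant_interaction")
  expect_equal(fit_gxe_snp(y, rep(1L, n), rbinom(n, 1, 0.5))$flag,
               "constant_dosage")
  expect_equal(fit_gxe_snp(y[1:4], g[1:4], c(0, 1, 0, 1))$flag,
               "too_few_complete_cases")
  # missing dosages use complete cases
  g2 <- g; g2[1:10] <- NA
  expect_equal(fit_gxe_snp(y, g2, rbinom(n, 1, 0.5))$n_used, 50)
})

test_that("Wald statistics agree with independent chi-square tail formulas", {
  w0 <- wald_tests(0, 0, 1, 1, 0)
  expect_equal(w0$wald_int, 0)
  expect_equal(w0$wald_joint, 0)
  expect_equal(w0$p_int, 1)
  expect_equal(w0$p_joint, 1)

  # z = 1.96 with diagonal covariance: chi2(1) tail equals 2*pnorm(-z)
  w1 <- wald_tests(0, 1.96, 1, 1, 0)
  expect_equal(w1$wald_int, 3.8416, tolerance = 1e-12)
  expect_equal(w1$p_int, 2 * pnorm(-1.96), tolerance = 1e-12)
  expect_equal(round(w1$p_int, 4), 0.05)

  # both z-scores 1.96, diagonal V: joint = 7.6832, chi2(2) tail = exp(-x/2)
  w2 <- wald_tests(1.96, 1.96, 1, 1, 0)
  expect_equal(w2$wald_joint, 7.6832, tolerance = 1e-12)
  expect_equal(w2$p_joint, exp(-7.6832 / 2), tolerance = 1e-12)

  # singular covariance flagged
  ws <- wald_tests(1, 1, 0, 0, 0)
  expect_equal(ws$flag, "singular_vcov")
  expect_true(is.na(ws$p_joint))
})

test_that("genomic lambda is definitional, scales linearly, needs 100 stats", {
  expect_equal(genomic_lambda(rep(0.4549364, 200), df = 1), 1,
               tolerance = 1e-6)
  expect_equal(genomic_lambda(rep(2 * log(2), 200), df = 2), 1,
               tolerance = 1e-12)
  set.seed(3)
  s <- 2 * rchisq(1e5, df = 1)
  expect_equal(genomic_lambda(s, df = 1), 2, tolerance = 0.05)
  expect_error(genomic_lambda(rchisq(99, 1)), "at least 100")
})

test_that("inverse normal transform uses Blom offsets, ranks, and ties", {
  x <- c(5, 1, 3)
  z <- inverse_normal_transform(x)
  expect_equal(z[3], 0)                       # middle of 3 -> median
  expect_equal(z[2], qnorm((1 - 3 / 8) / 3.25))
  expect_equal(z[2], -0.8694, tolerance = 1e-3)
  expect_equal(z[1], -z[2])                   # symmetry
  # strictly monotone transforms leave the output unchanged
  y <- exp(rnorm(100))
  expect_equal(inverse_normal_transform(y), inverse_normal_transform(log(y)))
  # ties share the average-rank value; missing stays missing
  zt <- inverse_normal_transform(c(1, 1, 2, NA))
  expect_equal(zt[1], zt[2])
  expect_true(is.na(zt[4]))
  # distinct values give a symmetric, mean-zero transform
  expect_lt(abs(mean(inverse_normal_transform(rnorm(101)))), 1e-12)
  expect_error(inverse_normal_transform(c(2, 2)), "at least 3")
  expect_error(inverse_normal_transform(rep(1, 10)), "identical")
})

test_that("Bonferroni threshold reproduces the genome-wide critical value", {
  expect_equal(signif(bonferroni_threshold(0.05, 344396), 3), 1.45e-7)
  expect_equal(bonferroni_threshold(0.05, 100), 5e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("BH step-up q-values match hand-run and stats::p.adjust oracles", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  # monotone after sorting
  p <- sort(runif(30))
  expect_true(all(diff(bh_fdr(p)) >= -1e-15))
})

test_that("a strongly planted SNP attains the smallest joint p-value", {
  planted <- data.frame(snp_index = 50L, beta_main = 60, beta_int = 0)
  cfg <- sim_config(n_subjects = 800L, n_snps = 200L,
                    maf_range = c(0.2, 0.4), planted_snps = planted,
                    seed = 61L)
  gm <- simulate_genotypes(cfg)
  co <- phenotype_cohort(plant_gxe_effects(simulate_cohort(cfg), gm, cfg))
  sc <- run_scan(co, gm, scan_config())
  expect_equal(which.min(sc$results$p_joint), 50L)
  expect_equal(nrow(sc$results), 200L)
  expect_true(all(sc$results$p_int > 0 & sc$results$p_int <= 1, na.rm = TRUE))
})

test_that("subject mismatch between phenotypes and genotypes is an error", {
  cfg <- small_config(n = 100L, m = 10L)
  gm <- simulate_genotypes(cfg)
  co <- phenotype_cohort(simulate_cohort(cfg))
  co$subject_id[1] <- "INTRUDER"
  expect_error(run_scan(co, gm, scan_config()), "INTRUDER")
})

test_that("interaction p-values stay null for main-effect SNPs under either exposure coding", {
  planted <- data.frame(snp_index = 1:50, beta_main = 20, beta_int = 0)
  cfg <- sim_config(n_subjects = 800L, n_snps = 300L,
                    maf_range = c(0.2, 0.4), planted_snps = planted,
                    seed = 83L)
  gm <- simulate_genotypes(cfg)
  co <- phenotype_cohort(plant_gxe_effects(simulate_cohort(cfg), gm, cfg))
  for (coding in c("early_binary", "aam_continuous")) {
    sc <- run_scan(co, gm, scan_config(exposure_coding = coding,
                                       lambda_gc_trigger = Inf))
    p_planted <- sc$results$p_int[1:50]
    ks <- suppressWarnings(ks.test(p_planted, "punif"))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("inverse-normal re-analysis triggers on inflated traits and reports both lambdas", {
  cfg <- sim_config(n_subjects = 1000L, n_snps = 300L,
                    maf_range = c(0.2, 0.4), seed = 29L)
  gm <- simulate_genotypes(cfg)
  co <- phenotype_cohort(simulate_cohort(cfg))
  # variance concentrated in the rare exposed group inflates the
  # interaction Wald statistics genome-wide
  set.seed(30)
  co$tg <- co$tg + co$early * rnorm(nrow(co), 0, 400)
  sc <- run_scan(co, gm, scan_config())
  expect_true(sc$int_applied)
  expect_gt(sc$lambda_int_raw, 1.05)
  expect_lt(sc$lambda_int, sc$lambda_int_raw)
  expect_equal(names(sc$qq), c("expected", "observed"))
})

test_that("the interaction test is calibrated marginally over replicate cohorts", {
  # conditional on one cohort the genome-wide type-I error and lambda vary
  # with the exposed subgroup's realized residuals (relative sd of lambda
  # ~ sqrt(2 / n_exposed)); averaged over cohorts both are near nominal
  mg <- null_scan_marginal(n_reps = 10L, n_subjects = 2000L, n_snps = 500L,
                           base_seed = 7000L)
  expect_gt(mg$type1_mean, 0.03)
  expect_lt(mg$type1_mean, 0.07)
  expect_gt(mg$lambda_int_mean, 0.85)
  expect_lt(mg$lambda_int_mean, 1.15)
  expect_gt(mg$lambda_joint_mean, 0.85)
  expect_lt(mg$lambda_joint_mean, 1.15)
  # and the per-cohort spread is itself substantial, as the theory predicts
  expect_gt(max(mg$lambda_int) - min(mg$lambda_int), 0.05)
})
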