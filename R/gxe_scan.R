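#' Scan configuration
#'
#' @param trait trait column name (quantitative) or binary outcome column.
#' @param family "linear" (identity link) or "logistic" (logit link).
#' @param exposure_coding "early_binary" (indicator of AAM <= 12, the
#'   default) or "aam_continuous" (AAM in years).
#' @param covariates covariate columns entered in every per-SNP model.
#' @param maf_threshold SNPs with MAF <= this are removed (default 0.05,
#'   inclusive).
#' @param missing_threshold SNPs with missing-call proportion > this are
#'   removed (default 0.005).
#' @param lambda_gc_trigger genomic-control inflation factor above which a
#'   quantitative trait is re-analysed on the inverse-normal scale
#'   (default 1.05).
#' @param alpha nominal significance level (default 0.05).
#' @return a `scan_config` list.
#' @export
scan_config <- function(trait = "tg", family = c("linear", "logistic"),
                        exposure_coding = c("early_binary", "aam_continuous"),
                        covariates = c("age", "area", "income", "education",
                                       "crp"),
                        maf_threshold = 0.05, missing_threshold = 0.005,
                        lambda_gc_trigger = 1.05, alpha = 0.05) {
  family <- match.arg(family)
  exposure_coding <- match.arg(exposure_coding)
  if (maf_threshold <= 0 || maf_threshold >= 1 ||
      missing_threshold <= 0 || missing_threshold >= 1)
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  structure(list(trait = trait, family = family,
                 exposure_coding = exposure_coding, covariates = covariates,
                 maf_threshold = maf_threshold,
                 missing_threshold = missing_threshold,
                 lambda_gc_trigger = lambda_gc_trigger, alpha = alpha),
            class = "scan_config")
}

#' SNP quality-control filter
#'
#' Drops SNPs with missing-call proportion above `missing_threshold` or
#' minor allele frequency at or below `maf_threshold` (the MAF bound is
#' inclusive: MAF exactly 0.05 is removed under the default). MAF is
#' recomputed from non-missing calls.
#'
#' @param genotypes a `genotype_matrix`.
#' @param maf_threshold,missing_threshold see [scan_config()].
#' @return list with the filtered `genotypes` and `report`, a named vector of
#'   counts `c(n_input, removed_missing, removed_maf, n_kept)` (a SNP failing
#'   both rules is counted under the missingness rule, applied first).
#' @export
qc_filter <- function(genotypes, maf_threshold = 0.05,
                      missing_threshold = 0.005) {
  dos <- genotypes$dosages
  if (is.null(dos) || ncol(dos) == 0) stop("empty genotype matrix",
                                           call. = FALSE)
  miss_prop <- colMeans(is.na(dos))
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  fail_miss <- miss_prop > missing_threshold
  fail_maf <- !fail_miss & maf <= maf_threshold
  keep <- !fail_miss & !fail_maf
  if (!any(keep)) stop("all SNPs removed by QC", call. = FALSE)
  out <- genotypes
  out$dosages <- dos[, keep, drop = FALSE]
  out$snps <- genotypes$snps[keep, , drop = FALSE]
  out$snps$maf <- maf[keep]
  rownames(out$snps) <- NULL
  list(genotypes = out,
       report = c(n_input = ncol(dos),
                  removed_missing = sum(fail_miss),
                  removed_maf = sum(fail_maf),
                  n_kept = sum(keep)))
}

#' Wald tests for the main and interaction coefficients
#'
#' 1-df interaction test: `(beta_int/se_int)^2` against chi-square(1);
#' 2-df joint test of `beta_main = beta_int = 0`: `b' V^{-1} b` with `b =
#' (beta_main, beta_int)` and `V` their 2x2 covariance, against
#' chi-square(2).
#'
#' @param beta_main,beta_int coefficient estimates.
#' @param se_main,se_int their standard errors.
#' @param cov_main_int their covariance.
#' @return list `wald_int`, `p_int`, `wald_joint`, `p_joint`, `flag`
#'   ("singular_vcov" if V cannot be inverted).
#' @export
wald_tests <- function(beta_main, beta_int, se_main, se_int, cov_main_int) {
  wald_int <- (beta_int / se_int)^2
  p_int <- stats::pchisq(wald_int, df = 1, lower.tail = FALSE)
  V <- matrix(c(se_main^2, cov_main_int, cov_main_int, se_int^2), 2, 2)
  b <- c(beta_main, beta_int)
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi) || !all(is.finite(Vi))) {
    return(list(wald_int = wald_int, p_int = p_int, wald_joint = NA_real_,
                p_joint = NA_real_, flag = "singular_vcov"))
  }
  wald_joint <- drop(t(b) %*% Vi %*% b)
  list(wald_int = wald_int, p_int = p_int, wald_joint = wald_joint,
       p_joint = stats::pchisq(wald_joint, df = 2, lower.tail = FALSE),
       flag = "")
}

unfit_row <- function(flag, n_used = NA_integer_) {
  list(beta_main = NA_real_, beta_int = NA_real_, se_main = NA_real_,
       se_int = NA_real_, cov_main_int = NA_real_, wald_int = NA_real_,
       wald_joint = NA_real_, p_int = NA_real_, p_joint = NA_real_,
       n_used = n_used, flag = flag)
}

#' Fit the gene-environment interaction model at one SNP
#'
#' Fits `Y ~ intercept + E + G + G:E + covariates` with an identity link
#' (quantitative trait) or logit link (binary outcome), using complete-case
#' deletion for missing dosages, and returns the (beta_main, beta_int)
#' estimates, their covariance block, and the 1-df/2-df Wald tests.
#'
#' @param y trait or 0/1 outcome vector.
#' @param g additive dosage vector (0/1/2, NA = missing).
#' @param e exposure vector (binary early indicator or continuous AAM).
#' @param covmat numeric covariate matrix or NULL.
#' @param family "linear" or "logistic".
#' @return list (one scan-result row): `beta_main`, `beta_int`, `se_main`,
#'   `se_int`, `cov_main_int`, `wald_int`, `wald_joint`, `p_int`, `p_joint`,
#'   `n_used`, `flag` ("" when cleanly fit).
#' @export
fit_gxe_snp <- function(y, g, e, covmat = NULL, family = "linear") {
  X0 <- cbind(`(Intercept)` = 1, E = e, G = g, GxE = g * e)
  if (!is.null(covmat)) X0 <- cbind(X0, covmat)
  cc <- stats::complete.cases(X0) & !is.na(y)
  X <- X0[cc, , drop = FALSE]
  yv <- as.numeric(y[cc])
  p <- ncol(X)
  n <- nrow(X)
  if (n < p + 2) return(unfit_row("too_few_complete_cases", n))
  if (stats::var(X[, "G"]) == 0) return(unfit_row("constant_dosage", n))
  if (stats::var(X[, "GxE"]) == 0) return(unfit_row("constant_interaction", n))

  if (family == "linear") {
    fit <- stats::lm.fit(X, yv)
    if (fit$rank < p) return(unfit_row("rank_deficient", n))
    beta <- fit$coefficients
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (n - p)
    R <- qr.R(fit$qr)
    Vun <- chol2inv(R)
    piv <- fit$qr$pivot
    Vfull <- matrix(NA_real_, p, p)
    Vfull[piv, piv] <- Vun
    V <- Vfull * sigma2
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(X, yv, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-8,
                                                  maxit = 100)))
    if (!fit$converged) return(unfit_row("nonconvergence", n))
    if (fit$rank < p) return(unfit_row("rank_deficient", n))
    beta <- fit$coefficients
    Vun <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
    piv <- fit$qr$pivot
    V <- matrix(NA_real_, p, p)
    V[piv, piv] <- Vun
  }
  ig <- which(colnames(X) == "G")
  ii <- which(colnames(X) == "GxE")
  wt <- wald_tests(beta[ig], beta[ii], sqrt(V[ig, ig]), sqrt(V[ii, ii]),
                   V[ig, ii])
  list(beta_main = unname(beta[ig]), beta_int = unname(beta[ii]),
       se_main = sqrt(V[ig, ig]), se_int = sqrt(V[ii, ii]),
       cov_main_int = V[ig, ii], wald_int = wt$wald_int,
       wald_joint = wt$wald_joint, p_int = wt$p_int, p_joint = wt$p_joint,
       n_used = n, flag = wt$flag)
}

#' Genomic-control inflation factor
#'
#' `lambda = median(observed statistics) / median(null chi-square)`; the null
#' median is 0.4549364 for 1 df and 2 log 2 = 1.3862944 for 2 df. Requires at
#' least 100 finite statistics.
#'
#' @param stats_ vector of chi-square statistics.
#' @param df degrees of freedom of the test (1 or 2).
#' @return the inflation factor (numeric scalar).
#' @export
genomic_lambda <- function(stats_, df = 1) {
  s <- stats_[is.finite(stats_)]
  if (length(s) < 100)
    stop("need at least 100 finite statistics to estimate lambda",
         call. = FALSE)
  stats::median(s) / stats::qchisq(0.5, df = df)
}

#' Rank-based inverse normal transformation
#'
#' Blom-offset transform `z_i = qnorm((r_i - 3/8) / (n + 1/4))` with average
#' ranks for ties; missing values stay missing. Requires at least 3
#' non-missing, non-constant values.
#'
#' @param x numeric vector.
#' @return transformed vector of the same length.
#' @export
inverse_normal_transform <- function(x) {
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 3) stop("need at least 3 non-missing values", call. = FALSE)
  if (length(unique(x[obs])) == 1L)
    stop("all values identical; no order information to transform",
         call. = FALSE)
  r <- rank(x[obs], ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[obs] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Bonferroni critical p-value
#'
#' @param alpha family-wise error rate.
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param pvalues numeric vector of p-values in [0, 1] (NA allowed).
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(pvalues))
  obs <- which(!is.na(pvalues))
  m <- length(obs)
  if (m == 0) return(q)
  ord <- obs[order(pvalues[obs])]
  adj <- pvalues[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  q[ord] <- pmin(adj, 1)
  q
}

scan_exposure <- function(cohort, coding) {
  switch(coding,
         early_binary = as.numeric(cohort$aam <= 12),
         aam_continuous = as.numeric(cohort$aam),
         stop("unknown exposure coding: ", coding, call. = FALSE))
}

scan_loop <- function(y, dos, e, covmat, family, snp_ids) {
  rows <- vector("list", ncol(dos))
  for (j in seq_len(ncol(dos))) {
    rows[[j]] <- fit_gxe_snp(y, dos[, j], e, covmat, family)
  }
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  cbind(data.frame(snp_id = snp_ids, stringsAsFactors = FALSE), out)
}

qq_data <- function(p) {
  p <- p[is.finite(p)]
  data.frame(expected = -log10(stats::ppoints(length(p))),
             observed = sort(-log10(p), decreasing = TRUE))
}

#' Genome-wide SNP x exposure interaction scan
#'
#' Fits the interaction model at every SNP, computes genomic-control
#' inflation factors for the 1-df interaction and 2-df joint statistics, and
#' — for a quantitative trait whose interaction lambda exceeds
#' `lambda_gc_trigger` — re-runs the whole scan with the rank-based
#' inverse-normal-transformed trait as the response (covariates retained in
#' the model). Both lambda sets are reported.
#'
#' @param cohort phenotyped cohort (needs `aam` and the trait/covariate
#'   columns); rows must correspond to `genotypes$samples` via `subject_id`.
#' @param genotypes a (QC'd) `genotype_matrix`.
#' @param config a [scan_config()].
#' @return list with `results` (one data.frame row per SNP; on the
#'   inverse-normal scale when the transform was triggered), `lambda_int`,
#'   `lambda_joint` (for the reported results), `lambda_int_raw`,
#'   `lambda_joint_raw` (raw-scale lambdas, identical when no transform was
#'   applied), `int_applied` (logical) and `qq` (expected vs observed
#'   -log10 p of the interaction test).
#' @export
run_scan <- function(cohort, genotypes, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  ids_g <- genotypes$samples
  ids_c <- cohort$subject_id
  if (!setequal(ids_g, ids_c) || anyDuplicated(ids_c) > 0) {
    off <- c(setdiff(ids_c, ids_g), setdiff(ids_g, ids_c))
    stop("subject mismatch between phenotypes and genotypes: ",
         paste(utils::head(off, 10), collapse = ", "),
         if (length(off) > 10) " ...", call. = FALSE)
  }
  dos <- genotypes$dosages[match(ids_c, ids_g), , drop = FALSE]
  e <- scan_exposure(cohort, config$exposure_coding)
  covmat <- prepare_covariates(cohort, config$covariates)
  y <- as.numeric(cohort[[config$trait]])
  if (is.null(cohort[[config$trait]])) stop("trait column not found")

  res <- scan_loop(y, dos, e, covmat, config$family, genotypes$snps$snp_id)
  lam_int_raw <- genomic_lambda(res$wald_int, df = 1)
  lam_joint_raw <- genomic_lambda(res$wald_joint, df = 2)

  int_applied <- FALSE
  lam_int <- lam_int_raw
  lam_joint <- lam_joint_raw
  if (config$family == "linear" && lam_int_raw > config$lambda_gc_trigger) {
    y2 <- inverse_normal_transform(y)
    res <- scan_loop(y2, dos, e, covmat, "linear", genotypes$snps$snp_id)
    lam_int <- genomic_lambda(res$wald_int, df = 1)
    lam_joint <- genomic_lambda(res$wald_joint, df = 2)
    int_applied <- TRUE
  }
  list(results = res, lambda_int = lam_int, lambda_joint = lam_joint,
       lambda_int_raw = lam_int_raw, lambda_joint_raw = lam_joint_raw,
       int_applied = int_applied, qq = qq_data(res$p_int))
}
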