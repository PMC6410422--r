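#' Build the numeric covariate matrix used by all adjusted models
#'
#' `area` is coded 0 = rural, 1 = urban; `income` and `education` enter as
#' ordinal integer scores 0/1/2 (accepted as-is when already numeric);
#' anything else must already be numeric.
#'
#' @param cohort phenotyped cohort data.frame.
#' @param covariates character vector of column names (default the adjusted
#'   models' set: age, area, income, education, crp).
#' @return numeric matrix with one column per covariate (or NULL if empty).
#' @export
prepare_covariates <- function(cohort,
                               covariates = c("age", "area", "income",
                                              "education", "crp")) {
  if (length(covariates) == 0) return(NULL)
  miss <- setdiff(covariates, names(cohort))
  if (length(miss) > 0)
    stop("covariate columns not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cols <- lapply(covariates, function(v) {
    x <- cohort[[v]]
    if (v == "area" && !is.numeric(x)) {
      bad <- setdiff(unique(as.character(x)), c("rural", "urban"))
      if (length(bad) > 0)
        stop("area must be rural/urban; found: ", paste(bad, collapse = ", "),
             call. = FALSE)
      x <- as.numeric(as.character(x) == "urban")
    }
    if (!is.numeric(x))
      stop("covariate '", v, "' is not numeric and has no documented coding",
           call. = FALSE)
    as.numeric(x)
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- covariates
  mat
}

category_design <- function(cohort) {
  fac <- cohort$aam_category
  if (is.null(fac)) stop("cohort has no aam_category; run phenotype_cohort()",
                         call. = FALSE)
  fac <- droplevels(factor(fac, levels = aam_levels()))
  empty <- setdiff(aam_levels(), levels(fac))
  if (length(empty) > 0)
    warning("empty AAM categories dropped: ", paste(empty, collapse = ", "))
  if (!("16" %in% levels(fac)))
    stop("reference category 16 is empty", call. = FALSE)
  stats::relevel(fac, ref = "16")
}

z975 <- 1.959964

#' Category-wise logistic model of a binary outcome against AAM category
#'
#' Fits one logistic regression of the outcome on the five non-reference AAM
#' category indicators (reference: 16 years) plus covariates, and reports
#' per-category odds ratios with Wald 95% confidence intervals. Fitting is
#' maximum likelihood via iteratively reweighted least squares (tolerance
#' 1e-8, at most 100 iterations).
#'
#' @param cohort phenotyped cohort (needs `aam_category`).
#' @param outcome name of a 0/1 (or logical) column, e.g. `"mets"`.
#' @param covariates covariate column names; `character(0)` for an unadjusted
#'   model. See [prepare_covariates()] for coding.
#' @return data.frame with one row per category: `category`, `estimate`
#'   (log-odds; 0 for the reference), `se`, `or` , `ci_low`, `ci_high`
#'   (on the OR scale), `p_value`, `n`, `n_cases`, `pct_cases`, `flag`
#'   ("" or a non-convergence/instability marker).
#' @export
fit_category_logistic <- function(cohort, outcome,
                                  covariates = c("age", "area", "income",
                                                 "education", "crp")) {
  y <- as.numeric(cohort[[outcome]])
  if (is.null(cohort[[outcome]])) stop("outcome column not found")
  if (!all(y %in% c(0, 1) | is.na(y))) stop("outcome must be binary 0/1")
  fac <- category_design(cohort)
  covmat <- prepare_covariates(cohort, covariates)
  df <- data.frame(y = y, fac = fac)
  form <- if (is.null(covmat)) y ~ fac else y ~ fac + covmat
  fit <- stats::glm(form, family = stats::binomial(), data = df,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  coefs <- summary(fit)$coefficients
  flag_global <- if (!fit$converged) "nonconvergence" else ""

  out <- lapply(levels(droplevels(fac)), function(lv) {
    nlv <- sum(fac == lv, na.rm = TRUE)
    ncase <- sum(y == 1 & fac == lv, na.rm = TRUE)
    if (lv == "16") {
      data.frame(category = lv, estimate = 0, se = NA_real_, or = 1,
                 ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
                 n = nlv, n_cases = ncase, pct_cases = 100 * ncase / nlv,
                 flag = "", stringsAsFactors = FALSE)
    } else {
      cn <- paste0("fac", lv)
      b <- coefs[cn, "Estimate"]; se <- coefs[cn, "Std. Error"]
      flag <- flag_global
      if (se > 100 || abs(b) > 15)
        flag <- paste0(flag, if (nzchar(flag)) ";", "possible_separation")
      data.frame(category = lv, estimate = b, se = se, or = exp(b),
                 ci_low = exp(b - z975 * se), ci_high = exp(b + z975 * se),
                 p_value = coefs[cn, "Pr(>|z|)"],
                 n = nlv, n_cases = ncase, pct_cases = 100 * ncase / nlv,
                 flag = flag, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  out[order(match(out$category, aam_levels())), , drop = FALSE]
}

#' Category-wise linear model of a quantitative trait against AAM category
#'
#' Ordinary least squares of the trait on the AAM category indicators
#' (reference: 16 years) plus covariates; per-category beta, Wald-normal 95%
#' CI (beta +/- 1.959964 SE) and t-based p-value. The reference row is
#' reported as 0 with NA confidence bounds.
#'
#' @inheritParams fit_category_logistic
#' @param trait name of a numeric trait column, e.g. `"tg"`.
#' @return data.frame as in [fit_category_logistic()] but with `beta` in
#'   trait units instead of `or`.
#' @export
fit_category_linear <- function(cohort, trait,
                                covariates = c("age", "area", "income",
                                               "education", "crp")) {
  y <- cohort[[trait]]
  if (is.null(y)) stop("trait column not found")
  fac <- category_design(cohort)
  covmat <- prepare_covariates(cohort, covariates)
  df <- data.frame(y = as.numeric(y), fac = fac)
  form <- if (is.null(covmat)) y ~ fac else y ~ fac + covmat
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- summary(fit)$coefficients
  degenerate <- summary(fit)$sigma < .Machine$double.eps^0.5

  out <- lapply(levels(droplevels(fac)), function(lv) {
    nlv <- sum(fac == lv, na.rm = TRUE)
    if (lv == "16") {
      data.frame(category = lv, estimate = 0, se = NA_real_, beta = 0,
                 ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
                 n = nlv, flag = "", stringsAsFactors = FALSE)
    } else {
      cn <- paste0("fac", lv)
      b <- coefs[cn, "Estimate"]; se <- coefs[cn, "Std. Error"]
      data.frame(category = lv, estimate = b, se = se, beta = b,
                 ci_low = b - z975 * se, ci_high = b + z975 * se,
                 p_value = coefs[cn, "Pr(>|t|)"],
                 n = nlv, flag = if (degenerate) "degenerate_zero_variance"
                 else "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  out[order(match(out$category, aam_levels())), , drop = FALSE]
}

#' Descriptive baseline table by AAM category
#'
#' Per-category n and percentage; mean +/- SD with an across-category
#' Kruskal-Wallis p-value for continuous variables; counts (%) with a Pearson
#' chi-square p-value (no continuity correction) for categorical variables.
#' No test p-values are emitted when fewer than two categories are present.
#'
#' @param cohort phenotyped cohort (needs `aam_category`).
#' @param continuous names of continuous columns to summarize.
#' @param categorical names of categorical columns to summarize.
#' @return list with `counts` (data.frame `category`, `n`, `pct`),
#'   `continuous` (long data.frame with per-category `mean`, `sd` and a
#'   per-variable `p_kruskal`) and `categorical` (long data.frame of level
#'   counts/percentages and a per-variable `p_chisq`).
#' @export
baseline_table <- function(cohort,
                           continuous = c("age", "crp", "alcohol",
                                          "obs_score"),
                           categorical = c("area", "smoking", "education",
                                           "income")) {
  fac <- droplevels(factor(cohort$aam_category, levels = aam_levels()))
  if (nlevels(fac) < length(aam_levels()))
    warning("categories with n = 0 omitted: ",
            paste(setdiff(aam_levels(), levels(fac)), collapse = ", "))
  ntot <- length(fac)
  counts <- data.frame(category = levels(fac),
                       n = as.integer(table(fac)),
                       stringsAsFactors = FALSE)
  counts$pct <- round(100 * counts$n / ntot, 1)
  do_tests <- nlevels(fac) >= 2

  cont <- do.call(rbind, lapply(intersect(continuous, names(cohort)),
                                function(v) {
    x <- as.numeric(cohort[[v]])
    p <- if (do_tests) stats::kruskal.test(x, fac)$p.value else NA_real_
    data.frame(variable = v, category = levels(fac),
               mean = as.numeric(tapply(x, fac, mean, na.rm = TRUE)),
               sd = as.numeric(tapply(x, fac, stats::sd, na.rm = TRUE)),
               p_kruskal = p, stringsAsFactors = FALSE)
  }))
  catg <- do.call(rbind, lapply(intersect(categorical, names(cohort)),
                                function(v) {
    x <- factor(cohort[[v]])
    tab <- table(x, fac)
    p <- if (do_tests && nlevels(x) >= 2)
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    else NA_real_
    d <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(d) <- c("level", "category", "n")
    d$pct <- round(100 * d$n / as.integer(table(fac)[d$category]), 1)
    d$variable <- v
    d$p_chisq <- p
    d[, c("variable", "category", "level", "n", "pct", "p_chisq")]
  }))
  list(counts = counts, continuous = cont, categorical = catg)
}
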