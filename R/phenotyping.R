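#' Apply the cohort's age-at-menarche exclusion filters
#'
#' Removes women with reported AAM <= 10 years, >= 19 years, or missing —
#' implausible or unusable recalls. The report counts exclusions in that
#' fixed order.
#'
#' @param cohort data.frame with an integer `aam` column (NA = missing).
#' @return list with `cohort` (retained rows) and `report`, a named integer
#'   vector `c(aam_le_10, aam_ge_19, aam_missing)`.
#' @export
apply_exclusions <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  aam <- cohort$aam
  report <- c(
    aam_le_10 = sum(!is.na(aam) & aam <= 10),
    aam_ge_19 = sum(!is.na(aam) & aam >= 19),
    aam_missing = sum(is.na(aam))
  )
  keep <- !is.na(aam) & aam >= 11 & aam <= 18
  list(cohort = cohort[keep, , drop = FALSE], report = report)
}

#' AAM category levels, in order
#' @export
aam_levels <- function() c("<=12", "13", "14", "15", "16", ">=17")

#' Categorize age at menarche
#'
#' Maps integer AAM in [11, 18] to the six analysis categories: 11-12 to
#' "<=12" (the early-menarche category), 13-16 to their own year, 17-18 to
#' ">=17". The reference category for all models is 16 years.
#'
#' @param aam integer vector of ages in years; values outside [11, 18] are an
#'   error (apply [apply_exclusions()] first).
#' @return factor with levels `aam_levels()`.
#' @export
categorize_aam <- function(aam) {
  if (any(is.na(aam)) || any(aam < 11 | aam > 18))
    stop("aam values must be non-missing and within [11, 18]; ",
         "apply exclusions first", call. = FALSE)
  lab <- ifelse(aam <= 12, "<=12", ifelse(aam >= 17, ">=17",
                                          as.character(aam)))
  factor(lab, levels = aam_levels())
}

#' Classify metabolic syndrome by the NCEP-ATP III criteria
#'
#' Component flags (Korean waist cutoff for women): central obesity
#' WC >= 85 cm; high TG >= 150 mg/dl; low HDL < 50 mg/dl; hypertension
#' SBP >= 130 or DBP >= 85 mmHg or antihypertensive medication; high fasting
#' glucose >= 100 mg/dl or antidiabetic medication. MetS = at least 3 of the
#' 5 criteria. A missing component yields a missing (not silently dropped)
#' result, with the offending components named in `missing_reason`;
#' medication flags force their criteria regardless of measured values.
#'
#' @param cohort data.frame with columns `wc`, `tg`, `hdl`, `sbp`, `dbp`,
#'   `fg`, `antihypertensive_med`, `antidiabetic_med`.
#' @return data.frame with logical columns `central_obesity`, `high_tg`,
#'   `low_hdl`, `hypertension`, `high_fg`, integer `n_criteria`, logical
#'   `mets`, character `missing_reason` (NA when complete).
#' @export
classify_mets <- function(cohort) {
  need <- c("wc", "tg", "hdl", "sbp", "dbp", "fg",
            "antihypertensive_med", "antidiabetic_med")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0)
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ahm <- as.logical(cohort$antihypertensive_med)
  adm <- as.logical(cohort$antidiabetic_med)
  central_obesity <- cohort$wc >= 85
  high_tg <- cohort$tg >= 150
  low_hdl <- cohort$hdl < 50
  # R's | propagates NA only when the result is undecidable: a TRUE measured
  # component or medication flag forces TRUE even if the other input is NA
  hypertension <- (cohort$sbp >= 130) | (cohort$dbp >= 85) | ahm
  high_fg <- (cohort$fg >= 100) | adm

  flags <- cbind(central_obesity, high_tg, low_hdl, hypertension, high_fg)
  n_criteria <- as.integer(rowSums(flags))
  mets <- n_criteria >= 3L
  missing_reason <- apply(flags, 1L, function(r) {
    bad <- colnames(flags)[is.na(r)]
    if (length(bad) == 0) NA_character_ else paste(bad, collapse = ",")
  })
  data.frame(central_obesity = central_obesity, high_tg = high_tg,
             low_hdl = low_hdl, hypertension = hypertension,
             high_fg = high_fg, n_criteria = n_criteria, mets = mets,
             missing_reason = missing_reason, stringsAsFactors = FALSE)
}

#' Phenotype a raw cohort end-to-end
#'
#' Applies the AAM exclusion filters, adds `aam_category` and the binary
#' `early` indicator (AAM <= 12), and appends the MetS component flags,
#' criterion count and MetS status.
#'
#' @param cohort raw cohort data.frame (see [simulate_cohort()] for schema).
#' @return the augmented, filtered data.frame; the exclusion report is
#'   attached as attribute `"exclusion_report"`.
#' @export
phenotype_cohort <- function(cohort) {
  ex <- apply_exclusions(cohort)
  out <- ex$cohort
  out$aam_category <- categorize_aam(out$aam)
  out$early <- as.integer(out$aam <= 12)
  out <- cbind(out, classify_mets(out))
  attr(out, "exclusion_report") <- ex$report
  out
}
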