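# Small in-code fixtures shared across test files.

small_config <- function(n = 400L, m = 50L, seed = 11L, ...) {
  sim_config(n_subjects = n, n_snps = m, maf_range = c(0.2, 0.4),
             seed = seed, ...)
}

# minimal raw cohort with explicit AAM values and neutral phenotypes
toy_cohort <- function(aam) {
  n <- length(aam)
  data.frame(
    subject_id = sprintf("T%03d", seq_len(n)),
    aam = aam, sbp = 110, dbp = 70, fg = 90, fi = 7, wc = 75, tg = 100,
    hdl = 60, antihypertensive_med = 0L, antidiabetic_med = 0L,
    age = 55, area = "rural", income = 1L, education = 1L, crp = 1,
    smoking = 0L, alcohol = 0, obs_score = 9,
    stringsAsFactors = FALSE
  )
}

# cohort with exactly two populated AAM categories, for 2x2 designs:
# "<=12" (exposed) and "16" (reference)
two_group_cohort <- function(n_exp, n_ref, outcome_exp, outcome_ref) {
  co <- toy_cohort(c(rep(12L, n_exp), rep(16L, n_ref)))
  co$aam_category <- categorize_aam(co$aam)
  co$mets <- c(outcome_exp, outcome_ref)
  co
}
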