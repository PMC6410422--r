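# gxemets

Gene-environment interaction analysis of **age at menarche (AAM)** and
**metabolic syndrome (MetS)** traits in women, as an end-to-end, tested R
pipeline:

1. **Phenotyping** — AAM exclusion filters and six-category binning
   (reference 16 years), NCEP-ATP III MetS classification with the Korean
   female waist cutoff (WC ≥ 85 cm, TG ≥ 150, HDL < 50, BP ≥ 130/85 or
   medication, FG ≥ 100 or medication; MetS = ≥ 3 of 5).
2. **Epidemiologic models** — per-category odds ratios (logistic) and beta
   coefficients (linear) for MetS and its components versus the reference
   category, adjusted for age, area, income, education and CRP, plus a
   descriptive baseline table (Kruskal-Wallis / chi-square).
3. **Genome-wide SNP×AAM scan** — per-SNP fits of
   `Y ~ E + G + G:E + covariates` with the 1-df interaction Wald test and
   the 2-df joint Wald test of `β_main = β_int = 0`; SNP QC
   (missingness > 0.5%, MAF ≤ 0.05); genomic-control λ for both tests
   with an automatic rank-based inverse-normal re-analysis of inflated
   quantitative traits; Bonferroni (`0.05/344396 = 1.45e-7`) and
   Benjamini-Hochberg multiplicity control.
4. **Pathway analysis** — SNP→gene mapping within 20 kb, best-SNP
   `-log10(p_int)` gene scores, pathway size filter [20, 200], weighted-KS
   enrichment scores with gene-label permutation, NES, nominal p and
   GSEA-style FDR q.
5. **Synthetic data** — a cohort/genotype/annotation simulator with the
   study's category frequencies and covariate scales, HWE genotypes,
   plantable per-SNP main and interaction effects, and a designated
   enriched pathway, so the whole pipeline is testable without the
   access-restricted cohort data it was designed around.

## Worked example

```r
library(gxemets)

cfg <- sim_config(n_subjects = 3180L, n_snps = 500L, seed = 42L)
cohort <- phenotype_cohort(simulate_cohort(cfg))
table(cohort$aam_category)
#> <=12   13   14   15   16 >=17
#>   71  291  535  645  665  973

fit_category_linear(cohort, "tg")[, c("category", "beta", "ci_low",
                                      "ci_high", "p_value")]
#>   category   beta ci_low ci_high  p_value
#>       <=12 34.793  15.23   54.36 0.000498
#>         13  2.023  -8.99   13.04 0.718881
#>         14 -4.452 -13.55    4.64 0.337524
#>         15  2.261  -6.40   10.92 0.608916
#>         16  0.000     NA      NA       NA
#>       >=17  0.187  -7.70    8.07 0.962907
```

The generator plants a 37.83 mg/dl TG shift for early menarche
(AAM ≤ 12); the fitted early-category beta of 34.8 (95% CI 15.2–54.4)
recovers it: early menarche raises TG, later categories do not differ
from the reference. The genome-wide scan on the same cohort reports its
inflation diagnostics:

```r
gm <- simulate_genotypes(cfg)
scan <- run_scan(cohort, gm, scan_config())
c(lambda_int = scan$lambda_int, lambda_joint = scan$lambda_joint)
#> lambda_int lambda_joint
#>      0.884        0.962
```

λ near 1 means no genomic inflation, so no inverse-normal re-analysis was
triggered (`scan$int_applied` is `FALSE`). The full pipeline
(simulate → phenotype → epi → scan → gsea, with provenance-headed TSV
outputs) runs as `run_pipeline(config, out_dir)`; a thin CLI wrapper with
the same stages lives in `inst/scripts/gxemets.R`.

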