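---
title: "Methods: gene-environment interaction analysis of age at menarche and metabolic syndrome traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-environment interaction analysis of age at menarche and metabolic syndrome traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxemets)
```

# Scope and model

`gxemets` implements a complete epidemiologic and genome-wide
interaction analysis of **age at menarche (AAM)** against **metabolic
syndrome (MetS)** traits in middle-aged women, together with a synthetic
data generator that reproduces the statistical structure such an analysis
assumes, so that every stage is testable without access to restricted
cohort data.

The central model, fitted once per SNP, is

$$Y_i \;=\; \beta_0 + \beta_1 E_i + \beta_{\text{main}} G_i +
\beta_{\text{int}} G_i E_i + \boldsymbol\gamma' \mathbf{c}_i + \varepsilon_i$$

with an identity link for quantitative traits (triglycerides, TG) and a
logit link for binary outcomes. Here $G_i \in \{0,1,2\}$ is the additive
ALT-allele dosage, $E_i$ the exposure, and $\mathbf{c}_i$ the covariates
(age, area, income, education, CRP). Two Wald tests are reported per SNP:

* **interaction (1 df)**: $W_{\text{int}} = (\hat\beta_{\text{int}} /
  \widehat{se}_{\text{int}})^2$ against $\chi^2_1$;
* **joint (2 df)**: $W_{\text{joint}} = \mathbf{b}' V^{-1} \mathbf{b}$ with
  $\mathbf{b} = (\hat\beta_{\text{main}}, \hat\beta_{\text{int}})$ and $V$
  their estimated $2\times 2$ covariance, against $\chi^2_2$.

The source text for the joint test is self-contradictory about its degrees
of freedom (it says "one df" in one sentence and "two dfs" in the next);
the package implements the standard 2-df joint test of
$\beta_{\text{main}} = \beta_{\text{int}} = 0$, which is the only reading
consistent with the covariance-based Wald form.

## Exposure coding

The exposure is, by default, the **early-menarche indicator**
($E_i = 1[\text{AAM} \le 12]$), matching the headline epidemiologic
contrast; continuous AAM in years is available
(`scan_config(exposure_coding = "aam_continuous")`). The published table
footnote that codes the dummy as "$\le 12$: 0, $>12$: 1" is inverted
relative to a positive early-menarche TG effect and is treated as a typo;
the package codes early = 1.

# Phenotyping

Exclusions remove implausible or missing AAM (reported AAM $\le 10$,
$\ge 19$, or missing, counted in that order); retained AAM in $[11, 18]$
is binned into six categories $\{\le 12, 13, 14, 15, 16, \ge 17\}$ with
**16 years as the reference** (the cohort median). MetS follows NCEP-ATP
III with the Korean female waist cutoff:

| component        | rule                                              |
|------------------|---------------------------------------------------|
| central obesity  | WC $\ge$ 85 cm                                    |
| high TG          | TG $\ge$ 150 mg/dl                                |
| low HDL          | HDL $<$ 50 mg/dl                                  |
| hypertension     | SBP $\ge$ 130 or DBP $\ge$ 85 mmHg, or medication |
| high glucose     | FG $\ge$ 100 mg/dl, or antidiabetic medication    |

MetS is $\ge 3$ of 5. Boundary conventions follow the printed symbols
exactly ($\ge$ inclusive, $<$ strict); the blood-pressure rule is read as
either-or (the standard ATP-III reading of "130/85"). Medication flags
force their criteria regardless of measured values. Missing components
propagate as a missing MetS status with the offending components named —
no imputation is performed, because none is described for the source
analysis.

# Epidemiologic models

`fit_category_logistic()` and `fit_category_linear()` fit one model per
outcome with five non-reference category indicators plus covariates.
Covariate coding (the source states only "adjusted for"): area binary
(urban = 1), income and education as ordinal scores 0/1/2, CRP and age
continuous. ORs and CIs use $\exp(\hat\beta \pm 1.959964\,\widehat{se})$;
linear CIs use the same normal multiplier with t-based p-values. The
reference row is reported as OR 1 / beta 0 with **no** CI: the published
table prints nonzero reference CIs (e.g. "0 (−8.24–8.24)"), which cannot
be derived from the stated model, so the package deliberately diverges and
prints none. Logistic fits use IRLS (tolerance 1e-8, max 100 iterations);
suspected separation (|log-OR| > 15 or SE > 100) and non-convergence are
flagged per row rather than raised. `baseline_table()` gives per-category
n (%), mean ± SD with Kruskal-Wallis p (tie-corrected) for continuous
variables, and counts (%) with Pearson chi-square p (no continuity
correction) for categorical ones.

# Genome-wide scan

SNP QC drops SNPs with missing-call proportion $> 0.5\%$ or MAF $\le 0.05$
(the MAF bound is **inclusive**, per the printed "$\le$"). Per SNP the
interaction model is fitted by QR least squares (or IRLS), with
complete-case deletion for missing dosages and `n_used` recorded;
constant dosage or interaction columns after subsetting flag the row as
unfit instead of crashing.

**Genomic control.** $\lambda = \text{median}(W) / m_{df}$ with
$m_1 = 0.4549364$ and $m_2 = 2\log 2 = 1.3862944$. If the trait is
quantitative and $\lambda_{\text{int}} > 1.05$, the scan is re-run with
the **rank-based inverse-normal transform** of the raw trait as the
response (Blom offsets, $z_i = \Phi^{-1}((r_i - 3/8)/(n + 1/4))$, average
ranks for ties), with covariates retained in the model; both lambda sets
are reported. The transform is applied to the raw trait, not to
residuals, mirroring the source workflow; dividing statistics by
$\lambda$ is not used as the default correction.

Multiplicity: `bonferroni_threshold(alpha, m)` ($0.05 / 344396 =
1.45\times 10^{-7}$ at the study's post-QC SNP count) and a hand-verified
Benjamini-Hochberg step-up (`bh_fdr()`, cross-checked against
`stats::p.adjust` in the tests).

## Conditional versus marginal calibration (a practical warning)

With a rare binary exposure, all $m$ interaction tests in one cohort
reuse the same small exposed subgroup: conditional on the cohort, the
genome-wide $\lambda_{\text{int}}$ concentrates not at 1 but at the ratio
of the exposed subgroup's realized residual variance to its expectation,
with relative standard deviation $\approx \sqrt{2/n_{\text{exposed}}}$
($\approx 0.20$ at $n = 2000$ with 2.4% exposed). The test is exactly
calibrated **marginally** — `null_scan_marginal()` averages the empirical
type-I error and $\lambda$ over replicate cohorts and the test suite
verifies both are near nominal — but any single-cohort estimate of
type-I error or $\lambda$ is itself noisy at this exposure frequency.
The package's validation therefore reports both the single-cohort
(conditional) and replicate-averaged (marginal) quantities. The same
effect implies that a sizeable share of an observed single-cohort
$\lambda$ (with only 77 exposed women, conditional sd $\approx 0.16$) can
be subgroup-sampling noise rather than systematic inflation.

# Pathway analysis

SNPs map to genes on the same chromosome within **20 kb** of the gene
body, boundaries inclusive; a SNP may map to several genes, each counted
fully. BED input is read as 0-based half-open and converted once to
1-based inclusive coordinates. The gene statistic is the **best-SNP**
$-\log_{10} p_{\text{int}}$; pathways are filtered to 20–200 genes *with
mapped SNPs* (both bounds inclusive, per the printed strict
inequalities). The enrichment score is the weighted Kolmogorov-Smirnov
running sum with weight exponent 1: member genes add
$s_j / \sum_{\text{members}} s$, non-members subtract $1/(N - N_H)$, and
the ES is the signed maximal deviation (agrees with `fgsea`'s statistic,
which the tests verify). The source cites an "improved GSEA" without
printing its statistic; the best-SNP statistic, weight 1, and
**gene-label permutation** (size-matched resampling of member positions on
the fixed ranking) are this package's documented choices — phenotype
permutation would require re-running the genome-wide scan per permutation
and is out of scope. NES is ES over the mean |null ES| of the same sign;
nominal p is $(1 + \#\{\text{null at least as extreme}\})/(k+1)$; FDR q
is GSEA-style from the pooled null NES. The "significant genes" count
uses a best-SNP $p_{\text{int}} < 0.001$ threshold (the source does not
define its column; the threshold is configurable and recorded in output).

# The synthetic cohort generator

`simulate_cohort()` emulates the marginal structure of the study cohort:
AAM category probabilities equal to the published category counts over
3180; within-category integer years uniform (the $\le 12$ bin is
$\{11, 12\}$, the $\ge 17$ bin $\{17, 18\}$ — no within-bin distribution
is stated, so uniform is used); age $\sim N(56.07, 8.88^2)$ truncated to
$[40, 69]$; area, income, education, smoking drawn with the published
marginal frequencies; CRP lognormal with mean 1.41 and SD 1.30 mg/dl;
alcohol zero-inflated with mean $\approx 1.44$ g/l; OBS
$\sim N(9.10, 2.51^2)$ truncated at 0. TG is
`tg_baseline_mean` (130 mg/dl) $+$ `early_menarche_tg_effect`
(default 37.83 mg/dl) $\cdot 1[\text{AAM} \le 12]$ $+$ Gaussian noise
(SD 80 mg/dl). The noise is deliberately *not* truncated: the generator's
contract is exact additivity and Gaussianity, which keeps planted-effect
recovery unbiased and the scan's null exactly calibrated; the price is
that a small fraction of simulated TG values can be non-positive. Other
MetS components are drawn from fixed plausible distributions independent
of AAM (no other component showed an AAM association in the source).

`simulate_genotypes()` draws per-SNP MAF uniformly in `maf_range` and
dosages $\sim \text{Binomial}(2, \text{MAF})$ — Hardy-Weinberg
equilibrium, no LD (the analysed method does not model LD), positions on
a 5 kb grid over chromosomes 1–22. Missing calls are planted
independently. `plant_gxe_effects()` adds
$\beta_{\text{main}} G + \beta_{\text{int}} G \cdot 1[\text{AAM} \le 12]$
to TG for each planted SNP. `simulate_annotation()` tiles genes over
consecutive SNPs (default 5 SNPs per gene) and groups genes into pathways
of 20–200 members; the designated enriched pathway contains every gene
harbouring a planted SNP. Determinism: each generator seeds its own
substream (`seed` + 0 cohort, +1 genotypes, +2 missingness, +3
annotation), so outputs depend only on the configuration.

What the generator does **not** emulate: linkage disequilibrium,
population structure, relatedness, X-chromosome dosage, the full joint
dependence of socioeconomic covariates on AAM (only marginals are
matched), and real TG skewness (noise is Gaussian by contract). Passing
tests therefore certify the statistical machinery under the assumed
model, not robustness to these real-data features.

# Validation studies and problem sizes

The test suite and the reproduction script (`scripts/acceptance.R`) run
the following studies, sized to complete on one CPU in a few minutes:

* **Null scan calibration**: one cohort of $n = 2000$, $m = 5000$ SNPs,
  no planted effects — single-cohort type-I error of $p_{\text{int}}$ and
  both lambdas; plus the marginal study (10 replicate cohorts,
  $m = 500$). The single-cohort quantities inherit the conditional
  variability described above, which the marginal study resolves.
* **Coverage**: 50 replicates at $n = 2000$, MAF 0.3, planted
  $\beta_{\text{int}} = 20$ mg/dl (a moderate effect at that size),
  checking 95% Wald CI coverage of the planted SNP's fit.
* **TG effect recovery**: one cohort of $n = 10^4$; the early-category
  linear beta must cover the planted 37.83 mg/dl.
* **Enrichment power**: 20 replicates at $n = 6000$, $m = 2000$ SNPs
  (MAF 0.3), 30 planted interaction SNPs in 30 genes of one pathway,
  1000 permutations. The per-SNP effect is the closed-form
  `design_beta_int(z_target = 5, ...)` — the effect whose *single-SNP*
  z-score is 5. Thirty such simultaneous effects necessarily inflate the
  exposed subgroup's trait variance
  ($\lambda \approx 1 + 29 \cdot 25/(n\,p_E)$), so the scan's
  inverse-normal genomic-control path always triggers in this study,
  exactly as in the motivating TG analysis; the cohort size was set by a
  pilot power grid ($n$ = 1500/3000/6000) to give roughly 90% design
  power after that transform.
* **Pathway null calibration**: one null scan ($n = 1000$, $m = 2000$),
  100 random gene sets of 25 genes, 500 permutations; nominal p-values
  checked for uniformity (KS).
* **Determinism**: the full pipeline run twice from one config and seed
  must produce byte-identical outputs (MD5).

# Known limitations

* Wald tests with pooled-variance OLS standard errors are the analysed
  method; no robust (sandwich) or mixed-model alternative is offered, and
  the conditional-calibration caveat above is a direct consequence.
* Gene-label permutation treats gene scores as exchangeable; correlated
  SNPs within a gene region (absent here by construction) would make real
  nulls less exchangeable than simulated ones.
* The reference-category CI convention and the "significant genes"
  threshold are package choices where the source is silent or
  inconsistent; both are documented above and configurable where
  meaningful.
* Logistic per-SNP scans are supported but the calibration and power
  studies exercise the quantitative-trait path, which is the analysis the
  pipeline was built around.
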