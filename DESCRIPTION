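Package: gxemets
Title: Gene-Environment Interaction Analysis of Age at Menarche and
    Metabolic Syndrome Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of the interaction between age at menarche
    and genetic polymorphisms on metabolic syndrome traits in women:
    NCEP-ATP III metabolic syndrome phenotyping with Korean waist cutoffs,
    category-wise logistic and linear epidemiologic models against a
    reference menarche age of 16 years, a genome-wide per-SNP scan of the
    model Y ~ E + G + G:E + covariates with 1-df interaction and 2-df joint
    Wald tests, genomic-control diagnostics with rank-based inverse normal
    transformation, Bonferroni and Benjamini-Hochberg multiplicity control,
    and a GSEA-style pathway enrichment analysis of interaction signals.
    Includes a synthetic cohort/genotype/annotation simulator with planted
    main and interaction effects so the whole pipeline is testable without
    access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
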