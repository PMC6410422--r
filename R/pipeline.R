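# Pipeline orchestration: simulate -> phenotype -> epi -> scan -> gsea,
# with per-stage outputs carrying a provenance header (config hash, seed,
# package version) so every artifact is reproducible from config + seed.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(enabled = TRUE, n_subjects = 500L, n_snps = 500L,
                    maf_range = c(0.1, 0.5), missing_genotype_rate = 0,
                    early_menarche_tg_effect = 37.83),
    phenotype = list(),
    epi = list(covariates = c("age", "area", "income", "education", "crp")),
    scan = list(trait = "tg", family = "linear",
                exposure_coding = "early_binary",
                covariates = c("age", "area", "income", "education", "crp"),
                maf_threshold = 0.05, missing_threshold = 0.005,
                lambda_gc_trigger = 1.05),
    gsea = list(window = 20000, min_size = 20, max_size = 200,
                k_perm = 200L, sig_threshold = 0.001),
    log_level = "info"
  )
}

#' Read a pipeline configuration file (YAML)
#'
#' Missing keys fall back to the package defaults; referenced input files
#' (when simulation is disabled) are checked for existence.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (k in names(user)) {
      if (is.list(user[[k]]) && is.list(cfg[[k]]))
        cfg[[k]] <- utils::modifyList(cfg[[k]], user[[k]])
      else cfg[[k]] <- user[[k]]
    }
  }
  for (f in c("pheno_file", "vcf_file", "bed_file", "gmt_file")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configured input does not exist: ", cfg[[f]], call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[sort(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

provenance_for <- function(cfg, stage) {
  c(stage = stage,
    package = paste0("gxemets ",
                     as.character(utils::packageVersion("gxemets"))),
    seed = as.character(cfg$seed),
    config_md5 = config_hash(unclass(cfg)))
}

pipe_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "warning")) return(invisible())
  message("[gxemets] ", ...)
}

run_stage <- function(name, cfg, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> phenotype -> epi -> scan -> gsea and
#' writes every stage's outputs under `out_dir`. Outputs carry a provenance
#' header (`# config_md5`, `# seed`, package version); reruns with the same
#' config and seed are byte-identical.
#'
#' @param config a `pipeline_config` (see [read_pipeline_config()]), a path
#'   to a YAML config, or `NULL` for the defaults.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config = NULL, out_dir = "gxemets_out") {
  cfg <- if (is.character(config)) read_pipeline_config(config)
  else if (is.null(config)) read_pipeline_config(NULL)
  else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  # -- simulate ------------------------------------------------------------
  if (isTRUE(cfg$simulate$enabled)) {
    run_stage("simulate", cfg, {
      sc <- sim_config(
        n_subjects = cfg$simulate$n_subjects,
        n_snps = cfg$simulate$n_snps,
        maf_range = as.numeric(cfg$simulate$maf_range),
        missing_genotype_rate = cfg$simulate$missing_genotype_rate,
        early_menarche_tg_effect = cfg$simulate$early_menarche_tg_effect,
        planted_snps = cfg$simulate$planted_snps,
        enriched_pathway_id = cfg$simulate$enriched_pathway_id,
        seed = cfg$seed)
      cohort <- simulate_cohort(sc)
      gm <- simulate_genotypes(sc)
      cohort <- plant_gxe_effects(cohort, gm, sc)
      ann <- simulate_annotation(gm, sc)
      paths$pheno <- file.path(out_dir, "cohort.tsv")
      paths$vcf <- file.path(out_dir, "genotypes.vcf")
      paths$bed <- file.path(out_dir, "genes.bed")
      paths$gmt <- file.path(out_dir, "pathways.gmt")
      write_pheno(cohort, paths$pheno)
      write_vcf(gm, paths$vcf)
      write_bed(ann$gene_intervals, paths$bed)
      write_gmt(ann$pathways, paths$gmt, ann$descriptions)
      pipe_log(cfg, "simulate: ", nrow(cohort), " subjects, ",
               nrow(gm$snps), " SNPs")
    })
  } else {
    paths$pheno <- cfg$pheno_file
    paths$vcf <- cfg$vcf_file
    paths$bed <- cfg$bed_file
    paths$gmt <- cfg$gmt_file
    for (f in c("pheno", "vcf", "bed", "gmt"))
      if (is.null(paths[[f]]) || !file.exists(paths[[f]]))
        stop("pipeline stage '", if (f == "pheno") "phenotype" else "scan",
             "' input missing: ", f, " file", call. = FALSE)
  }

  # -- phenotype -----------------------------------------------------------
  pheno <- run_stage("phenotype", cfg, {
    raw <- read_pheno(paths$pheno)
    ph <- phenotype_cohort(raw)
    paths$phenotyped <- file.path(out_dir, "phenotyped.tsv")
    write_results(ph, paths$phenotyped, provenance_for(cfg, "phenotype"))
    rep <- attr(ph, "exclusion_report")
    paths$exclusions <- file.path(out_dir, "exclusions.txt")
    writeLines(sprintf("%s\t%d", names(rep), rep), paths$exclusions)
    pipe_log(cfg, "phenotype: ", nrow(ph), " retained (excluded ",
             sum(rep), ")")
    ph
  })

  # -- epi -----------------------------------------------------------------
  run_stage("epi", cfg, {
    covs <- cfg$epi$covariates
    lg <- fit_category_logistic(pheno, "mets", covariates = covs)
    ln <- fit_category_linear(pheno, "tg", covariates = covs)
    paths$epi_logistic <- file.path(out_dir, "epi_mets_or.tsv")
    paths$epi_linear <- file.path(out_dir, "epi_tg_beta.tsv")
    write_results(lg, paths$epi_logistic, provenance_for(cfg, "epi"))
    write_results(ln, paths$epi_linear, provenance_for(cfg, "epi"))
    pipe_log(cfg, "epi: ", nrow(lg), " + ", nrow(ln), " category effects")
  })

  # -- scan ----------------------------------------------------------------
  scan <- run_stage("scan", cfg, {
    gm <- read_vcf(paths$vcf)
    qc <- qc_filter(gm, maf_threshold = cfg$scan$maf_threshold,
                    missing_threshold = cfg$scan$missing_threshold)
    sconf <- scan_config(trait = cfg$scan$trait, family = cfg$scan$family,
                         exposure_coding = cfg$scan$exposure_coding,
                         covariates = cfg$scan$covariates,
                         maf_threshold = cfg$scan$maf_threshold,
                         missing_threshold = cfg$scan$missing_threshold,
                         lambda_gc_trigger = cfg$scan$lambda_gc_trigger)
    sc <- run_scan(pheno, qc$genotypes, sconf)
    paths$scan <- file.path(out_dir, "scan.tsv")
    paths$qq <- file.path(out_dir, "scan_qq.tsv")
    prov <- c(provenance_for(cfg, "scan"),
              lambda_int = sprintf("%.4f", sc$lambda_int),
              lambda_joint = sprintf("%.4f", sc$lambda_joint),
              lambda_int_raw = sprintf("%.4f", sc$lambda_int_raw),
              inverse_normal_applied = as.character(sc$int_applied),
              qc_removed = as.character(sum(qc$report[c("removed_missing",
                                                        "removed_maf")])))
    write_results(sc$results, paths$scan, prov)
    write_results(sc$qq, paths$qq, provenance_for(cfg, "scan"))
    pipe_log(cfg, "scan: ", nrow(sc$results), " SNPs, lambda_int = ",
             sprintf("%.3f", sc$lambda_int))
    list(scan = sc, snps = qc$genotypes$snps)
  })

  # -- gsea ----------------------------------------------------------------
  run_stage("gsea", cfg, {
    genes <- read_bed(paths$bed)
    gmt <- read_gmt(paths$gmt)
    res <- run_pathway_analysis(scan$scan$results, scan$snps, genes,
                                gmt$pathways, window = cfg$gsea$window,
                                min_size = cfg$gsea$min_size,
                                max_size = cfg$gsea$max_size,
                                k_perm = cfg$gsea$k_perm, seed = cfg$seed,
                                sig_threshold = cfg$gsea$sig_threshold)
    tab <- report_pathways(res, gmt$descriptions)
    paths$gsea <- file.path(out_dir, "pathways.tsv")
    write_results(tab, paths$gsea, provenance_for(cfg, "gsea"))
    pipe_log(cfg, "gsea: ", nrow(tab), " pathways tested")
  })

  invisible(paths)
}
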