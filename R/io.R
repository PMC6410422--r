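# Readers/writers for the pipeline's plain-text formats: phenotype TSV,
# minimal VCF v4.2 (GT only), BED4 gene intervals, GMT gene sets, and
# provenance-headed result TSVs. Chromosome labels are normalized ("chr"
# prefix stripped) at read time so VCF and BED agree.

pheno_required_cols <- c("subject_id", "aam", "sbp", "dbp", "fg", "fi", "wc",
                         "tg", "hdl", "antihypertensive_med",
                         "antidiabetic_med", "age", "area", "income",
                         "education", "crp")

#' Read a phenotype/covariate table (TSV)
#'
#' Validates the mandatory column schema; unknown columns are preserved.
#' Missing values are "." or empty.
#'
#' @param path TSV file path.
#' @return cohort data.frame.
#' @export
read_pheno <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ".", ""))
  miss <- setdiff(pheno_required_cols, names(df))
  if (length(miss) > 0)
    stop("phenotype file lacks mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Write a table as TSV with an optional provenance header
#'
#' Missing values are written as "."; any column whose name contains
#' "p_value"/"p_int"/"p_joint"/"p_nominal"/"fdr_q" is formatted in
#' scientific notation with 4 significant digits. Header lines (provenance)
#' are prefixed with "#".
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param provenance named character vector written as `# key: value` lines.
#' @export
write_results <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  fmt <- df
  pcols <- grep("p_value|p_int|p_joint|p_nominal|fdr_q", names(fmt))
  for (j in pcols)
    fmt[[j]] <- ifelse(is.na(df[[j]]), NA,
                       formatC(df[[j]], format = "e", digits = 3))
  utils::write.table(fmt, con, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE)
  invisible(path)
}

#' Read a provenance-headed TSV written by [write_results()]
#' @param path file path.
#' @return data.frame (header lines skipped).
#' @export
read_results <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = c("NA", ".", ""))
}

#' Write a genotype matrix as minimal VCF v4.2
#'
#' GT-only FORMAT, one sample column per subject, unphased separators,
#' missing calls as "./.".
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output path.
#' @export
write_vcf <- function(genotypes, path) {
  dos <- genotypes$dosages
  sn <- genotypes$snps
  gt_codes <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$samples), collapse = "\t")), con)
  for (j in seq_len(nrow(sn))) {
    g <- dos[, j]
    gt <- ifelse(is.na(g), "./.", gt_codes[g + 1L])
    writeLines(paste(c(sn$chrom[j], sn$pos[j], sn$snp_id[j], sn$ref[j],
                       sn$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF (biallelic SNPs, GT field)
#'
#' Parses GT calls to additive ALT-allele dosages; "./." (or ".|.") is
#' missing; phased and unphased separators are accepted. Multiallelic rows
#' are skipped and counted. MAF is computed from non-missing calls.
#'
#' @param path VCF path (plain or bgzipped).
#' @return a `genotype_matrix`; the number of skipped multiallelic rows is
#'   attached as attribute `"n_multiallelic_skipped"`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  n_multi <- sum(multi)
  if (all(multi)) stop("no biallelic SNP rows in VCF", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  code <- function(s) {
    s <- gsub("\\|", "/", s)
    d <- rep(NA_integer_, length(s))
    d[s == "0/0"] <- 0L
    d[s %in% c("0/1", "1/0")] <- 1L
    d[s == "1/1"] <- 2L
    d
  }
  dos <- t(apply(gt, 1L, code))  # SNP x sample -> transpose below
  dos <- t(dos)
  colnames(dos) <- NULL
  af <- colMeans(dos, na.rm = TRUE) / 2
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[
    is.na(ids) | ids == "."]
  gm <- structure(list(
    dosages = dos,
    snps = data.frame(snp_id = ids, chrom = strip_chr(fix$CHROM),
                      pos = as.integer(fix$POS), ref = fix$REF,
                      alt = fix$ALT, maf = pmin(af, 1 - af),
                      stringsAsFactors = FALSE),
    samples = colnames(gt)
  ), class = "genotype_matrix")
  attr(gm, "n_multiallelic_skipped") <- n_multi
  gm
}

#' Read gene intervals from a BED4 file
#'
#' BED is 0-based half-open; coordinates are converted once, here, to the
#' 1-based inclusive convention used internally (`start + 1`, `end`).
#'
#' @param path BED file path (chrom, start, end, name).
#' @return data.frame `gene_id`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("BED file must have 4 columns", call. = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "gene_id")
  if (any(df$start >= df$end))
    stop("BED interval with start >= end at line(s): ",
         paste(utils::head(which(df$start >= df$end), 5), collapse = ", "),
         call. = FALSE)
  data.frame(gene_id = df$gene_id, chrom = strip_chr(df$chrom),
             start = df$start + 1L, end = df$end,
             stringsAsFactors = FALSE)
}

#' Write gene intervals (1-based inclusive) as BED4 (0-based half-open)
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_bed <- function(genes, path) {
  utils::write.table(
    data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: pathway id, description, then gene ids. Duplicate genes
#' within a set are removed with a warning.
#'
#' @param path GMT file path.
#' @return list with `pathways` (named list of gene-id vectors) and
#'   `descriptions` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  pathways <- list()
  descriptions <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line (need id, description, >= 1 gene): ",
           substr(ln, 1, 50), call. = FALSE)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes) > 0) {
      warning("duplicate gene ids in set ", f[1], "; deduplicated")
      genes <- unique(genes)
    }
    pathways[[f[1]]] <- genes
    descriptions[f[1]] <- f[2]
  }
  list(pathways = pathways, descriptions = descriptions)
}

#' Write gene sets as GMT
#' @param pathways named list pathway_id -> gene ids.
#' @param descriptions named character vector (optional).
#' @param path output path.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  lines <- vapply(names(pathways), function(id) {
    d <- if (is.null(descriptions) || is.na(descriptions[id])) "na" else
      descriptions[[id]]
    paste(c(id, d, pathways[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a cohort table as TSV
#' @param cohort data.frame.
#' @param path output path.
#' @export
write_pheno <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE)
  invisible(path)
}
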