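strip_chr <- function(x) sub("^chr", "", as.character(x))

#' Map SNPs to genes within a flanking window
#'
#' A SNP maps to a gene when it lies on the same chromosome and its position
#' falls within `[start - window, end + window]`, boundaries inclusive
#' (gene coordinates 1-based inclusive). A SNP may map to several genes.
#' Chromosome labels are compared after stripping any "chr" prefix.
#'
#' @param snps data.frame with `snp_id`, `chrom`, `pos`.
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param window flanking distance in base pairs (default 20000).
#' @return named list gene_id -> character vector of snp_ids (genes with no
#'   SNP are omitted); the number of SNPs mapping to no gene is attached as
#'   attribute `"n_unmapped_snps"`.
#' @export
map_snps_to_genes <- function(snps, genes, window = 20000) {
  sch <- strip_chr(snps$chrom)
  gch <- strip_chr(genes$chrom)
  hit_any <- rep(FALSE, nrow(snps))
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    idx <- which(sch == gch[i] &
                   snps$pos >= genes$start[i] - window &
                   snps$pos <= genes$end[i] + window)
    if (length(idx) > 0) {
      out[[i]] <- snps$snp_id[idx]
      hit_any[idx] <- TRUE
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  attr(out, "n_unmapped_snps") <- sum(!hit_any)
  out
}

#' Gene-level statistic from SNP interaction p-values
#'
#' Per gene: the maximum of -log10(p) over its mapped SNPs' interaction
#' p-values (best-SNP statistic). Genes whose SNPs all have missing p-values
#' are excluded (and counted).
#'
#' @param mapping named list gene_id -> snp_ids from [map_snps_to_genes()].
#' @param p_int named numeric vector of per-SNP interaction p-values (names
#'   are snp_ids).
#' @return named numeric vector of gene scores; the count of excluded genes
#'   is attached as attribute `"n_excluded_genes"`.
#' @export
gene_scores <- function(mapping, p_int) {
  sc <- vapply(mapping, function(sn) {
    p <- p_int[sn]
    p <- p[is.finite(p)]
    if (length(p) == 0) NA_real_ else max(-log10(p))
  }, numeric(1))
  excluded <- sum(is.na(sc))
  sc <- sc[!is.na(sc)]
  attr(sc, "n_excluded_genes") <- excluded
  sc
}

#' Filter pathways by mapped-gene-set size
#'
#' Retains pathways whose number of genes with at least one mapped SNP lies
#' in `[min_size, max_size]` (both bounds inclusive: the stated exclusions
#' are strictly fewer than 20 or strictly more than 200 genes).
#'
#' @param pathways named list pathway_id -> gene_id vector.
#' @param mapped_genes character vector of gene ids that carry mapped SNPs;
#'   `NULL` to count all listed genes.
#' @param min_size,max_size inclusive size bounds (defaults 20 and 200).
#' @return the retained subset of `pathways`.
#' @export
filter_pathways <- function(pathways, mapped_genes = NULL, min_size = 20,
                            max_size = 200) {
  sizes <- vapply(pathways, function(g) {
    if (is.null(mapped_genes)) length(unique(g))
    else length(intersect(unique(g), mapped_genes))
  }, integer(1))
  pathways[sizes >= min_size & sizes <= max_size]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' On a descending-ranked gene list: at rank j the running sum gains
#' `score_j / sum(member scores)` for a member gene and loses
#' `1 / (N - N_member)` for a non-member; the enrichment score is the
#' running-sum value of maximal absolute deviation (signed; the earliest
#' maximum on ties).
#'
#' @param scores numeric gene scores sorted in decreasing order.
#' @param member logical vector marking set membership along the ranking.
#' @return the enrichment score (in [-1, 1]); the full running sum is
#'   attached as attribute `"running_sum"`.
#' @export
enrichment_score <- function(scores, member) {
  N <- length(scores)
  nh <- sum(member)
  if (nh < 1 || nh >= N)
    stop("need at least one member and one non-member", call. = FALSE)
  nr <- sum(scores[member])
  if (nr <= 0) stop("zero total member score", call. = FALSE)
  inc <- ifelse(member, scores / nr, -1 / (N - nh))
  run <- cumsum(inc)
  es <- run[which.max(abs(run))]
  attr(es, "running_sum") <- run
  es
}

# ES for many permuted membership index sets on a fixed ranked score vector
perm_es <- function(scores, nh, k, miss_inc) {
  N <- length(scores)
  out <- numeric(k)
  for (b in seq_len(k)) {
    idx <- sample.int(N, nh)
    inc <- rep(miss_inc, N)
    inc[idx] <- scores[idx] / sum(scores[idx])
    run <- cumsum(inc)
    out[b] <- run[which.max(abs(run))]
  }
  out
}

#' Permutation-based pathway enrichment over gene scores
#'
#' For each pathway computes the observed enrichment score on the ranked
#' gene list, a size-matched gene-label permutation null (`k_perm` random
#' member sets on the fixed ranking), the normalized enrichment score
#' NES = ES / mean(|null ES| of the same sign), a one-sided nominal p-value
#' `(1 + #\{null at least as extreme, same sign\}) / (k_perm + 1)`, and a
#' GSEA-style FDR q from the pooled null NES distribution (fraction of
#' pooled null NES at least as extreme divided by the fraction of observed
#' NES at least as extreme, capped at 1). Deterministic given `seed`.
#'
#' @param pathways named list pathway_id -> gene ids (already size-filtered).
#' @param scores named numeric vector of gene scores ([gene_scores()]).
#' @param k_perm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @param sig_threshold gene-level p-value threshold defining the reported
#'   "significant genes" count (best-SNP p below it; default 0.001).
#' @return data.frame with one row per pathway: `pathway_id`, `es`, `nes`,
#'   `p_nominal`, `fdr_q`, `n_genes_total`, `n_genes_selected`,
#'   `n_genes_significant`, `flag`.
#' @export
permutation_test <- function(pathways, scores, k_perm = 1000, seed = 1,
                             sig_threshold = 0.001) {
  if (k_perm < 100) stop("k_perm must be >= 100", call. = FALSE)
  if (length(pathways) == 0) stop("no pathways to test", call. = FALSE)
  # deterministic ranking: score descending, gene id as tie-break
  ord <- order(-scores, names(scores))
  sc <- as.numeric(scores[ord])
  gid <- names(scores)[ord]
  N <- length(sc)
  sig_cut <- -log10(sig_threshold)
  set.seed(as.integer(seed))

  rows <- vector("list", length(pathways))
  null_nes <- vector("list", length(pathways))
  for (i in seq_along(pathways)) {
    pid <- names(pathways)[i]
    genes <- unique(pathways[[i]])
    member <- gid %in% genes
    nh <- sum(member)
    if (nh < 1 || nh >= N || sum(sc[member]) <= 0) {
      rows[[i]] <- data.frame(pathway_id = pid, es = NA_real_,
                              nes = NA_real_, p_nominal = NA_real_,
                              fdr_q = NA_real_,
                              n_genes_total = length(genes),
                              n_genes_selected = nh,
                              n_genes_significant = sum(sc[member] > sig_cut),
                              flag = "degenerate_set",
                              stringsAsFactors = FALSE)
      null_nes[[i]] <- numeric(0)
      next
    }
    es <- as.numeric(enrichment_score(sc, member))
    null <- perm_es(sc, nh, k_perm, -1 / (N - nh))
    same <- if (es >= 0) null[null >= 0] else null[null < 0]
    flag <- ""
    if (length(unique(null)) == 1L) flag <- "degenerate_null"
    if (length(same) == 0 || mean(abs(same)) == 0) {
      nes <- NA_real_
      p_nom <- 1 / (k_perm + 1)
      nn <- numeric(0)
      flag <- paste0(flag, if (nzchar(flag)) ";", "no_same_sign_null")
    } else {
      denom <- mean(abs(same))
      nes <- es / denom
      extreme <- if (es >= 0) sum(null >= es) else sum(null <= es)
      p_nom <- (1 + extreme) / (k_perm + 1)
      pos_mean <- mean(null[null >= 0])
      neg_mean <- mean(abs(null[null < 0]))
      nn <- ifelse(null >= 0,
                   if (is.nan(pos_mean) || pos_mean == 0) NA else
                     null / pos_mean,
                   if (is.nan(neg_mean) || neg_mean == 0) NA else
                     null / neg_mean)
      nn <- nn[is.finite(nn)]
    }
    rows[[i]] <- data.frame(pathway_id = pid, es = es, nes = nes,
                            p_nominal = p_nom, fdr_q = NA_real_,
                            n_genes_total = length(genes),
                            n_genes_selected = nh,
                            n_genes_significant = sum(sc[member] > sig_cut),
                            flag = flag, stringsAsFactors = FALSE)
    null_nes[[i]] <- nn
  }
  res <- do.call(rbind, rows)
  pooled <- unlist(null_nes)
  obs <- res$nes
  for (i in seq_len(nrow(res))) {
    nes <- obs[i]
    if (!is.finite(nes)) {
      if (res$flag[i] != "" && is.na(res$fdr_q[i])) res$fdr_q[i] <- 1
      next
    }
    if (nes >= 0) {
      num <- mean(pooled[pooled >= 0] >= nes)
      den <- mean(obs[is.finite(obs) & obs >= 0] >= nes)
    } else {
      num <- mean(pooled[pooled < 0] <= nes)
      den <- mean(obs[is.finite(obs) & obs < 0] <= nes)
    }
    q <- if (!is.finite(num) || !is.finite(den) || den == 0) 1 else num / den
    res$fdr_q[i] <- min(1, max(q, 0))
  }
  rownames(res) <- NULL
  res
}

#' Format pathway enrichment results as a report table
#'
#' Sorted by FDR q ascending, with descriptions and the gene counts
#' (significant <= selected <= total).
#'
#' @param results data.frame from [permutation_test()].
#' @param descriptions optional named character vector pathway_id -> text.
#' @return data.frame with columns `pathway_id`, `description`, `es`, `nes`,
#'   `p_nominal`, `fdr_q`, `n_genes_significant`, `n_genes_selected`,
#'   `n_genes_total`.
#' @export
report_pathways <- function(results, descriptions = NULL) {
  if (nrow(results) == 0)
    return(data.frame(pathway_id = character(0), description = character(0),
                      es = numeric(0), nes = numeric(0),
                      p_nominal = numeric(0), fdr_q = numeric(0),
                      n_genes_significant = integer(0),
                      n_genes_selected = integer(0),
                      n_genes_total = integer(0), stringsAsFactors = FALSE))
  desc <- if (is.null(descriptions)) rep("", nrow(results)) else
    unname(descriptions[results$pathway_id])
  desc[is.na(desc)] <- ""
  out <- cbind(results[, "pathway_id", drop = FALSE],
               description = desc,
               results[, c("es", "nes", "p_nominal", "fdr_q",
                           "n_genes_significant", "n_genes_selected",
                           "n_genes_total")])
  out <- out[order(out$fdr_q, out$p_nominal), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full pathway analysis on scan results
#'
#' Maps SNPs to genes within the window, scores genes by best-SNP
#' interaction p, filters pathways to [min_size, max_size] mapped genes, and
#' runs the permutation enrichment test.
#'
#' @param scan_results data.frame from [run_scan()] (`results` element).
#' @param snps SNP metadata (`snp_id`, `chrom`, `pos`).
#' @param genes gene intervals (`gene_id`, `chrom`, `start`, `end`).
#' @param pathways named list pathway_id -> gene ids.
#' @param window mapping window in bp (default 20000).
#' @param min_size,max_size pathway size bounds (defaults 20, 200).
#' @param k_perm permutations (default 1000).
#' @param seed RNG seed.
#' @param sig_threshold see [permutation_test()].
#' @return data.frame of enrichment results (see [permutation_test()]).
#' @export
run_pathway_analysis <- function(scan_results, snps, genes, pathways,
                                 window = 20000, min_size = 20,
                                 max_size = 200, k_perm = 1000, seed = 1,
                                 sig_threshold = 0.001) {
  mapping <- map_snps_to_genes(snps, genes, window = window)
  p_int <- stats::setNames(scan_results$p_int, scan_results$snp_id)
  sc <- gene_scores(mapping, p_int)
  kept <- filter_pathways(pathways, mapped_genes = names(sc),
                          min_size = min_size, max_size = max_size)
  if (length(kept) == 0)
    stop("no pathway passes the size filter", call. = FALSE)
  permutation_test(kept, sc, k_perm = k_perm, seed = seed,
                   sig_threshold = sig_threshold)
}
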