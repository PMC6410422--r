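test_that("SNP-gene mapping respects the inclusive 20 kb boundary", {
  genes <- data.frame(gene_id = "GENE1", chrom = "1", start = 100000L,
                      end = 105000L, stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = c("a", "b", "c", "d"), chrom = "1",
                     pos = c(80000L, 79999L, 125000L, 125001L),
                     stringsAsFactors = FALSE)
  m <- map_snps_to_genes(snps, genes, window = 20000)
  expect_equal(m$GENE1, c("a", "c"))
  expect_equal(attr(m, "n_unmapped_snps"), 2L)
  # chromosome mismatch never maps
  snps2 <- snps; snps2$chrom <- "2"
  m2 <- map_snps_to_genes(snps2, genes)
  expect_length(m2, 0)
})

test_that("mapping equals the brute-force all-pairs interval oracle", {
  set.seed(17)
  snps <- data.frame(snp_id = sprintf("s%03d", 1:100),
                     chrom = as.character(sample(1:3, 100, TRUE)),
                     pos = sample.int(5e5, 100), stringsAsFactors = FALSE)
  st <- sample.int(4e5, 10)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:10),
                      chrom = as.character(sample(1:3, 10, TRUE)),
                      start = st, end = st + sample.int(5e4, 10),
                      stringsAsFactors = FALSE)
  w <- 20000
  m <- map_snps_to_genes(snps, genes, window = w)
  for (i in seq_len(10)) {
    oracle <- character(0)
    for (j in seq_len(100)) {
      if (genes$chrom[i] == snps$chrom[j] &&
          snps$pos[j] >= genes$start[i] - w &&
          snps$pos[j] <= genes$end[i] + w)
        oracle <- c(oracle, snps$snp_id[j])
    }
    got <- if (genes$gene_id[i] %in% names(m)) m[[genes$gene_id[i]]]
    else character(0)
    expect_equal(got, oracle)
  }
})

test_that("gene statistic is the best-SNP -log10 interaction p", {
  mapping <- list(g1 = c("a", "b"), g2 = "c", g3 = "d")
  p <- c(a = 0.1, b = 0.001, c = 1, d = NA_real_)
  sc <- gene_scores(mapping, p)
  expect_equal(unname(sc["g1"]), 3)
  expect_equal(unname(sc["g2"]), 0)
  expect_false("g3" %in% names(sc))
  expect_equal(attr(sc, "n_excluded_genes"), 1L)
  # loop-based oracle on a random fixture
  set.seed(5)
  mapping2 <- lapply(1:20, function(i) sample(letters, sample(1:5, 1)))
  names(mapping2) <- paste0("G", 1:20)
  p2 <- setNames(runif(26), letters)
  sc2 <- gene_scores(mapping2, p2)
  for (g in names(mapping2)) {
    best <- -Inf
    for (s in mapping2[[g]]) best <- max(best, -log10(p2[[s]]))
    expect_equal(unname(sc2[g]), best)
  }
})

test_that("pathway size filter keeps exactly the [20, 200] mapped-gene range", {
  mk <- function(n) paste0("g", seq_len(n))
  sets <- list(too_small = mk(19), lo = mk(20), mid = mk(100), hi = mk(200),
               too_big = mk(201))
  kept <- filter_pathways(sets)
  expect_equal(names(kept), c("lo", "mid", "hi"))
  # counting only genes with mapped SNPs
  kept2 <- filter_pathways(list(s = mk(30)), mapped_genes = mk(19))
  expect_length(kept2, 0)
  kept3 <- filter_pathways(list(s = mk(30)), mapped_genes = mk(20))
  expect_equal(names(kept3), "s")
})

test_that("enrichment score follows the weighted running sum", {
  # all members ranked first -> ES = +1
  expect_equal(as.numeric(enrichment_score(c(5, 4, 3, 2, 1),
                                           c(TRUE, TRUE, FALSE, FALSE,
                                             FALSE))), 1)
  # 4-gene hand-run fixture: scores (3,2,1,0.5), members ranks {1, 3}:
  # increments (+3/4, -1/2, +1/4, -1/2) -> running sum (.75, .25, .5, 0)
  es <- enrichment_score(c(3, 2, 1, 0.5), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(as.numeric(es), 0.75)
  expect_equal(attr(es, "running_sum"), c(0.75, 0.25, 0.5, 0))
  # complement membership with equal scores flips the sign
  s <- rep(1, 6)
  m <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(as.numeric(enrichment_score(s, m)),
               -as.numeric(enrichment_score(s, !m)))
  expect_error(enrichment_score(c(1, 2), c(TRUE, TRUE)), "non-member")
  expect_error(enrichment_score(c(0, 1), c(TRUE, FALSE)), "zero total")
})

test_that("enrichment score agrees with fgsea's statistic on random fixtures", {
  skip_if_not_installed("fgsea")
  set.seed(23)
  for (i in 1:10) {
    sc <- sort(runif(40, 0.01, 5), decreasing = TRUE)
    idx <- sort(sample(40, 8))
    mine <- as.numeric(enrichment_score(sc, seq_len(40) %in% idx))
    ref <- fgsea::calcGseaStat(sc, selectedStats = idx, gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("permutation test is deterministic, valid, and finds a planted set", {
  set.seed(31)
  scores <- setNames(c(runif(80, 0, 1.5), runif(20, 4, 7)),
                     sprintf("g%03d", 1:100))
  sets <- list(TOP = names(scores)[81:100],
               RAND1 = sample(names(scores), 25),
               RAND2 = sample(names(scores), 25),
               RAND3 = sample(names(scores), 25))
  r1 <- permutation_test(sets, scores, k_perm = 500, seed = 7)
  r2 <- permutation_test(sets, scores, k_perm = 500, seed = 7)
  expect_identical(r1, r2)
  expect_true(all(r1$p_nominal >= 1 / 501))
  expect_true(all(r1$p_nominal <= 1 & r1$fdr_q <= 1))
  top <- r1[r1$pathway_id == "TOP", ]
  expect_equal(top$p_nominal, 1 / 501)
  expect_lt(top$fdr_q, 0.05)
  expect_equal(top$n_genes_selected, 20L)
  expect_equal(top$n_genes_significant, sum(scores[81:100] > 3))
  expect_true(all(r1$n_genes_significant <= r1$n_genes_selected))
  expect_true(all(r1$n_genes_selected <= r1$n_genes_total))
})

test_that("pathway report is sorted by FDR with descriptions attached", {
  res <- data.frame(pathway_id = c("a", "b", "c"),
                    es = c(0.5, 0.4, 0.6), nes = c(1.5, 1.2, 1.8),
                    p_nominal = c(0.002, 0.004, 0.001),
                    fdr_q = c(0.019, 0.021, 0.016),
                    n_genes_total = c(49L, 47L, 44L),
                    n_genes_selected = c(38L, 37L, 33L),
                    n_genes_significant = c(14L, 14L, 17L),
                    flag = "", stringsAsFactors = FALSE)
  tab <- report_pathways(res, c(a = "SAPK cascade", b = "JNK cascade",
                                c = "type 2 diabetes"))
  expect_equal(tab$pathway_id, c("c", "a", "b"))
  expect_equal(tab$fdr_q, c(0.016, 0.019, 0.021))
  expect_equal(tab$description[1], "type 2 diabetes")
  empty <- report_pathways(res[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("pathway_id", "fdr_q") %in% names(empty)))
})
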