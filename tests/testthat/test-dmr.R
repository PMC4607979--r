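make_tests_fixture <- function(scores4, breeds = c("A", "B", "C", "D")) {
  cols <- as.vector(t(outer(breeds, 1:2, paste0)))
  colnames(scores4) <- cols
  bmap <- stats::setNames(rep(breeds, each = 2), cols)
  pairwise_tests(fixture_enrichment(scores4, bmap))
}

test_that("four breeds give exactly six comparisons with symmetric structure", {
  set.seed(2)
  scores <- matrix(rgamma(160, 4, 1), ncol = 8)
  tst <- make_tests_fixture(scores)
  expect_equal(nrow(tst$pairs), choose(4, 2))
  expect_equal(ncol(tst$p), 6L)
  # swapping the pair order flips t sign and inverts fold change, p unchanged
  rev_scores <- scores[, c(3, 4, 1, 2, 5, 6, 7, 8)]
  tst2 <- make_tests_fixture(rev_scores, breeds = c("B", "A", "C", "D"))
  k <- which(tst$pairs$label == "A_vs_B")
  k2 <- which(tst2$pairs$label == "B_vs_A")
  expect_equal(tst2$t[, k2], -tst$t[, k], tolerance = 1e-12)
  expect_equal(tst2$fold_change[, k2], 1 / tst$fold_change[, k],
               tolerance = 1e-12)
  expect_equal(tst2$p[, k2], tst$p[, k], tolerance = 1e-12)
})

test_that("per-bin t and p match the closed-form pooled-variance test", {
  scores <- rbind(c(10, 10.2, 20, 19.8, 5, 5.2, 5.1, 4.9),
                  c(3, 3, 3, 3, 3, 3, 3, 3),
                  c(8, 9, 8.5, 9.5, 1, 1.2, 0.9, 1.1))
  tst <- make_tests_fixture(scores)
  k <- which(tst$pairs$label == "A_vs_B")
  o <- oracle_t(scores[1, 1:2], scores[1, 3:4])
  expect_equal(unname(tst$t[1, k]), o$t, tolerance = 1e-12)
  expect_equal(unname(tst$p[1, k]), o$p, tolerance = 1e-12)
  # groups (10,10.2) vs (20,19.8): strong difference, fold change ~0.5
  expect_lt(tst$p[1, k], 0.05)
  expect_equal(unname(tst$fold_change[1, k]), 10.1 / 19.9,
               tolerance = 1e-12)
  # identical groups: t = 0, p = 1, fold change 1
  expect_equal(tst$t[2, ], rep(0, 6), ignore_attr = TRUE)
  expect_equal(tst$p[2, ], rep(1, 6), ignore_attr = TRUE)
  expect_equal(tst$fold_change[2, ], rep(1, 6), ignore_attr = TRUE)
})

test_that("missing replication and missing breed map are rejected", {
  scores <- matrix(rgamma(30, 2, 1), ncol = 3,
                   dimnames = list(NULL, c("A1", "A2", "B1")))
  enr <- fixture_enrichment(scores, stats::setNames(c("A", "A", "B"),
                                                    colnames(scores)))
  expect_error(pairwise_tests(enr), "'B'")
  enr$breeds <- NULL
  expect_error(pairwise_tests(enr), "breed")
})

test_that("DMR definition: significant in at least one of the six pairs", {
  scores <- rbind(c(10, 10.1, 10.2, 9.9, 10, 10.1, 9.8, 10.2),  # null
                  c(10, 10.1, 30, 30.2, 10.1, 9.9, 10, 10.05))  # B elevated
  tst <- make_tests_fixture(scores)
  calls <- call_dmrs(tst, alpha = 0.05)
  expect_false(1L %in% calls$index)
  expect_true(2L %in% calls$index)
  rec <- calls[calls$index == 2L, ]
  expect_true(grepl("A_vs_B", rec$sig_pairs))
  expect_gte(rec$n_sig, 1L)
})

test_that("fold-change filter uses strict bounds (exactly 2.0 is removed)", {
  dmrs <- data.frame(index = 1:4, chrom = "chrX", start = 0L, end = 300L,
                     n_sig = 1L, sig_pairs = "A_vs_B", min_p = 0.01,
                     min_fc = c(0.6, 0.4, 1.0, 0.5),
                     max_fc = c(1.8, 1.2, 2.0, 2.5),
                     stringsAsFactors = FALSE)
  kept <- fold_change_filter(dmrs)
  expect_equal(kept$index, c(2L, 4L))  # 0.4 < 0.5; 2.5 > 2; 2.0 and 0.5 fail
})

test_that("breed-specificity requires all three pairs, consistency, others null", {
  base <- c(10, 10.1, 10.05, 9.95, 10.1, 9.9, 10, 10.08)
  up_b <- base; up_b[3:4] <- c(40, 40.3)                  # B alone elevated
  two_up <- base; two_up[3:4] <- c(40, 40.3); two_up[5:6] <- c(40.2, 39.9)
  # B elevated but an unrelated pair (C vs D) also separates cleanly
  b_plus_noise <- c(10, 10.1, 40, 40.3, 10.1, 10.12, 10.6, 10.58)
  scores <- rbind(base, up_b, two_up, b_plus_noise)
  tst <- make_tests_fixture(scores)
  spec <- breed_specific_dmrs(tst, alpha = 0.05)
  expect_equal(spec$specific_to[spec$index == 2L], "B")
  expect_equal(spec$direction[spec$index == 2L], "up")
  # jointly elevated breeds are specific to neither; null bin to none
  expect_false(1L %in% spec$index)
  expect_false(3L %in% spec$index)
  # a significant unrelated pair blocks specificity under the default rule
  expect_false(4L %in% spec$index)
  spec2 <- breed_specific_dmrs(tst, alpha = 0.05, others_null = FALSE)
  expect_equal(spec2$specific_to[spec2$index == 4L], "B")
})

test_that("DMR-to-gene mapping matches brute-force interval intersection", {
  genes <- fixture_genes()
  dmrs <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(100L, 9000L, 15900L, 4800L, 11000L),
    end = c(400L, 9300L, 16200L, 5100L, 11300L),
    stringsAsFactors = FALSE)
  mapped <- map_dmrs_to_genes(dmrs, genes)
  # brute force: gene territory = body + 2200 bp upstream of TSS
  naive <- lapply(seq_len(nrow(dmrs)), function(i) {
    hits <- character(0)
    for (g in seq_len(nrow(genes))) {
      s <- genes$start[g]; e <- genes$end[g]
      if (genes$strand[g] == "+") s <- s - 2200L else e <- e + 2200L
      if (genes$chrom[g] == dmrs$chrom[i] && dmrs$start[i] < e &&
          dmrs$end[i] > s) hits <- c(hits, genes$gene_id[g])
    }
    sort(hits)
  })
  expect_equal(mapped$gene_ids, naive)
  expect_equal(mapped$gene_ids[[1]], character(0))  # intergenic DMR
  expect_equal(mapped$gene_ids[[2]], "gA")          # promoter hit
})

test_that("hypergeometric enrichment matches enumeration and BH arithmetic", {
  background <- paste0("g", 1:40)
  dmg <- paste0("g", 1:10)
  sets <- list(all_dmg = dmg,                      # perfectly enriched
               half = paste0("g", c(1:5, 21:25)),  # half enriched
               none = paste0("g", 31:38))
  res <- gene_set_enrichment(dmg, background, sets)
  for (s in names(sets)) {
    k <- length(intersect(sets[[s]], dmg))
    expect_equal(res$p[res$set == s],
                 oracle_hyper(k, length(sets[[s]]), 40, 10),
                 tolerance = 1e-12)
  }
  # dmg = whole background -> overlap is forced, p = 1 for every set
  res_all <- gene_set_enrichment(background, background, sets)
  expect_equal(res_all$p, rep(1, 3))
  # adjusted p column is the BH transform of the raw p column
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
  expect_error(gene_set_enrichment(c(dmg, "novel"), background, sets),
               "novel")
})

test_that("clustering: distances are 1 - Pearson, duplicates merge at zero", {
  set.seed(9)
  scores <- matrix(rgamma(200, 3, 1), ncol = 4,
                   dimnames = list(NULL, c("a", "b", "c", "d")))
  scores <- scores[1:50, ]
  cl <- cluster_breeds(scores)
  d <- as.matrix(cl$dist)
  expect_equal(d["a", "b"], 1 - oracle_pearson(scores[, "a"], scores[, "b"]),
               tolerance = 1e-12)
  # ultrametric under average linkage: merge heights nondecreasing
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
  # duplicated unit merges first at height ~0
  scores2 <- cbind(scores, a_copy = scores[, "a"])
  cl2 <- cluster_breeds(scores2)
  expect_lt(cl2$hclust$height[1], 1e-12)
  first <- cl2$hclust$merge[1, ]
  expect_setequal(cl2$hclust$labels[-first], c("a", "a_copy"))
  expect_error(cluster_breeds(scores[, 1:2]), ">= 3")
  expect_error(cluster_breeds(scores[1, , drop = FALSE]), "bins")
  expect_match(cl$newick, "^\\(")
})

test_that("intergenic clustering input keeps covered intergenic bins only", {
  genes <- fixture_genes()
  bins <- make_bins(c(chr1 = 50000L, chr2 = 12000L), 300L)
  ann <- classify_bins(bins, genes)
  set.seed(4)
  counts <- matrix(rpois(nrow(bins) * 4, 30), ncol = 4,
                   dimnames = list(NULL, paste0("s", 1:4)))
  counts[1, ] <- c(11L, 11L, 10L, 50L)   # one unit at threshold -> dropped
  bc <- structure(list(bins = bins, counts = counts,
                       total_mapped = stats::setNames(rep(1e5, 4),
                                                      paste0("s", 1:4)),
                       unbinned = integer(4)),
                  class = "bin_counts")
  sel <- intergenic_cluster_input(bc, ann, min_reads = 10)
  keep <- ann$element == "intergenic" & apply(counts, 1, function(v) all(v > 10))
  expect_equal(nrow(sel), sum(keep))
  expect_false(1L %in% which(keep))
})
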