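test_that("generator outputs are byte-identical under a fixed seed", {
  cfg <- fast_config(seed = 5)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$genes$start, g2$genes$start)
  t1 <- simulate_truth(cfg, g1); t2 <- simulate_truth(cfg, g2)
  expect_identical(t1$propensity, t2$propensity)
  r1 <- simulate_reads(cfg, t1); r2 <- simulate_reads(cfg, t2)
  expect_identical(r1$reads, r2$reads)
  h1 <- simulate_haplotypes(cfg); h2 <- simulate_haplotypes(cfg)
  expect_identical(as.character(h1$sequences), as.character(h2$sequences))
  # and a different seed changes the sequence
  g3 <- simulate_genome(fast_config(seed = 6))
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))
})

test_that("zero island fraction leaves the whole genome CpG-depleted", {
  cfg <- sim_config(seed = 2, chrom_lengths = c(chr1 = 20000L), n_genes = 0L,
                    cpg_island_fraction = 0)
  gen <- simulate_genome(cfg)
  # brute-force O/E scan: no 200-bp window anywhere may exceed 0.6
  expect_equal(nrow(detect_cgi(gen$genome)), 0L)
  got <- oracle_cgi(as.character(gen$genome[["chr1"]])[1])
  expect_null(got)
})

test_that("designated island tracts carry detectable CpG enrichment", {
  cfg <- sim_config(seed = 3, chrom_lengths = c(chr1 = 60000L), n_genes = 5L,
                    cpg_island_fraction = 0.03)
  gen <- simulate_genome(cfg)
  expect_gt(nrow(gen$cgi_tracts), 0L)
  found <- detect_cgi(gen$genome)
  expect_gt(nrow(found), 0L)
  # most designated tracts overlap a detected island
  hit <- 0L
  for (i in seq_len(nrow(gen$cgi_tracts))) {
    tr <- gen$cgi_tracts[i, ]
    ov <- found$chrom == tr$chrom & found$start < tr$end & found$end > tr$start
    if (any(ov)) hit <- hit + 1L
  }
  expect_gte(hit / nrow(gen$cgi_tracts), 0.7)
})

test_that("degenerate gene counts and infeasible genes are handled", {
  cfg <- fast_config(seed = 4, n_genes = 0L)
  gen <- simulate_genome(cfg)
  expect_equal(nrow(gen$genes), 0L)
  expect_equal(sum(Biostrings::width(gen$genome)),
               sum(cfg$chrom_lengths))
  path <- withr::local_tempfile(fileext = ".bed12")
  write_bed12(gen$genes, path)
  expect_equal(nrow(read_bed12(path)), 0L)
  expect_error(simulate_genome(sim_config(chrom_lengths = c(chr1 = 3000L),
                                          n_genes = 2L)),
               "longer than")
})

test_that("planted truth keeps the exact fold ratio against every other breed", {
  cfg <- fast_config(seed = 9, dmr_fold = 4)
  gen <- simulate_genome(cfg)
  truth <- simulate_truth(cfg, gen)
  expect_gt(nrow(truth$planted), 0L)
  for (k in seq_len(nrow(truth$planted))) {
    i <- truth$planted$index[k]
    b <- truth$planted$breed[k]
    others <- setdiff(colnames(truth$propensity), b)
    ratio <- truth$propensity[i, b] / truth$propensity[i, others]
    if (truth$planted$direction[k] == "up") {
      expect_equal(unname(ratio), rep(4, 3), tolerance = 1e-12)
    } else {
      expect_equal(unname(ratio), rep(0.25, 3), tolerance = 1e-12)
    }
  }
})

test_that("read simulation emits exactly the requested number of records", {
  cfg <- fast_config(seed = 10, reads_per_sample = 1000L)
  gen <- simulate_genome(cfg)
  truth <- simulate_truth(cfg, gen)
  rd <- simulate_reads(cfg, truth)
  expect_equal(length(rd$reads),
               length(cfg$breeds) * cfg$replicates_per_breed)
  for (s in names(rd$reads)) expect_equal(nrow(rd$reads[[s]]), 1000L)
  # binned + unbinned reads conserve the total
  bc <- count_reads(truth$bins, rd$reads)
  expect_equal(unname(colSums(bc$counts) + bc$unbinned),
               rep(1000L, length(rd$reads)))
  # all-zero propensity is rejected
  truth$propensity[] <- 0
  expect_error(simulate_reads(cfg, truth), "all-zero")
})

test_that("noise-free replicates of one breed correlate at r >= 0.99", {
  cfg <- fast_config(seed = 14, replicate_noise_sd = 0)
  gen <- simulate_genome(cfg)
  truth <- simulate_truth(cfg, gen)
  rd <- simulate_reads(cfg, truth)
  bc <- count_reads(truth$bins, rd$reads)
  r <- oracle_pearson(bc$counts[, "UQ_R1"], bc$counts[, "UQ_R2"])
  expect_gte(r, 0.99)
})

test_that("doubling one bin's propensity doubles its expected count", {
  # hand-built truth: flat propensity except one doubled bin
  bins <- make_bins(c(chr1 = 15000L), 300L)   # 50 bins
  n <- nrow(bins)
  ratios <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s, chrom_lengths = c(chr1 = 15000L),
                      n_genes = 0L, reads_per_sample = 5000L, breeds = "X",
                      replicates_per_breed = 2L, n_planted_dmrs = 0L,
                      replicate_noise_sd = 0)
    prop <- matrix(1, n, 1, dimnames = list(NULL, "X"))
    prop[10, 1] <- 2
    truth <- structure(list(bins = bins, propensity = prop),
                       class = "sim_truth")
    rd <- simulate_reads(cfg, truth)
    cnt <- count_reads(bins, rd$reads["X_R1"])$counts[, 1]
    cnt[10] / mean(cnt[-10])
  }, 0)
  expect_equal(mean(ratios), 2, tolerance = 0.1)
})

test_that("expression coupling: noiseless positive slope gives r near +1", {
  cfg <- fast_config(seed = 20, well_noise_sd = 0, ref_noise_sd = 0,
                     expression_coupling = data.frame(
                       gene = "TG", site = "cg1", slope = 1.5,
                       noise_sd = 0, protein_slope = 0,
                       stringsAsFactors = FALSE))
  ex <- simulate_expression(cfg)
  rel <- relative_expression(ex$ct, reference_genes = c("ACTB", "RPL19"))
  res <- methylation_expression_correlation(ex$methylation, rel)
  expect_gt(res$r[res$gene == "TG"], 0.97)
  # reference Cts identical across samples when reference noise is off
  refs <- ex$ct[ex$ct$role == "reference" & ex$ct$gene == "ACTB", ]
  expect_equal(length(unique(refs$ct)), 1L)
})

test_that("null coupling (slope 0) rarely produces significant correlation", {
  hits <- 0L
  for (s in 1:100) {
    cfg <- fast_config(seed = s, expression_coupling = data.frame(
      gene = "TG", site = "cg1", slope = 0, noise_sd = 0.3,
      protein_slope = 0, stringsAsFactors = FALSE))
    ex <- simulate_expression(cfg)
    rel <- relative_expression(ex$ct, reference_genes = c("ACTB", "RPL19"))
    res <- methylation_expression_correlation(ex$methylation, rel)
    if (res$p[res$gene == "TG"] < 0.05) hits <- hits + 1L
  }
  expect_lte(hits, 10L)
})

test_that("haplotype panel: sizes, divergence-zero Fst, validation", {
  cfg <- sim_config(seed = 30, divergence = 0, pop_size = 50,
                    n_populations = 2)
  hp <- simulate_haplotypes(cfg)
  expect_equal(length(hp$sequences), 100L)
  expect_equal(nrow(hp$populations), 100L)
  # both populations drawn from one frequency vector: near-zero Fst
  hd <- collapse_haplotypes(hp$sequences, hp$populations)
  expect_lt(abs(pairwise_fst(hd)$fst["pop1", "pop2"]), 0.05)
  # collapsing recovers the planted haplotype partition
  expect_equal(hd$n_haplotypes, length(unique(hp$haplotype)))
  expect_error(simulate_haplotypes(sim_config(n_root_haplotypes = 0L)),
               ">= 1")
  expect_error(simulate_haplotypes(sim_config(n_populations = 1L)),
               "2 populations")
})

test_that("simulation files round-trip through the readers byte-identically", {
  cfg <- fast_config(seed = 40, reads_per_sample = 2000L)
  study <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_simulation(study, dir)
  # re-writing what the readers load reproduces the same bytes
  reads_back <- read_bed6(file.path(dir, "reads", "UQ_R1.bed"))
  expect_identical(reads_back, study$reads$reads[["UQ_R1"]])
  genes_back <- read_bed12(file.path(dir, "genes.bed12"))
  expect_equal(genes_back$gene_id, study$genes$gene_id)
  genome_back <- read_fasta(file.path(dir, "genome.fa"))
  expect_identical(as.character(genome_back), as.character(study$genome))
})
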