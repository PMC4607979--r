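# In-code fixtures shared across test files.

# a small gene set on two chromosomes, both strands, exons flush with ends
fixture_genes <- function() {
  g <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(10000L, 30000L, 5000L),
    end = c(16000L, 34000L, 9000L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
  g$exons <- list(
    cbind(c(10000L, 12000L, 15000L), c(10400L, 12500L, 16000L)),
    cbind(c(30000L, 33000L), c(30800L, 34000L)),
    cbind(c(5000L, 8000L), c(5300L, 9000L)))
  class(g) <- c("gene_models", "data.frame")
  g
}

# hand-built enrichment object (bins x samples score matrix)
fixture_enrichment <- function(scores, breeds) {
  n <- nrow(scores)
  bins <- make_bins(c(chrX = n * 300L), 300L)
  structure(list(bins = bins, scores = scores,
                 total_mapped = stats::setNames(rep(1e6, ncol(scores)),
                                                colnames(scores)),
                 breeds = breeds),
            class = "enrichment")
}

# small but complete synthetic study config, sized for speed
fast_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, chrom_lengths = c(chr1 = 60000L, chr2 = 30000L),
         n_genes = 6L, reads_per_sample = 30000L, n_planted_dmrs = 8L,
         dmr_expected_range = c(0, Inf), pop_size = 12L, hap_length = 400L),
    list(...))
  do.call(sim_config, args)
}

fixture_haplotypes <- function(hap, pop) {
  structure(list(individual = paste0("i", seq_along(hap)),
                 population = pop, haplotype = hap,
                 n_haplotypes = length(unique(hap)),
                 n_sites_used = 0L),
            class = "haplotype_data")
}
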