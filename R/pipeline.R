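#' Run the end-to-end synthetic-study analysis pipeline
#'
#' Generates (or reuses) a synthetic multi-breed MeDIP study, then runs every
#' analysis arm in dependency order: bin + count + filter + score,
#' genome annotation (elements, CpG islands, profiles), replicate QC and
#' breed averaging, DMR calling with fold-change filter, breed-specific sets
#' and gene mapping, hierarchical clustering of intergenic bins, haplotype
#' Fst with permutation P-values, and qPCR expression integration. All stage
#' outputs are written under `out_dir` as plain-text BED/TSV/Newick/JSON,
#' and a run manifest with md5 checksums is written last. Every stage is
#' also callable standalone through the exported functions.
#'
#' @param out_dir Output directory.
#' @param config A `sim_config` describing the synthetic study.
#' @param min_total Bin filter threshold (see [filter_bins()]).
#' @param alpha DMR significance level.
#' @param fc_low,fc_high Fold-change filter bounds.
#' @param cgi_min_len,cgi_oe CpG-island detector parameters.
#' @param cluster_min_reads Coverage threshold for clustering bins.
#' @param n_perm Fst permutations.
#' @param resume Reuse simulated input files already under
#'   `out_dir/inputs` instead of regenerating them.
#' @return A list with all in-memory stage results and `manifest_path`.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), min_total = 10L,
                         alpha = 0.05, fc_low = 0.5, fc_high = 2,
                         cgi_min_len = 200L, cgi_oe = 0.6,
                         cluster_min_reads = 10L, n_perm = 200L,
                         resume = FALSE) {
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- file.path(out_dir, "inputs")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  study <- stage("simulate", {
    if (!resume || !file.exists(file.path(inputs, "genome.fa"))) {
      sim <- simulate_study(config)
      write_simulation(sim, inputs)
    }
    NULL
  })
  # read everything back through the validating readers, so the pipeline
  # exercises exactly the same path as a run on user-supplied files
  genome <- read_fasta(file.path(inputs, "genome.fa"))
  genes <- read_bed12(file.path(inputs, "genes.bed12"))
  sample_sheet <- read_tsv(file.path(inputs, "samples.tsv"),
                           required = c("sample", "breed"))
  read_paths <- stats::setNames(
    file.path(inputs, "reads", paste0(sample_sheet$sample, ".bed")),
    sample_sheet$sample)
  breeds <- stats::setNames(sample_sheet$breed, sample_sheet$sample)

  binned <- stage("bin", {
    bins <- make_bins(config$chrom_lengths, config$bin_width)
    bc <- count_reads(bins, read_paths)
    fc <- filter_bins(bc, min_total = min_total)
    enr <- enrichment_matrix(fc, breeds = breeds)
    write_tsv(cbind(as.data.frame(fc$bins), as.data.frame(enr$scores)),
              file.path(out_dir, "enrichment_scores.tsv"))
    list(bins = bins, counts = bc, filtered = fc, enrichment = enr)
  })

  annotated <- stage("annotate", {
    ann <- classify_bins(binned$bins, genes)
    cgis <- classify_cgi_regions(
      detect_cgi(genome, min_len = cgi_min_len, oe_threshold = cgi_oe), genes)
    write_tsv(cgis, file.path(out_dir, "cpg_islands.tsv"))
    list(ann = ann, cgis = cgis)
  })
  ann_retained <- annotated$ann[binned$filtered$bins$index, , drop = FALSE]

  averaged <- stage("replicate_qc", {
    avg <- replicate_qc_and_average(binned$enrichment)
    write_tsv(avg$replicate_r, file.path(out_dir, "replicate_qc.tsv"))
    avg
  })

  profiles <- stage("profiles", {
    pr <- element_profiles(averaged$breed_scores, ann_retained,
                           annotated$cgis)
    write_tsv(pr, file.path(out_dir, "element_profiles.tsv"))
    pr
  })

  dmr <- stage("dmr", {
    tests <- pairwise_tests(binned$enrichment)
    calls <- call_dmrs(tests, alpha = alpha)
    filtered <- fold_change_filter(calls, low = fc_low, high = fc_high)
    specific <- breed_specific_dmrs(tests, alpha = alpha)
    mapped <- map_dmrs_to_genes(calls, genes)
    write_bed6(data.frame(chrom = calls$chrom, start = calls$start,
                          end = calls$end, name = calls$sig_pairs,
                          score = round(-log10(pmax(calls$min_p, 1e-300)), 4),
                          strand = "."),
               file.path(out_dir, "dmrs.bed"))
    write_tsv(mapped, file.path(out_dir, "dmrs_genes.tsv"))
    write_tsv(specific, file.path(out_dir, "breed_specific_dmrs.tsv"))
    list(tests = tests, calls = calls, fold_filtered = filtered,
         specific = specific, mapped = mapped)
  })

  clust <- stage("cluster", {
    scores <- intergenic_cluster_input(binned$filtered, ann_retained,
                                       min_reads = cluster_min_reads)
    cl <- cluster_breeds(scores)
    writeLines(cl$newick, file.path(out_dir, "clustering.nwk"))
    cl
  })

  fst <- stage("fst", {
    haps <- collapse_haplotypes(
      read_fasta(file.path(inputs, "haplotypes.fa")),
      read_tsv(file.path(inputs, "populations.tsv"),
               required = c("individual", "population")))
    res <- fst_permutation(haps, n_perm = n_perm, seed = config$seed)
    write_tsv(as.data.frame(res$fst), file.path(out_dir, "fst.tsv"))
    write_tsv(as.data.frame(res$p_perm), file.path(out_dir, "fst_pvalues.tsv"))
    list(haplotypes = haps, result = res)
  })

  expr <- stage("expression", {
    ct <- read_tsv(file.path(inputs, "qpcr_ct.tsv"),
                   required = c("sample", "gene", "role", "ct"))
    meth <- read_tsv(file.path(inputs, "cpg_methylation.tsv"),
                     required = c("region", "site", "sample", "fraction"))
    rel <- relative_expression(ct,
                               reference_genes = names(config$reference_genes))
    sites <- site_group_test(meth)
    corr <- methylation_expression_correlation(meth, rel)
    write_tsv(rel, file.path(out_dir, "relative_expression.tsv"))
    write_tsv(sites, file.path(out_dir, "site_tests.tsv"))
    write_tsv(corr, file.path(out_dir, "methylation_expression_corr.tsv"))
    list(relative = rel, site_tests = sites, correlation = corr)
  })

  manifest_path <- file.path(out_dir, "manifest.json")
  outputs <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                     manifest_path)
  manifest <- list(
    tool = "medipscape",
    version = as.character(utils::packageVersion("medipscape")),
    seed = config$seed,
    parameters = list(min_total = min_total, alpha = alpha, fc_low = fc_low,
                      fc_high = fc_high, cgi_min_len = cgi_min_len,
                      cgi_oe = cgi_oe, cluster_min_reads = cluster_min_reads,
                      n_perm = n_perm),
    checksums = as.list(tools::md5sum(outputs)),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(binned = binned, annotation = annotated,
                 averaged = averaged, profiles = profiles, dmr = dmr,
                 clustering = clust, fst = fst, expression = expr,
                 manifest_path = manifest_path))
}
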