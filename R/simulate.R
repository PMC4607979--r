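#' Configuration for the synthetic multi-breed MeDIP study generator
#'
#' Bundles and validates every parameter of the synthetic study design. The
#' defaults describe a desk-scale analogue of a four-breed, two-replicate
#' MeDIP-seq experiment: a 600-kb two-chromosome genome tiled into 300-bp
#' bins, ~150 reads expected per bin and sample, planted four-fold
#' breed-specific differentially methylated bins, element-dependent
#' methylation baselines (exons > introns; promoter CpG islands low), a
#' four-population haplotype panel, and qPCR expression linearly coupled to
#' methylation at designated CpG sites.
#'
#' @param seed Integer seed; every generator output is byte-identical under a
#'   fixed seed.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param n_genes Number of gene models to place.
#' @param breeds Breed labels.
#' @param replicates_per_breed Biological replicates per breed.
#' @param reads_per_sample Uniquely mapped reads simulated per sample.
#' @param bin_width Bin width in bp.
#' @param n_planted_dmrs Number of bins planted with a breed-specific
#'   methylation difference.
#' @param dmr_fold Propensity fold difference of planted bins (>= 1).
#' @param dmr_breeds Breeds to cycle planted bins through (default: all).
#' @param dmr_expected_range Expected per-sample read-coverage band
#'   `c(min, max)` a bin must fall in to be eligible for planting (default
#'   150-500). Differential methylation is only meaningful where there is
#'   methylation signal to differ, so planted effects go into bins whose
#'   coverage supports a two-replicate test; extreme-coverage bins are
#'   excluded because a several-fold change there would consume a visible
#'   share of the sample's fixed read budget and shift the depth
#'   normalization of every other bin.
#' @param replicate_noise_sd SD (log scale) of the multiplicative per-bin
#'   per-sample replicate noise; the default is calibrated so that
#'   within-breed replicate Pearson correlation is ~0.99.
#' @param bin_effect_sdlog SD (log scale) of the shared lognormal per-bin
#'   propensity effect that gives MeDIP coverage its long-tailed
#'   heterogeneity.
#' @param cpg_island_fraction Fraction of the genome covered by designated
#'   CpG-island tracts.
#' @param element_baselines Named relative read propensities per element
#'   class.
#' @param cgi_promoter_factor,cgi_body_factor Propensity multipliers for bins
#'   overlapping a designated CGI tract in promoter / non-promoter context
#'   (promoter CGIs are nearly unmethylated in vivo, hence the low default).
#' @param n_populations,pop_size Haplotype panel dimensions.
#' @param n_root_haplotypes Number of distinct root haplotypes (K).
#' @param divergence Between-population haplotype-frequency divergence in
#'   \[0, 1\]; 0 means all populations share one frequency vector.
#' @param hap_length Haplotype sequence length (bp).
#' @param expression_coupling data.frame `gene, site, slope, noise_sd,
#'   protein_slope` describing CpG sites whose methylation drives target-gene
#'   Ct (and optionally protein level).
#' @param expr_breeds,expr_replicates qPCR arm design (default: first three
#'   breeds, three animals each).
#' @param reference_genes,ref_noise_sd,well_noise_sd qPCR reference genes and
#'   technical noise (cycles).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 400000L, chr2 = 200000L),
                       n_genes = 40L,
                       breeds = c("UQ", "Tan", "StH", "Hu"),
                       replicates_per_breed = 2L,
                       reads_per_sample = 300000L,
                       bin_width = 300L,
                       n_planted_dmrs = 40L,
                       dmr_fold = 4,
                       dmr_breeds = NULL,
                       dmr_expected_range = c(150, 500),
                       replicate_noise_sd = 0.05,
                       bin_effect_sdlog = 1.0,
                       cpg_island_fraction = 0.02,
                       element_baselines = c(distal_promoter = 0.7,
                                             intermediate_promoter = 0.9,
                                             proximal_promoter = 1.2,
                                             exon = 2.0, intron = 1.0,
                                             intergenic = 0.8),
                       cgi_promoter_factor = 0.25,
                       cgi_body_factor = 1.3,
                       n_populations = 4L,
                       pop_size = 40L,
                       n_root_haplotypes = 10L,
                       divergence = 0.5,
                       hap_length = 1200L,
                       expression_coupling = data.frame(
                         gene = c("GENE_A", "GENE_B"),
                         site = c("site_1", "site_2"),
                         slope = c(2, -2),
                         noise_sd = c(0.17, 0.17),
                         protein_slope = c(0, -1),
                         stringsAsFactors = FALSE),
                       expr_breeds = NULL,
                       expr_replicates = 3L,
                       reference_genes = c(ACTB = 17, RPL19 = 19),
                       ref_noise_sd = 0.05,
                       well_noise_sd = 0.02) {
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              n_genes = as.integer(n_genes), breeds = breeds,
              replicates_per_breed = as.integer(replicates_per_breed),
              reads_per_sample = as.integer(reads_per_sample),
              bin_width = as.integer(bin_width),
              n_planted_dmrs = as.integer(n_planted_dmrs),
              dmr_fold = dmr_fold, dmr_breeds = dmr_breeds,
              dmr_expected_range = dmr_expected_range,
              replicate_noise_sd = replicate_noise_sd,
              bin_effect_sdlog = bin_effect_sdlog,
              cpg_island_fraction = cpg_island_fraction,
              element_baselines = element_baselines,
              cgi_promoter_factor = cgi_promoter_factor,
              cgi_body_factor = cgi_body_factor,
              n_populations = as.integer(n_populations),
              pop_size = as.integer(pop_size),
              n_root_haplotypes = as.integer(n_root_haplotypes),
              divergence = divergence, hap_length = as.integer(hap_length),
              expression_coupling = expression_coupling,
              expr_breeds = if (is.null(expr_breeds))
                breeds[seq_len(min(3L, length(breeds)))] else expr_breeds,
              expr_replicates = as.integer(expr_replicates),
              reference_genes = reference_genes,
              ref_noise_sd = ref_noise_sd, well_noise_sd = well_noise_sd)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (length(cfg$chrom_lengths) == 0L || any(cfg$chrom_lengths <= 0)) {
    stop("chrom_lengths must be nonempty and positive")
  }
  if (is.null(names(cfg$chrom_lengths))) stop("chrom_lengths must be named")
  if (cfg$dmr_fold < 1) stop("dmr_fold must be >= 1")
  if (cfg$replicate_noise_sd < 0) stop("replicate_noise_sd must be nonnegative")
  if (cfg$cpg_island_fraction < 0 || cfg$cpg_island_fraction > 1) {
    stop("cpg_island_fraction must be in [0, 1]")
  }
  pos <- c("replicates_per_breed", "reads_per_sample", "bin_width",
           "hap_length", "pop_size", "expr_replicates")
  for (p in pos) if (cfg[[p]] <= 0L) stop(p, " must be positive")
  if (cfg$n_genes < 0L || cfg$n_planted_dmrs < 0L) {
    stop("counts must be nonnegative")
  }
  if (!is.null(cfg$dmr_breeds) && !all(cfg$dmr_breeds %in% cfg$breeds)) {
    stop("dmr_breeds must be a subset of breeds")
  }
  if (cfg$divergence < 0 || cfg$divergence > 1) {
    stop("divergence must be in [0, 1]")
  }
  invisible(cfg)
}

#' Load a simulation configuration from a YAML file
#'
#' Named entries override the [sim_config()] defaults; `chrom_lengths`,
#' `element_baselines`, `reference_genes` and `expression_coupling` are
#' converted from YAML maps/records.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("chrom_lengths", "element_baselines", "reference_genes")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$expression_coupling)) {
    raw$expression_coupling <- do.call(rbind, lapply(raw$expression_coupling,
                                                     as.data.frame))
  }
  do.call(sim_config, raw)
}

# ---- genome ----------------------------------------------------------------

# CpG-free base stream with given C/G probabilities; CpGs are sprinkled in
# afterwards at controlled per-bp rates, so the window-level O/E is tunable.
.base_stream <- function(n, p_c, p_g, p_a, p_t) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
              prob = c(p_a, p_c, p_g, p_t))
  # remove chance CG adjacencies (redraw the G; final pass forces T)
  for (pass in 1:8) {
    cg <- which(s[-n] == "C" & s[-1L] == "G")
    if (!length(cg)) break
    s[cg + 1L] <- if (pass < 8) {
      sample(c("A", "C", "T"), length(cg), replace = TRUE,
             prob = c(p_a, p_c, p_t))
    } else "T"
  }
  s
}

#' Simulate a genome with designated CpG-island tracts and gene models
#'
#' Generates one random sequence per chromosome in which CpG dinucleotides
#' occur at a strongly depleted background rate, except inside designated
#' CpG-island tracts (GC-rich, CpG-dense) covering `cpg_island_fraction` of
#' the genome; roughly half of the tracts are centred on gene TSSs to mimic
#' promoter CGIs. Gene models get 2-5 exons, mixed strands, and first/last
#' exons flush with the gene ends.
#'
#' @param config A `sim_config`.
#' @return A list with `genome` ([Biostrings::DNAStringSet]), `genes`
#'   (`gene_models`), and `cgi_tracts` (data.frame of designated tracts,
#'   0-based half-open).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  lens <- config$chrom_lengths

  # gene geometry first (lengths decide placement feasibility)
  n_genes <- config$n_genes
  genes <- NULL
  if (n_genes > 0L) {
    k <- sample(2:5, n_genes, replace = TRUE)
    geom <- lapply(seq_len(n_genes), function(i) {
      ex <- round(stats::runif(k[i], 100, 400))
      intr <- if (k[i] > 1L) round(stats::runif(k[i] - 1L, 200, 1500)) else integer()
      list(ex = ex, intr = intr, len = sum(ex) + sum(intr))
    })
    glen <- vapply(geom, `[[`, 0, "len")
    margin <- 2500L
    if (any(glen + 2L * margin > max(lens))) {
      stop("gene longer than the longest chromosome: shrink genes or grow chroms")
    }
    chrom_of <- sample(names(lens), n_genes, replace = TRUE,
                       prob = lens / sum(lens))
    placed <- lapply(names(lens), function(ch) list())
    names(placed) <- names(lens)
    rows <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      # try the assigned chromosome first, then any other that can hold it
      cands <- unique(c(chrom_of[i], names(lens)))
      cands <- cands[glen[i] + 2L * margin <= lens[cands]]
      if (!length(cands)) stop("gene ", i, " does not fit on any chromosome")
      ok <- FALSE
      for (ch in cands) {
        for (try in 1:300) {
          s0 <- floor(stats::runif(1, margin, lens[[ch]] - glen[i] - margin))
          e0 <- s0 + glen[i]
          clash <- any(vapply(placed[[ch]], function(iv)
            s0 - margin < iv[2L] && e0 + margin > iv[1L], TRUE))
          if (!clash) { ok <- TRUE; break }
        }
        if (ok) break
      }
      if (!ok) stop("could not place gene ", i, ": genome too crowded")
      placed[[ch]][[length(placed[[ch]]) + 1L]] <- c(s0, e0)
      g <- geom[[i]]
      ex_start <- s0 + cumsum(c(0L, g$ex[-length(g$ex)] +
                                  if (length(g$intr)) g$intr else integer()))
      rows[[i]] <- list(gene_id = sprintf("gene_%03d", i), chrom = ch,
                        start = as.integer(s0), end = as.integer(e0),
                        strand = sample(c("+", "-"), 1L),
                        exons = cbind(as.integer(ex_start),
                                      as.integer(ex_start + g$ex)))
    }
    genes <- data.frame(
      gene_id = vapply(rows, `[[`, "", "gene_id"),
      chrom = vapply(rows, `[[`, "", "chrom"),
      start = vapply(rows, `[[`, 0L, "start"),
      end = vapply(rows, `[[`, 0L, "end"),
      strand = vapply(rows, `[[`, "", "strand"),
      stringsAsFactors = FALSE)
    genes$exons <- lapply(rows, `[[`, "exons")
  } else {
    genes <- empty_gene_models()
  }
  class(genes) <- c("gene_models", "data.frame")

  # designated CGI tracts: half at TSSs, half random
  tract_rows <- list()
  total_cgi <- round(cfg_num(config$cpg_island_fraction) * sum(lens))
  if (total_cgi > 0) {
    budget <- total_cgi
    tss_pool <- if (nrow(genes)) sample(seq_len(nrow(genes))) else integer()
    ti <- 1L
    while (budget > 0) {
      w <- min(round(stats::runif(1, 500, 2000)), budget)
      w <- max(w, 300)
      if (ti <= length(tss_pool) && (ti %% 2L == 1L)) {
        g <- genes[tss_pool[ti], ]
        t0 <- if (g$strand == "+") g$start else g$end
        ch <- g$chrom; s0 <- max(0L, t0 - round(w / 2))
      } else {
        ch <- sample(names(lens), 1L, prob = lens / sum(lens))
        s0 <- floor(stats::runif(1, 0, lens[[ch]] - w))
      }
      e0 <- min(s0 + w, lens[[ch]])
      tract_rows[[length(tract_rows) + 1L]] <-
        data.frame(chrom = ch, start = as.integer(s0), end = as.integer(e0),
                   stringsAsFactors = FALSE)
      budget <- budget - (e0 - s0)
      ti <- ti + 1L
    }
  }
  cgi_tracts <- if (length(tract_rows)) {
    tr <- do.call(rbind, tract_rows)
    # merge overlaps so tract bookkeeping matches what is written to sequence
    out <- lapply(split(tr, tr$chrom), function(d) {
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
      data.frame(chrom = d$chrom[1L], start = IRanges::start(ir) - 1L,
                 end = IRanges::end(ir), stringsAsFactors = FALSE)
    })
    r <- do.call(rbind, out); rownames(r) <- NULL; r
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  }

  # sequence synthesis: CpG-free stream, then CpG sprinkling (bg vs island)
  bg_cpg_rate <- 0.002
  island_cpg_rate <- 0.08
  seqs <- lapply(names(lens), function(ch) {
    L <- as.integer(lens[[ch]])
    s <- .base_stream(L, p_c = 0.21, p_g = 0.21, p_a = 0.29, p_t = 0.29)
    tr <- cgi_tracts[cgi_tracts$chrom == ch, , drop = FALSE]
    in_island <- rep(FALSE, L)
    if (nrow(tr)) {
      for (j in seq_len(nrow(tr))) {
        in_island[(tr$start[j] + 1L):tr$end[j]] <- TRUE
        # GC-enrich the island span
        span <- (tr$start[j] + 1L):tr$end[j]
        s[span] <- .base_stream(length(span), p_c = 0.3, p_g = 0.3,
                                p_a = 0.2, p_t = 0.2)
      }
    }
    rate <- ifelse(in_island[-L], island_cpg_rate, bg_cpg_rate)
    hit <- which(stats::runif(L - 1L) < rate)
    if (length(hit)) { s[hit] <- "C"; s[hit + 1L] <- "G" }
    paste(s, collapse = "")
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(lens)
  list(genome = genome, genes = genes, cgi_tracts = cgi_tracts)
}

cfg_num <- function(x) as.numeric(x)

# ---- truth -----------------------------------------------------------------

#' Derive the planted per-bin read propensities (the synthetic truth)
#'
#' Builds the bins x breeds propensity matrix that [simulate_reads()] samples
#' from: element-class baselines (exons > introns; promoter CGI tracts low) x
#' (1 + CpG density of the bin) x a shared lognormal per-bin effect. Planted
#' differentially methylated bins then get their propensity multiplied (or
#' divided) by `dmr_fold` in one breed, cycling through `dmr_breeds` with
#' alternating direction, so every planted bin has a propensity ratio of at
#' least `dmr_fold` against every other breed.
#'
#' @param config A `sim_config`.
#' @param gen Output of [simulate_genome()].
#' @return A `sim_truth` list: `bins`, `annotated`, `propensity`
#'   (bins x breeds), `planted` (data.frame `index, chrom, start, end, breed,
#'   direction`), `cpg_count`, plus the genome objects carried through.
#' @export
simulate_truth <- function(config, gen) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  bins <- make_bins(config$chrom_lengths, config$bin_width)
  ann <- classify_bins(bins, gen$genes)
  n <- nrow(bins)

  # CpG density per bin, straight off the simulated sequence
  cpg_count <- integer(n)
  offset <- 0L
  for (ch in names(gen$genome)) {
    s <- as.character(gen$genome[[ch]])
    r <- charToRaw(s)
    L <- length(r)
    cg_pos <- which(r[-L] == as.raw(67L) & r[-1L] == as.raw(71L))  # 1-based
    nb <- as.integer((L + config$bin_width - 1L) %/% config$bin_width)
    if (length(cg_pos)) {
      tab <- tabulate((cg_pos - 1L) %/% config$bin_width + 1L, nbins = nb)
      cpg_count[offset + seq_len(nb)] <- tab
    }
    offset <- offset + nb
  }

  base <- unname(config$element_baselines[as.character(ann$element)])
  if (nrow(gen$cgi_tracts)) {
    gbins <- .granges0(bins$chrom, bins$start, bins$end)
    in_cgi <- IRanges::overlapsAny(gbins, .granges0(gen$cgi_tracts$chrom,
                                                    gen$cgi_tracts$start,
                                                    gen$cgi_tracts$end))
    prom <- grepl("promoter", as.character(ann$element))
    base[in_cgi & prom] <- base[in_cgi & prom] * config$cgi_promoter_factor
    base[in_cgi & !prom] <- base[in_cgi & !prom] * config$cgi_body_factor
  }
  cpg_weight <- 1 + cpg_count / config$bin_width
  bin_effect <- stats::rlnorm(n, 0, config$bin_effect_sdlog)
  shared <- base * cpg_weight * bin_effect

  propensity <- matrix(shared, nrow = n, ncol = length(config$breeds),
                       dimnames = list(NULL, config$breeds))
  planted <- data.frame(index = integer(), chrom = character(),
                        start = integer(), end = integer(),
                        breed = character(), direction = character(),
                        stringsAsFactors = FALSE)
  if (config$n_planted_dmrs > 0L) {
    target_breeds <- if (is.null(config$dmr_breeds)) config$breeds else
      config$dmr_breeds
    expected <- shared / sum(shared) * config$reads_per_sample
    eligible <- which(expected >= config$dmr_expected_range[1L] &
                        expected <= config$dmr_expected_range[2L])
    if (length(eligible) < config$n_planted_dmrs) {
      warning("only ", length(eligible), " bins fall in the ",
              "dmr_expected_range coverage band; planting fewer DMRs")
    }
    idx <- eligible[sample.int(length(eligible),
                               min(config$n_planted_dmrs, length(eligible)))]
    breed_of <- rep(target_breeds, length.out = length(idx))
    dir_of <- rep(c("up", "down"), length.out = length(idx))
    for (j in seq_along(idx)) {
      f <- if (dir_of[j] == "up") config$dmr_fold else 1 / config$dmr_fold
      propensity[idx[j], breed_of[j]] <- propensity[idx[j], breed_of[j]] * f
    }
    planted <- data.frame(index = idx, chrom = bins$chrom[idx],
                          start = bins$start[idx], end = bins$end[idx],
                          breed = breed_of, direction = dir_of,
                          stringsAsFactors = FALSE)
  }
  structure(list(bins = bins, annotated = ann, propensity = propensity,
                 planted = planted, cpg_count = cpg_count,
                 genes = gen$genes, cgi_tracts = gen$cgi_tracts),
            class = "sim_truth")
}

# ---- reads -----------------------------------------------------------------

#' Simulate per-sample mapped read positions from the planted truth
#'
#' Each sample draws exactly `reads_per_sample` read 5' positions from a
#' multinomial over bins with weights `propensity[, breed] x lognormal
#' replicate noise` (one noise draw per bin per sample, SD
#' `replicate_noise_sd` on the log scale, mean 1); the position within the
#' bin is uniform and the strand random. Reads are emitted as BED6 records
#' whose strand-aware 5' end falls in the sampled bin.
#'
#' @param config A `sim_config`.
#' @param truth A `sim_truth` from [simulate_truth()].
#' @return A list with `reads` (named list of BED6 data.frames, one per
#'   sample), `samples` (data.frame `sample, breed, replicate`) and
#'   `total_mapped`.
#' @export
simulate_reads <- function(config, truth) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  bins <- truth$bins
  n <- nrow(bins)
  chrom_lengths <- config$chrom_lengths
  read_len <- 50L
  samples <- expand.grid(replicate = seq_len(config$replicates_per_breed),
                         breed = config$breeds, stringsAsFactors = FALSE)
  samples <- samples[, c("breed", "replicate")]
  samples$sample <- paste0(samples$breed, "_R", samples$replicate)
  sd <- config$replicate_noise_sd
  reads <- vector("list", nrow(samples))
  names(reads) <- samples$sample
  for (i in seq_len(nrow(samples))) {
    w <- truth$propensity[, samples$breed[i]]
    if (all(w == 0)) stop("all-zero read propensity for breed ",
                          samples$breed[i])
    if (sd > 0) w <- w * stats::rlnorm(n, -sd^2 / 2, sd)
    cnt <- as.vector(stats::rmultinom(1L, config$reads_per_sample, w / sum(w)))
    idx <- rep.int(seq_len(n), cnt)
    m <- length(idx)
    bw <- bins$end[idx] - bins$start[idx]
    pos5 <- bins$start[idx] + as.integer(floor(stats::runif(m) * bw))
    neg <- stats::runif(m) < 0.5
    chrom <- bins$chrom[idx]
    chlen <- unname(chrom_lengths[chrom])
    start <- pos5
    end <- pmin(pos5 + read_len, chlen)
    start[neg] <- pmax(pos5[neg] + 1L - read_len, 0L)
    end[neg] <- pos5[neg] + 1L
    reads[[i]] <- data.frame(chrom = chrom, start = as.integer(start),
                             end = as.integer(end),
                             name = paste0(samples$sample[i], "_read_",
                                           seq_len(m)),
                             score = 0,
                             strand = c("+", "-")[neg + 1L],
                             stringsAsFactors = FALSE)
  }
  list(reads = reads, samples = samples,
       total_mapped = stats::setNames(rep(config$reads_per_sample,
                                          nrow(samples)), samples$sample))
}

# ---- haplotypes ------------------------------------------------------------

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha  # numeric underflow guard at tiny alpha
  g / sum(g)
}

#' Simulate a multi-population haplotype panel
#'
#' K root haplotypes are mutated from one random ancestor (each root carries
#' a private diagnostic site, so all K are distinct). A base haplotype
#' frequency vector is drawn once; each population then draws its own
#' frequencies from a Dirichlet centred on it with concentration
#' `(1/divergence - 1) * K` (`divergence = 0` means every population uses
#' the base vector exactly). Individuals are sampled i.i.d. within
#' population.
#'
#' @param config A `sim_config`.
#' @return A list with `sequences` ([Biostrings::DNAStringSet], one per
#'   individual), `populations` (data.frame `individual, population`),
#'   `frequencies` (K x populations matrix) and `haplotype` (true id per
#'   individual).
#' @export
simulate_haplotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  K <- config$n_root_haplotypes
  if (K < 1L) stop("n_root_haplotypes must be >= 1")
  if (config$n_populations < 2L) stop("need at least 2 populations")
  if (config$pop_size < 2L) stop("need at least 2 individuals per population")
  L <- config$hap_length
  if (L < K + 1L) stop("hap_length too short for K distinct haplotypes")
  bases <- c("A", "C", "G", "T")
  ancestor <- sample(bases, L, replace = TRUE)
  roots <- matrix(rep(ancestor, K), nrow = K, byrow = TRUE)
  rotate <- function(b) bases[(match(b, bases)) %% 4L + 1L]
  for (k in seq_len(K)) {
    mut <- unique(c(k, sample(L, 8L)))   # position k is private to root k
    roots[k, mut] <- vapply(roots[k, mut], rotate, "")
  }
  root_seqs <- apply(roots, 1L, paste, collapse = "")

  f0 <- rdirichlet1(rep(2, K))
  pops <- paste0("pop", seq_len(config$n_populations))
  freqs <- matrix(0, nrow = K, ncol = length(pops),
                  dimnames = list(NULL, pops))
  for (p in pops) {
    freqs[, p] <- if (config$divergence <= 0) f0 else
      rdirichlet1(f0 * (1 / config$divergence - 1) * K)
  }
  ind <- character(0); pop <- character(0); hap <- integer(0)
  for (p in pops) {
    h <- sample.int(K, config$pop_size, replace = TRUE, prob = freqs[, p])
    ind <- c(ind, sprintf("%s_ind%02d", p, seq_len(config$pop_size)))
    pop <- c(pop, rep(p, config$pop_size))
    hap <- c(hap, h)
  }
  seqs <- Biostrings::DNAStringSet(root_seqs[hap])
  names(seqs) <- ind
  list(sequences = seqs,
       populations = data.frame(individual = ind, population = pop,
                                stringsAsFactors = FALSE),
       frequencies = freqs, haplotype = hap)
}

# ---- expression ------------------------------------------------------------

#' Simulate qPCR Ct tables and protein levels coupled to methylation
#'
#' For each coupled (gene, CpG site) pair, per-sample methylation fractions
#' are drawn uniformly on \[0.2, 0.8\] and the target-gene Ct is
#' `baseline - slope x methylation + Normal(0, noise_sd)`; a positive slope
#' therefore couples methylation positively to `E^-ddCt` expression.
#' Reference-gene Cts are stable across samples (SD `ref_noise_sd`), and all
#' genes are measured in triplicate wells (SD `well_noise_sd`). Protein
#' levels are linear in methylation with slope `protein_slope` (0 =
#' uncoupled).
#'
#' @param config A `sim_config`.
#' @param baseline_ct Target-gene baseline Ct (cycles).
#' @return A list with `ct` (data.frame `sample, gene, role, well, ct`),
#'   `methylation` (data.frame `region, site, sample, breed, fraction`) and
#'   `protein` (data.frame `sample, gene, level`).
#' @export
simulate_expression <- function(config, baseline_ct = 26) {
  validate_sim_config(config)
  set.seed(config$seed + 4L)
  cp <- config$expression_coupling
  if (nrow(cp) == 0L) stop("expression_coupling must designate >= 1 CpG site")
  samples <- as.vector(t(outer(config$expr_breeds,
                               seq_len(config$expr_replicates),
                               function(b, r) paste0(b, "_M", r))))
  breed_of <- rep(config$expr_breeds, each = config$expr_replicates)
  n <- length(samples)

  meth_rows <- list(); ct_rows <- list(); prot_rows <- list()
  for (j in seq_len(nrow(cp))) {
    meth <- stats::runif(n, 0.2, 0.8)
    meth_rows[[j]] <- data.frame(region = paste0("region_", cp$gene[j]),
                                 site = cp$site[j], sample = samples,
                                 breed = breed_of, fraction = meth,
                                 stringsAsFactors = FALSE)
    ct_true <- baseline_ct - cp$slope[j] * meth +
      stats::rnorm(n, 0, cp$noise_sd[j])
    for (w in 1:3) {
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        sample = samples, gene = cp$gene[j], role = "target", well = w,
        ct = ct_true + stats::rnorm(n, 0, config$well_noise_sd),
        stringsAsFactors = FALSE)
    }
    p_slope <- if ("protein_slope" %in% names(cp)) cp$protein_slope[j] else 0
    prot_rows[[j]] <- data.frame(
      sample = samples, gene = cp$gene[j],
      level = 1 + p_slope * meth + stats::rnorm(n, 0, cp$noise_sd[j] / 2),
      stringsAsFactors = FALSE)
  }
  for (g in names(config$reference_genes)) {
    ct_true <- config$reference_genes[[g]] +
      stats::rnorm(n, 0, config$ref_noise_sd)
    for (w in 1:3) {
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        sample = samples, gene = g, role = "reference", well = w,
        ct = ct_true + stats::rnorm(n, 0, config$well_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  list(ct = do.call(rbind, ct_rows),
       methylation = do.call(rbind, meth_rows),
       protein = do.call(rbind, prot_rows))
}

# ---- orchestration ---------------------------------------------------------

#' Run the whole synthetic study generator
#'
#' @param config A `sim_config`.
#' @return A `sim_study` list: `config`, `genome`, `genes`, `cgi_tracts`,
#'   `truth`, `reads` arm, `haplotypes` arm, `expression` arm.
#' @export
simulate_study <- function(config = sim_config()) {
  gen <- simulate_genome(config)
  truth <- simulate_truth(config, gen)
  reads <- simulate_reads(config, truth)
  haps <- simulate_haplotypes(config)
  expr <- simulate_expression(config)
  structure(list(config = config, genome = gen$genome, genes = gen$genes,
                 cgi_tracts = gen$cgi_tracts, truth = truth, reads = reads,
                 haplotypes = haps, expression = expr),
            class = "sim_study")
}

#' Write every generated input of a synthetic study to disk
#'
#' Emits the file set the pipeline consumes: genome FASTA, gene models
#' BED12, per-sample read BED6, sample sheet TSV, haplotype FASTA +
#' population map TSV, Ct/methylation/protein TSVs, and the planted-truth
#' table.
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_fasta(study$genome, p("genome.fa"))
  write_bed12(study$genes, p("genes.bed12"))
  dir.create(p("reads"), showWarnings = FALSE)
  for (s in names(study$reads$reads)) {
    write_bed6(study$reads$reads[[s]], p("reads", paste0(s, ".bed")))
  }
  write_tsv(study$reads$samples, p("samples.tsv"))
  write_fasta(study$haplotypes$sequences, p("haplotypes.fa"))
  write_tsv(study$haplotypes$populations, p("populations.tsv"))
  write_tsv(study$expression$ct, p("qpcr_ct.tsv"))
  write_tsv(study$expression$methylation, p("cpg_methylation.tsv"))
  write_tsv(study$expression$protein, p("protein_levels.tsv"))
  write_tsv(study$truth$planted, p("planted_truth.tsv"))
  invisible(dir)
}
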