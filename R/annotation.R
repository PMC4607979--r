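ELEMENT_CLASSES <- c("proximal_promoter", "intermediate_promoter",
                     "distal_promoter", "exon", "intron", "intergenic")
CGI_CLASSES <- c("promoter_cgi", "intragenic_cgi", "three_prime_cgi",
                 "intergenic_cgi")

# GRanges view of 0-based half-open intervals (clamped at the chromosome start)
.granges0 <- function(chrom, start, end) {
  start <- pmax(start, 0L)
  keep <- end > start
  GenomicRanges::GRanges(chrom[keep],
                         IRanges::IRanges(start = start[keep] + 1L, end = end[keep]))
}

# Promoter zones around the TSS, strand-aware; bounds in bp relative to TSS
# with negative = upstream. Printed closed bounds are used as half-open
# [TSS+lo, TSS+hi) on the + strand and mirrored on the - strand.
.tss_zone <- function(genes, lo, hi) {
  plus <- genes$strand == "+"
  t <- ifelse(plus, genes$start, genes$end)
  zs <- ifelse(plus, t + lo, t - hi)
  ze <- ifelse(plus, t + hi, t - lo)
  .granges0(genes$chrom, zs, ze)
}

# Same, anchored at the transcription end site (TES).
.tes_zone <- function(genes, lo, hi) {
  plus <- genes$strand == "+"
  t <- ifelse(plus, genes$end, genes$start)
  zs <- ifelse(plus, t + lo, t - hi)
  ze <- ifelse(plus, t + hi, t - lo)
  .granges0(genes$chrom, zs, ze)
}

#' Assign each bin to a genomic-element class
#'
#' Classifies bins into `proximal_promoter`, `intermediate_promoter`,
#' `distal_promoter`, `exon`, `intron` or `intergenic`. Promoter zones are
#' strand-aware around the TSS: distal -2200..-1000, intermediate
#' -1000..-200, proximal -200..+500 (negative = upstream). A bin overlapping
#' several features takes the highest-precedence class
#' (proximal > intermediate > distal promoter > exon > intron > intergenic);
#' any shared bp counts as overlap.
#'
#' @param bins A `genome_bins` data.frame.
#' @param genes A `gene_models` data.frame (see [read_bed12()]).
#' @param promoter_zones Named list of `c(lo, hi)` bp offsets relative to the
#'   TSS for the three promoter classes.
#' @return The bins data.frame with an added factor column `element`.
#' @export
classify_bins <- function(bins, genes,
                          promoter_zones = list(
                            proximal_promoter = c(-200L, 500L),
                            intermediate_promoter = c(-1000L, -200L),
                            distal_promoter = c(-2200L, -1000L))) {
  stopifnot(is.data.frame(bins))
  if (nrow(genes) > 0 && !all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  gbins <- .granges0(bins$chrom, bins$start, bins$end)
  element <- rep("intergenic", nrow(bins))
  if (nrow(genes) > 0L) {
    exons <- do.call(rbind, genes$exons)
    exon_chrom <- rep(genes$chrom, vapply(genes$exons, nrow, 0L))
    zones <- list(
      proximal_promoter = .tss_zone(genes, promoter_zones$proximal_promoter[1L],
                                    promoter_zones$proximal_promoter[2L]),
      intermediate_promoter = .tss_zone(genes,
                                        promoter_zones$intermediate_promoter[1L],
                                        promoter_zones$intermediate_promoter[2L]),
      distal_promoter = .tss_zone(genes, promoter_zones$distal_promoter[1L],
                                  promoter_zones$distal_promoter[2L]),
      exon = .granges0(exon_chrom, exons[, 1L], exons[, 2L]),
      intron = .granges0(genes$chrom, genes$start, genes$end))
    # precedence: first class claiming a bin wins
    for (cls in names(zones)) {
      hit <- IRanges::overlapsAny(gbins, zones[[cls]])
      claim <- hit & element == "intergenic"
      element[claim] <- cls
    }
  }
  out <- as.data.frame(bins)
  out$element <- factor(element, levels = ELEMENT_CLASSES)
  attr(out, "width") <- attr(bins, "width")
  attr(out, "chrom_lengths") <- attr(bins, "chrom_lengths")
  out
}

#' Detect CpG islands by the observed/expected CpG ratio
#'
#' Slides a `min_len`-bp window (step 1 bp) over each sequence and scores
#' CpG O/E = (#CpG x L) / (#C x #G) (Gardiner-Garden convention). Windows
#' with O/E above `oe_threshold` are merged when they overlap; each merged
#' island's O/E and GC fraction are recomputed on its full span. Windows
#' containing N are skipped.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @param min_len Window length in bp (default 200; also the minimum island
#'   length).
#' @param oe_threshold Qualification threshold on CpG O/E (default 0.6,
#'   strict inequality).
#' @return A data.frame `chrom, start, end, cpg_oe, gc_frac` (0-based,
#'   half-open coordinates).
#' @export
detect_cgi <- function(genome, min_len = 200L, oe_threshold = 0.6) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(toupper(unlist(genome)))
  }
  out <- list()
  for (ch in names(genome)) {
    s <- toupper(as.character(genome[[ch]]))
    len <- nchar(s)
    if (len < min_len) next
    r <- charToRaw(s)
    isC <- r == as.raw(67L)   # C
    isG <- r == as.raw(71L)   # G
    isN <- !(isC | isG | r == as.raw(65L) | r == as.raw(84L))  # not ACGT
    isCG <- isC[-len] & isG[-1L]
    csC <- c(0L, cumsum(isC)); csG <- c(0L, cumsum(isG))
    csN <- c(0L, cumsum(isN)); csCG <- c(0L, cumsum(isCG))
    i <- seq_len(len - min_len + 1L)          # 1-based window starts
    nC <- csC[i + min_len] - csC[i]
    nG <- csG[i + min_len] - csG[i]
    nN <- csN[i + min_len] - csN[i]
    nCG <- csCG[i + min_len - 1L] - csCG[i]
    oe <- ifelse(nCG == 0L, 0, nCG * min_len / (nC * nG))
    ok <- nN == 0L & oe > oe_threshold
    if (!any(ok)) next
    merged <- IRanges::reduce(IRanges::IRanges(start = which(ok), width = min_len))
    ms <- IRanges::start(merged); me <- IRanges::end(merged)
    L <- me - ms + 1L
    nC <- csC[me + 1L] - csC[ms]
    nG <- csG[me + 1L] - csG[ms]
    nCG <- csCG[me] - csCG[ms]   # CpG starts strictly inside the span
    oe <- ifelse(nCG == 0L, 0, nCG * L / (nC * nG))
    keep <- oe > oe_threshold
    if (!any(keep)) next
    out[[ch]] <- data.frame(chrom = ch, start = ms[keep] - 1L, end = me[keep],
                            cpg_oe = oe[keep],
                            gc_frac = ((nC + nG) / L)[keep],
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      cpg_oe = numeric(), gc_frac = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify CpG islands into gene-relative region classes
#'
#' Strand-aware zones: promoter CGI -1000..+300 around the TSS; intragenic
#' CGI from 300 bp downstream of the TSS to 300 bp upstream of the TES;
#' 3'-transcript CGI from 300 bp upstream to 1000 bp downstream of the TES;
#' everything else intergenic. Islands spanning boundaries take the
#' highest-precedence class (promoter > intragenic > 3'-transcript >
#' intergenic).
#'
#' @param cgis CGI data.frame from [detect_cgi()].
#' @param genes A `gene_models` data.frame.
#' @return `cgis` with an added factor column `region_class`.
#' @export
classify_cgi_regions <- function(cgis, genes) {
  region <- rep("intergenic_cgi", nrow(cgis))
  if (nrow(genes) > 0L && nrow(cgis) > 0L) {
    gcgi <- .granges0(cgis$chrom, cgis$start, cgis$end)
    # intragenic zone TSS+300 .. TES-300 is [start+300, end-300) on both strands
    zones <- list(
      promoter_cgi = .tss_zone(genes, -1000L, 300L),
      intragenic_cgi = .granges0(genes$chrom, genes$start + 300L,
                                 genes$end - 300L),
      three_prime_cgi = .tes_zone(genes, -300L, 1000L))
    for (cls in names(zones)) {
      hit <- IRanges::overlapsAny(gcgi, zones[[cls]])
      claim <- hit & region == "intergenic_cgi"
      region[claim] <- cls
    }
  }
  cgis$region_class <- factor(region, levels = CGI_CLASSES)
  cgis
}

#' Mean enrichment per element class (and CGI class) per breed
#'
#' Summarizes a per-breed enrichment matrix over the element annotation:
#' arithmetic mean score and bin count per (class x breed). When CGIs are
#' supplied, bins overlapping an island are additionally summarized by the
#' island's region class (overlaps resolved by the CGI class precedence).
#'
#' @param breed_scores Bins x breeds score matrix (e.g.
#'   `replicate_qc_and_average(...)$breed_scores`).
#' @param annotated Bins data.frame with `element` column, aligned row-wise
#'   with `breed_scores` ([classify_bins()] output subset to retained bins).
#' @param cgis Optional classified CGI data.frame ([classify_cgi_regions()]).
#' @return A tidy data.frame `scope, class, breed, n_bins, mean_score`;
#'   empty classes are reported with `n_bins = 0` and `mean_score = NA`.
#' @export
element_profiles <- function(breed_scores, annotated, cgis = NULL) {
  stopifnot(nrow(breed_scores) == nrow(annotated))
  summarize <- function(scope, cls_vec, levels) {
    rows <- list()
    for (cls in levels) {
      sel <- !is.na(cls_vec) & cls_vec == cls
      for (b in colnames(breed_scores)) {
        rows[[length(rows) + 1L]] <- data.frame(
          scope = scope, class = cls, breed = b, n_bins = sum(sel),
          mean_score = if (any(sel)) mean(breed_scores[sel, b]) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  out <- summarize("element", as.character(annotated$element), ELEMENT_CLASSES)
  if (!is.null(cgis) && nrow(cgis) > 0L) {
    gbins <- .granges0(annotated$chrom, annotated$start, annotated$end)
    cgi_cls <- rep(NA_character_, nrow(annotated))
    for (cls in rev(CGI_CLASSES)) {     # assign low precedence first, overwrite
      sel <- cgis$region_class == cls
      if (!any(sel)) next
      hit <- IRanges::overlapsAny(gbins, .granges0(cgis$chrom[sel],
                                                   cgis$start[sel],
                                                   cgis$end[sel]))
      cgi_cls[hit] <- cls
    }
    out <- rbind(out, summarize("cgi", cgi_cls, CGI_CLASSES))
  }
  out
}
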