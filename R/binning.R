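#' Tile a genome into fixed-width bins
#'
#' Partitions each chromosome into consecutive `width`-bp bins (0-based,
#' half-open). The final bin on each chromosome is truncated at the
#' chromosome end, so bins tile every chromosome exactly with no gaps or
#' overlaps.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param width Bin width in bp (default 300, the resolution at which MeDIP
#'   enrichment is scored).
#' @return A `genome_bins` data.frame with columns `chrom`, `start`, `end`,
#'   `index` and attributes `width` and `chrom_lengths`.
#' @export
make_bins <- function(chrom_lengths, width = 300L) {
  if (length(chrom_lengths) == 0L) stop("chrom_lengths must be nonempty")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be named by chromosome")
  }
  width <- as.integer(width)
  if (is.na(width) || width <= 0L) stop("bin width must be a positive integer")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  per_chrom <- lapply(names(chrom_lengths), function(ch) {
    L <- as.integer(chrom_lengths[[ch]])
    n <- (L + width - 1L) %/% width      # ceiling(L / width)
    start <- (seq_len(n) - 1L) * width
    data.frame(chrom = ch, start = start, end = pmin(start + width, L),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, per_chrom)
  bins$index <- seq_len(nrow(bins))
  attr(bins, "width") <- width
  attr(bins, "chrom_lengths") <- chrom_lengths
  class(bins) <- c("genome_bins", "data.frame")
  bins
}

#' Count reads per bin from mapped read positions
#'
#' Attributes each read to the single bin containing its 5' start
#' (strand-aware: `start` for `+`/`.` reads, `end - 1` for `-` reads), so no
#' read is ever double counted at bin boundaries. Reads on chromosomes absent
#' from the binning are tallied as unbinned and reported via a message, not
#' silently dropped.
#'
#' @param bins A `genome_bins` object from [make_bins()].
#' @param reads A named list of per-sample read data.frames (BED6 columns, as
#'   returned by [read_bed6()]), or a named character vector of BED6 paths.
#' @return A `bin_counts` list with elements `bins`, `counts` (bins x samples
#'   integer matrix), `total_mapped` (per-sample read totals, the
#'   "total unique mapped reads" of the enrichment formula) and `unbinned`.
#' @export
count_reads <- function(bins, reads) {
  stopifnot(inherits(bins, "genome_bins"))
  if (is.character(reads)) {
    paths <- reads
    reads <- lapply(paths, read_bed6)
    names(reads) <- if (is.null(names(paths))) basename(paths) else names(paths)
  }
  if (is.null(names(reads)) || any(!nzchar(names(reads)))) {
    stop("reads must be a named list (one element per sample)")
  }
  width <- attr(bins, "width")
  chrom_lengths <- attr(bins, "chrom_lengths")
  # first bin index of each chromosome, for O(1) position -> bin lookup
  chrom_offset <- c(0L, cumsum(vapply(chrom_lengths,
    function(L) as.integer((L + width - 1L) %/% width), 0L)))[seq_along(chrom_lengths)]
  names(chrom_offset) <- names(chrom_lengths)

  n_bins <- nrow(bins)
  counts <- matrix(0L, nrow = n_bins, ncol = length(reads),
                   dimnames = list(NULL, names(reads)))
  total <- integer(length(reads)); names(total) <- names(reads)
  unbinned <- integer(length(reads)); names(unbinned) <- names(reads)
  for (s in seq_along(reads)) {
    rd <- reads[[s]]
    total[s] <- nrow(rd)
    if (nrow(rd) == 0L) next
    pos5 <- ifelse(rd$strand == "-", rd$end - 1L, rd$start)
    known <- rd$chrom %in% names(chrom_lengths)
    inside <- known
    inside[known] <- pos5[known] < chrom_lengths[rd$chrom[known]] & pos5[known] >= 0L
    unbinned[s] <- sum(!inside)
    if (any(!known)) {
      message(sprintf("%s: %d read(s) on chromosomes absent from the binning",
                      names(reads)[s], sum(!known)))
    }
    idx <- chrom_offset[rd$chrom[inside]] + pos5[inside] %/% width + 1L
    tab <- tabulate(idx, nbins = n_bins)
    counts[, s] <- counts[, s] + as.integer(tab)
  }
  structure(list(bins = bins, counts = counts, total_mapped = total,
                 unbinned = unbinned),
            class = "bin_counts")
}

#' Filter bins by minimum total read support
#'
#' Removes low-coverage bins before enrichment scoring. The default rule
#' drops bins with fewer than `min_total` reads summed over all samples
#' ("across all individuals"); set `per_sample = TRUE` for the stricter
#' variant that requires every sample individually to reach `min_total`.
#'
#' @param x A `bin_counts` object.
#' @param min_total Minimum read count (default 10).
#' @param per_sample Apply the threshold per sample instead of to the sum.
#' @return A filtered `bin_counts` object; bin order is preserved.
#' @export
filter_bins <- function(x, min_total = 10L, per_sample = FALSE) {
  stopifnot(inherits(x, "bin_counts"))
  if (nrow(x$counts) == 0L) stop("empty bin count matrix")
  keep <- if (per_sample) {
    apply(x$counts, 1L, function(v) all(v >= min_total))
  } else {
    rowSums(x$counts) >= min_total
  }
  x$bins <- x$bins[keep, , drop = FALSE]
  x$counts <- x$counts[keep, , drop = FALSE]
  x
}

#' Depth- and length-normalized methylation enrichment score
#'
#' The per-bin MeDIP statistic: `count * 1e9 / (width * total_unique_mapped)`,
#' an RPKM-style read density that makes bins comparable across samples with
#' different sequencing depths.
#'
#' @param count Read count(s) in the bin.
#' @param total_unique_mapped Total uniquely mapped reads for the sample.
#' @param width Bin width in bp (default 300).
#' @return Numeric score(s); 0 exactly when `count` is 0.
#' @export
enrichment_score <- function(count, total_unique_mapped, width = 300) {
  if (any(total_unique_mapped <= 0)) {
    stop("total_unique_mapped must be positive")
  }
  if (any(count < 0)) stop("counts must be nonnegative")
  count * 1e9 / (width * total_unique_mapped)
}

#' Enrichment score matrix from binned counts
#'
#' @param x A (typically filtered) `bin_counts` object.
#' @param breeds Optional named character vector mapping sample name to
#'   breed/group label; stored for downstream tests and averaging.
#' @return An `enrichment` list with `bins`, `scores` (bins x samples),
#'   `total_mapped` and `breeds`.
#' @export
enrichment_matrix <- function(x, breeds = NULL) {
  stopifnot(inherits(x, "bin_counts"))
  width <- attr(x$bins, "width")
  scores <- sweep(x$counts, 2L, x$total_mapped,
                  function(cnt, tot) enrichment_score(cnt, tot, width))
  if (!is.null(breeds)) {
    missing <- setdiff(colnames(scores), names(breeds))
    if (length(missing)) stop("no breed label for sample(s): ",
                              paste(missing, collapse = ", "))
    breeds <- breeds[colnames(scores)]
  }
  structure(list(bins = x$bins, scores = scores,
                 total_mapped = x$total_mapped, breeds = breeds),
            class = "enrichment")
}

#' Large-window RPKM track for genome-wide landscape plots
#'
#' Computes the same normalized read density as [enrichment_score()] over
#' large windows (default 100 kb), one track per sample, e.g. to draw a
#' whole-genome methylation landscape.
#'
#' @param reads As in [count_reads()].
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param window Window width in bp (default 1e5).
#' @return A data.frame `chrom, start, end, index, <one score column per sample>`.
#' @export
windowed_rpkm <- function(reads, chrom_lengths, window = 100000L) {
  bins <- make_bins(chrom_lengths, width = window)
  bc <- count_reads(bins, reads)
  enr <- enrichment_matrix(bc)
  cbind(as.data.frame(bins)[, c("chrom", "start", "end", "index")],
        as.data.frame(enr$scores))
}

#' Replicate QC and per-breed averaging of enrichment scores
#'
#' Computes the Pearson correlation between every within-breed replicate pair
#' over retained bins (the replicate QC of a multi-replicate MeDIP design),
#' then collapses replicates to one profile per breed by the arithmetic mean
#' of their per-bin scores.
#'
#' @param enr An `enrichment` object whose `breeds` mapping is set
#'   (see [enrichment_matrix()]).
#' @return A list with `breed_scores` (bins x breeds matrix), `replicate_r`
#'   (data.frame breed, sample_a, sample_b, r) and the input `bins`.
#' @export
replicate_qc_and_average <- function(enr) {
  stopifnot(inherits(enr, "enrichment"))
  if (is.null(enr$breeds)) stop("enrichment object has no sample->breed mapping")
  breeds <- enr$breeds
  levels <- unique(breeds)
  qc <- list()
  breed_scores <- matrix(0, nrow = nrow(enr$scores), ncol = length(levels),
                         dimnames = list(NULL, levels))
  for (b in levels) {
    cols <- names(breeds)[breeds == b]
    if (length(cols) < 2L) {
      warning("breed '", b, "' has a single replicate; QC skipped")
    } else {
      pairs <- utils::combn(cols, 2L)
      for (k in seq_len(ncol(pairs))) {
        qc[[length(qc) + 1L]] <- data.frame(
          breed = b, sample_a = pairs[1L, k], sample_b = pairs[2L, k],
          r = stats::cor(enr$scores[, pairs[1L, k]], enr$scores[, pairs[2L, k]]),
          stringsAsFactors = FALSE)
      }
    }
    breed_scores[, b] <- rowMeans(enr$scores[, cols, drop = FALSE])
  }
  list(bins = enr$bins, breed_scores = breed_scores,
       replicate_r = if (length(qc)) do.call(rbind, qc) else
         data.frame(breed = character(), sample_a = character(),
                    sample_b = character(), r = numeric()))
}
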