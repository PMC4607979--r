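#' Pairwise per-bin t-tests between all breed pairs
#'
#' For every retained bin and every unordered pair of breeds, computes a
#' two-sample Student's t-test on per-sample enrichment scores
#' (pooled-variance by default: with two replicates per breed the Welch
#' degrees of freedom degenerate) and the fold change of breed means. Bins
#' where both groups have zero variance are assigned p = 1. A pseudo-score
#' of `eps` is added to zero means so fold changes stay finite.
#'
#' @param enr An `enrichment` object with its `breeds` mapping set.
#' @param var_equal Use the pooled-variance t-test (default `TRUE`).
#' @param eps Pseudo-score added to zero means in fold changes.
#' @return A `dmr_tests` list: `bins`, `pairs` (data.frame `a, b, label`),
#'   matrices `t`, `p`, `fold_change` (bins x pairs), and `breed_means`.
#' @export
pairwise_tests <- function(enr, var_equal = TRUE, eps = 0.01) {
  stopifnot(inherits(enr, "enrichment"))
  if (is.null(enr$breeds)) stop("enrichment object has no sample->breed mapping")
  breeds <- unique(enr$breeds)
  for (b in breeds) {
    if (sum(enr$breeds == b) < 2L) {
      stop("breed '", b, "' has fewer than 2 samples; t-tests need replicates")
    }
  }
  scores <- enr$scores
  nb <- nrow(scores)
  stat <- lapply(breeds, function(b) {
    x <- scores[, names(enr$breeds)[enr$breeds == b], drop = FALSE]
    m <- rowMeans(x)
    list(n = ncol(x), mean = m, var = rowSums((x - m)^2) / (ncol(x) - 1L))
  })
  names(stat) <- breeds
  pairs <- t(utils::combn(breeds, 2L))
  labels <- paste(pairs[, 1L], pairs[, 2L], sep = "_vs_")
  tmat <- pmat <- fmat <- matrix(NA_real_, nrow = nb, ncol = nrow(pairs),
                                 dimnames = list(NULL, labels))
  for (k in seq_len(nrow(pairs))) {
    sa <- stat[[pairs[k, 1L]]]; sb <- stat[[pairs[k, 2L]]]
    diff <- sa$mean - sb$mean
    if (var_equal) {
      df <- sa$n + sb$n - 2L
      sp2 <- ((sa$n - 1L) * sa$var + (sb$n - 1L) * sb$var) / df
      se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    } else {
      se2a <- sa$var / sa$n; se2b <- sb$var / sb$n
      se <- sqrt(se2a + se2b)
      df <- (se2a + se2b)^2 /
        (se2a^2 / (sa$n - 1L) + se2b^2 / (sb$n - 1L))
    }
    t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
    p <- ifelse(se > 0, 2 * stats::pt(-abs(t), df), 1)
    ma <- ifelse(sa$mean == 0, eps, sa$mean)
    mb <- ifelse(sb$mean == 0, eps, sb$mean)
    tmat[, k] <- t; pmat[, k] <- p; fmat[, k] <- ma / mb
  }
  structure(list(bins = enr$bins,
                 pairs = data.frame(a = pairs[, 1L], b = pairs[, 2L],
                                    label = labels, stringsAsFactors = FALSE),
                 t = tmat, p = pmat, fold_change = fmat,
                 breed_means = vapply(stat, `[[`, numeric(nb), "mean")),
            class = "dmr_tests")
}

#' Call differentially methylated regions (DMRs)
#'
#' A bin is a DMR when at least one pairwise comparison is significant at
#' `alpha`. P-values are used raw by default; per-pair multiple-testing
#' correction across bins is available via `adjust`.
#'
#' @param tests A `dmr_tests` object.
#' @param alpha Significance level (default 0.05).
#' @param adjust A [stats::p.adjust()] method applied across bins within
#'   each pair ("none" by default).
#' @return A `dmr_calls` data.frame of DMR bins with `index, chrom, start,
#'   end, n_sig, sig_pairs, min_p, min_fc, max_fc`.
#' @export
call_dmrs <- function(tests, alpha = 0.05, adjust = "none") {
  stopifnot(inherits(tests, "dmr_tests"))
  p <- tests$p
  if (adjust != "none") p <- apply(p, 2L, stats::p.adjust, method = adjust)
  sig <- p < alpha
  is_dmr <- rowSums(sig) >= 1L
  idx <- which(is_dmr)
  out <- data.frame(
    index = tests$bins$index[idx], chrom = tests$bins$chrom[idx],
    start = tests$bins$start[idx], end = tests$bins$end[idx],
    n_sig = rowSums(sig)[idx],
    sig_pairs = vapply(idx, function(i)
      paste(colnames(p)[sig[i, ]], collapse = ","), ""),
    min_p = apply(p[idx, , drop = FALSE], 1L, min),
    min_fc = apply(tests$fold_change[idx, , drop = FALSE], 1L, min),
    max_fc = apply(tests$fold_change[idx, , drop = FALSE], 1L, max),
    stringsAsFactors = FALSE)
  class(out) <- c("dmr_calls", "data.frame")
  out
}

#' Filter DMRs by fold change
#'
#' Keeps DMRs whose fold change exceeds `high` or falls below `low` in at
#' least one comparison (strict inequalities: a fold change of exactly 2 is
#' removed).
#'
#' @param dmrs A `dmr_calls` data.frame.
#' @param low,high Fold-change bounds (default 0.5 and 2).
#' @return The filtered `dmr_calls`.
#' @export
fold_change_filter <- function(dmrs, low = 0.5, high = 2) {
  keep <- dmrs$max_fc > high | dmrs$min_fc < low
  dmrs[keep, , drop = FALSE]
}

#' Breed-specific DMR sets
#'
#' Under the default (strictest) rule a bin is specific to breed B when all
#' comparisons involving B are significant at `alpha` with a consistent
#' direction (B above or below all other breeds) and no comparison between
#' the other breeds is significant. Set `others_null = FALSE` to drop the
#' last condition.
#'
#' @param tests A `dmr_tests` object.
#' @param alpha Significance level (default 0.05).
#' @param others_null Require non-B pairs to be non-significant.
#' @return A data.frame of breed-specific bins: `index, chrom, start, end,
#'   specific_to, direction`.
#' @export
breed_specific_dmrs <- function(tests, alpha = 0.05, others_null = TRUE) {
  stopifnot(inherits(tests, "dmr_tests"))
  breeds <- colnames(tests$breed_means)
  sig <- tests$p < alpha
  rows <- list()
  for (b in breeds) {
    inv <- tests$pairs$a == b | tests$pairs$b == b
    # orient each involving pair so positive t means B above the other breed
    or_sign <- ifelse(tests$pairs$a[inv] == b, 1, -1)
    tb <- sweep(tests$t[, inv, drop = FALSE], 2L, or_sign, `*`)
    all_sig <- rowSums(sig[, inv, drop = FALSE]) == sum(inv)
    consistent <- rowSums(tb > 0) == sum(inv) | rowSums(tb < 0) == sum(inv)
    ok <- all_sig & consistent
    if (others_null && any(!inv)) {
      ok <- ok & rowSums(sig[, !inv, drop = FALSE]) == 0L
    }
    if (any(ok)) {
      idx <- which(ok)
      rows[[b]] <- data.frame(
        index = tests$bins$index[idx], chrom = tests$bins$chrom[idx],
        start = tests$bins$start[idx], end = tests$bins$end[idx],
        specific_to = b,
        direction = ifelse(rowSums(tb[idx, , drop = FALSE] > 0) == sum(inv),
                           "up", "down"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(index = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      specific_to = character(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map DMRs to overlapping genes
#'
#' A DMR is assigned to every gene whose promoter-or-body territory it
#' overlaps (gene body extended `upstream` bp past the TSS, strand-aware).
#' The deduplicated gene list per DMR set is the differentially methylated
#' gene (DMG) list.
#'
#' @param dmrs A data.frame of bins (needs `chrom, start, end`), e.g.
#'   `dmr_calls` or breed-specific sets.
#' @param genes A `gene_models` data.frame.
#' @param upstream Promoter extension upstream of the TSS in bp (default
#'   2200, the distal promoter bound).
#' @return `dmrs` with a list-column `gene_ids`; the DMG list is
#'   `sort(unique(unlist(out$gene_ids)))`.
#' @export
map_dmrs_to_genes <- function(dmrs, genes, upstream = 2200L) {
  gene_ids <- rep(list(character(0)), nrow(dmrs))
  if (nrow(genes) > 0L && nrow(dmrs) > 0L) {
    plus <- genes$strand == "+"
    terr_s <- ifelse(plus, genes$start - upstream, genes$start)
    terr_e <- ifelse(plus, genes$end, genes$end + upstream)
    terr <- .granges0(genes$chrom, terr_s, terr_e)
    gdmr <- .granges0(dmrs$chrom, dmrs$start, dmrs$end)
    hits <- GenomicRanges::findOverlaps(gdmr, terr)
    if (length(hits)) {
      by_dmr <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                      S4Vectors::queryHits(hits))
      for (q in names(by_dmr)) {
        gene_ids[[as.integer(q)]] <- sort(unique(by_dmr[[q]]))
      }
    }
  }
  dmrs$gene_ids <- gene_ids
  dmrs
}

#' Hypergeometric gene-set enrichment with Benjamini-Hochberg adjustment
#'
#' Tests each named gene set for over-representation in a differentially
#' methylated gene list against a background universe (upper-tail
#' hypergeometric, i.e. one-sided Fisher), then adjusts across sets by
#' Benjamini-Hochberg.
#'
#' @param dmg Character vector of differentially methylated genes (must be a
#'   subset of `background`).
#' @param background Character vector: the gene universe.
#' @param sets Named list of character vectors (gene sets); genes outside the
#'   background are ignored.
#' @return A data.frame `set, set_size, overlap, p, p_adj`, ordered by p.
#' @export
gene_set_enrichment <- function(dmg, background, sets) {
  dmg <- unique(dmg); background <- unique(background)
  stray <- setdiff(dmg, background)
  if (length(stray)) {
    stop("dmg genes missing from background: ", paste(stray, collapse = ", "))
  }
  if (!length(sets)) stop("no gene sets supplied")
  N <- length(background); n <- length(dmg)
  res <- lapply(names(sets), function(s) {
    set <- intersect(unique(sets[[s]]), background)
    k <- length(intersect(set, dmg))
    data.frame(set = s, set_size = length(set), overlap = k,
               p = stats::phyper(k - 1L, length(set), N - length(set), n,
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Hierarchical clustering of methylation profiles
#'
#' Clusters samples or breeds on their per-bin enrichment vectors with
#' distance `1 - Pearson correlation` and average linkage. Columns are
#' sorted by label first so the leaf order is deterministic.
#'
#' @param scores Bins x units numeric matrix with column names (e.g.
#'   intergenic bins passing a coverage filter; see
#'   [intergenic_cluster_input()]).
#' @param method Linkage passed to [stats::hclust()] (default "average").
#' @return A list with `hclust`, `phylo` (ape), `newick` string and the
#'   `dist` matrix.
#' @export
cluster_breeds <- function(scores, method = "average") {
  if (is.null(colnames(scores)) || ncol(scores) < 3L) {
    stop("need >= 3 labelled units to cluster")
  }
  if (nrow(scores) < 2L) stop("need >= 2 usable bins to cluster")
  scores <- scores[, order(colnames(scores)), drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(scores))
  hc <- stats::hclust(d, method = method)
  phy <- ape::as.phylo(hc)
  list(hclust = hc, phylo = phy, newick = ape::write.tree(phy), dist = d)
}

#' Select intergenic bins with full coverage for clustering
#'
#' Restricts a count matrix to bins annotated as intergenic whose read count
#' exceeds `min_reads` in every unit, and returns the corresponding
#' enrichment scores.
#'
#' @param counts A `bin_counts` object (filtered or not).
#' @param annotated Bins data.frame with `element`, row-aligned with
#'   `counts$counts`.
#' @param min_reads Coverage threshold (strictly greater than; default 10).
#' @return Bins x samples score matrix over the selected bins.
#' @export
intergenic_cluster_input <- function(counts, annotated, min_reads = 10L) {
  stopifnot(inherits(counts, "bin_counts"),
            nrow(annotated) == nrow(counts$counts))
  keep <- annotated$element == "intergenic" &
    apply(counts$counts, 1L, function(v) all(v > min_reads))
  width <- attr(counts$bins, "width")
  scores <- sweep(counts$counts[keep, , drop = FALSE], 2L,
                  counts$total_mapped,
                  function(cnt, tot) enrichment_score(cnt, tot, width))
  scores
}

#' Identify the outgroup leaf of a dendrogram
#'
#' Returns the label of the unit that joins the rest of the tree at the
#' final (highest) merge, or `NA` when the root merge joins two
#' multi-member clusters.
#'
#' @param hc An [stats::hclust] object.
#' @return A single label or `NA_character_`.
#' @export
dendrogram_outgroup <- function(hc) {
  root <- hc$merge[nrow(hc$merge), ]
  single <- root < 0
  if (sum(single) == 1L) hc$labels[-root[single]] else NA_character_
}
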