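#' Collapse aligned sequences to haplotypes
#'
#' Uppercases the (equal-length, aligned) sequences, removes every alignment
#' column containing a gap, `N` or other ambiguity in any sequence
#' (complete deletion; the number of dropped sites is reported via a
#' message), then collapses exact-identical sequences to haplotype ids.
#'
#' @param sequences A [Biostrings::DNAStringSet] or named character vector,
#'   one sequence per individual.
#' @param populations data.frame with columns `individual`, `population`
#'   covering every sequence.
#' @return A `haplotype_data` list: `individual`, `population`,
#'   `haplotype` (integer id; identical sequences share an id),
#'   `n_haplotypes`, `n_sites_used`.
#' @export
collapse_haplotypes <- function(sequences, populations) {
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named by individual")
  seqs <- stats::setNames(toupper(as.character(sequences)), ids)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences must be aligned to equal length (got lengths ",
         paste(unique(lens), collapse = ", "), ")")
  }
  missing <- setdiff(names(seqs), populations$individual)
  if (length(missing)) {
    stop("no population label for: ", paste(missing, collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  keep <- apply(mat, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  if (any(!keep)) {
    message(sum(!keep), " site(s) with gaps/ambiguity removed before collapsing")
  }
  mat <- mat[, keep, drop = FALSE]
  key <- apply(mat, 1L, paste, collapse = "")
  hap <- as.integer(factor(key, levels = unique(key)))
  pop <- populations$population[match(names(seqs), populations$individual)]
  structure(list(individual = names(seqs), population = pop, haplotype = hap,
                 n_haplotypes = length(unique(hap)),
                 n_sites_used = sum(keep)),
            class = "haplotype_data")
}

# AMOVA Fst between two populations from haplotype count vectors, using
# identity (0/1) distances. With d(i,j) = 0/1 the sums of squared distances
# reduce to functions of the per-haplotype counts, so no distance matrix is
# ever formed.
.fst_from_counts <- function(c1, c2) {
  n1 <- sum(c1); n2 <- sum(c2); N <- n1 + n2
  ssd_w <- (n1^2 - sum(c1^2)) / (2 * n1) + (n2^2 - sum(c2^2)) / (2 * n2)
  ssd_t <- (N^2 - sum((c1 + c2)^2)) / (2 * N)
  ssd_a <- ssd_t - ssd_w
  ms_a <- ssd_a                      # df_among = 1 for a pair
  ms_w <- ssd_w / (N - 2)
  n_c <- (N - (n1^2 + n2^2) / N)     # / (P - 1) = 1
  sigma_a <- (ms_a - ms_w) / n_c
  denom <- sigma_a + ms_w
  if (denom == 0) return(NA_real_)   # both populations fixed and identical
  sigma_a / denom
}

.hap_counts <- function(hd) {
  K <- max(hd$haplotype)
  pops <- unique(hd$population)
  out <- vapply(pops, function(p) tabulate(hd$haplotype[hd$population == p], K),
                integer(K))
  matrix(out, nrow = K, dimnames = list(NULL, pops))
}

#' Pairwise AMOVA Fst between populations on haplotype identity
#'
#' Computes, for every population pair, the two-level AMOVA fixation index
#' on haplotype identity (0/1) distances:
#' `Fst = sigma2_among / (sigma2_among + sigma2_within)`. Small negative
#' estimates are reported as computed. Pairs of populations fixed for the
#' same single haplotype have no variance to partition and give `NA`.
#'
#' @param hd A `haplotype_data` from [collapse_haplotypes()].
#' @return An `fst_result` list with `fst` (symmetric matrix, 0 diagonal)
#'   and `counts` (haplotypes x populations).
#' @export
pairwise_fst <- function(hd) {
  stopifnot(inherits(hd, "haplotype_data"))
  counts <- .hap_counts(hd)
  pops <- colnames(counts)
  sizes <- colSums(counts)
  if (any(sizes < 2L)) {
    stop("population(s) with < 2 individuals: ",
         paste(pops[sizes < 2L], collapse = ", "))
  }
  P <- length(pops)
  fst <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      fst[i, j] <- fst[j, i] <- .fst_from_counts(counts[, i], counts[, j])
    }
  }
  structure(list(fst = fst, counts = counts), class = "fst_result")
}

#' Permutation P-values for pairwise Fst
#'
#' For each population pair, individuals are permuted between the two
#' populations (keeping sizes fixed), Fst recomputed, and
#' `p = (1 + #[Fst_perm >= Fst_obs]) / (n_perm + 1)` (add-one estimator, so
#' p is never 0). Deterministic under `seed`.
#'
#' @param hd A `haplotype_data`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return The `fst_result` of [pairwise_fst()] with added `p_perm` matrix
#'   (diagonal `NA`) and `n_permutations`.
#' @export
fst_permutation <- function(hd, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  res <- pairwise_fst(hd)
  set.seed(seed)
  counts <- res$counts
  pops <- colnames(counts)
  P <- length(pops)
  p_perm <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      obs <- res$fst[i, j]
      if (is.na(obs)) next
      haps <- c(hd$haplotype[hd$population == pops[i]],
                hd$haplotype[hd$population == pops[j]])
      n1 <- sum(hd$population == pops[i])
      K <- max(hd$haplotype)
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        pick <- sample.int(length(haps), n1)
        c1 <- tabulate(haps[pick], K)
        c2 <- tabulate(haps[-pick], K)
        f <- .fst_from_counts(c1, c2)
        if (!is.na(f) && f >= obs) exceed <- exceed + 1L
      }
      p_perm[i, j] <- p_perm[j, i] <- (1 + exceed) / (n_perm + 1)
    }
  }
  res$p_perm <- p_perm
  res$n_permutations <- as.integer(n_perm)
  res
}
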