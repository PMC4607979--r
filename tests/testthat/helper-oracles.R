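# Independently coded brute-force oracles. These deliberately use naive
# loops and closed forms, never the package's own code paths.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# read counting by linear interval scan over every (read, bin) pair
oracle_count <- function(bins, reads) {
  out <- integer(nrow(bins))
  for (i in seq_len(nrow(reads))) {
    pos <- if (reads$strand[i] == "-") reads$end[i] - 1L else reads$start[i]
    for (j in seq_len(nrow(bins))) {
      if (bins$chrom[j] == reads$chrom[i] &&
          pos >= bins$start[j] && pos < bins$end[j]) {
        out[j] <- out[j] + 1L
        break
      }
    }
  }
  out
}

# element classification: enumerate every feature interval a bin overlaps,
# then apply the precedence order
oracle_classify <- function(bins, genes) {
  prec <- c("proximal_promoter", "intermediate_promoter", "distal_promoter",
            "exon", "intron", "intergenic")
  zone <- function(t, lo, hi, strand) {
    if (strand == "+") c(t + lo, t + hi) else c(t - hi, t - lo)
  }
  res <- character(nrow(bins))
  for (i in seq_len(nrow(bins))) {
    found <- "intergenic"
    classes <- character(0)
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] != bins$chrom[i]) next
      tss <- if (genes$strand[g] == "+") genes$start[g] else genes$end[g]
      ivs <- list(
        proximal_promoter = zone(tss, -200, 500, genes$strand[g]),
        intermediate_promoter = zone(tss, -1000, -200, genes$strand[g]),
        distal_promoter = zone(tss, -2200, -1000, genes$strand[g]),
        intron = c(genes$start[g], genes$end[g]))
      for (nm in names(ivs)) {
        if (bins$start[i] < ivs[[nm]][2] && bins$end[i] > ivs[[nm]][1]) {
          classes <- c(classes, nm)
        }
      }
      ex <- genes$exons[[g]]
      for (e in seq_len(nrow(ex))) {
        if (bins$start[i] < ex[e, 2] && bins$end[i] > ex[e, 1]) {
          classes <- c(classes, "exon")
        }
      }
    }
    if (length(classes)) found <- prec[min(match(classes, prec))]
    res[i] <- found
  }
  res
}

# CpG island detection by exhaustive window enumeration on a single sequence
oracle_cgi <- function(seq, min_len = 200L, thr = 0.6) {
  s <- toupper(seq)
  L <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  win_oe <- function(a, b) {
    sub <- chars[a:b]
    nC <- sum(sub == "C"); nG <- sum(sub == "G")
    nCG <- 0L
    for (k in a:(b - 1L)) {
      if (chars[k] == "C" && chars[k + 1L] == "G") nCG <- nCG + 1L
    }
    if (nCG == 0L) 0 else nCG * (b - a + 1L) / (nC * nG)
  }
  covered <- logical(L)
  for (a in seq_len(L - min_len + 1L)) {
    b <- a + min_len - 1L
    if (any(!chars[a:b] %in% c("A", "C", "G", "T"))) next
    if (win_oe(a, b) > thr) covered[a:b] <- TRUE
  }
  # contiguous covered runs = merged islands
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- NULL
  for (k in which(r$values)) {
    oe <- win_oe(starts[k], ends[k])
    if (oe > thr) {
      out <- rbind(out, data.frame(start = starts[k] - 1L, end = ends[k],
                                   cpg_oe = oe))
    }
  }
  out
}

# hypergeometric upper tail by direct summation of choose() point masses
oracle_hyper <- function(k, set_size, N, n) {
  kk <- k:min(set_size, n)
  sum(choose(set_size, kk) * choose(N - set_size, n - kk)) / choose(N, n)
}

# two-population AMOVA Fst from the explicit pairwise 0/1 distance matrix
oracle_fst <- function(hap1, hap2) {
  hap <- c(hap1, hap2)
  pop <- c(rep(1L, length(hap1)), rep(2L, length(hap2)))
  N <- length(hap)
  d2 <- outer(hap, hap, FUN = function(a, b) as.numeric(a != b))
  ssd_t <- sum(d2) / (2 * N)
  ssd_w <- 0
  for (p in 1:2) {
    idx <- which(pop == p)
    ssd_w <- ssd_w + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ssd_a <- ssd_t - ssd_w
  ms_a <- ssd_a / 1
  ms_w <- ssd_w / (N - 2)
  n_c <- (N - (length(hap1)^2 + length(hap2)^2) / N) / 1
  sigma_a <- (ms_a - ms_w) / n_c
  sigma_a / (sigma_a + ms_w)
}

# pooled-variance two-sample t-test, closed form
oracle_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2))
}
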