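#' Relative expression by the E^-ddCt method
#'
#' Technical replicate wells are averaged per (sample, gene); each sample's
#' dCt is `Ct_target - mean(Ct_references)`; ddCt subtracts the mean dCt of
#' the calibrator samples (per gene); relative expression is
#' `efficiency^(-ddCt)`. Calibrator samples therefore average to expression
#' 1 on the log scale, and changing the calibrator rescales all values by
#' one constant.
#'
#' @param ct data.frame with columns `sample, gene, role, ct` (`role` is
#'   "target" or "reference"); a `well` column marks technical replicates.
#' @param reference_genes Reference gene names (default ACTB and RPL19); all
#'   must be measured in every sample.
#' @param calibrator Character vector of calibrator sample names, or a
#'   single prefix matching a group of samples; default: all samples
#'   (mean-centred ddCt).
#' @param efficiency Amplification base E (default 2: one cycle = one
#'   doubling).
#' @return data.frame `sample, gene, dct, ddct, rel_expr` for target genes.
#' @export
relative_expression <- function(ct, reference_genes = c("ACTB", "RPL19"),
                                calibrator = NULL, efficiency = 2) {
  need <- c("sample", "gene", "role", "ct")
  missing <- setdiff(need, names(ct))
  if (length(missing)) stop("ct table lacks columns: ",
                            paste(missing, collapse = ", "))
  # average technical wells
  avg <- stats::aggregate(ct ~ sample + gene + role, data = ct, FUN = mean)
  samples <- unique(avg$sample)
  refs <- avg[avg$role == "reference" & avg$gene %in% reference_genes, ]
  for (s in samples) {
    got <- refs$gene[refs$sample == s]
    if (!all(reference_genes %in% got)) {
      stop("sample '", s, "' is missing reference gene(s): ",
           paste(setdiff(reference_genes, got), collapse = ", "))
    }
  }
  ref_mean <- tapply(refs$ct, refs$sample, mean)
  targets <- avg[avg$role == "target", ]
  targets$dct <- as.numeric(targets$ct - ref_mean[targets$sample])
  if (is.null(calibrator)) {
    cal_samples <- samples
  } else if (length(calibrator) == 1L && !calibrator %in% samples) {
    cal_samples <- samples[startsWith(samples, calibrator)]
    if (!length(cal_samples)) stop("no samples match calibrator '",
                                   calibrator, "'")
  } else {
    cal_samples <- calibrator
    if (!all(cal_samples %in% samples)) {
      stop("calibrator sample(s) not in table: ",
           paste(setdiff(cal_samples, samples), collapse = ", "))
    }
  }
  cal_dct <- tapply(targets$dct[targets$sample %in% cal_samples],
                    targets$gene[targets$sample %in% cal_samples], mean)
  targets$ddct <- as.numeric(targets$dct - cal_dct[targets$gene])
  targets$rel_expr <- efficiency^(-targets$ddct)
  rownames(targets) <- NULL
  targets[, c("sample", "gene", "dct", "ddct", "rel_expr")]
}

#' Per-CpG-site group comparisons of methylation fractions
#'
#' Two-sample pooled-variance t-test per CpG site and group pair on
#' per-sample methylation fractions. Sites where both groups are constant
#' get p = 1.
#'
#' @param methylation data.frame `site, sample, fraction` plus a group
#'   column.
#' @param group Name of the grouping column (default "breed").
#' @return data.frame `site, a, b, n_a, n_b, mean_a, mean_b, t, p`.
#' @export
site_group_test <- function(methylation, group = "breed") {
  need <- c("site", "sample", "fraction", group)
  missing <- setdiff(need, names(methylation))
  if (length(missing)) stop("methylation table lacks columns: ",
                            paste(missing, collapse = ", "))
  if (any(methylation$fraction < 0 | methylation$fraction > 1)) {
    stop("methylation fractions must be in [0, 1]")
  }
  groups <- unique(methylation[[group]])
  if (length(groups) < 2L) stop("need >= 2 groups")
  pairs <- t(utils::combn(groups, 2L))
  rows <- list()
  for (site in unique(methylation$site)) {
    d <- methylation[methylation$site == site, ]
    for (k in seq_len(nrow(pairs))) {
      xa <- d$fraction[d[[group]] == pairs[k, 1L]]
      xb <- d$fraction[d[[group]] == pairs[k, 2L]]
      if (length(xa) < 2L || length(xb) < 2L) {
        stop("site '", site, "': < 2 samples in a group")
      }
      df <- length(xa) + length(xb) - 2L
      sp2 <- ((length(xa) - 1L) * stats::var(xa) +
                (length(xb) - 1L) * stats::var(xb)) / df
      se <- sqrt(sp2 * (1 / length(xa) + 1 / length(xb)))
      diff <- mean(xa) - mean(xb)
      t <- if (se > 0) diff / se else if (diff == 0) 0 else sign(diff) * Inf
      p <- if (se > 0) 2 * stats::pt(-abs(t), df) else 1
      rows[[length(rows) + 1L]] <- data.frame(
        site = site, a = pairs[k, 1L], b = pairs[k, 2L],
        n_a = length(xa), n_b = length(xb),
        mean_a = mean(xa), mean_b = mean(xb), t = t, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate CpG methylation with expression or protein level
#'
#' Pearson correlation between per-sample methylation fractions and a
#' per-sample quantity (relative expression or protein densitometry),
#' paired by sample name; p from `t = r sqrt(n-2) / sqrt(1-r^2)`. Site/gene
#' combinations with zero variance on either side are reported with `NA`.
#'
#' @param methylation data.frame `site, sample, fraction`.
#' @param values data.frame `sample, gene` and a value column.
#' @param value_col Name of the value column (default "rel_expr").
#' @return data.frame `site, gene, n, r, p`.
#' @export
methylation_expression_correlation <- function(methylation, values,
                                               value_col = "rel_expr") {
  if (!value_col %in% names(values)) {
    stop("values table lacks column '", value_col, "'")
  }
  rows <- list()
  for (site in unique(methylation$site)) {
    msub <- methylation[methylation$site == site, ]
    for (g in unique(values$gene)) {
      vsub <- values[values$gene == g, ]
      common <- intersect(msub$sample, vsub$sample)
      if (length(common) < 3L) next
      x <- msub$fraction[match(common, msub$sample)]
      y <- vsub[[value_col]][match(common, vsub$sample)]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          site = site, gene = g, n = length(common), r = NA_real_,
          p = NA_real_, stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(x, y, method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        site = site, gene = g, n = length(common),
        r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(site = character(), gene = character(), n = integer(),
                      r = numeric(), p = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Modified body mass index
#'
#' `MBMI = body weight / body length^2` (kg/m^2), the body-size phenotype
#' used to rank breeds.
#'
#' @param weight Body weight in kg (positive).
#' @param length Body length in m (positive).
#' @return MBMI in kg/m^2.
#' @export
mbmi <- function(weight, length) {
  if (any(weight <= 0) || any(length <= 0)) {
    stop("weight and length must be positive")
  }
  weight / length^2
}
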