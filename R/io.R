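#' Read a BED6 file of mapped read positions
#'
#' Strict reader for six-column BED (`chrom start end name score strand`).
#' Coordinates are 0-based, half-open, as in the BED standard. Malformed
#' records are rejected with the offending line number.
#'
#' @param path Path to a BED6 file. CRLF line endings and a missing trailing
#'   newline are tolerated.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L)
  if (length(bad)) {
    stop(sprintf("%s:%d: expected >= 6 tab-separated fields, got %d",
                 path, bad[1L], nf[bad[1L]]))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("%s:%d: non-integer start/end coordinates", path, bad[1L]))
  }
  bad <- which(start < 0L | start >= end)
  if (length(bad)) {
    stop(sprintf("%s:%d: invalid interval [%d, %d): require 0 <= start < end",
                 path, bad[1L], start[bad[1L]], end[bad[1L]]))
  }
  bad <- which(!m[, 6L] %in% c("+", "-", "."))
  if (length(bad)) {
    stop(sprintf("%s:%d: invalid strand '%s'", path, bad[1L], m[bad[1L], 6L]))
  }
  data.frame(chrom = m[, 1L], start = start, end = end, name = m[, 4L],
             score = suppressWarnings(as.numeric(m[, 5L])), strand = m[, 6L],
             stringsAsFactors = FALSE)
}

#' Write reads or intervals as BED6
#'
#' @param x A data.frame with columns `chrom`, `start`, `end`, and optionally
#'   `name`, `score`, `strand` (defaulted to `.`, 0, `.`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(x, path) {
  name <- if ("name" %in% names(x)) x$name else rep(".", nrow(x))
  score <- if ("score" %in% names(x)) x$score else rep(0, nrow(x))
  strand <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
  out <- paste(x$chrom, format_bp(x$start), format_bp(x$end),
               name, score, strand, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Read gene models from a BED12 file
#'
#' Parses gene models (one transcript per line) from 12-column BED. Exon
#' blocks are reconstructed from `blockSizes`/`blockStarts` and validated to
#' be sorted, non-overlapping and inside the gene body.
#'
#' @param path Path to a BED12 file.
#' @return A `gene_models` data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand` and a list-column `exons` (two-column matrix of
#'   0-based half-open exon intervals per gene).
#' @export
read_bed12 <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) == 0L) return(empty_gene_models())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 12L)
  if (length(bad)) {
    stop(sprintf("%s:%d: expected 12 tab-separated fields, got %d",
                 path, bad[1L], nf[bad[1L]]))
  }
  n <- length(fields)
  genes <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    start <- as.integer(f[2L]); end <- as.integer(f[3L])
    if (is.na(start) || is.na(end) || start < 0L || start >= end) {
      stop(sprintf("%s:%d: invalid gene interval", path, i))
    }
    if (!f[6L] %in% c("+", "-")) {
      stop(sprintf("%s:%d: gene strand must be '+' or '-', got '%s'",
                   path, i, f[6L]))
    }
    nblk <- as.integer(f[10L])
    sizes <- as.integer(strsplit(f[11L], ",", fixed = TRUE)[[1L]])
    offs <- as.integer(strsplit(f[12L], ",", fixed = TRUE)[[1L]])
    if (length(sizes) != nblk || length(offs) != nblk) {
      stop(sprintf("%s:%d: blockCount disagrees with blockSizes/blockStarts",
                   path, i))
    }
    ex <- cbind(start + offs, start + offs + sizes)
    if (any(ex[, 2L] > end) || is.unsorted(ex[, 1L]) ||
        (nblk > 1L && any(ex[-nblk, 2L] > ex[-1L, 1L]))) {
      stop(sprintf("%s:%d: exon blocks must be sorted, non-overlapping and inside the gene",
                   path, i))
    }
    genes[[i]] <- list(gene_id = f[4L], chrom = f[1L], start = start,
                       end = end, strand = f[6L], exons = ex)
  }
  out <- data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    start = vapply(genes, `[[`, 0L, "start"),
    end = vapply(genes, `[[`, 0L, "end"),
    strand = vapply(genes, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  out$exons <- lapply(genes, `[[`, "exons")
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Write gene models as BED12
#'
#' @param genes A `gene_models` data.frame (see [read_bed12()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    paste(genes$chrom[i], format_bp(genes$start[i]), format_bp(genes$end[i]),
          genes$gene_id[i], 0L, genes$strand[i],
          format_bp(genes$start[i]), format_bp(genes$end[i]), "0", nrow(ex),
          paste0(paste(ex[, 2L] - ex[, 1L], collapse = ","), ","),
          paste0(paste(ex[, 1L] - genes$start[i], collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()] so every module shares one entry point.
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_fasta
#' @param seqs A named `DNAStringSet` or named character vector.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read / write tab-separated tables
#'
#' @param path TSV path with a header row.
#' @param required Character vector of column names that must be present.
#' @return A data.frame.
#' @export
read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         comment.char = "", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop(path, ": missing required columns: ", paste(missing, collapse = ", "))
  }
  x
}

#' @rdname read_tsv
#' @param x Data frame to write.
#' @export
write_tsv <- function(x, path) {
  # flatten list columns (e.g. gene_ids) into comma-separated strings
  x <- as.data.frame(lapply(x, function(col) {
    if (is.list(col)) vapply(col, function(v) paste(v, collapse = ","), "") else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read lines tolerating CRLF and missing trailing newline; drop blank tails.
read_text_lines <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines[nzchar(lines)]
}

# Integer-safe coordinate formatting (avoids scientific notation in BED).
format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

empty_gene_models <- function() {
  out <- data.frame(gene_id = character(), chrom = character(),
                    start = integer(), end = integer(), strand = character(),
                    stringsAsFactors = FALSE)
  out$exons <- list()
  class(out) <- c("gene_models", "data.frame")
  out
}
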