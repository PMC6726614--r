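# File formats.  Everything is headered TSV except BED (0-based half-open,
# read through rtracklayer).  Contact maps are accepted either dense
# (bins x bins) or as COO triples (bin_i, bin_j, count).

#' Read a bin table
#'
#' @param path TSV with header `chrom start end`.
#' @return Data frame `(chrom, start, end)`.
#' @export
read_bins <- function(path) {
  bins <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(bins)))
    stop(sprintf("%s: bin table must have columns chrom, start, end", path))
  bins
}

#' Write a bin table
#' @param bins data frame `(chrom, start, end)`.
#' @param path output TSV path.
#' @export
write_bins <- function(bins, path) {
  utils::write.table(bins[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a contact map (dense or COO TSV)
#'
#' Dense input is a headerless numeric bins-x-bins matrix.  COO input has
#' three columns `bin_i bin_j count` (1-based bin indices, header optional);
#' it may list the upper triangle or both triangles, and is symmetrised on
#' load with a consistency check.  Malformed COO lines are reported with
#' their line number.
#'
#' @param path contact TSV path.
#' @param bins a bin table data frame, or a path to one.
#' @param format `"auto"` (dense iff the field count equals the line
#'   count), `"dense"` or `"coo"`.
#' @return A [contact_map()].
#' @export
read_contact_map <- function(path, bins = NULL,
                             format = c("auto", "dense", "coo")) {
  format <- match.arg(format)
  if (is.character(bins)) bins <- read_bins(bins)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("%s: empty contact map", path))
  nfield <- length(strsplit(lines[[1]], "\t", fixed = TRUE)[[1]])
  if (format == "auto")
    format <- if (nfield == 3L && length(lines) != 3L) "coo" else "dense"
  if (format == "dense") {
    counts <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
    dimnames(counts) <- NULL
    return(contact_map(counts, bins = bins))
  }
  header <- grepl("^[A-Za-z]", lines[[1]])
  start_line <- if (header) 2L else 1L
  n_entries <- length(lines) - start_line + 1L
  i <- integer(n_entries); j <- integer(n_entries); cnt <- numeric(n_entries)
  for (li in seq_len(n_entries)) {
    ln <- start_line + li - 1L
    f <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(f) != 3L || anyNA(v) || v[1] != round(v[1]) ||
        v[2] != round(v[2]) || v[3] < 0)
      stop(sprintf("%s: malformed COO record at line %d: '%s'",
                   path, ln, lines[[ln]]))
    i[li] <- v[1]; j[li] <- v[2]; cnt[li] <- v[3]
  }
  n <- if (!is.null(bins)) nrow(bins) else max(i, j)
  if (any(i < 1 | i > n | j < 1 | j > n))
    stop(sprintf("%s: COO bin index outside 1..%d", path, n))
  counts <- matrix(0, n, n)
  seen <- matrix(FALSE, n, n)
  for (li in seq_len(n_entries)) {
    a <- i[li]; b <- j[li]
    if (seen[a, b] && counts[a, b] != cnt[li])
      stop(sprintf("%s: inconsistent duplicate entry for bins (%d, %d)",
                   path, a, b))
    counts[a, b] <- cnt[li]; seen[a, b] <- TRUE
    if (seen[b, a] && counts[b, a] != cnt[li])
      stop(sprintf("%s: asymmetric entries for bins (%d, %d)", path, a, b))
    counts[b, a] <- cnt[li]; seen[b, a] <- TRUE
  }
  diag(counts) <- 0
  contact_map(counts, bins = bins)
}

#' Write a contact map as COO TSV (upper triangle, nonzero entries)
#' @param map a [contact_map()].
#' @param path output path.
#' @export
write_contact_map <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  up <- which(upper.tri(map$counts) & map$counts > 0, arr.ind = TRUE)
  df <- data.frame(bin_i = up[, 1], bin_j = up[, 2],
                   count = map$counts[up])
  df <- df[order(df$bin_i, df$bin_j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an embedding TSV (`chrom bin_index x y z`)
#' @param path TSV path.
#' @return An [embedding3d()].
#' @export
read_embedding <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  cn <- intersect(c("x", "y", "z"), names(df))
  if (!all(c("chrom", "bin_index") %in% names(df)) || length(cn) < 2L)
    stop(sprintf("%s: embedding needs columns chrom, bin_index, x, y[, z]",
                 path))
  embedding3d(unname(as.matrix(df[, cn])), chrom = df$chrom,
              bin_index = df$bin_index)
}

#' @rdname read_embedding
#' @param emb an [embedding3d()].
#' @export
write_embedding <- function(emb, path) {
  stopifnot(inherits(emb, "embedding3d"))
  df <- data.frame(chrom = emb$chrom, bin_index = emb$bin_index)
  cn <- c("x", "y", "z")[seq_len(ncol(emb$coords))]
  df[cn] <- as.data.frame(emb$coords)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a label TSV (`chrom bin_index label`)
#' @param path TSV path.
#' @return Integer 0/1 vector with attributes `chrom` and `bin_index`.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("chrom", "bin_index", "label") %in% names(df)))
    stop(sprintf("%s: labels need columns chrom, bin_index, label", path))
  structure(as.integer(df$label), chrom = df$chrom, bin_index = df$bin_index)
}

#' @rdname read_labels
#' @param labels 0/1 vector.
#' @param chrom,bin_index per-bin genomic metadata.
#' @export
write_labels <- function(labels, chrom, bin_index, path) {
  utils::write.table(data.frame(chrom = chrom, bin_index = bin_index,
                                label = as.integer(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of annotation intervals
#'
#' @param path BED path (3+ columns, 0-based half-open).
#' @return Data frame `(chrom, start, end[, name])` in 0-based half-open
#'   coordinates.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  nm <- gr$name
  if (!is.null(nm)) df$name <- nm
  df
}

#' Results table for search/control runs
#'
#' Assembles the standard results row for one annotation set and method.
#' @param dataset,annotation identifiers.
#' @param search an `"smhg_search"`.
#' @param p_sim optional simulation-control p-value.
#' @param qvalue optional BH q-value.
#' @param seed seed used for the run.
#' @return One-row data frame with the documented column set.
#' @export
result_row <- function(dataset, annotation, search, p_sim = NA_real_,
                       qvalue = NA_real_, seed = NA_integer_) {
  piv <- search$pivot
  data.frame(dataset = dataset, annotation = annotation,
             method = search$method,
             pivot_x = piv[1], pivot_y = piv[2],
             pivot_z = if (length(piv) > 2) piv[3] else NA_real_,
             threshold_n = search$threshold_n,
             b_at_threshold = search$b_at_threshold,
             score = search$score, pvalue = search$pvalue, qvalue = qvalue,
             p_sim = p_sim, radius = search$radius,
             pivots_evaluated = search$pivots_evaluated, seed = seed,
             stringsAsFactors = FALSE)
}

#' @rdname result_row
#' @param results data frame of result rows.
#' @param path output TSV.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
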