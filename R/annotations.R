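#' Uniform genome binning
#'
#' Tiles each chromosome with half-open 0-based bins `[start, end)` of
#' `bin_size` bp (the last bin of a chromosome may be shorter).
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param bin_size bin width in bp.
#' @return A data frame `(chrom, start, end)` with attribute `bin_size`.
#' @export
genome_binning <- function(chrom_sizes, bin_size) {
  stopifnot(bin_size >= 1, all(chrom_sizes >= 1), !is.null(names(chrom_sizes)))
  out <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    starts <- seq(0, chrom_sizes[[ch]] - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, chrom_sizes[[ch]]))
  }))
  rownames(out) <- NULL
  attr(out, "bin_size") <- bin_size
  out
}

bins_to_granges <- function(bins) {
  GenomicRanges::GRanges(bins$chrom,
                         IRanges::IRanges(start = bins$start + 1L,
                                          end = bins$end))
}

#' Map an annotation's intervals to binary bin labels
#'
#' A bin is labelled 1 iff it overlaps at least one annotation interval by
#' at least 1 bp (intervals are 0-based half-open, BED-style).  Sets
#' mapping to fewer than `min_positive` positive bins are rejected (a typed
#' rejection result, not an error), mirroring the `B < 4` filter applied to
#' annotation cohorts.  Intervals on chromosomes absent from the binning
#' are skipped with a warning.
#'
#' @param intervals data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param bins a bin table `(chrom, start, end)` as from [genome_binning()]
#'   or a [contact_map()]'s `bins`.
#' @param name annotation set name.
#' @param min_positive minimum number of positive bins (default 4).
#' @return An object of class `"annotation_set"`: `name`, `labels` (0/1 per
#'   bin), `B`, `rejected` (logical) and `reason`.
#' @export
map_annotation_to_bins <- function(intervals, bins, name = "annotation",
                                   min_positive = 4L) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  known <- intervals$chrom %in% unique(bins$chrom)
  if (any(!known)) {
    warning(sprintf("skipping %d interval(s) on unknown chromosome(s)",
                    sum(!known)))
    intervals <- intervals[known, , drop = FALSE]
  }
  labels <- integer(nrow(bins))
  if (nrow(intervals) > 0L) {
    hits <- GenomicRanges::findOverlaps(bins_to_granges(bins),
                                        bins_to_granges(intervals))
    labels[unique(S4Vectors::queryHits(hits))] <- 1L
  }
  B <- sum(labels)
  structure(list(name = name, labels = labels, B = B,
                 rejected = B < min_positive,
                 reason = if (B < min_positive)
                   sprintf("B = %d < %d positive bins", B, min_positive)
                 else NA_character_),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set '%s': B = %d positive bins%s\n", x$name, x$B,
              if (x$rejected) sprintf(" [REJECTED: %s]", x$reason) else ""))
  invisible(x)
}

#' Resolve gene identifiers to genomic intervals
#'
#' Exact-match lookup of gene ids in a gene table (e.g. read from a gene
#' BED file); unresolved ids are dropped with a warning.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param gene_table data frame with columns `chrom`, `start`, `end`,
#'   `name`.
#' @return The matching rows of `gene_table`.
#' @export
genes_to_intervals <- function(gene_ids, gene_table) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(gene_table)))
  idx <- match(gene_ids, gene_table$name)
  if (anyNA(idx))
    warning(sprintf("%d gene id(s) not found in the gene table",
                    sum(is.na(idx))))
  gene_table[idx[!is.na(idx)], c("chrom", "start", "end"), drop = FALSE]
}

#' Binarize a CGH (copy-number) profile over genomic bins
#'
#' Probe log-ratios are aggregated per bin as `sum / sqrt(n_probes)`
#' (a Stouffer-style statistic up-weighting well-covered bins; plain means
#' are available via `aggregate = "mean"`).  Bins with fewer than
#' `min_probes` probes are masked out.  Kept bins are labelled 1 iff their
#' value exceeds `mu + z_cut * sigma`, where `mu`, `sigma` are the mean and
#' standard deviation over kept bins.
#'
#' @param probes data frame with columns `chrom`, `position`, `value`.
#' @param bins a bin table `(chrom, start, end)`.
#' @param min_probes minimum probes per kept bin (default 20).
#' @param z_cut binarization threshold in standard deviations (default 2,
#'   one-sided high as duplications are flagged).
#' @param aggregate `"stouffer"` (default) or `"mean"`.
#' @return List with `labels` (0/1 per bin; masked bins are 0), `kept`
#'   (logical mask), `values` (per-bin statistic, `NA` where masked) and
#'   `n_probes`.
#' @export
binarize_cgh <- function(probes, bins, min_probes = 20L, z_cut = 2,
                         aggregate = c("stouffer", "mean")) {
  stopifnot(all(c("chrom", "position", "value") %in% names(probes)))
  aggregate <- match.arg(aggregate)
  pr <- GenomicRanges::GRanges(probes$chrom,
                               IRanges::IRanges(start = probes$position + 1L,
                                                width = 1L))
  hits <- GenomicRanges::findOverlaps(pr, bins_to_granges(bins))
  nb <- nrow(bins)
  sums <- rep(0, nb)
  cnt <- rep(0L, nb)
  bh <- S4Vectors::subjectHits(hits)
  qh <- S4Vectors::queryHits(hits)
  for (i in seq_along(bh)) {
    sums[bh[i]] <- sums[bh[i]] + probes$value[qh[i]]
    cnt[bh[i]] <- cnt[bh[i]] + 1L
  }
  kept <- cnt >= min_probes
  if (!any(kept)) stop("no bin holds at least min_probes probes")
  v <- rep(NA_real_, nb)
  v[kept] <- if (aggregate == "stouffer") sums[kept] / sqrt(cnt[kept])
             else sums[kept] / cnt[kept]
  mu <- mean(v[kept])
  sig <- stats::sd(v[kept])
  labels <- integer(nb)
  if (is.finite(sig) && sig > 0)
    labels[kept & !is.na(v) & v > mu + z_cut * sig] <- 1L
  list(labels = labels, kept = kept, values = v, n_probes = cnt)
}

zscore_or_zero <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Label loci whose local contact structure changed between two maps
#'
#' Differential Hi-C binarization: per chromosome, each intra-chromosomal
#' sub-matrix of the reference and variant maps is Z-scored against its own
#' mean and standard deviation (including zero entries), entries farther
#' than `band` bins from the diagonal are masked to 0, and each locus `i`
#' is summarised by the Euclidean distance between its masked row in the
#' two maps.  These distances are Z-scored per chromosome, and a locus is
#' labelled 1 iff `|Z| > z_cut`.  A zero-variance Z step yields all-zero
#' scores (hence no labels).
#'
#' @param ref,var [contact_map()] objects with identical binning.
#' @param band diagonal half-width kept, in bins (`|i - j| <= band`; default
#'   5).
#' @param z_cut two-sided threshold on the distance Z-scores (default 1.96).
#' @param include_zeros if `FALSE`, the matrix Z-scoring population excludes
#'   zero entries.
#' @return Integer 0/1 label vector over bins.
#' @export
differential_hic_labels <- function(ref, var, band = 5L, z_cut = 1.96,
                                    include_zeros = TRUE) {
  stopifnot(inherits(ref, "contact_map"), inherits(var, "contact_map"))
  if (!identical(dim(ref$counts), dim(var$counts)) ||
      !identical(ref$bins$chrom, var$bins$chrom) ||
      !identical(ref$bins$start, var$bins$start))
    stop("reference and variant maps must share the same binning")
  labels <- integer(nrow(ref$counts))
  for (ch in unique(ref$bins$chrom)) {
    sel <- which(ref$bins$chrom == ch)
    n <- length(sel)
    if (n < 2L) next
    zs <- function(M) {
      pop <- if (include_zeros) M else M[M != 0]
      s <- stats::sd(pop)
      if (!is.finite(s) || s == 0) return(matrix(0, n, n))
      (M - mean(pop)) / s
    }
    Zr <- zs(ref$counts[sel, sel, drop = FALSE])
    Zv <- zs(var$counts[sel, sel, drop = FALSE])
    mask <- abs(outer(seq_len(n), seq_len(n), "-")) > band
    Zr[mask] <- 0
    Zv[mask] <- 0
    d <- sqrt(rowSums((Zr - Zv)^2))
    labels[sel][abs(zscore_or_zero(d)) > z_cut] <- 1L
  }
  labels
}
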