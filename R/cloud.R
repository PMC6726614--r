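#' Labelled point cloud over embedded genomic bins
#'
#' The central data container: `N` points in 2- or 3-dimensional embedding
#' space, each carrying a binary label, and (optionally) the chromosome and
#' within-chromosome bin index needed by the genomic-order control.
#'
#' @param coords numeric matrix, one row per bin, 2 or 3 columns.
#' @param labels 0/1 vector, one entry per bin.
#' @param chrom optional chromosome identifier per bin.
#' @param bin_index optional integer genomic order per bin; must be strictly
#'   increasing within each chromosome.
#' @return An object of class `"labeled_cloud"` with elements `coords`,
#'   `labels`, `chrom`, `bin_index`, `N`, `B` and `d`.
#' @export
labeled_cloud <- function(coords, labels, chrom = NULL, bin_index = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!ncol(coords) %in% c(2L, 3L))
    stop("coords must have 2 or 3 columns")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  labels <- as.integer(labels)
  if (length(labels) != nrow(coords))
    stop("labels length must match the number of points")
  if (anyNA(labels) || any(labels != 0L & labels != 1L))
    stop("labels must be 0/1")
  if (!is.null(chrom)) {
    chrom <- as.character(chrom)
    if (length(chrom) != nrow(coords))
      stop("chrom length must match the number of points")
  }
  if (!is.null(bin_index)) {
    bin_index <- as.integer(bin_index)
    if (length(bin_index) != nrow(coords))
      stop("bin_index length must match the number of points")
    grp <- if (is.null(chrom)) rep("*", nrow(coords)) else chrom
    for (g in unique(grp)) {
      bi <- bin_index[grp == g]
      if (any(diff(bi) <= 0L))
        stop("bin_index must be strictly increasing within each chromosome")
    }
  }
  structure(list(coords = coords, labels = labels, chrom = chrom,
                 bin_index = bin_index, N = nrow(coords),
                 B = sum(labels), d = ncol(coords)),
            class = "labeled_cloud")
}

#' @export
print.labeled_cloud <- function(x, ...) {
  cat(sprintf("labeled_cloud: N = %d points in %dD, B = %d positive labels",
              x$N, x$d, x$B))
  if (!is.null(x$chrom))
    cat(sprintf(", %d chromosome(s)", length(unique(x$chrom))))
  cat("\n")
  invisible(x)
}

#' Attach binary labels to an embedding
#'
#' @param embedding an `"embedding3d"` object (see [embedding3d()]).
#' @param labels 0/1 vector, one entry per embedded bin.
#' @return A [labeled_cloud()].
#' @export
as_labeled_cloud <- function(embedding, labels) {
  stopifnot(inherits(embedding, "embedding3d"))
  labeled_cloud(embedding$coords, labels, chrom = embedding$chrom,
                bin_index = embedding$bin_index)
}

bbox_diag <- function(coords) {
  rng <- apply(coords, 2, range)
  sqrt(sum((rng[2, ] - rng[1, ])^2))
}
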