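#' Perpendicular bisecting hyperplanes between oppositely labelled points
#'
#' One bisector per ('1', '0') point pair: the hyperplane perpendicular to
#' the connecting segment through its midpoint, written as
#' `a*X + b*Y (+ c*Z) + d = 0` with a unit normal pointing from the '1'
#' point towards the '0' point (so the plane value is negative on the
#' positive point's side).  The arrangement of these planes tessellates the
#' embedding space into cells of constant distance-ranking.
#'
#' Coincident oppositely labelled points admit no bisector; such pairs are
#' skipped with a warning.
#'
#' @param cloud a [labeled_cloud()].
#' @return An object of class `"bisector_set"`: list with `coeffs` (an
#'   `m x (d+1)` matrix, columns = unit normal then offset), `pos_idx`,
#'   `neg_idx` (generating point indices, in lexicographic pair order) and
#'   `skipped` (number of coincident pairs dropped).
#' @export
build_bisectors <- function(cloud) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  d <- cloud$d
  pos <- which(cloud$labels == 1L)
  neg <- which(cloud$labels == 0L)
  m <- length(pos) * length(neg)
  if (m == 0L) {
    return(structure(list(coeffs = matrix(numeric(0), 0, d + 1),
                          pos_idx = integer(0), neg_idx = integer(0),
                          skipped = 0L),
                     class = "bisector_set"))
  }
  pi_ <- rep(pos, each = length(neg))
  ni_ <- rep(neg, times = length(pos))
  dif <- cloud$coords[ni_, , drop = FALSE] - cloud$coords[pi_, , drop = FALSE]
  len <- sqrt(rowSums(dif^2))
  tol <- 1e-12 * max(1, bbox_diag(cloud$coords))
  keep <- len > tol
  if (any(!keep))
    warning(sprintf("skipping %d coincident oppositely-labelled pair(s)",
                    sum(!keep)))
  pi_ <- pi_[keep]; ni_ <- ni_[keep]
  dif <- dif[keep, , drop = FALSE]; len <- len[keep]
  a <- dif / len
  mid <- (cloud$coords[pi_, , drop = FALSE] +
          cloud$coords[ni_, , drop = FALSE]) / 2
  off <- -rowSums(a * mid)
  structure(list(coeffs = cbind(a, off, deparse.level = 0),
                 pos_idx = pi_, neg_idx = ni_, skipped = sum(!keep)),
            class = "bisector_set")
}

#' @export
print.bisector_set <- function(x, ...) {
  cat(sprintf("bisector_set: %d hyperplanes (%d coincident pairs skipped)\n",
              nrow(x$coeffs), x$skipped))
  invisible(x)
}

#' Rank cloud points by Euclidean distance from a pivot
#'
#' Produces the binary vector induced by sorting all points by nondecreasing
#' distance from `pivot` (ties broken by input index).
#'
#' @param pivot numeric vector of length `d`.
#' @param cloud a [labeled_cloud()].
#' @return List with `labels` (the ranked binary vector), `order` (the
#'   permutation of point indices) and `distances` (sorted distances).
#' @export
rank_by_distance <- function(pivot, cloud) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  pivot <- as.numeric(pivot)
  if (length(pivot) != cloud$d || !all(is.finite(pivot)))
    stop("pivot must be a finite point of the cloud's dimension")
  d2 <- colSums((t(cloud$coords) - pivot)^2)
  ord <- order(d2)
  list(labels = cloud$labels[ord], order = ord, distances = sqrt(d2[ord]))
}

#' Score a single pivot
#'
#' Composition of [rank_by_distance()] and [mhg_statistic()]; the radius is
#' the distance from the pivot to its `threshold_n`-th ranked point, i.e.
#' the ball that realises the optimal prefix.
#'
#' @inheritParams rank_by_distance
#' @param pvalue if `TRUE` also compute the exact corrected p-value.
#' @return A list of class `"pivot_score"`: `pivot`, `score`, `threshold_n`,
#'   `b_at_threshold`, `radius`, and optionally `pvalue`.
#' @export
score_pivot <- function(pivot, cloud, pvalue = FALSE) {
  rk <- rank_by_distance(pivot, cloud)
  st <- mhg_statistic(rk$labels)
  out <- list(pivot = as.numeric(pivot), score = st$score,
              threshold_n = st$threshold_n,
              b_at_threshold = st$b_at_threshold,
              radius = rk$distances[st$threshold_n],
              N = st$N, B = st$B)
  if (pvalue)
    out$pvalue <- if (st$B == 0L || st$B == st$N) 1
                  else mhg_exact_pvalue(st$N, st$B, st$score)
  class(out) <- "pivot_score"
  out
}

#' @export
print.pivot_score <- function(x, ...) {
  cat(sprintf(
    "pivot (%s): score %.4g at n = %d (b = %d), radius %.4g%s\n",
    paste(signif(x$pivot, 4), collapse = ", "), x$score, x$threshold_n,
    x$b_at_threshold, x$radius,
    if (is.null(x$pvalue)) "" else sprintf(", p = %.4g", x$pvalue)))
  invisible(x)
}

default_eps <- function(coords) {
  dg <- bbox_diag(coords)
  if (dg <= 0) 1e-6 else 1e-6 * dg
}

#' Cell-interior pivot from a tuple of bisectors
#'
#' `d` bisectors in general position meet in a single vertex of the
#' arrangement.  The returned pivot is that vertex displaced into the
#' interior of the cell lying just above it: one coordinate is perturbed by
#' `+eps`, each bisector is re-solved for its dependent coordinate, and the
#' solutions are averaged.  The result is the "bottom-most" representative
#' of its cell with respect to the perturbed axis.
#'
#' @param bisectors a `"bisector_set"`.
#' @param tuple integer vector of `d` distinct bisector indices.
#' @param eps step size in embedding units; default `1e-6` times the
#'   coefficient scale.
#' @return A numeric pivot of length `d`.  Parallel or otherwise degenerate
#'   tuples raise an error.
#' @export
sample_pivot_from_tuple <- function(bisectors, tuple, eps = 1e-6) {
  stopifnot(inherits(bisectors, "bisector_set"))
  d <- ncol(bisectors$coeffs) - 1L
  tuple <- as.integer(tuple)
  if (length(tuple) != d || anyDuplicated(tuple))
    stop(sprintf("tuple must contain %d distinct bisector indices", d))
  p <- solve_tuples_cpp(bisectors$coeffs, matrix(tuple, 1L), eps)
  if (anyNA(p)) stop("degenerate tuple: bisectors have no unique intersection")
  as.numeric(p)
}

#' Enumerate candidate pivots from the bisector arrangement
#'
#' Generates one pivot per non-degenerate `d`-tuple of bisectors (see
#' [sample_pivot_from_tuple()]).  In general position this yields
#' `choose(m, d)` pivots for `m = B(N-B)` bisectors.  When the number of
#' tuples exceeds `max_tuples` a seeded uniform subsample of tuples is used
#' instead of the full enumeration.
#'
#' @param cloud a [labeled_cloud()].
#' @param eps step size; default `1e-6` times the bounding-box diagonal.
#' @param max_tuples enumeration budget; `Inf` forces full enumeration.
#' @param seed RNG seed used only when subsampling tuples.
#' @return A numeric matrix of pivots (rows), with attributes `n_bisectors`,
#'   `n_tuples`, `degenerate` (skipped tuple count) and `eps`.
#' @export
enumerate_sample_pivots <- function(cloud, eps = NULL, max_tuples = 2e4,
                                    seed = 1L) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  d <- cloud$d
  bis <- build_bisectors(cloud)
  m <- nrow(bis$coeffs)
  if (is.null(eps)) eps <- default_eps(cloud$coords)
  if (m < d) {
    out <- matrix(numeric(0), 0, d)
    attr(out, "n_bisectors") <- m
    attr(out, "n_tuples") <- 0L
    attr(out, "degenerate") <- 0L
    attr(out, "eps") <- eps
    return(out)
  }
  total <- choose(m, d)
  if (total <= max_tuples) {
    tuples <- t(utils::combn(m, d))
  } else {
    tuples <- with_seed(seed, {
      t(vapply(seq_len(max_tuples),
               function(i) sort(sample.int(m, d)), integer(d)))
    })
    tuples <- unique(tuples)
  }
  piv <- solve_tuples_cpp(bis$coeffs, tuples, eps)
  ok <- stats::complete.cases(piv)
  out <- piv[ok, , drop = FALSE]
  attr(out, "n_bisectors") <- m
  attr(out, "n_tuples") <- nrow(tuples)
  attr(out, "degenerate") <- sum(!ok)
  attr(out, "eps") <- eps
  out
}
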