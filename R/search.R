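# Shared constructor for search results; `scores` is the matrix returned by
# score_pivots_cpp (columns: score, threshold_n, b_at_threshold, radius).
make_search_result <- function(method, cloud, pivot, score, threshold_n,
                               b_at_threshold, radius, pivots_evaluated,
                               opt_trace = NULL, extra = list()) {
  pv <- if (cloud$B == 0L || cloud$B == cloud$N) 1
        else mhg_exact_pvalue(cloud$N, cloud$B, score)
  res <- c(list(method = method, pivot = as.numeric(pivot), score = score,
                threshold_n = as.integer(threshold_n),
                b_at_threshold = as.integer(b_at_threshold),
                radius = radius, pvalue = pv,
                pivots_evaluated = pivots_evaluated,
                opt_trace = opt_trace, N = cloud$N, B = cloud$B),
           extra)
  class(res) <- "smhg_search"
  res
}

#' @export
print.smhg_search <- function(x, ...) {
  cat(sprintf(
    "smHG search [%s]: score %.4g (exact p = %.4g) at n = %d, b = %d/%d\n",
    x$method, x$score, x$pvalue, x$threshold_n, x$b_at_threshold, x$B))
  cat(sprintf("  pivot (%s), radius %.4g, %g pivots evaluated\n",
              paste(signif(x$pivot, 4), collapse = ", "), x$radius,
              x$pivots_evaluated))
  invisible(x)
}

best_from_scores <- function(scores) {
  i <- which.min(scores[, 1])
  list(i = i, score = scores[i, 1], n = scores[i, 2], b = scores[i, 3],
       radius = scores[i, 4])
}

opt_trace_from_scores <- function(scores) {
  cm <- cummin(scores[, 1])
  imp <- which(c(TRUE, diff(cm) < 0))
  data.frame(t = imp, score = cm[imp])
}

#' Sampling search over the bisector arrangement
#'
#' Evaluates the mHG score at every pivot produced by
#' [enumerate_sample_pivots()] plus every bead (data-point) pivot, and
#' returns the minimum.  On small instances (all `choose(m, d)` tuples
#' within `max_tuples`) this is the exhaustive cell-sampling strategy.
#'
#' @inheritParams enumerate_sample_pivots
#' @return An object of class `"smhg_search"` with the best
#'   [score_pivot()]-style fields, the exact corrected p-value, the number
#'   of pivots evaluated and the running-optimum trace.
#' @export
smhg_sample <- function(cloud, eps = NULL, max_tuples = 2e4, seed = 1L) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  piv <- enumerate_sample_pivots(cloud, eps = eps, max_tuples = max_tuples,
                                 seed = seed)
  pivots <- rbind(piv, cloud$coords)
  tails <- mhg_tail_table(cloud$N, cloud$B)
  scores <- score_pivots_cpp(cloud$coords, cloud$labels, pivots, tails)
  b <- best_from_scores(scores)
  make_search_result("sample", cloud, pivots[b$i, ], b$score, b$n, b$b,
                     b$radius, nrow(pivots),
                     opt_trace = opt_trace_from_scores(scores),
                     extra = list(n_bisectors = attr(piv, "n_bisectors"),
                                  degenerate_tuples = attr(piv, "degenerate")))
}

grid_root <- function(coords, slack) {
  rng <- apply(coords, 2, range)
  ctr <- colMeans(rng)
  ext <- rng[2, ] - rng[1, ]
  dg <- sqrt(sum(ext^2))
  half <- max(ext) / 2 + slack * max(dg, 1e-9)
  if (half <= 0) half <- 1
  list(center = ctr, half = half)
}

#' Octree branch-and-bound search
#'
#' Recursively refines a cube hierarchy rooted at the (slack-expanded)
#' bounding box of the data, scoring each cube's center as a pivot.  Cubes
#' are traversed best-first by a lower bound on the best achievable score
#' inside the cube (see [cube_lower_bound()]); a cube whose bound exceeds
#' the current optimum is pruned, and a cube intersected by no bisector has
#' constant ranking and is not split further.
#'
#' @param cloud a [labeled_cloud()].
#' @param budget maximum number of pivots (cube centers) to evaluate.
#' @param slack root-cube margin as a fraction of the bounding-box diagonal,
#'   allowing pivots outside the convex hull of the data.
#' @param max_depth maximum octree depth.
#' @param prune if `FALSE`, branch-and-bound pruning is disabled (the full
#'   tree up to `max_depth`/`budget` is traversed); used to verify that
#'   pruning never changes the result.
#' @return An `"smhg_search"` object (see [smhg_sample()]).
#' @export
smhg_grid <- function(cloud, budget = 1e5, slack = 0.1, max_depth = 30L,
                      prune = TRUE) {
  stopifnot(inherits(cloud, "labeled_cloud"), budget >= 1)
  bis <- build_bisectors(cloud)
  tails <- mhg_tail_table(cloud$N, cloud$B)
  root <- grid_root(cloud$coords, slack)
  res <- grid_search_cpp(cloud$coords, cloud$labels, tails, bis$coeffs,
                         root$center, root$half, budget,
                         as.integer(max_depth), prune)
  make_search_result("grid", cloud, res$pivot, res$score, res$threshold_n,
                     res$b_at_threshold, res$radius, res$pivots_evaluated,
                     opt_trace = data.frame(t = res$trace_t,
                                            score = res$trace_score),
                     extra = list(root = root,
                                  n_bisectors = nrow(bis$coeffs)))
}

#' Lower bound on the best achievable score within a cube
#'
#' For the axis-aligned cube given by `center` and `half_width`: scores the
#' center, counts the active bisectors (those intersecting the cube) that
#' the center leaves unsatisfied (`k`), and bounds the best score any pivot
#' in the cube could achieve by optimistically promoting up to `k`
#' '0'-to-'1' swaps after every prefix of the center's ranking, never
#' exceeding `B` ones in total.
#'
#' @param center cube center (length `d`).
#' @param half_width half the cube edge length.
#' @param cloud a [labeled_cloud()].
#' @param bisectors optional precomputed `"bisector_set"`.
#' @return List with `bound`, `k`, `n_active` and `center_score`;
#'   `bound <= center_score` always, with equality when `k == 0`.
#' @export
cube_lower_bound <- function(center, half_width, cloud, bisectors = NULL) {
  stopifnot(inherits(cloud, "labeled_cloud"), half_width >= 0)
  if (is.null(bisectors)) bisectors <- build_bisectors(cloud)
  tails <- mhg_tail_table(cloud$N, cloud$B)
  cube_bound_cpp(as.numeric(center), half_width, cloud$coords, cloud$labels,
                 tails, bisectors$coeffs)
}

#' Exhaustive small-instance oracle
#'
#' Ground-truth minimiser for testing: evaluates every arrangement-sampled
#' pivot, every bead pivot, and a dense `grid_n^d` lattice over the
#' slack-expanded bounding box, returning the global minimum encountered.
#' Guarded against large instances.
#'
#' @param cloud a [labeled_cloud()] with at most `max_points` points.
#' @param grid_n lattice resolution per axis.
#' @param slack bounding-box expansion fraction.
#' @param max_points resource guard on `N`.
#' @return An `"smhg_search"` object with method `"oracle"`.
#' @export
exhaustive_oracle <- function(cloud, grid_n = 200L, slack = 0.1,
                              max_points = 40L) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  if (cloud$N > max_points)
    stop("resource guard: exhaustive_oracle is restricted to small instances")
  m <- cloud$B * (cloud$N - cloud$B)
  if (choose(m, cloud$d) > 2e6)
    stop("resource guard: too many bisector tuples for exhaustive enumeration")
  tails <- mhg_tail_table(cloud$N, cloud$B)
  piv <- enumerate_sample_pivots(cloud, max_tuples = Inf)
  pivots <- rbind(piv, cloud$coords)
  scores <- score_pivots_cpp(cloud$coords, cloud$labels, pivots, tails)
  b <- best_from_scores(scores)
  best <- list(pivot = pivots[b$i, ], score = b$score, n = b$n, bb = b$b,
               radius = b$radius)
  evaluated <- nrow(pivots)
  root <- grid_root(cloud$coords, slack)
  axes <- lapply(seq_len(cloud$d), function(j)
    seq(root$center[j] - root$half, root$center[j] + root$half,
        length.out = grid_n))
  # evaluate the lattice in slabs along the last axis to cap memory
  base <- as.matrix(expand.grid(axes[-cloud$d], KEEP.OUT.ATTRS = FALSE))
  for (z in axes[[cloud$d]]) {
    slab <- cbind(base, z, deparse.level = 0)
    sc <- score_pivots_cpp(cloud$coords, cloud$labels, slab, tails)
    bi <- which.min(sc[, 1])
    evaluated <- evaluated + nrow(slab)
    if (sc[bi, 1] < best$score)
      best <- list(pivot = slab[bi, ], score = sc[bi, 1], n = sc[bi, 2],
                   bb = sc[bi, 3], radius = sc[bi, 4])
  }
  make_search_result("oracle", cloud, best$pivot, best$score, best$n,
                     best$bb, best$radius, evaluated)
}
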