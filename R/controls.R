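#' Bead-pivot control
#'
#' Restricts candidate pivots to the embedded data points themselves (the
#' "beads" along the genome) — the earlier published approach that spatial
#' pivot search generalises.  Each bead ranks itself first at distance zero,
#' with its own label counted.
#'
#' @param cloud a [labeled_cloud()].
#' @return An `"smhg_search"` object with method `"bead"`.
#' @export
bead_control <- function(cloud) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  tails <- mhg_tail_table(cloud$N, cloud$B)
  scores <- score_pivots_cpp(cloud$coords, cloud$labels, cloud$coords, tails)
  b <- best_from_scores(scores)
  make_search_result("bead", cloud, cloud$coords[b$i, ], b$score, b$n, b$b,
                     b$radius, cloud$N,
                     opt_trace = opt_trace_from_scores(scores),
                     extra = list(bead_index = b$i))
}

#' Genomic-order (1D) control
#'
#' Ranks bins by absolute genomic distance `|i - j|` from each bead pivot
#' instead of by embedded Euclidean distance, per chromosome (genomic
#' distance between chromosomes is undefined).  Filters out enrichments
#' explainable by linear genome order alone.  Equidistant up/downstream ties
#' rank the upstream (smaller `bin_index`) bin first.
#'
#' @param cloud a [labeled_cloud()] with `chrom` and `bin_index` set.
#' @return A named list of `"smhg_search"` objects (method `"1d"`), one per
#'   chromosome with at least two bins; the null model uses per-chromosome
#'   `N` and `B`.
#' @export
genomic_1d_control <- function(cloud) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  if (is.null(cloud$chrom) || is.null(cloud$bin_index))
    stop("genomic_1d_control requires chrom and bin_index")
  out <- list()
  for (ch in unique(cloud$chrom)) {
    sel <- which(cloud$chrom == ch)
    if (length(sel) < 2L) next
    g <- cloud$bin_index[sel]
    lab <- cloud$labels[sel]
    Nc <- length(sel)
    Bc <- sum(lab)
    tails <- mhg_tail_table(Nc, Bc)
    best <- NULL
    for (i in seq_len(Nc)) {
      ord <- order(abs(g - g[i]), g)
      b_n <- cumsum(lab[ord])
      tv <- tails[cbind(seq_len(Nc) + 1L, b_n + 1L)]
      j <- which.min(tv)
      if (is.null(best) || tv[j] < best$score)
        best <- list(i = i, score = tv[j], n = j, b = b_n[j],
                     radius = abs(g[ord[j]] - g[i]))
    }
    sub <- labeled_cloud(cloud$coords[sel, , drop = FALSE], lab)
    out[[ch]] <- make_search_result(
      "1d", sub, cloud$coords[sel[best$i], ], best$score, best$n, best$b,
      best$radius, Nc,
      extra = list(chrom = ch, bead_index = sel[best$i],
                   bin_index = g[best$i]))
  }
  if (length(out) == 0L)
    warning("no chromosome with at least two bins; empty 1D control")
  out
}

#' Label-shuffle simulation control (P_sim)
#'
#' Permutes the label vector `n_shuffles` times; for each shuffle the
#' statistic is the minimum score over the selected search heuristics
#' (both the grid and the sampling search by default, as for the observed
#' data).  `P_sim` is the empirical survival probability of the observed
#' statistic with the add-one convention `(r + 1) / (n + 1)`, never exactly
#' zero; when no shuffle beats the observation the result is also reported
#' as `"< 1/n_shuffles"`.
#'
#' @param cloud a [labeled_cloud()].
#' @param n_shuffles number of label permutations (100 by default).
#' @param seed RNG seed (also seeds the tuple subsampling per shuffle).
#' @param use which heuristics form the statistic.
#' @param grid_budget,sample_max_tuples,eps,slack,max_depth search
#'   parameters, applied identically to the observed data and to every
#'   shuffle.
#' @return List of class `"simulation_control"`: `p_sim`, `r` (shuffles at
#'   least as extreme), `n_shuffles`, `observed`, `shuffle_stats`, `display`.
#' @export
simulation_control <- function(cloud, n_shuffles = 100L, seed = 1L,
                               use = c("both", "grid", "sample"),
                               grid_budget = 2000, sample_max_tuples = 2000,
                               eps = NULL, slack = 0.1, max_depth = 30L) {
  stopifnot(inherits(cloud, "labeled_cloud"), n_shuffles >= 1)
  use <- match.arg(use)
  stat_fun <- function(cl, s) {
    v <- Inf
    if (use %in% c("both", "grid"))
      v <- min(v, smhg_grid(cl, budget = grid_budget, slack = slack,
                            max_depth = max_depth)$score)
    if (use %in% c("both", "sample"))
      v <- min(v, smhg_sample(cl, eps = eps,
                              max_tuples = sample_max_tuples, seed = s)$score)
    v
  }
  observed <- stat_fun(cloud, seed)
  perms <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(j) sample(cloud$labels),
           integer(cloud$N))
  })
  stats_sh <- vapply(seq_len(n_shuffles), function(j) {
    cl <- labeled_cloud(cloud$coords, perms[, j], chrom = cloud$chrom,
                        bin_index = cloud$bin_index)
    stat_fun(cl, seed + j)
  }, numeric(1))
  r <- sum(stats_sh <= observed * (1 + 1e-12) + 1e-300)
  p <- (r + 1) / (n_shuffles + 1)
  structure(list(p_sim = p, r = r, n_shuffles = n_shuffles,
                 observed = observed, shuffle_stats = stats_sh,
                 display = if (r == 0) sprintf("< %g", 1 / n_shuffles)
                           else sprintf("%.4g", p)),
            class = "simulation_control")
}

#' @export
print.simulation_control <- function(x, ...) {
  cat(sprintf("P_sim %s (r = %d of %d shuffles; observed statistic %.4g)\n",
              x$display, x$r, x$n_shuffles, x$observed))
  invisible(x)
}

#' Permutation test for the assignment of elements to candidate sites
#'
#' Shuffles the assignment of the positive elements over the candidate bins
#' (e.g. retrotransposon insertions over telomeric bins) and compares the
#' median (or mean) pairwise Euclidean distance of the observed positives
#' against the permutation null.  Small p-values indicate the positives are
#' mutually closer in the embedding than a random assignment.
#'
#' @param cloud a [labeled_cloud()].
#' @param positive_bins indices of the observed positive bins (>= 2).
#' @param candidate_bins indices of all bins the positives could occupy;
#'   must contain `positive_bins`.
#' @param n_perm number of permutations.
#' @param statistic `"median"` (default) or `"mean"` pairwise distance.
#' @param seed RNG seed.
#' @return List with `p` (empirical CDF with the `(r+1)/(n+1)` convention),
#'   `observed`, `null_stats`, `r`, `n_perm`.
#' @export
assignment_permutation_test <- function(cloud, positive_bins, candidate_bins,
                                        n_perm = 10000L,
                                        statistic = c("median", "mean"),
                                        seed = 1L) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  statistic <- match.arg(statistic)
  positive_bins <- as.integer(positive_bins)
  candidate_bins <- as.integer(candidate_bins)
  if (length(positive_bins) < 2L) stop("need at least two positive bins")
  if (!all(positive_bins %in% candidate_bins))
    stop("positive_bins must be a subset of candidate_bins")
  if (length(candidate_bins) < length(positive_bins))
    stop("candidate_bins must be at least as large as positive_bins")
  fun <- if (statistic == "median") stats::median else mean
  pair_stat <- function(idx)
    fun(stats::dist(cloud$coords[idx, , drop = FALSE]))
  observed <- pair_stat(positive_bins)
  k <- length(positive_bins)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) pair_stat(sample(candidate_bins, k)), numeric(1))
  })
  r <- sum(null_stats <= observed * (1 + 1e-12) + 1e-300)
  list(p = (r + 1) / (n_perm + 1), observed = observed,
       null_stats = null_stats, r = r, n_perm = n_perm)
}

#' Cross-set spatial proximity permutation test
#'
#' Fixes one set of bins, and asks whether a second observed set lies
#' unusually close to it: the statistic is the mean over all cross-pair
#' Euclidean distances between the two sets, and the null redraws the
#' second set uniformly from all bins outside the fixed set.
#'
#' @param cloud a [labeled_cloud()].
#' @param fixed_set indices of the fixed bins (nonempty).
#' @param observed_set indices of the observed second set.
#' @param other_set_size size of the redrawn set (defaults to
#'   `length(observed_set)`).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return List as in [assignment_permutation_test()].
#' @export
cross_set_proximity_test <- function(cloud, fixed_set, observed_set,
                                     other_set_size = length(observed_set),
                                     n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  fixed_set <- as.integer(fixed_set)
  observed_set <- as.integer(observed_set)
  if (length(fixed_set) < 1L) stop("fixed_set must be nonempty")
  if (other_set_size < 1L) stop("other_set_size must be >= 1")
  pool <- setdiff(seq_len(cloud$N), fixed_set)
  if (length(pool) < other_set_size)
    stop("insufficient bins outside fixed_set to draw the second set")
  cross_stat <- function(idx) {
    a <- cloud$coords[fixed_set, , drop = FALSE]
    b <- cloud$coords[idx, , drop = FALSE]
    dd <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
      sqrt(rowSums((a[i, , drop = FALSE] - b[j, , drop = FALSE])^2)))
    mean(dd)
  }
  observed <- cross_stat(observed_set)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) cross_stat(sample(pool, other_set_size)), numeric(1))
  })
  r <- sum(null_stats <= observed * (1 + 1e-12) + 1e-300)
  list(p = (r + 1) / (n_perm + 1), observed = observed,
       null_stats = null_stats, r = r, n_perm = n_perm)
}
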