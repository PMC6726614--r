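#' Spatial mHG enrichment analysis of a labelled embedding
#'
#' The main fitting interface: searches the embedding space for the pivot
#' minimising the mHG score of the distance-ranked label vector, and
#' (optionally) attaches the three guard controls — the bead-pivot control,
#' the per-chromosome genomic-order control, and the label-shuffle
#' simulation control `P_sim`.
#'
#' @param cloud a [labeled_cloud()] (see [as_labeled_cloud()] to combine an
#'   embedding with labels).
#' @param method search strategy for the headline result: octree
#'   branch-and-bound (`"grid"`, default), bisector-arrangement sampling
#'   (`"sample"`), or the bead / genomic-order controls run as the primary
#'   method.
#' @param controls compute the guard controls alongside the main search.
#' @param seed RNG seed for the shuffle control and tuple subsampling.
#' @param n_shuffles shuffles for `P_sim`.
#' @param budget,slack,max_depth grid-search parameters (see [smhg_grid()]).
#' @param eps,max_tuples sampling-search parameters (see [smhg_sample()]).
#' @param sim_grid_budget,sim_sample_tuples reduced search budgets used
#'   inside the shuffle control (applied equally to observed and shuffled
#'   labels).
#' @return An object of class `"smhg"` with elements `result` (an
#'   `"smhg_search"`), `bead`, `one_d`, `sim`, `cloud` and `call`; it has
#'   `print`, `summary` and `plot` methods.
#' @examples
#' spec <- synthetic_spec(n_chrom = 1, bins_per_chrom = 40, seed = 7)
#' truth <- generate_polymer(spec)
#' hs <- plant_hotspot(truth, n_inside = 6, seed = 7)
#' fit <- smhg(hs$cloud, controls = FALSE, budget = 500)
#' fit
#' @export
smhg <- function(cloud, method = c("grid", "sample", "bead", "1d"),
                 controls = TRUE, seed = 1L, n_shuffles = 100L,
                 budget = 1e5, slack = 0.1, max_depth = 30L, eps = NULL,
                 max_tuples = 2e4, sim_grid_budget = 2000,
                 sim_sample_tuples = 2000) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  method <- match.arg(method)
  result <- switch(method,
    grid = smhg_grid(cloud, budget = budget, slack = slack,
                     max_depth = max_depth),
    sample = smhg_sample(cloud, eps = eps, max_tuples = max_tuples,
                         seed = seed),
    bead = bead_control(cloud),
    `1d` = {
      ctl <- genomic_1d_control(cloud)
      ctl[[which.min(vapply(ctl, `[[`, numeric(1), "score"))]]
    })
  bead <- one_d <- sim <- NULL
  if (controls) {
    bead <- bead_control(cloud)
    if (!is.null(cloud$chrom) && !is.null(cloud$bin_index))
      one_d <- genomic_1d_control(cloud)
    sim <- simulation_control(cloud, n_shuffles = n_shuffles, seed = seed,
                              grid_budget = sim_grid_budget,
                              sample_max_tuples = sim_sample_tuples,
                              eps = eps, slack = slack,
                              max_depth = max_depth)
  }
  structure(list(result = result, bead = bead, one_d = one_d, sim = sim,
                 cloud = cloud, method = method, seed = seed,
                 call = match.call()),
            class = "smhg")
}

#' @export
print.smhg <- function(x, ...) {
  cat(sprintf("Spatial mHG enrichment (method: %s)\n", x$method))
  cat(sprintf("  N = %d bins (%dD), B = %d positive\n", x$cloud$N,
              x$cloud$d, x$cloud$B))
  cat(sprintf("  best score %.4g, exact corrected p = %.4g\n",
              x$result$score, x$result$pvalue))
  cat(sprintf("  pivot (%s), ball radius %.4g covering n = %d bins (b = %d)\n",
              paste(signif(x$result$pivot, 4), collapse = ", "),
              x$result$radius, x$result$threshold_n,
              x$result$b_at_threshold))
  if (!is.null(x$bead))
    cat(sprintf("  bead control:    p = %.4g\n", x$bead$pvalue))
  if (!is.null(x$one_d) && length(x$one_d))
    cat(sprintf("  1D control:      min p = %.4g over %d chromosome(s)\n",
                min(vapply(x$one_d, `[[`, numeric(1), "pvalue")),
                length(x$one_d)))
  if (!is.null(x$sim))
    cat(sprintf("  shuffle control: P_sim %s\n", x$sim$display))
  invisible(x)
}

#' @export
summary.smhg <- function(object, ...) {
  print(object)
  tr <- object$result$opt_trace
  if (!is.null(tr) && nrow(tr))
    cat(sprintf("  optimum trace: %d improvement(s), final after %g pivots\n",
                nrow(tr), tr$t[nrow(tr)]))
  cat(sprintf("  pivots evaluated: %g\n", object$result$pivots_evaluated))
  invisible(object)
}

#' @export
plot.smhg <- function(x, dims = c(1, 2), ...) {
  co <- x$cloud$coords
  graphics::plot(co[, dims[1]], co[, dims[2]], asp = 1,
                 col = ifelse(x$cloud$labels == 1, "red3", "grey60"),
                 pch = ifelse(x$cloud$labels == 1, 19, 1),
                 xlab = sprintf("dim %d", dims[1]),
                 ylab = sprintf("dim %d", dims[2]), ...)
  piv <- x$result$pivot
  graphics::points(piv[dims[1]], piv[dims[2]], pch = 4, cex = 2,
                   col = "darkgreen", lwd = 2)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(piv[dims[1]] + x$result$radius * cos(th),
                  piv[dims[2]] + x$result$radius * sin(th),
                  col = "darkgreen", lty = 2)
  invisible(x)
}

#' Run the full enrichment pipeline over annotation sets
#'
#' For each (non-rejected) annotation set: runs the grid and sampling
#' searches, the bead and genomic-order controls and the shuffle control,
#' then computes BH q-values across the family of sets per method.
#'
#' @param embedding an [embedding3d()].
#' @param annotations a named list of 0/1 label vectors or
#'   `"annotation_set"` objects.
#' @param dataset dataset identifier for the results table.
#' @param seed RNG seed.
#' @param n_shuffles shuffles for `P_sim`.
#' @param ... further arguments passed to [smhg()].
#' @return A results data frame (one row per set and method) as documented
#'   in [result_row()].
#' @export
smhg_run <- function(embedding, annotations, dataset = "dataset", seed = 1L,
                     n_shuffles = 100L, ...) {
  stopifnot(inherits(embedding, "embedding3d"))
  if (!is.list(annotations)) annotations <- list(set = annotations)
  rows <- list()
  for (nm in names(annotations)) {
    ann <- annotations[[nm]]
    if (inherits(ann, "annotation_set")) {
      if (ann$rejected) {
        message(sprintf("skipping rejected set '%s' (%s)", nm, ann$reason))
        next
      }
      ann <- ann$labels
    }
    cloud <- as_labeled_cloud(embedding, ann)
    fit <- smhg(cloud, method = "grid", controls = TRUE, seed = seed,
                n_shuffles = n_shuffles, ...)
    samp <- smhg_sample(cloud, seed = seed)
    rows[[length(rows) + 1L]] <-
      result_row(dataset, nm, fit$result, p_sim = fit$sim$p_sim, seed = seed)
    rows[[length(rows) + 1L]] <-
      result_row(dataset, nm, samp, p_sim = fit$sim$p_sim, seed = seed)
    rows[[length(rows) + 1L]] <- result_row(dataset, nm, fit$bead, seed = seed)
    if (!is.null(fit$one_d))
      for (ch in names(fit$one_d)) {
        r <- result_row(dataset, paste0(nm, ":", ch), fit$one_d[[ch]],
                        seed = seed)
        rows[[length(rows) + 1L]] <- r
      }
  }
  if (length(rows) == 0L) return(data.frame())
  res <- do.call(rbind, rows)
  # q-values: one BH family per method across annotation sets
  for (m in unique(res$method)) {
    sel <- res$method == m
    res$qvalue[sel] <- fdr_qvalues(res$pvalue[sel])
  }
  res
}
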