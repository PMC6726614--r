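#' Binned contact map
#'
#' A symmetric nonnegative matrix of contact read counts over genomic bins,
#' plus a bin table `(chrom, start, end)` ordered by (chrom, start).
#' Slight asymmetries (within `tol` relative) are symmetrised by averaging.
#'
#' @param counts square numeric matrix of nonnegative counts.
#' @param bins data frame with columns `chrom`, `start`, `end`, one row per
#'   matrix row; defaults to a single chromosome with unit bins.
#' @param resolution bin size in bp (metadata only).
#' @param tol relative symmetry tolerance.
#' @return An object of class `"contact_map"`.
#' @export
contact_map <- function(counts, bins = NULL, resolution = NULL, tol = 1e-8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative")
  asym <- max(abs(counts - t(counts)))
  if (asym > tol * max(1, max(counts)))
    stop("counts matrix is not symmetric")
  counts <- (counts + t(counts)) / 2
  n <- nrow(counts)
  if (is.null(bins)) {
    bins <- data.frame(chrom = rep("chr1", n), start = seq_len(n) - 1L,
                       end = seq_len(n))
  }
  if (nrow(bins) != n) stop("bin table must have one row per matrix row")
  stopifnot(all(c("chrom", "start", "end") %in% names(bins)))
  structure(list(counts = counts, bins = bins, resolution = resolution),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d bins, %d chromosome(s), %.3g total reads\n",
              nrow(x$counts), length(unique(x$bins$chrom)),
              sum(x$counts) / 2))
  invisible(x)
}

#' Map contact counts to dissimilarities
#'
#' A monotone-decreasing transform from counts to dissimilarities for
#' nonmetric embedding.  Zero-count pairs are marked missing (`NA`) and
#' excluded from the embedding stress rather than forced to the maximum
#' distance, since unobserved Hi-C pairs are censored, not maximal.
#' Nonmetric MDS depends only on ranks, so `"inverse"` and `"rank"` are
#' rank-equivalent.
#'
#' @param map a [contact_map()].
#' @param transform `"inverse"` (`(1+c)^-1`, default), `"rank"` (reversed
#'   count ranks) or `"power"` (`(1+c)^-alpha`).
#' @param alpha exponent for the `"power"` transform.
#' @return An object of class `"dissimilarity"`: list with `values`
#'   (symmetric matrix, `NA` for unobserved pairs, zero diagonal) and
#'   `bins`.
#' @export
counts_to_dissimilarity <- function(map,
                                    transform = c("inverse", "rank", "power"),
                                    alpha = 1) {
  stopifnot(inherits(map, "contact_map"))
  transform <- match.arg(transform)
  c0 <- map$counts
  n <- nrow(c0)
  off <- upper.tri(c0)
  if (all(c0[off] == 0)) stop("all-zero contact map")
  obs <- off & c0 > 0
  d <- matrix(NA_real_, n, n)
  if (transform == "rank") {
    d[obs] <- rank(-c0[obs])
    d[obs] <- d[obs] / max(d[obs])
  } else {
    a <- if (transform == "inverse") 1 else alpha
    v <- (1 + c0[obs])^(-a)
    rngv <- range(v)
    d[obs] <- if (rngv[2] > rngv[1])
      (v - rngv[1]) / (rngv[2] - rngv[1]) else v
  }
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  diag(d) <- 0
  structure(list(values = d, bins = map$bins), class = "dissimilarity")
}

#' sNMDS configuration
#'
#' @param n_dims embedding dimension (3 for the genomic pipeline).
#' @param nmds_max_iter maximum stress-minimisation iterations per NMDS fit.
#' @param smooth_z_threshold Z-score (in units of the pooled
#'   consecutive-bin distance distribution) above which a discrete
#'   derivative marks a discontinuity.
#' @param smooth_max_iter maximum smoothing rounds.
#' @param seed RNG seed (used only for degenerate initialisations).
#' @return A list of class `"snmds_config"`.
#' @export
snmds_config <- function(n_dims = 3L, nmds_max_iter = 500L,
                         smooth_z_threshold = 3, smooth_max_iter = 10L,
                         seed = 1L) {
  stopifnot(n_dims >= 1, nmds_max_iter >= 1, smooth_z_threshold > 0,
            smooth_max_iter >= 1)
  structure(list(n_dims = as.integer(n_dims),
                 nmds_max_iter = as.integer(nmds_max_iter),
                 smooth_z_threshold = smooth_z_threshold,
                 smooth_max_iter = as.integer(smooth_max_iter),
                 seed = as.integer(seed)),
            class = "snmds_config")
}

#' 3D embedding of genomic bins
#'
#' @param coords numeric matrix of embedded coordinates (unitless).
#' @param chrom,bin_index genomic metadata per bin.
#' @param stress final NMDS stress, if produced by an embedding fit.
#' @return An object of class `"embedding3d"`.
#' @export
embedding3d <- function(coords, chrom = NULL, bin_index = NULL,
                        stress = NA_real_) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) stop("embedding coordinates must be finite")
  n <- nrow(coords)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(bin_index))
    bin_index <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  structure(list(coords = coords, chrom = as.character(chrom),
                 bin_index = as.integer(bin_index), stress = stress),
            class = "embedding3d")
}

#' @export
print.embedding3d <- function(x, ...) {
  cat(sprintf("embedding3d: %d bins in %dD, %d chromosome(s)%s\n",
              nrow(x$coords), ncol(x$coords), length(unique(x$chrom)),
              if (is.na(x$stress)) "" else sprintf(", stress %.4g", x$stress)))
  invisible(x)
}

#' Nonmetric MDS embedding of a dissimilarity matrix
#'
#' Fits a `n_dims`-dimensional configuration minimising nonmetric stress
#' (monotone regression of embedded distances on dissimilarity ranks) via
#' [vegan::monoMDS()], deterministically initialised from classical scaling
#' of the (missing-imputed) dissimilarities unless `init` is given.
#' Missing dissimilarities are excluded from the stress.
#'
#' @param D a `"dissimilarity"` object, or a symmetric matrix with `NA` for
#'   missing pairs.
#' @param config an [snmds_config()].
#' @param init optional starting configuration (matrix).
#' @param chrom,bin_index genomic metadata (taken from `D$bins` when
#'   available).
#' @return An [embedding3d()] with the final stress; a warning (and attribute
#'   `converged = FALSE`) flags non-convergence.
#' @export
nmds_embed <- function(D, config = snmds_config(), init = NULL,
                       chrom = NULL, bin_index = NULL) {
  if (inherits(D, "dissimilarity")) {
    if (is.null(chrom) && !is.null(D$bins)) {
      chrom <- D$bins$chrom
      bin_index <- stats::ave(seq_len(nrow(D$values)), chrom, FUN = seq_along)
    }
    D <- D$values
  }
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 4L) stop("need at least 4 bins to embed")
  if (is.null(init)) {
    Dimp <- D
    mx <- max(D, na.rm = TRUE)
    Dimp[is.na(Dimp)] <- mx
    init <- stats::cmdscale(stats::as.dist(Dimp), k = config$n_dims)
    if (ncol(init) < config$n_dims) {
      pad <- with_seed(config$seed,
                       matrix(stats::rnorm(n * (config$n_dims - ncol(init)),
                                           sd = 1e-4), n))
      init <- cbind(init, pad)
    }
  }
  fit <- vegan::monoMDS(stats::as.dist(D), y = init, k = config$n_dims,
                        model = "global", maxit = config$nmds_max_iter)
  converged <- fit$icause != 4L  # 4 = iteration cap reached
  if (!converged)
    warning("NMDS did not converge within nmds_max_iter iterations")
  out <- embedding3d(unname(fit$points), chrom = chrom,
                     bin_index = bin_index, stress = fit$stress)
  attr(out, "converged") <- converged
  out
}

consecutive_derivatives <- function(emb) {
  out <- NULL
  for (ch in unique(emb$chrom)) {
    sel <- which(emb$chrom == ch)
    sel <- sel[order(emb$bin_index[sel])]
    if (length(sel) < 3L) next
    dd <- sqrt(rowSums((emb$coords[sel[-1], , drop = FALSE] -
                        emb$coords[sel[-length(sel)], , drop = FALSE])^2))
    out <- rbind(out, data.frame(chrom = ch, from = sel[-length(sel)],
                                 to = sel[-1], dist = dd))
  }
  out
}

#' Detect genomic-neighbour discontinuities in an embedding
#'
#' Computes the distances between genomically consecutive bins (the discrete
#' derivative) within each chromosome, Z-scores them against the pooled
#' distribution of all consecutive distances, and flags the bins flanking
#' any derivative with `Z > z_threshold`.  Chromosomes with fewer than 3
#' bins are skipped; a zero-variance derivative distribution yields no
#' outliers.
#'
#' @param emb an [embedding3d()].
#' @param z_threshold outlier threshold in Z units.
#' @return Sorted integer vector of flagged bin indices (rows of
#'   `emb$coords`).
#' @export
detect_discontinuities <- function(emb, z_threshold = 3) {
  stopifnot(inherits(emb, "embedding3d"), z_threshold > 0)
  der <- consecutive_derivatives(emb)
  if (is.null(der) || nrow(der) < 2L) return(integer(0))
  s <- stats::sd(der$dist)
  if (!is.finite(s) || s == 0) return(integer(0))
  z <- (der$dist - mean(der$dist)) / s
  bad <- z > z_threshold
  sort(unique(c(der$from[bad], der$to[bad])))
}

#' Correct flagged bins by linear interpolation
#'
#' Each flagged bin is replaced by linear interpolation between its nearest
#' non-flagged genomic neighbours on the same chromosome; runs of
#' consecutive flagged bins are spaced evenly along the neighbour segment,
#' and chromosome-terminal runs are extrapolated from the two nearest valid
#' bins.  A chromosome whose bins are all flagged is left unchanged with a
#' warning.
#'
#' @param emb an [embedding3d()].
#' @param outliers integer indices of flagged bins (as returned by
#'   [detect_discontinuities()]).
#' @return The corrected [embedding3d()].
#' @export
interpolate_outliers <- function(emb, outliers) {
  stopifnot(inherits(emb, "embedding3d"))
  outliers <- as.integer(outliers)
  if (length(outliers) == 0L) return(emb)
  if (any(outliers < 1L | outliers > nrow(emb$coords)))
    stop("outlier index out of bounds")
  coords <- emb$coords
  for (ch in unique(emb$chrom)) {
    sel <- which(emb$chrom == ch)
    sel <- sel[order(emb$bin_index[sel])]
    flag <- sel %in% outliers
    if (!any(flag)) next
    if (all(flag)) {
      warning(sprintf("all bins flagged on chromosome %s; left unchanged", ch))
      next
    }
    nsel <- length(sel)
    runs <- rle(flag)
    pos <- cumsum(c(1L, runs$lengths))
    for (ri in which(runs$values)) {
      a <- pos[ri]                 # first flagged position in sel
      b <- pos[ri + 1L] - 1L       # last flagged position
      len <- b - a + 1L
      left <- a - 1L
      right <- b + 1L
      if (left >= 1L && right <= nsel) {
        p0 <- coords[sel[left], ]
        p1 <- coords[sel[right], ]
        for (j in seq_len(len)) {
          t <- j / (len + 1)
          coords[sel[a + j - 1L], ] <- p0 + t * (p1 - p0)
        }
      } else if (right <= nsel - 1L) {        # run touches chromosome start
        p1 <- coords[sel[right], ]
        step <- coords[sel[right + 1L], ] - p1
        for (j in seq_len(len))
          coords[sel[b - j + 1L], ] <- p1 - j * step
      } else if (left >= 2L) {                # run touches chromosome end
        p0 <- coords[sel[left], ]
        step <- p0 - coords[sel[left - 1L], ]
        for (j in seq_len(len))
          coords[sel[a + j - 1L], ] <- p0 + j * step
      }
    }
  }
  embedding3d(coords, chrom = emb$chrom, bin_index = emb$bin_index,
              stress = emb$stress)
}

#' Smoothed nonmetric MDS (sNMDS) of a contact map
#'
#' The embedding pipeline: map counts to dissimilarities, fit an NMDS
#' configuration, then iteratively detect genomic-neighbour discontinuities,
#' correct them by linear interpolation, and refit the NMDS initialised at
#' the corrected configuration.  Iteration stops when no discontinuity is
#' found, when the flagged set stops changing, or at `smooth_max_iter`
#' rounds; in the latter two cases a final interpolation pass leaves the
#' returned configuration free of flagged derivatives.
#'
#' @param map a [contact_map()].
#' @param config an [snmds_config()].
#' @param transform,alpha passed to [counts_to_dissimilarity()].
#' @return An object of class `"snmds"` (also an `"embedding3d"`), with
#'   additional fields `n_smooth_iter`, `outlier_history` (flagged counts
#'   per round) and `hit_iteration_cap`.
#' @export
snmds <- function(map, config = snmds_config(),
                  transform = c("inverse", "rank", "power"), alpha = 1) {
  stopifnot(inherits(map, "contact_map"))
  D <- counts_to_dissimilarity(map, transform = match.arg(transform),
                               alpha = alpha)
  emb <- nmds_embed(D, config)
  history <- integer(0)
  prev <- NULL
  hit_cap <- FALSE
  for (it in seq_len(config$smooth_max_iter)) {
    out <- detect_discontinuities(emb, config$smooth_z_threshold)
    history <- c(history, length(out))
    if (length(out) == 0L) break
    emb <- interpolate_outliers(emb, out)
    stalled <- !is.null(prev) && identical(prev, out)
    prev <- out
    if (it == config$smooth_max_iter || stalled) {
      # the contact data would re-create the same discontinuities; keep
      # the interpolated (smooth) configuration
      hit_cap <- it == config$smooth_max_iter
      break
    }
    emb <- suppressWarnings(nmds_embed(D, config, init = emb$coords))
  }
  # Interpolation tightens the pooled derivative distribution, which can
  # push previously marginal derivatives over the threshold; iterate the
  # coordinate-only correction to a fixed point.
  cleanup <- 0L
  repeat {
    out <- detect_discontinuities(emb, config$smooth_z_threshold)
    if (length(out) == 0L || cleanup >= 20L) break
    emb <- interpolate_outliers(emb, out)
    cleanup <- cleanup + 1L
  }
  emb$n_smooth_iter <- length(history)
  emb$outlier_history <- history
  emb$cleanup_passes <- cleanup
  emb$hit_iteration_cap <- hit_cap || length(out) > 0L
  class(emb) <- c("snmds", class(emb))
  emb
}

#' @export
print.snmds <- function(x, ...) {
  cat(sprintf(
    "sNMDS embedding: %d bins, stress %.4g, %d smoothing round(s) [%s]\n",
    nrow(x$coords), x$stress, x$n_smooth_iter,
    paste(x$outlier_history, collapse = ", ")))
  invisible(x)
}

#' Procrustes alignment of two embeddings
#'
#' Finds the similarity transform (rotation, optional reflection, optional
#' isotropic scale, translation) of `mov` minimising the sum of squared
#' distances to `ref`, for comparing embeddings across conditions or time
#' points.
#'
#' @param ref,mov [embedding3d()] objects with identical bin count/order.
#' @param scale allow isotropic rescaling.
#' @param allow_reflection if `FALSE` the rotation is constrained to be
#'   proper (determinant +1).
#' @return The transformed `mov` embedding, with attributes `disparity`
#'   (residual sum of squares), `rotation` and `scale`.
#' @export
procrustes_align <- function(ref, mov, scale = TRUE, allow_reflection = TRUE) {
  stopifnot(inherits(ref, "embedding3d"), inherits(mov, "embedding3d"))
  X <- ref$coords
  Y <- mov$coords
  if (!all(dim(X) == dim(Y)) || !identical(ref$chrom, mov$chrom) ||
      !identical(ref$bin_index, mov$bin_index))
    stop("embeddings must share bin count and order")
  cx <- colMeans(X)
  cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx)
  Y0 <- sweep(Y, 2, cy)
  sv <- svd(crossprod(Y0, X0))
  sgn <- rep(1, length(sv$d))
  Q <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(Q) < 0) {
    sgn[length(sgn)] <- -1
    Q <- sv$u %*% diag(sgn) %*% t(sv$v)
  }
  s <- if (scale) sum(sv$d * sgn) / sum(Y0^2) else 1
  aligned <- s * Y0 %*% Q
  disparity <- sum((X0 - aligned)^2)
  out <- embedding3d(sweep(aligned, 2, -cx), chrom = mov$chrom,
                     bin_index = mov$bin_index, stress = mov$stress)
  attr(out, "disparity") <- disparity
  attr(out, "rotation") <- Q
  attr(out, "scale") <- s
  out
}
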