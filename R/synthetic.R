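#' Specification for synthetic multi-chromosome test data
#'
#' Defines the conditions emulated by the generators: a nuclear-confined
#' multi-chromosome polymer, distance-decay Poisson contact counts, and a
#' planted co-localization hotspot.  Defaults model a small unicellular
#' genome at desk scale: 4 chromosomes of 50 bins, unit step, decay
#' exponent 1 (mild decay preserves long-range ordinal signal for the
#' embedding), sequencing depth 1e6 expected read pairs, and a hotspot of
#' 12 positive bins with no stray positives.
#'
#' @param n_chrom number of chromosomes.
#' @param bins_per_chrom bins per chromosome.
#' @param step random-walk step standard deviation (embedding units).
#' @param alpha contact distance-decay exponent (counts ~ distance^-alpha).
#' @param depth expected total read pairs in a generated contact map.
#' @param n_positive_inside,n_positive_outside planted '1' labels inside and
#'   outside the hotspot ball.
#' @param hotspot_radius ball radius; `NULL` (default) uses the distance
#'   from the hotspot center to its `2 * n_positive_inside`-th nearest bin,
#'   so the planted bins occupy about half the ball.
#' @param seed RNG seed.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_chrom = 4L, bins_per_chrom = 50L, step = 1,
                           alpha = 1, depth = 1e6, n_positive_inside = 12L,
                           n_positive_outside = 0L, hotspot_radius = NULL,
                           seed = 1L) {
  stopifnot(n_chrom >= 1, bins_per_chrom >= 2, step > 0, alpha > 0,
            depth > 0, n_positive_inside >= 0, n_positive_outside >= 0,
            is.null(hotspot_radius) || hotspot_radius > 0)
  structure(list(n_chrom = as.integer(n_chrom),
                 bins_per_chrom = as.integer(bins_per_chrom), step = step,
                 alpha = alpha, depth = depth,
                 n_positive_inside = as.integer(n_positive_inside),
                 n_positive_outside = as.integer(n_positive_outside),
                 hotspot_radius = hotspot_radius, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a smoothed confined random-walk polymer
#'
#' Per chromosome: the bin-to-bin *directions* come from a Gaussian random
#' walk smoothed by a 5-bin moving average (partial windows at the ends),
#' and the bond lengths are redrawn as `step` times a bounded uniform
#' jitter in \[0.9, 1.1\].  The bounded bonds keep the consecutive-bin
#' distance distribution tight (its spread never reaches the Z = 3
#' discontinuity threshold), so in round-trip experiments every detected
#' discontinuity is an injected one.  Each chromosome is centred and
#' placed at a territory center drawn uniformly from a ball of radius
#' `step * sqrt(bins_per_chrom)`.  Deterministic per seed.
#'
#' @param spec a [synthetic_spec()].
#' @return An [embedding3d()] ground-truth configuration with per-bin
#'   `chrom` and `bin_index`.
#' @export
generate_polymer <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nb <- spec$bins_per_chrom
  conf_r <- spec$step * sqrt(nb)
  with_seed(spec$seed, {
    coords <- NULL
    for (k in seq_len(spec$n_chrom)) {
      steps <- matrix(stats::rnorm(3L * nb, sd = spec$step), nb, 3L)
      path <- apply(steps, 2, cumsum)
      sm <- apply(path, 2, function(x)
        vapply(seq_len(nb),
               function(i) mean(x[max(1L, i - 2L):min(nb, i + 2L)]),
               numeric(1)))
      dirs <- diff(sm)
      lens <- sqrt(rowSums(dirs^2))
      lens[lens < 1e-12] <- 1e-12
      bond <- spec$step * stats::runif(nb - 1L, 0.9, 1.1)
      pos <- apply(rbind(0, dirs / lens * bond), 2, cumsum)
      pos <- sweep(pos, 2, colMeans(pos))
      u <- stats::rnorm(3L)
      center <- u / sqrt(sum(u^2)) * conf_r * stats::runif(1)^(1 / 3)
      coords <- rbind(coords, sweep(pos, 2, -center))
    }
    embedding3d(coords,
                chrom = rep(sprintf("chr%d", seq_len(spec$n_chrom)),
                            each = nb),
                bin_index = rep(seq_len(nb), spec$n_chrom))
  })
}

#' Generate a Poisson distance-decay contact map from a configuration
#'
#' Counts between bins i, j are drawn as
#' `Poisson(k * d_ij^-alpha)` with `k` calibrated so the expected total
#' read-pair count equals `depth`; the matrix is symmetric with a zero
#' diagonal.
#'
#' @param truth an [embedding3d()] ground-truth configuration.
#' @param alpha distance-decay exponent.
#' @param depth expected total read pairs.
#' @param seed RNG seed.
#' @param resolution bin size metadata (bp).
#' @return A [contact_map()].
#' @export
generate_contact_map <- function(truth, alpha = 1, depth = 1e6, seed = 1L,
                                 resolution = 1e4) {
  stopifnot(inherits(truth, "embedding3d"), alpha > 0, depth > 0)
  dmat <- as.matrix(stats::dist(truth$coords))
  n <- nrow(dmat)
  up <- upper.tri(dmat)
  w <- dmat[up]^(-alpha)
  k <- depth / sum(w)
  counts <- matrix(0, n, n)
  counts[up] <- with_seed(seed, stats::rpois(sum(up), k * w))
  counts <- counts + t(counts)
  bins <- data.frame(chrom = truth$chrom,
                     start = (truth$bin_index - 1L) * resolution,
                     end = truth$bin_index * resolution)
  contact_map(counts, bins = bins, resolution = resolution)
}

#' Plant a co-localization hotspot in a configuration
#'
#' Labels `n_positive_inside` bins drawn uniformly from the ball of radius
#' `radius` around `center`, plus `n_positive_outside` bins drawn uniformly
#' from the rest; all other labels are 0.
#'
#' @param truth an [embedding3d()].
#' @param n_inside,n_outside positive labels inside / outside the ball.
#' @param radius ball radius; `NULL` uses the distance from `center` to its
#'   `2 * n_inside`-th nearest bin.
#' @param center ball center; `NULL` picks a seeded random bin's position.
#' @param seed RNG seed.
#' @return List with `labels` (0/1 per bin), `center`, `radius`,
#'   `inside` (indices of bins within the ball) and `cloud` (the resulting
#'   [labeled_cloud()]).
#' @export
plant_hotspot <- function(truth, n_inside = 12L, n_outside = 0L,
                          radius = NULL, center = NULL, seed = 1L) {
  stopifnot(inherits(truth, "embedding3d"), n_inside >= 0, n_outside >= 0)
  n <- nrow(truth$coords)
  with_seed(seed, {
    if (is.null(center))
      center <- truth$coords[sample.int(n, 1L), ]
    center <- as.numeric(center)
    d <- sqrt(colSums((t(truth$coords) - center)^2))
    if (is.null(radius))
      radius <- sort(d)[min(n, max(2L * n_inside, 2L))]
    inside <- which(d <= radius)
    if (length(inside) < n_inside)
      stop("infeasible hotspot: fewer bins inside the ball than n_inside")
    outside <- setdiff(seq_len(n), inside)
    if (length(outside) < n_outside)
      stop("infeasible hotspot: fewer bins outside the ball than n_outside")
    labels <- integer(n)
    labels[sample(inside, n_inside)] <- 1L
    if (n_outside > 0L) labels[sample(outside, n_outside)] <- 1L
    list(labels = labels, center = center, radius = radius, inside = inside,
         cloud = as_labeled_cloud(truth, labels))
  })
}

#' Inject teleportation discontinuities into an embedding
#'
#' Displaces `k` randomly chosen non-adjacent interior bins by `magnitude`
#' in a random direction, emulating the embedding artefacts that sNMDS
#' smoothing corrects.  Non-adjacency keeps interpolation well posed.
#'
#' @param emb an [embedding3d()].
#' @param k number of bins to displace (`k <` bin count).
#' @param magnitude displacement length; default 10 times the median
#'   consecutive-bin distance.
#' @param seed RNG seed.
#' @return The corrupted [embedding3d()], with attribute `displaced` (the
#'   chosen bin indices).
#' @export
inject_discontinuities <- function(emb, k, magnitude = NULL, seed = 1L) {
  stopifnot(inherits(emb, "embedding3d"), k >= 0)
  n <- nrow(emb$coords)
  if (k >= n) stop("k must be smaller than the number of bins")
  if (k == 0L) return(emb)
  der <- consecutive_derivatives(emb)
  if (is.null(magnitude))
    magnitude <- 10 * stats::median(der$dist)
  interior <- which(stats::ave(seq_len(n), emb$chrom, FUN = function(i)
    seq_along(i) > 1 & seq_along(i) < length(i)) == 1)
  with_seed(seed, {
    chosen <- integer(0)
    pool <- interior
    while (length(chosen) < k && length(pool) > 0L) {
      pick <- pool[sample.int(length(pool), 1L)]
      chosen <- c(chosen, pick)
      pool <- setdiff(pool, (pick - 1L):(pick + 1L))
    }
    if (length(chosen) < k)
      stop("could not place k non-adjacent interior discontinuities")
    coords <- emb$coords
    if (magnitude > 0) {
      for (i in chosen) {
        u <- stats::rnorm(ncol(coords))
        coords[i, ] <- coords[i, ] + u / sqrt(sum(u^2)) * magnitude
      }
    }
    out <- embedding3d(coords, chrom = emb$chrom, bin_index = emb$bin_index,
                       stress = emb$stress)
    attr(out, "displaced") <- sort(chosen)
    out
  })
}
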