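make_helix <- function(n = 60, chrom = "chr1") {
  t <- seq(0, 6 * pi, length.out = n)
  embedding3d(cbind(cos(t), sin(t), t / 6), chrom = rep(chrom, n),
              bin_index = seq_len(n))
}

test_that("count transforms are monotone and censor unobserved pairs", {
  counts <- rbind(c(0, 0, 1), c(0, 0, 3), c(1, 3, 0))
  map <- contact_map(counts)
  d <- counts_to_dissimilarity(map)$values
  expect_true(is.na(d[1, 2]))
  expect_lt(d[2, 3], d[1, 3])  # higher count -> smaller dissimilarity
  expect_equal(diag(d), rep(0, 3))
  dr <- counts_to_dissimilarity(map, transform = "rank")$values
  expect_equal(order(dr[upper.tri(dr)][!is.na(dr[upper.tri(dr)])]),
               order(-counts[upper.tri(counts)][counts[upper.tri(counts)] > 0]))
  expect_error(counts_to_dissimilarity(contact_map(matrix(0, 3, 3))),
               "all-zero")
  expect_error(contact_map(rbind(c(0, 1), c(2, 0))), "symmetric")
})

test_that("NMDS recovers a line exactly and a 3D shape up to similarity", {
  x <- seq(0, 10, length.out = 20)
  D <- as.matrix(dist(x))
  emb <- nmds_embed(D, snmds_config())
  expect_lt(emb$stress, 1e-3)
  expect_true(all(diff(order(emb$coords[, 1])) == 1) ||
              all(diff(order(emb$coords[, 1])) == -1))

  truth <- make_helix(40)
  emb2 <- nmds_embed(as.matrix(dist(truth$coords)), snmds_config())
  al <- procrustes_align(truth, emb2)
  rmsd <- sqrt(attr(al, "disparity") / 40)
  expect_lt(rmsd, 0.05 * max(dist(truth$coords)))

  expect_error(nmds_embed(as.matrix(dist(1:3))), "at least 4")
})

test_that("discontinuity detection flags teleported bins and only those", {
  helix <- make_helix(60)
  expect_length(detect_discontinuities(helix, 3), 0)
  # uniform line: zero-variance derivatives, no outliers
  line <- embedding3d(cbind(1:20, 0, 0))
  expect_length(detect_discontinuities(line, 3), 0)
  # teleport one interior bin far away
  bad <- helix
  bad$coords[30, ] <- bad$coords[30, ] + c(30, 0, 0)
  out <- detect_discontinuities(bad, 3)
  expect_true(30 %in% out)
  expect_true(all(out %in% 29:31))
})

test_that("interpolation restores runs linearly and handles edge cases", {
  line <- embedding3d(rbind(c(0, 0, 0), c(5, 5, 5), c(2, 0, 0)))
  fixed <- interpolate_outliers(line, 2L)
  expect_equal(fixed$coords[2, ], c(1, 0, 0))
  # identity on empty outlier set
  expect_equal(interpolate_outliers(line, integer(0))$coords, line$coords)
  # a run of two consecutive outliers is evenly spaced on the segment
  seg <- embedding3d(rbind(c(0, 0, 0), c(9, 1, 1), c(-4, 2, 2), c(3, 0, 0)))
  fx <- interpolate_outliers(seg, c(2L, 3L))
  expect_equal(fx$coords[2, ], c(1, 0, 0))
  expect_equal(fx$coords[3, ], c(2, 0, 0))
  # terminal outlier: extrapolated from the two nearest valid bins
  fx2 <- interpolate_outliers(embedding3d(rbind(c(9, 9, 9), c(1, 0, 0),
                                                c(2, 0, 0))), 1L)
  expect_equal(fx2$coords[1, ], c(0, 0, 0))
  expect_warning(
    interpolate_outliers(embedding3d(matrix(rnorm(9), 3, 3)), 1:3),
    "left unchanged")
})

test_that("sNMDS removes injected discontinuities and preserves ordinality", {
  spec <- synthetic_spec(n_chrom = 2, bins_per_chrom = 50, seed = 8)
  truth <- generate_polymer(spec)
  corrupt <- inject_discontinuities(truth, k = 4, seed = 8)
  expect_gt(length(detect_discontinuities(corrupt, 3)), 0)
  map <- generate_contact_map(corrupt, depth = 1e6, seed = 8)
  emb <- snmds(map)
  expect_length(detect_discontinuities(emb, 3), 0)
  sp <- cor(as.vector(dist(truth$coords)), as.vector(dist(emb$coords)),
            method = "spearman")
  expect_gt(sp, 0.8)
  # an already-smooth map needs no corrections
  map2 <- generate_contact_map(truth, depth = 1e6, seed = 9)
  emb2 <- snmds(map2)
  expect_equal(emb2$outlier_history[1], 0L)
  expect_equal(emb2$n_smooth_iter, 1L)
})

test_that("sNMDS is deterministic given its configuration", {
  spec <- synthetic_spec(n_chrom = 1, bins_per_chrom = 40, seed = 2)
  map <- generate_contact_map(generate_polymer(spec), seed = 2)
  e1 <- snmds(map)
  e2 <- snmds(map)
  expect_identical(e1$coords, e2$coords)
})

test_that("Procrustes alignment matches vegan and handles reflection", {
  truth <- make_helix(30)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mov <- embedding3d(truth$coords %*% R * 1.7 + 3, chrom = truth$chrom,
                     bin_index = truth$bin_index)
  al <- procrustes_align(truth, mov)
  expect_lt(attr(al, "disparity"), 1e-16 * sum(truth$coords^2) + 1e-10)
  expect_equal(al$coords, truth$coords, tolerance = 1e-6)

  # independent cross-check of the optimum against vegan
  set.seed(20)
  A <- matrix(rnorm(90), 30, 3)
  Bm <- matrix(rnorm(90), 30, 3)
  ea <- embedding3d(A); eb <- embedding3d(Bm)
  ours <- procrustes_align(ea, eb)
  veg <- vegan::procrustes(A, Bm, scale = TRUE, symmetric = FALSE)
  expect_equal(attr(ours, "disparity"), veg$ss, tolerance = 1e-8)

  # a reflected copy is exact only when reflections are allowed
  mirror <- embedding3d(truth$coords %*% diag(c(1, 1, -1)),
                        chrom = truth$chrom, bin_index = truth$bin_index)
  al_ref <- procrustes_align(truth, mirror, allow_reflection = TRUE)
  al_rot <- procrustes_align(truth, mirror, allow_reflection = FALSE)
  expect_lt(attr(al_ref, "disparity"), 1e-10)
  expect_gt(attr(al_rot, "disparity"), 1)
  expect_gte(det(attr(al_rot, "rotation")), 0)

  # disparity grows with added noise
  set.seed(4)
  disp <- vapply(c(0.01, 0.1, 0.5), function(s) {
    noisy <- embedding3d(truth$coords + matrix(rnorm(90, sd = s), 30, 3),
                         chrom = truth$chrom, bin_index = truth$bin_index)
    attr(procrustes_align(truth, noisy), "disparity")
  }, numeric(1))
  expect_true(all(diff(disp) > 0))
  expect_error(procrustes_align(truth, embedding3d(matrix(rnorm(30), 10, 3))),
               "share bin count")
})
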