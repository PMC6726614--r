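test_that("the symmetric two-row construct defeats bead pivots only", {
  cl <- two_row_cloud()
  bead <- bead_control(cl)
  grid <- smhg_grid(cl, budget = 2e4)
  # a mid-gap pivot captures both positive clusters at once; no bead can
  expect_lt(grid$score, bead$score)
  expect_lt(grid$pvalue, bead$pvalue)
  mid <- score_pivot(c(1, 2), cl)
  expect_lt(mid$score, bead$score)
  expect_equal(mid$b_at_threshold, 6)
})

test_that("bead control handles a single point and nests above the grid", {
  cl1 <- labeled_cloud(matrix(c(0, 0), 1, 2), 1)
  expect_equal(bead_control(cl1)$score, 1)
  cl <- rand_cloud(25, 6, d = 3, seed = 77)
  expect_gte(bead_control(cl)$score,
             smhg_grid(cl, budget = 2e4)$score - 1e-12)
})

test_that("1D control recovers genomic runs and matches closed forms", {
  set.seed(10)
  co <- matrix(rnorm(60), 20, 3)
  # contiguous run of 4 positives: perfect prefix from a run-center bead
  lab <- c(rep(0, 8), rep(1, 4), rep(0, 8))
  cl <- labeled_cloud(co, lab, chrom = rep("chr1", 20), bin_index = 1:20)
  od <- genomic_1d_control(cl)
  expect_equal(od$chr1$score, 1 / choose(20, 4), tolerance = 1e-12)
  # alternating labels: no prefix enrichment beyond chance
  lab2 <- rep(c(1, 0), 10)
  cl2 <- labeled_cloud(co, lab2, chrom = rep("chr1", 20), bin_index = 1:20)
  expect_gt(genomic_1d_control(cl2)$chr1$score, 0.1)
})

test_that("1D control equals bead control on a uniform straight line", {
  co <- cbind(1:15, 0)
  set.seed(2)
  lab <- sample(c(rep(1, 5), rep(0, 10)))
  cl <- labeled_cloud(co, lab, chrom = rep("chr1", 15), bin_index = 1:15)
  expect_equal(genomic_1d_control(cl)$chr1$score, bead_control(cl)$score,
               tolerance = 1e-12)
})

test_that("1D control is computed per chromosome with local N and B", {
  cl <- two_row_cloud()
  od <- genomic_1d_control(cl)
  expect_named(od, c("chrA", "chrB"))
  expect_equal(od$chrA$N, 10)
  expect_equal(od$chrA$B, 3)
  # contiguous run of 3 at the chromosome start
  expect_equal(od$chrA$score, 1 / choose(10, 3), tolerance = 1e-12)
})

test_that("shuffle control follows the add-one empirical convention", {
  # with a single positive, every shuffle ties the observed statistic
  set.seed(1)
  cl <- labeled_cloud(matrix(rnorm(30), 15, 2), c(1, rep(0, 14)))
  sim <- simulation_control(cl, n_shuffles = 1, seed = 2,
                            grid_budget = 200, sample_max_tuples = 100)
  expect_equal(sim$p_sim, 1)
  expect_equal(sim$r, 1)
  # a planted tight hotspot is beaten by no shuffle
  spec <- synthetic_spec(n_chrom = 1, bins_per_chrom = 60, seed = 3)
  truth <- generate_polymer(spec)
  hs <- plant_hotspot(truth, n_inside = 8, seed = 3)
  sim2 <- simulation_control(hs$cloud, n_shuffles = 30, seed = 3,
                             grid_budget = 300, sample_max_tuples = 300)
  expect_equal(sim2$r, 0)
  expect_equal(sim2$p_sim, 1 / 31)
  expect_match(sim2$display, "<")
})

test_that("assignment permutation test detects planted clusters and is exact
           in degenerate cases", {
  set.seed(12)
  co <- rbind(matrix(rnorm(16, sd = 0.05), 8, 2),
              matrix(rnorm(64, sd = 3), 32, 2))
  cl <- labeled_cloud(co, rep(0, 40))
  p <- assignment_permutation_test(cl, 1:8, 1:40, n_perm = 500, seed = 4)$p
  expect_lte(p, 2 / 501)
  # positives occupying all candidates: the null is a point mass
  p2 <- assignment_permutation_test(cl, 1:5, 1:5, n_perm = 100, seed = 4)$p
  expect_equal(p2, 1)
  expect_error(assignment_permutation_test(cl, 1:3, 4:10, n_perm = 10),
               "subset")
  expect_error(assignment_permutation_test(cl, 5, 1:10), "at least two")
})

test_that("cross-set proximity test flags nearest neighbours, degenerates to 1", {
  set.seed(13)
  co <- rbind(matrix(rnorm(12, sd = 0.1), 6, 2),
              matrix(rnorm(12, sd = 0.1) + 0.2, 6, 2),
              matrix(rnorm(56, sd = 4), 28, 2))
  cl <- labeled_cloud(co, rep(0, 40))
  p <- cross_set_proximity_test(cl, 1:6, 7:12, n_perm = 500, seed = 5)$p
  expect_lte(p, 5 / 501)
  # the "other" set exhausting the pool is a point mass
  p2 <- cross_set_proximity_test(cl, 1:6, 7:40, n_perm = 50, seed = 5)$p
  expect_equal(p2, 1)
  expect_error(cross_set_proximity_test(cl, 1:39, 40, other_set_size = 5),
               "insufficient")
})
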