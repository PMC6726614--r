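test_that("genome binning tiles chromosomes half-open", {
  bins <- genome_binning(c(chr1 = 25, chr2 = 10), bin_size = 10)
  expect_equal(nrow(bins), 4)
  expect_equal(bins$start, c(0, 10, 20, 0))
  expect_equal(bins$end, c(10, 20, 25, 10))
})

test_that("annotations map to bins by any-overlap and apply the B >= 4 filter", {
  bins <- genome_binning(c(chr1 = 100), bin_size = 10)
  # three genes in three distinct bins: rejected
  iv <- data.frame(chrom = "chr1", start = c(1, 21, 41), end = c(5, 25, 45))
  ann <- map_annotation_to_bins(iv, bins)
  expect_true(ann$rejected)
  expect_equal(ann$B, 3)
  expect_match(ann$reason, "< 4")
  # a gene spanning a bin boundary labels both bins
  iv2 <- data.frame(chrom = "chr1", start = 8, end = 12)
  ann2 <- map_annotation_to_bins(iv2, bins, min_positive = 1)
  expect_equal(which(ann2$labels == 1), c(1, 2))
  # two genes in one bin still yield a single positive bin
  iv3 <- data.frame(chrom = "chr1", start = c(1, 3), end = c(2, 6))
  expect_equal(map_annotation_to_bins(iv3, bins, min_positive = 1)$B, 1)
  # intervals on unknown chromosomes are skipped with a warning
  iv4 <- data.frame(chrom = c("chr1", "chrX"), start = c(1, 1),
                    end = c(95, 5))
  expect_warning(ann4 <- map_annotation_to_bins(iv4, bins, min_positive = 1),
                 "unknown")
  expect_equal(ann4$B, 10)
  # idempotent and order-independent
  ivs <- data.frame(chrom = "chr1", start = c(55, 1, 31, 71),
                    end = c(58, 5, 35, 75))
  a1 <- map_annotation_to_bins(ivs, bins)
  a2 <- map_annotation_to_bins(ivs[sample(4), ], bins)
  expect_identical(a1$labels, a2$labels)
  expect_false(a1$rejected)
})

test_that("CGH binarization masks thin bins and flags high outliers", {
  bins <- genome_binning(c(chr1 = 100), bin_size = 10)
  # 25 probes per bin in bins 1..8, 19 probes in bin 9, none in bin 10
  probes <- do.call(rbind, lapply(1:9, function(b) {
    np <- if (b == 9) 19 else 25
    data.frame(chrom = "chr1",
               position = (b - 1) * 10 + (seq_len(np) - 1) %% 10,
               value = 0)
  }))
  probes$value <- 0
  # shift bin 3 strongly upward
  probes$value[probes$position >= 20 & probes$position < 30] <- 5
  cg <- binarize_cgh(probes, bins)
  expect_false(cg$kept[9])   # 19 probes < 20
  expect_false(cg$kept[10])
  expect_equal(which(cg$labels == 1), 3)
  expect_equal(cg$n_probes[9], 19)
  # equal values everywhere: nothing exceeds mu + 2 sigma
  probes$value <- 1
  cg2 <- binarize_cgh(probes, bins)
  expect_equal(sum(cg2$labels), 0)
  # the label count matches an independent recomputation
  set.seed(6)
  probes$value <- rnorm(nrow(probes))
  cg3 <- binarize_cgh(probes, bins)
  v <- cg3$values[cg3$kept]
  expect_equal(sum(cg3$labels), sum(v > mean(v) + 2 * sd(v)))
})

test_that("differential contact labels respect the diagonal band and symmetry", {
  set.seed(15)
  n <- 40
  base <- matrix(rpois(n * n, 20), n, n)
  base <- base + t(base)
  diag(base) <- 0
  bins <- genome_binning(c(chr1 = n * 10), bin_size = 10)
  ref <- contact_map(base, bins)
  # identical maps: zero distances everywhere, no labels
  expect_equal(sum(differential_hic_labels(ref, ref)), 0)
  # perturb the near-diagonal band around locus 20
  pert <- base
  for (j in 15:25) {
    if (abs(20 - j) <= 5 && j != 20) {
      pert[20, j] <- pert[20, j] + 200
      pert[j, 20] <- pert[20, j]
    }
  }
  var <- contact_map(pert, bins)
  lab <- differential_hic_labels(ref, var)
  expect_equal(lab[20], 1L)
  # swapping REF and VAR gives the same labels
  expect_identical(lab, differential_hic_labels(var, ref))
  # perturbations outside the band are invisible
  pert2 <- base
  pert2[10, 17] <- pert2[10, 17] + 500  # |i - j| = 7 > 5
  pert2[17, 10] <- pert2[10, 17]
  lab2 <- differential_hic_labels(ref, contact_map(pert2, bins))
  expect_equal(lab2[10], 0L)
  expect_error(
    differential_hic_labels(ref,
                            contact_map(base[1:20, 1:20], bins[1:20, ])),
    "binning")
})

test_that("gene ids resolve to intervals by exact match", {
  gt <- data.frame(chrom = "chr1", start = c(0, 50), end = c(10, 60),
                   name = c("geneA", "geneB"))
  expect_warning(iv <- genes_to_intervals(c("geneB", "geneZ"), gt),
                 "not found")
  expect_equal(iv$start, 50)
})
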