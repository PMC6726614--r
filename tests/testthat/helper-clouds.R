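# Fixture builders shared across test files; everything is generated in
# code so the suite has no stored data.

# seeded uniform cloud in general position
rand_cloud <- function(N, B, d = 2, seed = 1, sd_labels = NULL) {
  set.seed(seed)
  co <- matrix(runif(N * d), N, d)
  lab <- sample(c(rep(1L, B), rep(0L, N - B)))
  labeled_cloud(co, lab)
}

# two parallel genomic "rows" with the positives clustered at one end of
# each row; the midpoint between the clusters is a better pivot than any
# bead (the construct that motivates off-bead pivots)
two_row_cloud <- function(n_per_row = 10, n_pos = 3, gap = 4) {
  co <- rbind(cbind(seq_len(n_per_row) - 1, 0),
              cbind(seq_len(n_per_row) - 1, gap))
  lab <- rep(c(rep(1L, n_pos), rep(0L, n_per_row - n_pos)), 2)
  labeled_cloud(co, lab,
                chrom = rep(c("chrA", "chrB"), each = n_per_row),
                bin_index = rep(seq_len(n_per_row), 2))
}

# brute-force mHG oracle: direct binomial arithmetic over all prefixes
brute_mhg <- function(labels) {
  N <- length(labels)
  B <- sum(labels)
  if (B == 0 || B == N) return(1)
  b_n <- cumsum(labels)
  min(vapply(seq_len(N), function(n) {
    i <- b_n[n]:min(n, B)
    sum(choose(n, i) * choose(N - n, B - i)) / choose(N, B)
  }, numeric(1)))
}

lambda_key <- function(pivot, cloud) {
  paste(rank_by_distance(pivot, cloud)$labels, collapse = "")
}

expect_search_equal <- function(a, b, tol = 1e-12) {
  expect_lt(abs(a$score - b$score), tol)
}
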