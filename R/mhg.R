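#' Hypergeometric tail probability of a ranked-prefix one-count
#'
#' Probability of observing at least `b` successes when a prefix of length
#' `n` is drawn from a population of `N` elements of which `B` are
#' successes, i.e. \eqn{\sum_{i=b}^{\min(n,B)} \binom{n}{i}\binom{N-n}{B-i} /
#' \binom{N}{B}}.  This is the per-prefix building block of the minimum
#' hypergeometric (mHG) statistic.  Computed through [stats::phyper()],
#' which works in log space and is stable for `N` well beyond 1e4.
#'
#' @param N population size (number of ranked elements).
#' @param B number of '1'-labelled elements in the population.
#' @param n prefix length, `0 <= n <= N`.
#' @param b observed number of '1's in the prefix, `0 <= b <= min(n, B)`.
#' @return The upper-tail probability, in (0, 1]. Vectorised over all
#'   arguments.
#' @examples
#' hypergeometric_tail(4, 2, 2, 2) # 1/6
#' @export
hypergeometric_tail <- function(N, B, n, b) {
  if (any(N < 0 | B < 0 | n < 0 | b < 0) ||
      any(B > N | n > N | b > pmin(n, B)))
    stop("invalid bounds: need 0 <= b <= min(n, B) <= N and B <= N")
  stats::phyper(b - 1, n, N - n, B, lower.tail = FALSE)
}

# Lookup table of hypergeometric tails; row n+1 = prefix length n (0..N),
# column b+1 = prefix one-count b (0..B).  Cells with b > min(n, B) are
# unreachable by any ranking and set to 1 so they never win a minimum.
mhg_tail_table <- function(N, B) {
  n <- rep(0:N, times = B + 1L)
  b <- rep(0:B, each = N + 1L)
  v <- stats::phyper(b - 1, n, N - n, B, lower.tail = FALSE)
  v[b > pmin(n, B)] <- 1
  matrix(v, N + 1L, B + 1L)
}

#' Minimum hypergeometric (mHG) statistic of a binary vector
#'
#' Scans every prefix of the ranked binary vector and reports the minimum
#' hypergeometric tail over prefix lengths `1..N`.  Degenerate vectors
#' (`B == 0` or `B == N`) score 1 at threshold 1 by convention.
#'
#' @param labels a vector of 0/1 labels in rank order.
#' @return A list of class `"mhg_result"` with elements `score` (the minimal
#'   tail), `threshold_n` (the smallest prefix length attaining it),
#'   `b_at_threshold`, `N` and `B`.
#' @examples
#' mhg_statistic(c(1, 1, 0, 0)) # score 1/6 at n = 2
#' @export
mhg_statistic <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) < 1L) stop("labels must have length >= 1")
  if (anyNA(labels) || any(labels != 0L & labels != 1L))
    stop("labels must be 0/1")
  N <- length(labels)
  B <- sum(labels)
  if (B == 0L || B == N) {
    res <- list(score = 1, threshold_n = 1L, b_at_threshold = labels[1L],
                N = N, B = B)
    class(res) <- "mhg_result"
    return(res)
  }
  b_n <- cumsum(labels)
  n <- seq_len(N)
  tails <- stats::phyper(b_n - 1, n, N - n, B, lower.tail = FALSE)
  i <- which.min(tails)
  res <- list(score = tails[i], threshold_n = i, b_at_threshold = b_n[i],
              N = N, B = B)
  class(res) <- "mhg_result"
  res
}

#' @export
print.mhg_result <- function(x, ...) {
  cat(sprintf("mHG: score %.4g at prefix n = %d (b = %d of B = %d, N = %d)\n",
              x$score, x$threshold_n, x$b_at_threshold, x$B, x$N))
  if (!is.null(x$pvalue)) cat(sprintf("exact corrected p-value: %.4g\n", x$pvalue))
  invisible(x)
}

#' Exact multiple-testing-corrected mHG p-value
#'
#' The probability, under uniform random placement of `B` ones among `N`
#' positions, that the mHG statistic is at most `s`.  Computed by the exact
#' lattice dynamic program over the (prefix length, prefix one-count) grid:
#' path probabilities are propagated and absorbed at cells whose
#' hypergeometric tail is `<= s`, so the complement of the surviving mass is
#' the corrected p-value.  Probabilities (not path counts) are carried, so
#' there is no overflow for large `N`; results are floating point.
#'
#' @param N number of ranked elements.
#' @param B number of '1' labels.
#' @param s an mHG score in (0, 1].
#' @return `P(mHG <= s)`, in \[0, 1\].
#' @examples
#' mhg_exact_pvalue(4, 2, 1 / 6) # exactly 1/6
#' @export
mhg_exact_pvalue <- function(N, B, s) {
  N <- as.integer(N); B <- as.integer(B)
  if (length(s) != 1L || !is.finite(s) || s <= 0)
    stop("invalid bounds: score s must lie in (0, 1]")
  if (N < 1L || B < 0L || B > N) stop("invalid bounds: need 0 <= B <= N")
  if (s >= 1) return(1)
  if (B == 0L || B == N) return(0)  # the statistic is constantly 1
  thr <- s * (1 + 1e-9)
  tails <- mhg_tail_table(N, B)
  prob <- c(1, rep(0, B))  # survival mass by prefix one-count (index b + 1)
  bb <- 0:B
  absorbed <- 0  # mass accumulated at significant cells; summing the
                 # absorbed side directly avoids the catastrophic
                 # cancellation of 1 - survival for tiny p-values
  for (n in seq_len(N)) {
    rem <- N - n + 1
    p1 <- (B - bb) / rem
    new <- prob * (1 - p1)
    new[-1L] <- new[-1L] + prob[-(B + 1L)] * p1[-(B + 1L)]
    bad <- tails[n + 1L, ] <= thr
    absorbed <- absorbed + sum(new[bad])
    new[bad] <- 0
    prob <- new
  }
  min(1, absorbed)
}

#' mHG statistic with its exact corrected p-value
#'
#' Convenience wrapper combining [mhg_statistic()] and
#' [mhg_exact_pvalue()].  Degenerate vectors return score 1, p-value 1.
#'
#' @inheritParams mhg_statistic
#' @return An `"mhg_result"` with an additional `pvalue` element.
#' @export
mhg_test <- function(labels) {
  res <- mhg_statistic(labels)
  res$pvalue <- if (res$B == 0L || res$B == res$N) 1
                else mhg_exact_pvalue(res$N, res$B, res$score)
  res
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment across a family of mHG p-values
#' (typically one per annotation set tested on one embedding).
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return Monotone q-values, each at least its p-value.
#' @export
fdr_qvalues <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
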