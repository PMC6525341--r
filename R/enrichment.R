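# Resampling-based category enrichment, its analytic hypergeometric
# counterpart, BH FDR, and the two-sample equality-of-proportions test.

#' Upper-tail hypergeometric probability
#'
#' Exact `P(X >= k)` when `n` items are drawn without replacement from a
#' population of `N` items of which `K` are successes. This is the analytic
#' counterpart of [permutation_enrichment()] and is used as its oracle in
#' tests.
#'
#' @param N Population size.
#' @param K Number of successes in the population.
#' @param n Draw size.
#' @param k Observed number of successes.
#' @return `P(X >= k)`.
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  assert_scalar_number(N, "N", min = 0)
  assert_scalar_number(K, "K", min = 0, max = N)
  assert_scalar_number(n, "n", min = 0, max = N)
  assert_scalar_number(k, "k", min = 0)
  if (k <= 0) {
    return(1)
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Resampling test for category enrichment
#'
#' For each category of size `n` with `k` observed positives, draws `n`
#' families without replacement from the background (`total` families of
#' which `positives` are positive) `n_draws` times and reports the fraction
#' of draws with at least `k` positives. A reported 0 means no draw reached
#' the observed count (less than `1/n_draws`); no pseudo-count is added.
#'
#' @param total Background size (number of families).
#' @param positives Number of positive families in the background.
#' @param categories Data frame with columns `category`, `n`, `k` (size and
#'   observed positives per category).
#' @param n_draws Number of random draws (default 100,000).
#' @param seed Integer seed.
#' @return `categories` with a `p_raw` column appended.
#' @export
permutation_enrichment <- function(total, positives, categories,
                                   n_draws = 1e5, seed = 1) {
  assert_scalar_number(total, "total", min = 1)
  assert_scalar_number(positives, "positives", min = 0, max = total)
  assert_scalar_number(n_draws, "n_draws", min = 1)
  if (!is.data.frame(categories) || !all(c("category", "n", "k") %in% names(categories))) {
    abort("`categories` must have columns category, n, k.")
  }
  if (any(categories$n > total)) {
    abort("Category size exceeds the background total.")
  }
  if (any(categories$k > categories$n) || any(categories$k < 0)) {
    abort("Observed positives must lie in [0, n] for each category.")
  }
  n_draws <- as.integer(n_draws)
  categories <- tibble::as_tibble(categories)
  categories$p_raw <- with_seed(seed, {
    vapply(seq_len(nrow(categories)), function(i) {
      n_i <- categories$n[i]
      k_i <- categories$k[i]
      if (k_i == 0) {
        return(1)
      }
      hits <- 0L
      for (d in seq_len(n_draws)) {
        # the first `positives` background indices are the positive families
        if (sum(sample.int(total, n_i) <= positives) >= k_i) hits <- hits + 1L
      }
      hits / n_draws
    }, numeric(1))
  })
  categories
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment returned in input order; `m` is the number of
#' tests supplied (all categories tested, not just those with positives).
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Two-sample test for equality of proportions
#'
#' Chi-squared test on the 2x2 table of successes and failures, with the
#' Yates continuity correction applied by default.
#'
#' @param k1,n1 Successes and trials in the first sample.
#' @param k2,n2 Successes and trials in the second sample.
#' @param continuity Apply the continuity correction (default TRUE).
#' @return Tibble with `chi2`, `df`, `p_value`.
#' @export
prop_test_2x2 <- function(k1, n1, k2, n2, continuity = TRUE) {
  assert_scalar_number(n1, "n1", min = 1)
  assert_scalar_number(n2, "n2", min = 1)
  assert_scalar_number(k1, "k1", min = 0, max = n1)
  assert_scalar_number(k2, "k2", min = 0, max = n2)
  if ((k1 + k2 == 0) || (k1 + k2 == n1 + n2)) {
    abort("Degenerate 2x2 table: one outcome margin is empty.")
  }
  res <- suppressWarnings(
    prop.test(c(k1, k2), c(n1, n2), correct = continuity)
  )
  tibble::tibble(
    chi2 = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value
  )
}

#' Category enrichment table with FDR
#'
#' Runs [permutation_enrichment()] and appends BH-adjusted values across all
#' supplied categories.
#'
#' @inheritParams permutation_enrichment
#' @return Tibble `category`, `n`, `k`, `p_raw`, `fdr`.
#' @export
enrichment_table <- function(total, positives, categories, n_draws = 1e5, seed = 1) {
  out <- permutation_enrichment(total, positives, categories, n_draws, seed)
  out$fdr <- bh_adjust(out$p_raw)
  out
}
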