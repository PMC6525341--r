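test_that("transition probabilities match identities and the equal-rates closed form", {
  # t = 0 is the identity kernel
  expect_equal(bd_transition_prob(3, 3, 0, 0.002, 0.001), 1)
  expect_equal(bd_transition_prob(3, 2, 0, 0.002, 0.001), 0)
  # absorbing zero state
  expect_equal(bd_transition_prob(0, 0, 500, 0.01, 0.01), 1)
  expect_equal(bd_transition_prob(0, 4, 500, 0.01, 0.01), 0)
  # lambda = mu closed form: P(0 | 1, t) = lt / (1 + lt)
  expect_equal(bd_transition_prob(1, 0, 100, 0.002, 0.002), 1 / 6,
               tolerance = 1e-12)
  expect_error(bd_transition_prob(-1, 0, 1, 0.01, 0.01), "non-negative")
  # one-sided zero rates stay proper distributions
  expect_equal(bd_transition_prob(2, 1, 50, 0, 0.01),
               choose(2, 1) * (1 - exp(-0.5)) * exp(-0.5), tolerance = 1e-12)
  expect_equal(sum(bd_transition_prob(rep(1, 40), 0:39, 80, 0.005, 0)), 1,
               tolerance = 1e-10)
})

test_that("transition rows sum to one within truncation and match the matrix builder", {
  for (rates in list(c(0.002, 0.0018), c(0.01, 0.01), c(0.001, 0.004))) {
    P <- bd_transition_matrix(60, 90, rates[1], rates[2])
    expect_true(all(P >= 0 & P <= 1))
    expect_true(all(rowSums(P[1:11, ]) > 1 - 1e-8))
    Pf <- outer(0:10, 0:10, function(s, c)
      bd_transition_prob(s, c, 90, rates[1], rates[2]))
    expect_equal(P[1:11, 1:11], Pf, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("pruning likelihood matches brute-force enumeration on a 3-tip tree", {
  tr3 <- three_tip_tree()
  tr3$edge.length <- tr3$edge.length * 50 # My-ish scale
  for (counts in list(c(A = 2L, B = 1L, C = 3L), c(A = 0L, B = 2L, C = 1L),
                      c(A = 5L, B = 5L, C = 4L))) {
    root_max <- max(counts)
    got <- family_log_likelihood(tr3, counts, 0.004, 0.003,
                                 root_prior_max = root_max, cap = 12)
    want <- bd_loglik_bruteforce(tr3, as.list(counts), 0.004, 0.003,
                                 root_max = root_max, cap = 12)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("likelihood is insensitive to the truncation cap beyond 2x the maximum", {
  tr <- fixture_tree()
  counts <- setNames(c(rep(2L, 9), rep(6L, 9)), tr$tip.label)
  base <- family_log_likelihood(tr, counts, 0.002, 0.0018, cap = 12)
  for (cap in c(20, 40, 80)) {
    expect_equal(family_log_likelihood(tr, counts, 0.002, 0.0018, cap = cap),
                 base, tolerance = 1e-8)
  }
})

test_that("degenerate rates force the uniform-root-prior likelihood", {
  tr <- fixture_tree()
  counts <- setNames(rep(3L, 18), tr$tip.label)
  expect_equal(family_log_likelihood(tr, counts, 0, 0, root_prior_max = 3),
               log(1 / 3), tolerance = 1e-12)
  expect_error(family_log_likelihood(tr, counts[-1], 0.001, 0.001), "missing tips")
})

test_that("rate optimization finds the grid optimum and degenerates sensibly", {
  tr <- random_tree(3, depth = 200, seed = 8)
  tab <- simulate_count_table(tr, 0.003, 0.002, n_families = 200, root_max = 5,
                              seed = 12)
  tab <- filter_shared_families(tab, attr(tr, "regime_map"))
  fit <- fit_global_rates(tab, tr, mode = "distinct")
  # 50 x 50 grid oracle on log-spaced rates, same root prior
  m <- lsexpand:::count_matrix(tab)
  trav <- lsexpand:::tree_traversal(tr)
  grid <- exp(seq(log(1e-4), log(0.05), length.out = 50))
  best <- c(-Inf, NA, NA)
  for (lam in grid) {
    ll <- vapply(grid, function(mu) sum(lsexpand:::bd_loglik_table_prior(
      m, trav, lam, mu, root_prior_max = fit$root_prior_max)), numeric(1))
    i <- which.max(ll)
    if (ll[i] > best[1]) best <- c(ll[i], lam, grid[i])
  }
  expect_gte(fit$logLik, best[1] - 1e-6)
  # within one grid cell of the grid argmax
  step <- log(grid[2]) - log(grid[1])
  expect_lt(abs(log(fit$lambda) - log(best[2])), step + 1e-9)
  expect_lt(abs(log(fit$mu) - log(best[3])), step + 1e-9)

  # constant families across tips push both rates to the lower bound
  const <- tibble::tibble(family = sprintf("F%d", 1:30))
  for (tip in tr$tip.label) const[[tip]] <- rep(3L, 30)
  fit0 <- fit_global_rates(const, tr, mode = "distinct")
  expect_lt(fit0$lambda, 1e-6)
  expect_lt(fit0$mu, 1e-6)
})

test_that("distinct-rate likelihood dominates single-rate and the LRT is exact", {
  tr <- fixture_tree()
  tab <- filter_shared_families(
    simulate_count_table(tr, 0.002, 0.002, n_families = 300, seed = 33),
    beetle_groups())
  fd <- fit_global_rates(tab, tr, mode = "distinct")
  fs <- fit_global_rates(tab, tr, mode = "single",
                         root_prior_max = fd$root_prior_max)
  expect_gte(fd$logLik, fs$logLik - 1e-6)
  lrt <- likelihood_ratio_test(fs, fd)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$p_value, pchisq(lrt$statistic, 1, lower.tail = FALSE))
  # true rates are equal here, so the two modes nearly coincide
  expect_lt(lrt$statistic, qchisq(0.999, 1) + 2)

  expect_equal(likelihood_ratio_test(-199989, -199981)$statistic, 16)
  expect_error(likelihood_ratio_test(-100, -150), "below")

  expect_error(likelihood_ratio_test(
    structure(list(logLik = -10, root_prior_max = 5), class = "bd_fit"),
    structure(list(logLik = -9, root_prior_max = 7), class = "bd_fit")),
    "root prior")
})

test_that("tidiers expose rates and fit metadata", {
  tr <- random_tree(3, depth = 100, seed = 2)
  tab <- filter_shared_families(
    simulate_count_table(tr, 0.005, 0.005, n_families = 50, seed = 3),
    attr(tr, "regime_map"))
  fit <- fit_global_rates(tab, tr, mode = "single")
  td <- tidy(fit)
  expect_tibble_cols(td, c("term", "estimate"))
  expect_equal(td$term, c("lambda", "mu"))
  expect_equal(td$estimate[1], td$estimate[2]) # single mode
  gl <- glance(fit)
  expect_equal(gl$mode, "single")
  expect_equal(gl$n_families, nrow(tab))
})
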