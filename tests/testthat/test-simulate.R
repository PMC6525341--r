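test_that("fixture tree is the study layout and fully deterministic", {
  tr <- fixture_tree()
  expect_equal(validate_ultrametric(tr), 250)
  expect_equal(ape::Ntip(tr), 18)
  cm <- attr(tr, "regime_map")
  expect_equal(vapply(cm, length, integer(1)),
               c(Adephaga = 9L, Polyphaga = 9L))
  for (side in names(cm)) {
    mrca <- ape::getMRCA(tr, cm[[side]])
    nodes <- lsexpand:::subtree_nodes(tr, mrca)
    expect_setequal(tr$tip.label[nodes[nodes <= 18]], cm[[side]])
  }
  expect_identical(write_newick(fixture_tree()), write_newick(fixture_tree()))
})

test_that("random trees are seeded, depth-true, and topology-uniform at 3 tips", {
  t1 <- random_tree(5, depth = 120, seed = 4)
  t2 <- random_tree(5, depth = 120, seed = 4)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_false(identical(write_newick(t1), write_newick(random_tree(5, 120, 5))))
  expect_lt(abs(validate_ultrametric(t1) - 120), 1e-9)

  # both labelled resolutions of a 3-tip clade appear about equally often
  picks <- vapply(1:400, function(s) {
    tr <- random_tree(3, depth = 10, seed = 1000 + s)
    cl <- prune_tree(tr, c("A01", "A02", "A03"))
    sisters <- cl$tip.label[lsexpand:::subtree_nodes(cl, 5)]
    paste(sort(setdiff(c("A01", "A02", "A03"), sisters)), collapse = "")
  }, character(1))
  counts <- table(picks)
  expect_equal(length(counts), 3L)
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.001)
})

test_that("count simulation honors degenerate rates, seeds, and moments", {
  tr <- fixture_tree()
  # zero rates copy the root draw to every tip
  tab0 <- simulate_count_table(tr, 0, 0, n_families = 25, seed = 2)
  m0 <- lsexpand:::count_matrix(tab0)
  expect_true(all(apply(m0, 1, function(x) length(unique(x))) == 1))
  expect_true(all(m0[, 1] >= 1 & m0[, 1] <= 10))

  expect_identical(simulate_count_table(tr, 0.002, 0.0018, 50, seed = 7),
                   simulate_count_table(tr, 0.002, 0.0018, 50, seed = 7))

  # mean tip count matches E[root] * exp((lambda - mu) T) within 3 SE
  lam <- 0.003; mu <- 0.002
  tab <- simulate_count_table(tr, lam, mu, n_families = 10000, root_max = 8,
                              seed = 5)
  m <- lsexpand:::count_matrix(tab)
  expected <- mean(1:8) * exp((lam - mu) * 250)
  tip_means <- rowMeans(m)
  se <- sd(tip_means) / sqrt(length(tip_means))
  expect_lt(abs(mean(tip_means) - expected), 3 * se)

  # equal-rates variance: Var[X(t) | X(0)=s] = 2 lambda t s on one branch
  tr2 <- read_newick("(A:100,B:100);")
  tabv <- simulate_count_table(tr2, 0.002, 0.002, n_families = 10000,
                               root_sizes = 5, seed = 6)
  x <- lsexpand:::count_matrix(tabv)[, "A"]
  v_hat <- var(x)
  v_true <- 2 * 0.002 * 100 * 5
  se_v <- sd((x - mean(x))^2) / sqrt(length(x))
  expect_lt(abs(v_hat - v_true), 3 * se_v)
})

test_that("transition-law sampling agrees with the event-by-event simulator", {
  tr2 <- read_newick("(A:100,B:100);")
  fast <- simulate_count_table(tr2, 0.004, 0.003, n_families = 4000,
                               root_sizes = 3, seed = 8)
  slow <- simulate_counts_gillespie(tr2, 0.004, 0.003, n_families = 4000,
                                    root_sizes = 3, seed = 9)
  xf <- lsexpand:::count_matrix(fast)[, "A"]
  xs <- lsexpand:::count_matrix(slow)[, "A"]
  # both match the analytic transition law: compare binned frequencies
  probs <- bd_transition_prob(rep(3, 12), 0:11, 100, 0.004, 0.003)
  bin <- function(x) tabulate(pmin(x, 11) + 1L, nbins = 12) / length(x)
  expect_lt(max(abs(bin(xf) - probs)), 4 * sqrt(max(probs) / 4000))
  expect_lt(max(abs(bin(xs) - probs)), 4 * sqrt(max(probs) / 4000))
})

test_that("trait simulation is exact for degenerate and sampled cases", {
  tr <- small_painted_tree(depth = 100)
  # sigma2 = 0 under BM keeps the root value everywhere
  s0 <- simulate_trait(tr, "BM1", list(sigma2 = 0, root_value = 2.5), seed = 1)
  expect_true(all(s0$value == 2.5))
  # sigma2 = 0 under OU converges deterministically toward theta
  sou <- simulate_trait(tr, "OU1", list(sigma2 = 0, alpha = 0.2, theta = 4,
                                        root_value = 0), seed = 1)
  expect_true(all(abs(sou$value - 4) < 4 * exp(-0.2 * 70) + 1e-9))
  expect_true(all(sou$value <= 4))
  # determinism
  p <- list(sigma2 = 0.5, alpha = 0.05, theta = c(A = 1, B = 5))
  expect_identical(simulate_trait(tr, "OUM", p, n = 3, seed = 11),
                   simulate_trait(tr, "OUM", p, n = 3, seed = 11))

  # sample covariance across replicates matches model_covariance within 3 SE
  n <- 20000
  sims <- simulate_trait(tr, "OUMV",
                         list(sigma2 = c(A = 0.4, B = 1.1), alpha = 0.03,
                              theta = c(A = 2, B = 7), root_value = 4),
                         n = n, seed = 12)
  M <- matrix(sims$value, nrow = 6)
  rownames(M) <- sims$species[1:6]
  V <- model_covariance(tr, "OUMV",
                        list(sigma2 = c(A = 0.4, B = 1.1), alpha = 0.03))
  for (pair in list(c("a1", "a2"), c("b1", "b2"), c("a1", "a1"), c("b3", "b3"))) {
    emp <- cov(M[pair[1], ], M[pair[2], ])
    truth <- V[pair[1], pair[2]]
    se <- sqrt((V[pair[1], pair[1]] * V[pair[2], pair[2]] + truth^2) / n)
    expect_lt(abs(emp - truth), 3 * se)
  }
})

test_that("planted categories flag positives at their configured rates", {
  flags <- plant_categories(n_background = 500, background_positive_rate = 0,
                            category_spec = tibble::tibble(
                              name = "GST", n = 6, positive_rate = 0.5),
                            seed = 3)
  expect_equal(sum(flags$positive[flags$category == "background"]), 0L)
  expect_identical(flags, plant_categories(500, 0,
                                           tibble::tibble(name = "GST", n = 6,
                                                          positive_rate = 0.5),
                                           seed = 3))
  # a planted category stands out against a sparse background
  flags2 <- plant_categories(n_background = 2000,
                             background_positive_rate = 0.009,
                             category_spec = tibble::tibble(
                               name = "GST", n = 40, positive_rate = 0.5),
                             seed = 4)
  k <- sum(flags2$positive[flags2$category == "GST"])
  K <- sum(flags2$positive)
  p <- hypergeometric_tail(nrow(flags2), K, 40, k)
  expect_lt(p, 0.01)
})
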