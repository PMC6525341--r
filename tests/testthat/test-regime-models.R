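test_that("aicc follows the small-sample formula", {
  expect_equal(aicc(0, 2, 18), 4 + 2 * 2 * 3 / 15)
  expect_error(aicc(0, 5, 6), "n > k")
  # strictly increasing in k at fixed lnL and n
  vals <- vapply(1:5, function(k) aicc(-10, k, 18), numeric(1))
  expect_true(all(diff(vals) > 0))
  # identity: aicc - aic = 2k(k+1)/(n-k-1) on a grid
  for (k in 1:5) {
    for (n in c(10, 18, 40)) {
      aic <- -2 * (-3.5) + 2 * k
      expect_equal(aicc(-3.5, k, n) - aic, 2 * k * (k + 1) / (n - k - 1))
    }
  }
})

test_that("model covariances match direct path integration and limits", {
  # two tips splitting at the root under BM1
  tr2 <- paint_regimes(read_newick("(A:7,B:7);"), list(R = c("A", "B")))
  V <- model_covariance(tr2, "BM1", list(sigma2 = 2))
  expect_equal(V, matrix(c(14, 0, 0, 14), 2, dimnames = dimnames(V)))

  tr <- small_painted_tree(depth = 100)
  # OU at vanishing alpha equals BM
  Vbm <- model_covariance(tr, "BM1", list(sigma2 = 1.3))
  Vou <- model_covariance(tr, "OU1", list(sigma2 = 1.3, alpha = 1e-10))
  expect_lt(max(abs(Vou - Vbm)) / max(Vbm), 1e-6)

  # per-pair numeric path integration oracle, including regime-specific rates
  s2 <- c(A = 0.8, B = 2.5)
  alpha <- 0.03
  Vmv <- model_covariance(tr, "OUMV", list(sigma2 = s2, alpha = alpha))
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(Vmv[i, j], ou_cov_pair_oracle(tr, i, j, alpha, s2),
                   tolerance = 1e-8)
    }
  }
  # diagonal: variance accumulated along the whole lineage
  lin_var <- ou_cov_pair_oracle(tr, 1, 1, alpha, s2)
  expect_equal(unname(diag(Vmv)[1]), lin_var, tolerance = 1e-8)

  # BMS covariance is the rate-weighted shared path length (depths scaled x10)
  Vbms <- model_covariance(tr, "BMS", list(sigma2 = s2))
  expect_equal(Vbms["a1", "a2"], 0.8 * 70, tolerance = 1e-10) # 70 My shared in A
  expect_equal(Vbms["b1", "b3"], 2.5 * 30, tolerance = 1e-10) # 30 My shared in B
  expect_equal(Vbms["a1", "b1"], 0, tolerance = 1e-12)
})

test_that("Hansen weights conserve mass and honor limits", {
  tr <- small_painted_tree(depth = 100)
  for (alpha in c(1e-4, 0.01, 0.3, 5)) {
    W <- ou_weights(tr, alpha)
    expect_equal(unname(rowSums(W)), rep(1, 6), tolerance = 1e-9)
  }
  # alpha -> infinity: each tip's expectation is its terminal regime's optimum
  th <- c(A = 3, B = 11)
  e_inf <- ou_expectation(tr, 50, th)
  expect_equal(unname(e_inf), c(3, 3, 3, 11, 11, 11), tolerance = 1e-6)
  # single regime: expectation is theta everywhere
  tr1 <- paint_regimes(three_tip_tree(), list(Z = c("A", "B", "C")))
  expect_equal(unname(ou_expectation(tr1, 0.4, c(Z = 6))), rep(6, 3))
  # random painted trees conserve mass too
  for (seed in 1:3) {
    trr <- random_tree(4, depth = 120, seed = seed)
    expect_equal(unname(rowSums(ou_weights(trr, 0.05))), rep(1, 8),
                 tolerance = 1e-9)
  }
})

test_that("BM1 on two tips matches the closed-form MLE", {
  tr2 <- paint_regimes(read_newick("(A:9,B:9);"), list(R = c("A", "B")))
  y <- c(A = 4, B = 10)
  fit <- fit_trait_model(y, tr2, "BM1")
  # AICc is undefined at n = 2 for k = 2 but the MLE itself is exact
  expect_true(is.na(fit$aicc))
  # root state is the midpoint; sigma2_hat = (yA - yB)^2 / (2 * 2T)
  expect_equal(fit$root_state, 7, tolerance = 1e-8)
  expect_equal(unname(fit$sigma2), (4 - 10)^2 / (2 * 2 * 9), tolerance = 1e-8)
  # lnL equals the bivariate normal density at the MLE
  V <- fit$sigma2 * diag(2)
  dens <- -log(2 * pi) - 0.5 * log(det(V * 9)) -
    0.5 * sum((y - 7)^2 / (fit$sigma2 * 9))
  expect_equal(fit$lnL, dens, tolerance = 1e-8)
})

test_that("fitted likelihoods equal dense MVN evaluation and respect nesting", {
  tr <- fixture_tree()
  sim <- simulate_trait(tr, "OUM",
                        list(sigma2 = 0.6, alpha = 0.04,
                             theta = c(Adephaga = 2, Polyphaga = 8)),
                        n = 3, seed = 14)
  for (r in 1:3) {
    y <- setNames(sim$value[sim$rep == r], sim$species[sim$rep == r])
    fits <- fit_regime_models(y, tr)
    # dense MVN density oracle at the returned parameters
    for (mod in c("BM1", "OU1", "OUM", "OUMV")) {
      f <- fits[[mod]]
      V <- model_covariance(tr, mod, list(sigma2 = f$sigma2, alpha = f$alpha))
      mu_vec <- if (!is.null(f$theta)) {
        ou_expectation(tr, f$alpha, f$theta)
      } else {
        rep(f$root_state, 18)
      }
      yv <- y[rownames(V)]
      dens <- -9 * log(2 * pi) - 0.5 * determinant(V)$modulus -
        0.5 * drop(t(yv - mu_vec) %*% solve(V, yv - mu_vec))
      expect_equal(f$lnL, unname(as.numeric(dens)), tolerance = 1e-6)
    }
    # nesting within the optimizer tolerance
    expect_gte(fits$BMS$lnL, fits$BM1$lnL - 1e-6)
    expect_gte(fits$OUM$lnL, fits$OU1$lnL - 1e-6)
    expect_gte(fits$OUMV$lnL, fits$OUM$lnL - 1e-6)
  }
})

test_that("OUM collapses to OU1 under equal optima and OU to BM as alpha vanishes", {
  tr <- fixture_tree()
  sim <- simulate_trait(tr, "OU1",
                        list(sigma2 = 0.4, alpha = 0.03, theta = c(5)),
                        n = 1, seed = 15)
  y <- setNames(sim$value, sim$species)
  ou1 <- fit_trait_model(y, tr, "OU1")
  # at OU1's alpha, constraining both optima to the OU1 theta reproduces lnL
  V <- model_covariance(tr, "OUM", list(sigma2 = 1, alpha = ou1$alpha))
  W <- ou_weights(tr, ou1$alpha)
  mu_vec <- drop(W %*% rep(ou1$theta[1], 2))
  yv <- y[rownames(V)]
  g <- lsexpand:::gls_profile(yv, matrix(1, 18, 1), V)
  expect_equal(g$lnL, ou1$lnL, tolerance = 1e-6)
  expect_equal(unname(mu_vec), rep(unname(ou1$theta[1]), 18), tolerance = 1e-10)

  # BM-simulated data: OU fit at the shrunken alpha bound reproduces BM lnL
  simbm <- simulate_trait(tr, "BM1", list(sigma2 = 0.05, root_value = 4),
                          n = 1, seed = 16)
  yb <- setNames(simbm$value, simbm$species)
  bm <- fit_trait_model(yb, tr, "BM1")
  Vou <- model_covariance(tr, "OU1", list(sigma2 = 1, alpha = 1e-10))
  gou <- lsexpand:::gls_profile(yb[rownames(Vou)], matrix(1, 18, 1), Vou)
  expect_equal(gou$lnL, bm$lnL, tolerance = 1e-4)
})

test_that("group means average per regime and match simulated optima at high pull", {
  gm <- list(A = c("a1", "a2", "a3"), P = c("p1", "p2", "p3"))
  y <- c(a1 = 1, a2 = 1, a3 = 1, p1 = 3, p2 = 3, p3 = 3)
  expect_equal(group_means(y, gm), c(A = 1, P = 3))
  yp <- y[c(2, 1, 3, 6, 5, 4)]
  expect_equal(group_means(yp, gm), c(A = 1, P = 3))
  expect_error(group_means(y[-1], gm), "at least one species")

  tr <- fixture_tree()
  sim <- simulate_trait(tr, "OUM",
                        list(sigma2 = 0.1, alpha = 1,
                             theta = c(Adephaga = 3, Polyphaga = 9)),
                        n = 200, seed = 18)
  means <- sim |>
    dplyr::mutate(group = ifelse(.data$species %in% beetle_groups()$Adephaga,
                                 "Adephaga", "Polyphaga")) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(m = mean(.data$value))
  expect_equal(means$m[means$group == "Adephaga"], 3, tolerance = 0.05)
  expect_equal(means$m[means$group == "Polyphaga"], 9, tolerance = 0.05)
})

test_that("model selection applies the strict delta-AICc rule independent of order", {
  # a published-style row: OUMV preferred, Polyphaga optimum higher
  aiccs <- c(BM1 = 86.24, BMS = 87.76, OU1 = 76.05, OUM = 74.40, OUMV = 72.12)
  sel <- select_model(aiccs, means = c(Adephaga = 1.71, Polyphaga = 3.16))
  expect_true(sel$positive)
  expect_equal(sel$best_h0, "OU1")
  expect_equal(sel$best_h1, "OUMV")
  expect_equal(sel$delta_aicc, 76.05 - 72.12)
  expect_equal(sel$direction, "Polyphaga")
  # shuffling the vector changes nothing
  sel2 <- select_model(aiccs[c(4, 1, 5, 3, 2)],
                       means = c(Adephaga = 1.71, Polyphaga = 3.16))
  expect_equal(sel2, sel)
  # a delta of exactly 2 is not positive (strict inequality)
  border <- c(BM1 = 10, BMS = 11, OU1 = 12, OUM = 8, OUMV = 9)
  selb <- select_model(border, means = c(A = 1, B = 2))
  expect_equal(selb$delta_aicc, 2)
  expect_false(selb$positive)
  expect_true(is.na(selb$direction))
  expect_error(select_model(aiccs[-1]), "Missing model")
})

test_that("direction recovery meets the planted-OUM and BM false-positive targets", {
  tr <- fixture_tree()
  ctx <- lsexpand:::regime_context(tr)
  alpha <- 0.05
  sigma2 <- 0.5
  theta <- c(Adephaga = 2,
             Polyphaga = 2 + 3 * sqrt(sigma2 / (2 * alpha)))
  n_rep <- 200
  sim <- simulate_trait(tr, "OUM",
                        list(sigma2 = sigma2, alpha = alpha, theta = theta,
                             root_value = mean(theta)),
                        n = n_rep, seed = 19)
  hits <- 0L
  for (r in seq_len(n_rep)) {
    y <- setNames(sim$value[sim$rep == r], sim$species[sim$rep == r])
    sel <- select_model(fit_regime_models(y, tr, ctx = ctx))
    if (isTRUE(sel$positive) && identical(sel$direction, "Polyphaga")) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_rep, 0.8)

  simbm <- simulate_trait(tr, "BM1", list(sigma2 = 0.02, root_value = 5),
                          n = n_rep, seed = 20)
  fp <- 0L
  for (r in seq_len(n_rep)) {
    y <- setNames(simbm$value[simbm$rep == r], simbm$species[simbm$rep == r])
    if (isTRUE(select_model(fit_regime_models(y, tr, ctx = ctx))$positive)) {
      fp <- fp + 1L
    }
  }
  expect_lte(fp / n_rep, 0.1)
})

test_that("regime-fit tidiers report parameters per regime", {
  tr <- small_painted_tree()
  y <- c(a1 = 1, a2 = 2, a3 = 1.5, b1 = 6, b2 = 7, b3 = 6.5)
  fit <- fit_trait_model(y, tr, "OUM")
  td <- tidy(fit)
  expect_setequal(unique(td$term), c("sigma2", "alpha", "theta"))
  expect_equal(sum(td$term == "theta"), 2)
  gl <- glance(fit)
  expect_equal(gl$model, "OUM")
  expect_equal(gl$k, 4)
  expect_equal(gl$AICc, aicc(gl$logLik, 4, 6))
  # OUMV at n = 6 fits but its AICc is undefined (n <= k + 1)
  expect_true(is.na(fit_trait_model(y, tr, "OUMV")$aicc))
})
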