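# Multi-regime Brownian-motion / Ornstein-Uhlenbeck models of per-species
# gene counts treated as a continuous trait on a painted ultrametric tree.
#
# Five models are compared: BM1 (one diffusion rate), BMS (one rate per
# regime), OU1 (one optimum), OUM (two optima, one variance), OUMV (two
# optima, two variances). The first three are the no-adaptive-expansion null
# hypotheses; OUM/OUMV are the alternatives. Model choice uses AICc with a
# delta > 2 retention rule.

REGIME_MODELS <- c("BM1", "BMS", "OU1", "OUM", "OUMV")

as_trait_vector <- function(trait, tree) {
  if (is.data.frame(trait)) {
    if (!all(c("species", "value") %in% names(trait))) {
      abort("`trait` data frame must have columns `species` and `value`.")
    }
    trait <- setNames(trait$value, trait$species)
  }
  if (is.null(names(trait))) {
    abort("`trait` must be named by tip labels.")
  }
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing) > 0) {
    abort(sprintf("Trait is missing tips: %s", paste(missing, collapse = ", ")))
  }
  y <- as.numeric(trait[tree$tip.label])
  if (any(!is.finite(y))) {
    abort("Trait values must be finite.")
  }
  setNames(y, tree$tip.label)
}

# sigma2 per edge from a scalar or regime-named vector.
edge_sigma2 <- function(tree, sigma2) {
  er <- edge_regimes(tree)
  if (length(sigma2) == 1 && is.null(names(sigma2))) {
    return(rep(as.numeric(sigma2), length(er)))
  }
  missing <- setdiff(unique(er), names(sigma2))
  if (length(missing) > 0) {
    abort(sprintf("`sigma2` missing regimes: %s", paste(missing, collapse = ", ")))
  }
  as.numeric(sigma2[er])
}

#' Trait covariance matrix under a BM or OU regime model
#'
#' For Brownian models the covariance of two tips is the rate-weighted shared
#' path length. For OU models the variance accumulates along each edge as
#' `v(end) = v(start) e^(-2 a l) + s2 (1 - e^(-2 a l)) / (2 a)` from a fixed
#' root (v(root) = 0) and decays with time since the last common ancestor:
#' `V_ij = v(mrca) e^(-2 a (T - t_mrca))`. An `alpha` of (numerically) zero
#' reduces to the Brownian case.
#'
#' @param tree A painted ultrametric tree ([paint_regimes()]).
#' @param model One of `"BM1"`, `"BMS"`, `"OU1"`, `"OUM"`, `"OUMV"`.
#' @param params List with `sigma2` (scalar, or regime-named vector for
#'   BMS/OUMV) and `alpha` (OU models).
#' @return Species-by-species covariance matrix in tip-label order.
#' @export
model_covariance <- function(tree, model, params) {
  model_covariance_ctx(regime_context(tree), model, params)
}

# Per-tree quantities reused across many likelihood evaluations.
regime_context <- function(tree) {
  edge <- tree$edge
  depths <- node_depths(tree)
  ntip <- ape::Ntip(tree)
  list(
    tree = tree,
    edge = edge,
    elen = tree$edge.length,
    er = edge_regimes(tree),
    regimes = names(attr(tree, "regime_map")),
    depths = depths,
    preorder = order(depths[edge[, 2]]),
    ntip = ntip,
    nnode_all = ntip + tree$Nnode,
    T_depth = max(depths[seq_len(ntip)]),
    mrca = ape::mrca(unclass_painted(tree)),
    lineages = tip_lineages(tree),
    tip_labels = tree$tip.label
  )
}

model_covariance_ctx <- function(ctx, model, params) {
  model <- match.arg(model, REGIME_MODELS)
  s2 <- if (length(params$sigma2) == 1 && is.null(names(params$sigma2))) {
    rep(as.numeric(params$sigma2), length(ctx$er))
  } else {
    missing <- setdiff(unique(ctx$er), names(params$sigma2))
    if (length(missing) > 0) {
      abort(sprintf("`sigma2` missing regimes: %s", paste(missing, collapse = ", ")))
    }
    as.numeric(params$sigma2[ctx$er])
  }
  is_ou <- model %in% c("OU1", "OUM", "OUMV")
  alpha <- if (is_ou) params$alpha else 0
  if (is.null(alpha) || alpha < 1e-12) {
    alpha <- 0
  }
  edge <- ctx$edge
  elen <- ctx$elen
  v <- numeric(ctx$nnode_all)
  if (alpha == 0) {
    for (k in ctx$preorder) {
      v[edge[k, 2]] <- v[edge[k, 1]] + s2[k] * elen[k]
    }
  } else {
    for (k in ctx$preorder) {
      l <- elen[k]
      v[edge[k, 2]] <- v[edge[k, 1]] * exp(-2 * alpha * l) +
        s2[k] * (-expm1(-2 * alpha * l)) / (2 * alpha)
    }
  }
  V <- matrix(v[ctx$mrca], ctx$ntip, ctx$ntip,
              dimnames = list(ctx$tip_labels, ctx$tip_labels))
  if (alpha > 0) {
    V <- V * exp(-2 * alpha * (ctx$T_depth - ctx$depths[ctx$mrca]))
  }
  V
}

#' Hansen regime weights along root-to-tip lineages
#'
#' Row `i` gives the weight each regime's optimum contributes to the
#' expectation of tip `i` under an OU process with pull `alpha`: each lineage
#' segment in regime `r` adds `e^(-a (T - t1)) - e^(-a (T - t0))`, and the
#' residual root mass `e^(-a T)` is assigned to the regime of the most basal
#' segment (stationarity convention; the root's own label is not a free
#' optimum). Rows sum to one.
#'
#' @param tree Painted ultrametric tree.
#' @param alpha OU pull strength (> 0), 1/My.
#' @return Matrix of dimension tips x regimes.
#' @export
ou_weights <- function(tree, alpha) {
  ou_weights_ctx(regime_context(tree), alpha)
}

ou_weights_ctx <- function(ctx, alpha) {
  assert_scalar_number(alpha, "alpha", min = 1e-300)
  W <- matrix(0, ctx$ntip, length(ctx$regimes),
              dimnames = list(ctx$tip_labels, ctx$regimes))
  T_depth <- ctx$T_depth
  for (i in seq_len(ctx$ntip)) {
    seg <- ctx$lineages[[i]]
    w <- exp(-alpha * (T_depth - seg$t1)) - exp(-alpha * (T_depth - seg$t0))
    for (k in seq_len(nrow(seg))) {
      W[i, seg$regime[k]] <- W[i, seg$regime[k]] + w[k]
    }
    W[i, seg$regime[1]] <- W[i, seg$regime[1]] + exp(-alpha * T_depth)
  }
  W
}

#' Expected tip values under a multi-optimum OU model
#'
#' @inheritParams ou_weights
#' @param theta Named vector of optima, one per regime.
#' @return Named numeric vector of tip expectations.
#' @export
ou_expectation <- function(tree, alpha, theta) {
  W <- ou_weights(tree, alpha)
  missing <- setdiff(colnames(W), names(theta))
  if (length(missing) > 0) {
    abort(sprintf("`theta` missing regimes: %s", paste(missing, collapse = ", ")))
  }
  drop(W %*% theta[colnames(W)])
}

#' Small-sample corrected Akaike information criterion
#'
#' `aicc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param lnL Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size (number of tips); must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(lnL, k, n) {
  if (any(n <= k + 1)) {
    abort("AICc undefined: need n > k + 1.")
  }
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Profiled Gaussian log-likelihood: given unit-scale covariance C and design
# X, the GLS coefficients and the common scale are analytic.
gls_profile <- function(y, X, C) {
  n <- length(y)
  R <- tryCatch(chol(C), error = function(e) {
    abort("Singular trait covariance matrix; cannot fit model.")
  })
  z <- backsolve(R, y, transpose = TRUE)
  Zx <- backsolve(R, X, transpose = TRUE)
  qrx <- qr(Zx)
  beta <- qr.coef(qrx, z)
  resid <- z - Zx %*% beta
  q <- sum(resid^2)
  s2 <- max(q / n, 1e-12)
  lnL <- -0.5 * n * (log(2 * pi) + 1 + log(s2)) - sum(log(diag(R)))
  list(beta = beta, scale = s2, lnL = lnL)
}

ALPHA_BOUNDS <- log(c(1e-5, 10))
RATIO_BOUNDS <- c(-8, 8)

# 1-D bounded maximization: coarse grid then optimize() on the bracketing
# interval. Deterministic.
grid_refine_1d <- function(f, lower, upper, n_grid = 15) {
  xs <- seq(lower, upper, length.out = n_grid)
  vals <- vapply(xs, f, numeric(1))
  i <- which.max(vals)
  lo <- xs[max(1, i - 1)]
  hi <- xs[min(n_grid, i + 1)]
  o <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  if (o$objective >= vals[i]) {
    list(par = o$maximum, value = o$objective)
  } else {
    list(par = xs[i], value = vals[i])
  }
}

#' Fit one trait model to per-species gene counts
#'
#' Maximum likelihood under the multivariate normal implied by the model:
#' optima (or the Brownian root state) are profiled out by generalized least
#' squares and the overall variance scale analytically, leaving a bounded
#' 0-2 dimensional numeric search over `log(alpha)` (OU models) and the log
#' variance ratio between regimes (BMS/OUMV), run from a deterministic grid
#' of starts.
#'
#' @param trait Named numeric vector (or `species`/`value` data frame) of the
#'   per-species gene counts of one family.
#' @param tree Painted ultrametric tree with two clade regimes.
#' @param model One of `"BM1"`, `"BMS"`, `"OU1"`, `"OUM"`, `"OUMV"`.
#' @param ctx Optional precomputed tree context (internal use; lets callers
#'   amortize tree preprocessing over many families).
#' @return An object of class `regime_fit`: `model`, `lnL`, `k`, `n`, `aicc`,
#'   `sigma2` (named per regime where applicable), `alpha`, `theta` (OU) or
#'   `root_state` (BM).
#' @export
fit_trait_model <- function(trait, tree, model = REGIME_MODELS, ctx = NULL) {
  model <- match.arg(model)
  y <- as_trait_vector(trait, tree)
  n <- length(y)
  regimes <- names(attr(tree, "regime_map"))
  if (is.null(regimes)) {
    abort("Tree must be painted (see paint_regimes()).")
  }
  ctx <- ctx %||% regime_context(tree)
  k <- c(BM1 = 2L, BMS = 3L, OU1 = 3L, OUM = 4L, OUMV = 5L)[[model]]
  n_mean <- if (model %in% c("OUM", "OUMV")) 2L else 1L
  if (n <= n_mean) {
    abort(sprintf("Need more than %d tips to fit %s.", n_mean, model))
  }
  ones <- matrix(1, n, 1)
  two_sigma <- model %in% c("BMS", "OUMV")
  two_theta <- model %in% c("OUM", "OUMV")
  is_ou <- model %in% c("OU1", "OUM", "OUMV")
  if (two_sigma && length(regimes) != 2) {
    abort(sprintf("%s requires exactly two regimes; tree has %d.", model, length(regimes)))
  }

  eval_fit <- function(par) {
    alpha <- if (is_ou) exp(par[["log_alpha"]]) else NULL
    sigma2 <- if (two_sigma) {
      setNames(c(1, exp(par[["log_ratio"]])), regimes)
    } else {
      1
    }
    C <- model_covariance_ctx(ctx, model, list(sigma2 = sigma2, alpha = alpha))
    X <- if (two_theta) ou_weights_ctx(ctx, alpha) else ones
    out <- gls_profile(y, X, C)
    out$alpha <- alpha
    out$sigma2_rel <- sigma2
    out$X <- X
    out
  }

  par <- c()
  if (model == "BM1") {
    sol <- eval_fit(c())
  } else if (model %in% c("OU1", "OUM")) {
    best <- grid_refine_1d(function(a) eval_fit(c(log_alpha = a))$lnL,
                           ALPHA_BOUNDS[1], ALPHA_BOUNDS[2])
    par <- c(log_alpha = best$par)
    sol <- eval_fit(par)
  } else if (model == "BMS") {
    best <- grid_refine_1d(function(r) eval_fit(c(log_ratio = r))$lnL,
                           RATIO_BOUNDS[1], RATIO_BOUNDS[2])
    par <- c(log_ratio = best$par)
    sol <- eval_fit(par)
  } else { # OUMV: 2-D search, grid then Nelder-Mead from the best cells
    grid <- expand.grid(
      log_alpha = seq(ALPHA_BOUNDS[1], ALPHA_BOUNDS[2], length.out = 7),
      log_ratio = seq(RATIO_BOUNDS[1], RATIO_BOUNDS[2], length.out = 7)
    )
    vals <- vapply(seq_len(nrow(grid)), function(i) {
      eval_fit(c(log_alpha = grid$log_alpha[i], log_ratio = grid$log_ratio[i]))$lnL
    }, numeric(1))
    starts <- head(order(vals, decreasing = TRUE), 5)
    nll <- function(p) {
      p <- pmin(pmax(p, c(ALPHA_BOUNDS[1], RATIO_BOUNDS[1])),
                c(ALPHA_BOUNDS[2], RATIO_BOUNDS[2]))
      -eval_fit(c(log_alpha = p[1], log_ratio = p[2]))$lnL
    }
    best <- NULL
    for (s in starts) {
      o <- tryCatch(
        optim(c(grid$log_alpha[s], grid$log_ratio[s]), nll,
              method = "Nelder-Mead", control = list(reltol = 1e-10)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) {
      abort("OUMV optimization failed to converge from all starts.")
    }
    p <- pmin(pmax(best$par, c(ALPHA_BOUNDS[1], RATIO_BOUNDS[1])),
              c(ALPHA_BOUNDS[2], RATIO_BOUNDS[2]))
    par <- c(log_alpha = p[1], log_ratio = p[2])
    sol <- eval_fit(par)
  }

  sigma2 <- sol$scale * sol$sigma2_rel
  if (two_sigma) names(sigma2) <- regimes
  beta <- drop(sol$beta)
  fit <- list(
    model = model,
    lnL = sol$lnL,
    k = k,
    n = n,
    # AICc needs n > k + 1; NA marks fits that cannot enter model selection
    aicc = if (n > k + 1) aicc(sol$lnL, k, n) else NA_real_,
    sigma2 = sigma2,
    alpha = sol$alpha,
    theta = NULL,
    root_state = NULL
  )
  if (is_ou) {
    fit$theta <- if (two_theta) setNames(beta, colnames(sol$X)) else
      setNames(rep(beta, length(regimes)), regimes)
  } else {
    fit$root_state <- unname(beta)
  }
  structure(fit, class = "regime_fit")
}

#' @export
print.regime_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, k = %d, AICc = %.4f\n", x$model, x$lnL, x$k, x$aicc))
  if (!is.null(x$alpha)) cat(sprintf("  alpha = %.5g /My\n", x$alpha))
  cat(sprintf("  sigma2 = %s\n", paste(sprintf("%.5g", x$sigma2), collapse = ", ")))
  if (!is.null(x$theta)) {
    cat(sprintf("  theta = %s\n",
                paste(sprintf("%s: %.4g", names(x$theta), x$theta), collapse = ", ")))
  } else {
    cat(sprintf("  root state = %.4g\n", x$root_state))
  }
  invisible(x)
}

#' Fit all five regime models to one family
#'
#' @inheritParams fit_trait_model
#' @param models Subset of the five model names (default all).
#' @param ctx Optional precomputed tree context (internal use; lets callers
#'   amortize tree preprocessing over many families).
#' @return Named list of `regime_fit` objects.
#' @export
fit_regime_models <- function(trait, tree, models = REGIME_MODELS, ctx = NULL) {
  models <- match.arg(models, REGIME_MODELS, several.ok = TRUE)
  ctx <- ctx %||% regime_context(tree)
  setNames(lapply(models, function(m) fit_trait_model(trait, tree, m, ctx = ctx)), models)
}

#' Per-regime trait means
#'
#' @param trait Named numeric vector or `species`/`value` data frame.
#' @param groups Named list `group -> species` or species/group data frame
#'   partitioning the species.
#' @return Named numeric vector of arithmetic means per group.
#' @export
group_means <- function(trait, groups) {
  gm <- as_group_map(groups)
  if (is.data.frame(trait)) {
    trait <- setNames(trait$value, trait$species)
  }
  out <- vapply(gm, function(tips) {
    if (length(tips) == 0 || !all(tips %in% names(trait))) {
      abort("Every group must contain at least one species present in `trait`.")
    }
    mean(trait[tips])
  }, numeric(1))
  out
}

#' Model selection between null and adaptive-expansion hypotheses
#'
#' The best null model (minimum AICc among BM1, BMS, OU1) is compared with
#' the best alternative (minimum AICc among OUM, OUMV). The alternative is
#' retained only when `delta_aicc = best_h0 - best_h1` strictly exceeds 2;
#' the direction is then the regime with the larger optimum of the winning
#' alternative model (falling back on the larger group mean when optima are
#' unavailable, e.g. when selecting from published AICc values).
#'
#' @param fits Named list of `regime_fit` objects (all five models), or a
#'   named numeric vector of AICc values with names among the five models.
#' @param means Optional named per-regime trait means (see [group_means()]),
#'   used for the direction call when fitted optima are absent.
#' @return One-row tibble: `best_h0`, `best_h0_aicc`, `best_h1`,
#'   `best_h1_aicc`, `delta_aicc`, `positive`, `direction` (NA unless
#'   positive).
#' @export
select_model <- function(fits, means = NULL) {
  h0_models <- c("BM1", "BMS", "OU1")
  h1_models <- c("OUM", "OUMV")
  if (is.numeric(fits)) {
    aiccs <- fits
    fit_list <- NULL
  } else {
    aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
    fit_list <- fits
  }
  missing <- setdiff(c(h0_models, h1_models), names(aiccs))
  if (length(missing) > 0) {
    abort(sprintf("Missing model fits: %s", paste(missing, collapse = ", ")))
  }
  if (anyNA(aiccs[c(h0_models, h1_models)])) {
    abort("AICc is undefined for some fits (too few tips); cannot select.")
  }
  a0 <- aiccs[h0_models]
  a1 <- aiccs[h1_models]
  best_h0 <- h0_models[which.min(a0)]
  best_h1 <- h1_models[which.min(a1)]
  delta <- unname(a0[best_h0] - a1[best_h1])
  positive <- isTRUE(delta > 2 + 1e-9) # ties at the boundary resolve to H0
  direction <- NA_character_
  if (positive) {
    theta <- if (!is.null(fit_list)) fit_list[[best_h1]]$theta else NULL
    src <- theta %||% means
    if (is.null(src)) {
      abort("Cannot call a direction without fitted optima or group means.")
    }
    direction <- names(src)[which.max(src)]
  }
  tibble::tibble(
    best_h0 = best_h0,
    best_h0_aicc = unname(a0[best_h0]),
    best_h1 = best_h1,
    best_h1_aicc = unname(a1[best_h1]),
    delta_aicc = delta,
    positive = positive,
    direction = direction
  )
}
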