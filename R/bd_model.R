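# Linear birth-death model of gene-family size evolution.
#
# Each gene copy independently duplicates at rate lambda and is lost at rate
# mu (events/gene/My); a family of size 0 stays at 0 (no within-family
# innovation). The single-lineage transition distribution over an interval t
# is geometric-type with
#   alpha = mu * E,  beta = lambda * E,
#   E = (exp((lambda-mu) t) - 1) / (lambda exp((lambda-mu) t) - mu),
# and in the lambda = mu limit alpha = beta = lambda t / (1 + lambda t).
# A parent of size s yields a child size distributed as the s-fold
# convolution of the single-lineage law, equivalently the classical sum
#   P(c|s,t) = sum_j C(s,j) C(s+c-j-1, s-1) alpha^(s-j) beta^(c-j) (1-alpha-beta)^j.

bd_alpha_beta <- function(t, lambda, mu) {
  if (t == 0 || (lambda == 0 && mu == 0)) {
    return(c(alpha = 0, beta = 0))
  }
  if (abs(lambda - mu) < 1e-12 * max(lambda, mu)) {
    a <- lambda * t / (1 + lambda * t)
    return(c(alpha = a, beta = a))
  }
  g <- (lambda - mu) * t
  # E = (e^g - 1) / (lambda e^g - mu), computed via expm1 for small g
  E <- expm1(g) / (lambda * exp(g) - mu)
  c(alpha = mu * E, beta = lambda * E)
}

#' Birth-death transition probability for a gene family
#'
#' Probability that a family of size `s` in the parent has size `c` in a
#' descendant after time `t` under the linear birth-death model. Size 0 is
#' absorbing.
#'
#' @param s Parent count (non-negative integer, vectorized).
#' @param c Child count (non-negative integer, vectorized).
#' @param t Elapsed time (e.g. My).
#' @param lambda Gain rate (events/gene/My).
#' @param mu Loss rate (events/gene/My).
#' @return Transition probabilities in `[0, 1]`.
#' @examples
#' bd_transition_prob(1, 0, t = 100, lambda = 0.002, mu = 0.002) # = 1/6
#' @export
bd_transition_prob <- function(s, c, t, lambda, mu) {
  if (any(s < 0) || any(c < 0) || any(t < 0) || lambda < 0 || mu < 0) {
    abort("`s`, `c`, `t`, `lambda`, `mu` must all be non-negative.")
  }
  n <- max(length(s), length(c))
  s <- rep_len(as.integer(s), n)
  c <- rep_len(as.integer(c), n)
  ab <- bd_alpha_beta(t, lambda, mu)
  alpha <- ab[["alpha"]]
  beta <- ab[["beta"]]
  la <- if (alpha > 0) log(alpha) else -Inf
  lb <- if (beta > 0) log(beta) else -Inf
  lg <- if (1 - alpha - beta > 0) log1p(-(alpha + beta)) else -Inf
  # k * lx with the convention 0 * (-Inf) := 0 (zero exponent drops the factor)
  lpow <- function(lx, k) ifelse(k == 0, 0, k * lx)
  vapply(seq_len(n), function(i) {
    si <- s[i]
    ci <- c[i]
    if (t == 0 || (alpha == 0 && beta == 0)) {
      return(as.numeric(ci == si))
    }
    if (si == 0) {
      return(as.numeric(ci == 0))
    }
    j <- 0:min(si, ci)
    terms <- lchoose(si, j) + lchoose(si + ci - j - 1, si - 1) +
      lpow(la, si - j) + lpow(lb, ci - j) + lpow(lg, j)
    m <- max(terms)
    if (!is.finite(m)) return(0)
    p <- sum(exp(terms - m)) * exp(m)
    min(max(p, 0), 1)
  }, numeric(1))
}

#' Birth-death transition matrix on a truncated state space
#'
#' Rows index the parent count 0..cap, columns the child count 0..cap. Rows
#' are computed by iterated convolution of the single-lineage offspring law,
#' so entries are exact for the truncated range (mass beyond `cap` is simply
#' absent, making row sums at most 1).
#'
#' @inheritParams bd_transition_prob
#' @param cap State-space truncation (maximum count).
#' @return A `(cap+1) x (cap+1)` matrix.
#' @export
bd_transition_matrix <- function(cap, t, lambda, mu) {
  assert_scalar_number(cap, "cap", min = 1)
  cap <- as.integer(cap)
  ab <- bd_alpha_beta(t, lambda, mu)
  alpha <- ab[["alpha"]]
  beta <- ab[["beta"]]
  P <- matrix(0, cap + 1L, cap + 1L)
  if (t == 0 || (alpha == 0 && beta == 0)) {
    diag(P) <- 1
    return(P)
  }
  # single-lineage law over 0..cap
  p1 <- numeric(cap + 1L)
  p1[1] <- alpha
  if (cap >= 1) {
    p1[2:(cap + 1L)] <- (1 - alpha) * (1 - beta) * beta^(0:(cap - 1L))
  }
  P[1, 1] <- 1 # absorbing zero
  # lower-triangular Toeplitz operator of p1: (T v)[c] = sum_a p1[c-a] v[a]
  Tm <- matrix(0, cap + 1L, cap + 1L)
  for (j in seq_len(cap + 1L)) {
    Tm[j:(cap + 1L), j] <- p1[1:(cap + 2L - j)]
  }
  r <- p1
  P[2, ] <- r
  if (cap >= 2) {
    for (s in 2:cap) {
      r <- as.vector(Tm %*% r)
      P[s + 1L, ] <- r
    }
  }
  P
}

# Tip conditional likelihoods over states 0..cap for one observed count,
# with the optional observation-error smear: mass 1-2*eps on the observed
# count and eps on each neighbour (boundary mass at -1 folded onto 0).
tip_state_likelihood <- function(obs, cap, epsilon = 0) {
  v <- numeric(cap + 1L)
  o <- min(obs, cap)
  if (epsilon == 0) {
    v[o + 1L] <- 1
    return(v)
  }
  v[o + 1L] <- 1 - 2 * epsilon
  lo <- o - 1L
  hi <- o + 1L
  if (lo >= 0) v[lo + 1L] <- v[lo + 1L] + epsilon else v[1L] <- v[1L] + epsilon
  if (hi <= cap) v[hi + 1L] <- v[hi + 1L] + epsilon
  v
}

# Postorder edge traversal bundle reused by likelihood/Viterbi code.
tree_traversal <- function(tree) {
  tree <- unclass_painted(tree)
  post <- ape::reorder.phylo(tree, "postorder")
  list(
    tree = tree,
    edge = post$edge,
    edge_length = post$edge.length,
    ntip = ape::Ntip(tree),
    nnode = tree$Nnode,
    root = ape::Ntip(tree) + 1L
  )
}

# Batched pruning log-likelihood for a set of families sharing a cap.
# counts: families x species integer matrix (columns named by tip labels).
# Returns log-likelihood per family under a uniform root prior on
# 1..max(1, max(count)) per family (or `root_prior_max` if supplied).
bd_loglik_batch <- function(counts, trav, cap, lambda, mu, epsilon = 0,
                            root_prior_max = NULL) {
  nfam <- nrow(counts)
  tips <- trav$tree$tip.label
  if (!all(tips %in% colnames(counts))) {
    abort(sprintf("Counts are missing tips: %s",
                  paste(setdiff(tips, colnames(counts)), collapse = ", ")))
  }
  counts <- counts[, tips, drop = FALSE]
  nstate <- cap + 1L
  # unique transition matrices per branch length
  ulen <- unique(trav$edge_length)
  Pmap <- lapply(ulen, function(len) bd_transition_matrix(cap, len, lambda, mu))
  names(Pmap) <- sprintf("%.17g", ulen)
  # conditional likelihood per node: list of (nstate x nfam) matrices
  L <- vector("list", trav$ntip + trav$nnode)
  logscale <- numeric(nfam)
  for (i in seq_len(trav$ntip)) {
    M <- matrix(0, nstate, nfam)
    obs <- counts[, i]
    if (epsilon == 0) {
      M[cbind(pmin(obs, cap) + 1L, seq_len(nfam))] <- 1
    } else {
      for (f in seq_len(nfam)) M[, f] <- tip_state_likelihood(obs[f], cap, epsilon)
    }
    L[[i]] <- M
  }
  edge <- trav$edge
  elen <- trav$edge_length
  for (k in seq_len(nrow(edge))) {
    parent <- edge[k, 1]
    child <- edge[k, 2]
    P <- Pmap[[sprintf("%.17g", elen[k])]]
    contrib <- P %*% L[[child]]
    # rescale each family column to avoid underflow on deep trees
    sc <- colSums(contrib)
    sc[sc <= 0] <- 1
    contrib <- contrib / rep(sc, each = nstate)
    logscale <- logscale + log(sc)
    if (is.null(L[[parent]])) {
      L[[parent]] <- contrib
    } else {
      L[[parent]] <- L[[parent]] * contrib
    }
  }
  rootL <- L[[trav$root]]
  M <- if (is.null(root_prior_max)) {
    pmax(apply(counts, 1, max), 1L)
  } else {
    rep_len(pmax(as.integer(root_prior_max), 1L), nfam)
  }
  M <- pmin(M, cap)
  lik <- vapply(seq_len(nfam), function(f) {
    sum(rootL[2:(M[f] + 1L), f]) / M[f]
  }, numeric(1))
  out <- log(lik) + logscale
  names(out) <- rownames(counts)
  out
}

# Tier caps: smallest of 20, 40, 80, ... that is >= 2 * family max count.
cap_tier <- function(max_count) {
  cap <- 20L
  while (cap < 2L * max_count) cap <- cap * 2L
  cap
}

#' Log-likelihood of one family's counts under the birth-death model
#'
#' Computed by postorder pruning over count states `0..cap` with the root
#' likelihood averaged over root sizes `1..root_prior_max` under a uniform
#' prior.
#'
#' @param tree Ultrametric `phylo` (painting ignored).
#' @param counts_row Named integer vector (or one-row data frame) of counts,
#'   covering all tips.
#' @param lambda,mu Gain and loss rates (events/gene/My).
#' @param root_prior_max Upper end of the uniform root-size prior; defaults
#'   to `max(1, max(counts_row))`.
#' @param epsilon Optional tip observation-error weight in `[0, 0.5)`.
#' @param cap State-space truncation; defaults to
#'   `max(2 * max(counts_row), 20)`.
#' @return The log-likelihood (a single number).
#' @export
family_log_likelihood <- function(tree, counts_row, lambda, mu,
                                  root_prior_max = NULL, epsilon = 0,
                                  cap = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(counts_row)) {
    counts_row <- unlist(counts_row[vapply(counts_row, is.numeric, logical(1))])
  }
  if (is.null(names(counts_row))) {
    abort("`counts_row` must be named by tip labels.")
  }
  if (epsilon < 0 || epsilon >= 0.5) {
    abort("`epsilon` must lie in [0, 0.5).")
  }
  missing <- setdiff(tree$tip.label, names(counts_row))
  if (length(missing) > 0) {
    abort(sprintf("Counts are missing tips: %s", paste(missing, collapse = ", ")))
  }
  m <- matrix(as.integer(counts_row[tree$tip.label]), nrow = 1,
              dimnames = list("family", tree$tip.label))
  cap <- cap %||% max(2L * max(m), 20L)
  trav <- tree_traversal(tree)
  unname(bd_loglik_batch(m, trav, as.integer(cap), lambda, mu, epsilon,
                         root_prior_max = root_prior_max))
}

#' Fit global gene gain and loss rates
#'
#' Maximizes the summed per-family pruning log-likelihood over the gain rate
#' lambda (mode `"single"`, where loss = gain) or over (lambda, mu) jointly
#' (mode `"distinct"`). The search runs in log-rate space with bounds
#' `[1e-8, 1]` events/gene/My from deterministic multi-starts; for the
#' distinct-rate mode the single-rate optimum seeds the search, which also
#' guarantees the nesting inequality `lnL(distinct) >= lnL(single)`.
#'
#' For rate estimation the root-size prior is a single uniform distribution
#' `1..R` shared by all families. A per-family prior tied to each family's
#' own maximum count would correlate the prior with the family's realized
#' trajectory and systematically inflate the loss rate, so `R` is instead
#' moment-matched to the table: the prior mean `(R+1)/2` is set to the mean
#' tip count corrected for drift, `R = 2 * mean(counts) * exp(-(lambda-mu)
#' * depth) - 1`, iterating the drift correction once. Pass `root_prior_max`
#' to fix `R` (e.g. to share one prior between the two modes for a
#' likelihood-ratio test; [likelihood_ratio_test()] checks this).
#'
#' @param counts Count table (tibble, `family` first) that already passed
#'   [filter_shared_families()].
#' @param tree Ultrametric `phylo`.
#' @param mode `"single"` or `"distinct"`.
#' @param epsilon Optional tip observation-error weight.
#' @param root_prior_max Fixed upper end of the shared uniform root prior;
#'   `NULL` (default) estimates it from the table as described.
#' @return An object of class `bd_fit`: list with `lambda`, `mu`, `mode`,
#'   `logLik`, `n_params`, `n_families`, `root_prior_max`, `epsilon`.
#' @export
fit_global_rates <- function(counts, tree, mode = c("distinct", "single"),
                             epsilon = 0, root_prior_max = NULL) {
  mode <- match.arg(mode)
  m <- count_matrix(counts)
  depth <- validate_ultrametric(tree)
  trav <- tree_traversal(tree)
  estimate_R <- is.null(root_prior_max)
  R <- if (estimate_R) max(2L, round(2 * mean(m) - 1)) else as.integer(root_prior_max)
  fit <- bd_optimize_rates(m, trav, mode, epsilon, R)
  if (estimate_R) {
    R2 <- max(2L, round(2 * mean(m) * exp(-(fit$lambda - fit$mu) * depth) - 1))
    if (R2 != R) {
      R <- R2
      fit <- bd_optimize_rates(m, trav, mode, epsilon, R,
                               warm = log(c(fit$lambda, fit$mu)))
    }
  }
  fit$root_prior_max <- R
  fit
}

# Rate optimization at a fixed shared root prior 1..R.
bd_optimize_rates <- function(m, trav, mode, epsilon, R, warm = NULL) {
  lb <- log(1e-8)
  ub <- log(1)
  tot <- function(lam, mu) {
    v <- sum(bd_loglik_table_prior(m, trav, lam, mu, epsilon, root_prior_max = R))
    # rates so extreme that the truncated likelihood underflows to zero:
    # return a finite penalty so bounded quasi-Newton search can recover
    if (!is.finite(v)) -1e12 else v
  }
  # single-rate optimum: coarse grid + golden-section refinement
  f1 <- function(lp) tot(exp(lp), exp(lp))
  o1 <- grid_refine_1d(f1, lb, ub, n_grid = 13)
  if (!is.finite(o1$value)) {
    abort("Rate optimization failed to converge (non-finite likelihood).")
  }
  if (mode == "single") {
    lam <- exp(o1$par)
    return(new_bd_fit(lam, lam, "single", o1$value, 1L, nrow(m), epsilon))
  }
  starts <- list(
    c(o1$par, o1$par),
    o1$par + c(log(2), -log(2)),
    o1$par + c(-log(2), log(2))
  )
  if (!is.null(warm)) {
    starts <- c(list(pmin(pmax(warm, lb), ub)), starts)
  }
  nll2 <- function(lp) -tot(exp(lp[1]), exp(lp[2]))
  fit2 <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, nll2, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(factr = 1e5)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(fit2) || o$value < fit2$value)) {
      fit2 <- o
    }
  }
  if (is.null(fit2)) {
    abort("Rate optimization failed to converge from all starts.")
  }
  # enforce nesting against the single-rate optimum
  if (-fit2$value < o1$value) {
    fit2 <- list(par = c(o1$par, o1$par), value = -o1$value)
  }
  new_bd_fit(exp(fit2$par[1]), exp(fit2$par[2]), "distinct", -fit2$value, 2L,
             nrow(m), epsilon)
}

new_bd_fit <- function(lambda, mu, mode, logLik, n_params, n_families, epsilon) {
  structure(
    list(lambda = lambda, mu = mu, mode = mode, logLik = logLik,
         n_params = n_params, n_families = n_families, epsilon = epsilon,
         root_prior_max = NA_integer_),
    class = "bd_fit"
  )
}

#' @export
print.bd_fit <- function(x, ...) {
  cat(sprintf("Birth-death fit (%s rates, %d families)\n", x$mode, x$n_families))
  cat(sprintf("  lambda (gain): %.6g events/gene/My\n", x$lambda))
  cat(sprintf("  mu     (loss): %.6g events/gene/My\n", x$mu))
  cat(sprintf("  log-likelihood: %.4f (k = %d)\n", x$logLik, x$n_params))
  invisible(x)
}

#' Per-clade gain and loss rates
#'
#' Prunes the tree to each group's tips, drops families absent from the
#' group, and refits the birth-death rates, giving one `bd_fit` per group.
#'
#' @inheritParams fit_global_rates
#' @param groups Named list `group -> species` or species/group data frame.
#' @return Named list of `bd_fit` objects.
#' @export
fit_clade_rates <- function(counts, tree, groups, mode = "distinct", epsilon = 0) {
  gm <- as_group_map(groups)
  counts <- validate_count_table(counts)
  purrr::map(gm, function(tips) {
    sub <- prune_tree(tree, tips)
    cols <- c("family", tips)
    tab <- counts[, cols]
    tab <- tab[rowSums(as.matrix(tab[-1])) > 0, , drop = FALSE]
    fit_global_rates(tab, sub, mode = mode, epsilon = epsilon)
  })
}

#' Likelihood-ratio test between single- and distinct-rate fits
#'
#' @param fit_single,fit_distinct `bd_fit` objects (or anything with a
#'   `logLik` element) fitted on the same data.
#' @return A tibble with `statistic` (`2 * (lnL_distinct - lnL_single)`),
#'   `df`, and `p_value` from the chi-squared distribution with 1 df.
#' @export
likelihood_ratio_test <- function(fit_single, fit_distinct) {
  if (is.list(fit_single) && is.list(fit_distinct)) {
    r0 <- fit_single$root_prior_max
    r1 <- fit_distinct$root_prior_max
    if (!is.null(r0) && !is.null(r1) && !anyNA(c(r0, r1)) && r0 != r1) {
      abort("Fits use different root priors; refit with a shared `root_prior_max`.")
    }
  }
  l0 <- if (is.list(fit_single)) fit_single$logLik else fit_single
  l1 <- if (is.list(fit_distinct)) fit_distinct$logLik else fit_distinct
  stat <- 2 * (l1 - l0)
  if (stat < -1e-6) {
    abort(sprintf(
      "Distinct-rate log-likelihood (%.6f) is below the single-rate one (%.6f); optimization failure.",
      l1, l0))
  }
  stat <- max(stat, 0)
  tibble::tibble(statistic = stat, df = 1L,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}
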