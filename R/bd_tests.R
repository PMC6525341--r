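# Monte Carlo family screening and ancestral gene-count reconstruction.

# Fast exact sampler for child counts given parent counts on one branch:
# survivors ~ Binomial(s, 1 - alpha); each survivor contributes
# 1 + Geometric(1 - beta) descendants, so the total extra mass is
# NegBinomial(size = survivors, prob = 1 - beta).
bd_sample_children <- function(s, t, lambda, mu) {
  ab <- bd_alpha_beta(t, lambda, mu)
  alpha <- ab[["alpha"]]
  beta <- ab[["beta"]]
  if (alpha == 0 && beta == 0) {
    return(s)
  }
  surv <- rbinom(length(s), s, 1 - alpha)
  extra <- integer(length(s))
  pos <- surv > 0
  if (any(pos)) {
    extra[pos] <- rnbinom(sum(pos), size = surv[pos], prob = 1 - beta)
  }
  surv + extra
}

# Simulate tip-count rows for n families down the tree, root sizes given.
bd_simulate_tips <- function(tree, root_sizes, lambda, mu) {
  tree <- unclass_painted(tree)
  edge <- tree$edge
  elen <- tree$edge.length
  ntip <- ape::Ntip(tree)
  ord <- order(node_depths(tree)[edge[, 2]]) # preorder by child depth
  states <- matrix(0L, max(edge), length(root_sizes))
  states[ntip + 1L, ] <- as.integer(root_sizes)
  for (k in ord) {
    states[edge[k, 2], ] <- bd_sample_children(states[edge[k, 1], ], elen[k], lambda, mu)
  }
  m <- t(states[seq_len(ntip), , drop = FALSE])
  colnames(m) <- tree$tip.label
  m
}

#' Monte Carlo p-values for accelerated gene gain and loss
#'
#' Null families are simulated under the fitted global rates with the root
#' size drawn from the fit's shared uniform root prior. The screening
#' statistic -- the family log-likelihood under its own uniform root prior
#' (1..max observed count) -- is computed identically for the observed and
#' the simulated families. Because the raw statistic scales with family
#' size, each family is compared only against null families of similar size:
#' the null sample is partitioned into up to `n_bins` groups by quantiles of
#' its maximum tip count, the family is assigned to the group its own
#' maximum falls in, and the p-value is the fraction of that group's
#' statistics at or below the observed one. Conditioning on a binned
#' observed statistic keeps the p-values uniform under the fitted model
#' (each bin's conditional p is uniform, and the mixture of uniforms is
#' uniform) while retaining power against families whose counts are
#' unusually distributed for their size. In total `n_sim * n_bins` null
#' families are simulated so every bin holds about `n_sim` comparisons.
#'
#' @param counts Count table (tibble, `family` column first).
#' @param tree Ultrametric `phylo`.
#' @param fit A `bd_fit` from [fit_global_rates()] (or a list with `lambda`,
#'   `mu`; the root prior is then re-estimated from the table).
#' @param n_sim Null simulations per size bin (default 1000).
#' @param seed Integer seed; same seed, same p-values.
#' @param epsilon Tip observation-error weight used in the likelihoods.
#' @param n_bins Number of size-matched null bins (default 8).
#' @return A tibble `family`, `log_lik`, `p_value`.
#' @export
family_p_values <- function(counts, tree, fit, n_sim = 1000, seed = 1,
                            epsilon = 0, n_bins = 8) {
  if (n_sim < 1) {
    abort("`n_sim` must be at least 1.")
  }
  m <- count_matrix(counts)
  m <- m[, tree$tip.label, drop = FALSE]
  trav <- tree_traversal(tree)
  lambda <- fit$lambda
  mu <- fit$mu
  R <- fit$root_prior_max
  if (is.null(R) || is.na(R)) {
    depth <- validate_ultrametric(tree)
    R <- max(2L, round(2 * mean(m) * exp(-(lambda - mu) * depth) - 1))
  }
  obs_ll <- bd_loglik_table_prior(m, trav, lambda, mu, epsilon)
  obs_max <- apply(m, 1, max)
  n_total <- as.integer(n_sim) * as.integer(n_bins)
  sim <- with_seed(seed, {
    roots <- sample.int(R, n_total, replace = TRUE)
    bd_simulate_tips(tree, roots, lambda, mu)
  })
  sim_ll <- bd_loglik_table_prior(sim, trav, lambda, mu, epsilon)
  sim_max <- apply(sim, 1, max)
  # size bins from null quantiles; the top bin is open-ended so families
  # larger than anything the null produces compare against the largest nulls
  edges <- unique(stats::quantile(sim_max, probs = seq_len(n_bins - 1) / n_bins,
                                  type = 1))
  sim_bin <- findInterval(sim_max, edges, left.open = TRUE) + 1L
  obs_bin <- findInterval(obs_max, edges, left.open = TRUE) + 1L
  p <- numeric(nrow(m))
  for (b in unique(obs_bin)) {
    pool <- sort(sim_ll[sim_bin == b])
    rows <- which(obs_bin == b)
    p[rows] <- findInterval(obs_ll[rows], pool) / length(pool)
  }
  tibble::tibble(family = rownames(m), log_lik = unname(obs_ll),
                 p_value = unname(p))
}

# Per-family log-likelihood where the root prior max is the family's own
# observed maximum (default) or a fixed M, batched by cap tier.
bd_loglik_table_prior <- function(m, trav, lambda, mu, epsilon = 0,
                                  root_prior_max = NULL) {
  fam_max <- pmax(apply(m, 1, max), 1L)
  prior_max <- if (is.null(root_prior_max)) fam_max else rep_len(root_prior_max, nrow(m))
  tiers <- vapply(pmax(fam_max, prior_max), cap_tier, integer(1))
  out <- numeric(nrow(m))
  names(out) <- rownames(m)
  for (cap in sort(unique(tiers))) {
    rows <- which(tiers == cap)
    out[rows] <- bd_loglik_batch(
      m[rows, , drop = FALSE], trav, cap, lambda, mu, epsilon,
      root_prior_max = if (is.null(root_prior_max)) NULL else root_prior_max)
  }
  out
}

#' p-value for a single family
#'
#' Convenience wrapper around [family_p_values()] for one named counts row.
#'
#' @inheritParams family_log_likelihood
#' @inheritParams family_p_values
#' @return The Monte Carlo p-value (single number).
#' @export
family_p_value <- function(tree, counts_row, fit, n_sim = 1000, seed = 1,
                           epsilon = 0) {
  if (is.data.frame(counts_row)) {
    counts_row <- unlist(counts_row[vapply(counts_row, is.numeric, logical(1))])
  }
  tab <- tibble::as_tibble(as.list(counts_row))
  tab <- dplyr::bind_cols(tibble::tibble(family = "f1"), tab)
  family_p_values(tab, tree, fit, n_sim = n_sim, seed = seed,
                  epsilon = epsilon)$p_value
}

#' Max-product ancestral gene counts and branch change calls
#'
#' Viterbi-style reconstruction over count states: the jointly most probable
#' assignment of ancestral counts given the observed tip counts, the fitted
#' rates, and the uniform root prior. Ties in the argmax resolve to the
#' smaller count. Each branch is called `expansion` if the child count
#' exceeds the parent count, `contraction` if below, else `stasis`.
#'
#' @inheritParams family_log_likelihood
#' @return A tibble with one row per non-root node: `node` (label), `parent`
#'   (label), `count`, `parent_count`, `call`.
#' @export
ancestral_counts <- function(tree, counts_row, lambda, mu, epsilon = 0) {
  if (is.data.frame(counts_row)) {
    counts_row <- unlist(counts_row[vapply(counts_row, is.numeric, logical(1))])
  }
  if (is.null(names(counts_row))) {
    abort("`counts_row` must be named by tip labels.")
  }
  m <- matrix(as.integer(counts_row[tree$tip.label]), nrow = 1,
              dimnames = list("f", tree$tip.label))
  rec <- bd_viterbi_batch(m, tree, lambda, mu, epsilon)
  rec[, c("node", "parent", "count", "parent_count", "call")]
}

node_labels <- function(tree) {
  ntip <- ape::Ntip(tree)
  internal <- if (!is.null(tree$node.label) && all(nzchar(tree$node.label))) {
    tree$node.label
  } else {
    paste0("N", seq_len(tree$Nnode) + ntip)
  }
  c(tree$tip.label, internal)
}

# Batched Viterbi reconstruction for a set of families (rows of m).
# Returns a tibble: family, node, parent, count, parent_count, call.
bd_viterbi_batch <- function(m, tree, lambda, mu, epsilon = 0) {
  trav <- tree_traversal(tree)
  labels <- node_labels(trav$tree)
  fam_max <- pmax(apply(m, 1, max), 1L)
  tiers <- vapply(fam_max, cap_tier, integer(1))
  edge <- trav$edge
  elen <- trav$edge_length
  out <- vector("list", length(unique(tiers)))
  t_i <- 0L
  for (cap in sort(unique(tiers))) {
    t_i <- t_i + 1L
    rows <- which(tiers == cap)
    sub <- m[rows, , drop = FALSE]
    sub <- sub[, trav$tree$tip.label, drop = FALSE]
    nstate <- cap + 1L
    ulen <- unique(elen)
    logP <- lapply(ulen, function(len) log(bd_transition_matrix(cap, len, lambda, mu)))
    names(logP) <- sprintf("%.17g", ulen)
    res <- lapply(seq_len(nrow(sub)), function(f) {
      V <- vector("list", trav$ntip + trav$nnode)
      for (i in seq_len(trav$ntip)) {
        v <- log(tip_state_likelihood(sub[f, i], cap, epsilon))
        V[[i]] <- v
      }
      ptr <- vector("list", nrow(edge))
      for (k in seq_len(nrow(edge))) {
        parent <- edge[k, 1]
        child <- edge[k, 2]
        lp <- logP[[sprintf("%.17g", elen[k])]]
        # score[x, y] = logP[x, y] + V_child[y]; best child state per parent state
        score <- sweep(lp, 2, V[[child]], "+")
        best <- max.col(score, ties.method = "first") # smallest y on ties
        ptr[[k]] <- best
        contrib <- score[cbind(seq_len(nstate), best)]
        V[[parent]] <- if (is.null(V[[parent]])) contrib else V[[parent]] + contrib
      }
      M <- min(fam_max[rows[f]], cap)
      root_states <- 2:(M + 1L)
      root_v <- V[[trav$root]][root_states]
      root_state <- root_states[which.max(root_v)] # first max = smallest count
      state <- integer(trav$ntip + trav$nnode)
      state[trav$root] <- root_state - 1L
      for (k in rev(seq_len(nrow(edge)))) { # preorder
        state[edge[k, 2]] <- ptr[[k]][state[edge[k, 1]] + 1L] - 1L
      }
      tibble::tibble(
        family = rownames(sub)[f],
        node = labels[edge[, 2]],
        parent = labels[edge[, 1]],
        count = state[edge[, 2]],
        parent_count = state[edge[, 1]]
      )
    })
    out[[t_i]] <- dplyr::bind_rows(res)
  }
  res <- dplyr::bind_rows(out)
  res$call <- dplyr::case_when(
    res$count > res$parent_count ~ "expansion",
    res$count < res$parent_count ~ "contraction",
    TRUE ~ "stasis"
  )
  res
}

#' Ancestral reconstructions for every family in a table
#'
#' @inheritParams family_p_values
#' @param lambda,mu Gain and loss rates (take them from a [fit_global_rates()]
#'   fit).
#' @return A tibble `family`, `node`, `parent`, `count`, `parent_count`,
#'   `call` with one row per family and non-root node.
#' @export
reconstruct_families <- function(counts, tree, lambda, mu, epsilon = 0) {
  m <- count_matrix(counts)
  bd_viterbi_batch(m, tree, lambda, mu, epsilon)
}

#' Per-node counts of expanding and contracting families
#'
#' Tallies, for every node, how many families have an expansion or a
#' contraction call on the branch subtending that node (the Fig.-style pie
#' numbers). Optionally restricted to a subset of families, e.g. candidate
#' categories.
#'
#' @param calls Reconstruction table from [reconstruct_families()].
#' @param only_families Optional character vector restricting the tally.
#' @return A tibble `node`, `n_expanding`, `n_contracting`, `n_stasis`.
#' @export
summarize_node_changes <- function(calls, only_families = NULL) {
  stopifnot(is.data.frame(calls),
            all(c("family", "node", "call") %in% names(calls)))
  if (!is.null(only_families)) {
    calls <- calls[calls$family %in% only_families, , drop = FALSE]
  }
  nodes <- unique(calls$node)
  base <- tibble::tibble(node = nodes)
  tallied <- calls |>
    dplyr::count(.data$node, .data$call) |>
    tidyr::pivot_wider(names_from = "call", values_from = "n", values_fill = 0L)
  for (col in c("expansion", "contraction", "stasis")) {
    if (!col %in% names(tallied)) tallied[[col]] <- 0L
  }
  dplyr::left_join(base, tallied, by = "node") |>
    dplyr::transmute(
      node = .data$node,
      n_expanding = dplyr::coalesce(.data$expansion, 0L),
      n_contracting = dplyr::coalesce(.data$contraction, 0L),
      n_stasis = dplyr::coalesce(.data$stasis, 0L)
    )
}
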