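# Shared fixtures and independent oracles used across test files.

three_tip_tree <- function() read_newick("((A:1,B:1):1,C:2);")

beetle_groups <- function() {
  tr <- fixture_tree()
  attr(tr, "regime_map")
}

# Tiny painted tree for regime-model tests: two clades of three tips.
small_painted_tree <- function(depth = 10) {
  tr <- read_newick(paste0(
    "(((a1:3,a2:3):4,a3:7):3,((b1:2,b2:2):5,b3:7):3);"))
  tr <- scale_tree_depth(tr, depth)
  paint_regimes(tr, list(A = c("a1", "a2", "a3"), B = c("b1", "b2", "b3")))
}

# Brute-force birth-death family likelihood: sum over all internal-node
# state assignments, states 0..cap, uniform root prior on 1..root_max.
bd_loglik_bruteforce <- function(tree, counts, lambda, mu, root_max, cap = 12) {
  edge <- tree$edge
  ntip <- ape::Ntip(tree)
  n_internal <- tree$Nnode
  states <- 0:cap
  internal_ids <- ntip + seq_len(n_internal)
  grids <- do.call(expand.grid, rep(list(states), n_internal))
  total <- 0
  for (g in seq_len(nrow(grids))) {
    assign_int <- as.integer(grids[g, ])
    state_of <- function(node) {
      if (node <= ntip) counts[[tree$tip.label[node]]] else assign_int[node - ntip]
    }
    root_state <- state_of(ntip + 1L)
    if (root_state < 1 || root_state > root_max) next
    p <- 1 / root_max
    for (k in seq_len(nrow(edge))) {
      p <- p * bd_transition_prob(state_of(edge[k, 1]), state_of(edge[k, 2]),
                                  tree$edge.length[k], lambda, mu)
      if (p == 0) break
    }
    total <- total + p
  }
  log(total)
}

# Brute-force max-product reconstruction over all internal assignments.
bd_viterbi_bruteforce <- function(tree, counts, lambda, mu, root_max, cap = 8) {
  edge <- tree$edge
  ntip <- ape::Ntip(tree)
  n_internal <- tree$Nnode
  grids <- do.call(expand.grid, rep(list(0:cap), n_internal))
  best <- -Inf
  best_assign <- NULL
  for (g in seq_len(nrow(grids))) {
    assign_int <- as.integer(grids[g, ])
    state_of <- function(node) {
      if (node <= ntip) counts[[tree$tip.label[node]]] else assign_int[node - ntip]
    }
    root_state <- state_of(ntip + 1L)
    if (root_state < 1 || root_state > root_max) next
    lp <- 0
    for (k in seq_len(nrow(edge))) {
      pk <- bd_transition_prob(state_of(edge[k, 1]), state_of(edge[k, 2]),
                               tree$edge.length[k], lambda, mu)
      lp <- lp + log(pk)
      if (!is.finite(lp)) break
    }
    # strict > keeps the first (smallest counts) assignment on ties, matching
    # the documented tie-break because expand.grid varies low states first
    if (is.finite(lp) && lp > best + 1e-12) {
      best <- lp
      best_assign <- assign_int
    }
  }
  list(log_prob = best, internal_states = best_assign)
}

# Direct per-pair OU covariance by integrating variance inflow along the
# shared root-to-mrca path (identified by edge identity) and decaying it to
# the present.
ou_cov_pair_oracle <- function(tree, i, j, alpha, sigma2_by_regime) {
  T_depth <- max(lsexpand:::tip_depths(tree))
  depths <- lsexpand:::node_depths(tree)
  er <- edge_regimes(tree)
  edge <- tree$edge
  root <- ape::Ntip(tree) + 1L
  path_edges <- function(tip) {
    rows <- integer(0)
    node <- tip
    while (node != root) {
      k <- which(edge[, 2] == node)
      rows <- c(k, rows)
      node <- edge[k, 1]
    }
    rows
  }
  pi_ <- path_edges(i)
  pj <- path_edges(j)
  shared <- pi_[seq_len(min(length(pi_), length(pj)))]
  shared <- shared[shared == pj[seq_along(shared)]]
  if (length(shared) == 0) return(0)
  acc <- 0
  for (k in shared) {
    s2 <- sigma2_by_regime[[er[k]]]
    f <- function(u) s2 * exp(-2 * alpha * (T_depth - u))
    acc <- acc + stats::integrate(f, depths[edge[k, 1]], depths[edge[k, 2]],
                                  rel.tol = 1e-12)$value
  }
  acc
}

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
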