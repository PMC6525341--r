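#' Read a newick tree
#'
#' @param x Newick text (recognized by containing `(`), or a file path.
#' @return An [ape::read.tree()] `phylo` object with labels preserved.
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  tr <- tryCatch({
    if (grepl("(", x, fixed = TRUE)) ape::read.tree(text = x) else ape::read.tree(x)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    abort(sprintf("Malformed newick input%s.",
                  if (grepl("(", x, fixed = TRUE)) "" else sprintf(" in file '%s'", x)))
  }
  if (is.null(tr$edge.length)) {
    abort("Newick input has no branch lengths.")
  }
  tr
}

#' Write a tree as newick text
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; if `NULL` the newick string is returned.
#' @return The newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(path)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = path)
    invisible(ape::write.tree(tree))
  }
}

# Depth of every node measured from the root, in branch-length units.
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

tip_depths <- function(tree) {
  node_depths(tree)[seq_len(ape::Ntip(tree))]
}

#' Validate that a tree is ultrametric and return its depth
#'
#' All root-to-tip path lengths must agree within `rel_tol` times the tree
#' depth. The deviation check is inclusive, so a tree exactly at the
#' tolerance boundary is accepted.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param rel_tol Relative tolerance on tip-depth deviations.
#' @return The tree depth (maximum root-to-tip length), e.g. in My.
#' @export
validate_ultrametric <- function(tree, rel_tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  assert_scalar_number(rel_tol, "rel_tol", min = 0)
  if (is.null(tree$edge.length)) {
    abort("Tree has no branch lengths.")
  }
  d <- tip_depths(tree)
  ref <- stats::median(d)
  dev <- abs(d - ref)
  bad <- dev > rel_tol * ref
  if (any(bad)) {
    abort(sprintf(
      "Tree is not ultrametric at rel_tol = %g; offending tips: %s",
      rel_tol, paste(tree$tip.label[bad], collapse = ", ")))
  }
  max(d)
}

#' Prune a tree to a set of tips
#'
#' Unbranched internal nodes created by the pruning are suppressed with their
#' branch lengths summed, so tip depths (and hence ultrametricity) are
#' preserved. A painted tree is re-painted from its stored regime map,
#' restricted to the kept tips.
#'
#' @param tree A `phylo` or painted tree.
#' @param keep Character vector of tip labels to retain (at least two).
#' @return The induced subtree.
#' @export
prune_tree <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- as.character(keep)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown tips: %s", paste(unknown, collapse = ", ")))
  }
  if (length(keep) < 2) {
    abort("`keep` must contain at least two tips.")
  }
  regime_map <- attr(tree, "regime_map")
  root_regime <- attr(tree, "root_regime")
  pruned <- ape::keep.tip(unclass_painted(tree), keep)
  if (!is.null(regime_map)) {
    new_map <- lapply(regime_map, intersect, keep)
    new_map <- new_map[vapply(new_map, length, integer(1)) > 0]
    pruned <- paint_regimes(pruned, new_map, root_regime = root_regime)
  }
  pruned
}

# Strip painting attributes, returning a plain phylo.
unclass_painted <- function(tree) {
  attr(tree, "edge_regime") <- NULL
  attr(tree, "regime_map") <- NULL
  attr(tree, "root_regime") <- NULL
  class(tree) <- "phylo"
  tree
}

#' Rescale an ultrametric tree to a target depth
#'
#' Multiplies all branch lengths by `target_depth / depth(tree)`, e.g. to set
#' the root age to a known clade age such as the ~250 My crown age of beetles.
#'
#' @param tree An ultrametric `phylo` (painting is preserved).
#' @param target_depth Desired root-to-tip length.
#' @return The rescaled tree.
#' @export
scale_tree_depth <- function(tree, target_depth) {
  assert_scalar_number(target_depth, "target_depth", min = 1e-12)
  depth <- validate_ultrametric(tree)
  tree$edge.length <- tree$edge.length * (target_depth / depth)
  tree
}

# Node numbers of the subtree rooted at `node` (including `node` itself).
subtree_nodes <- function(tree, node) {
  edge <- tree$edge
  nodes <- node
  frontier <- node
  while (length(frontier) > 0) {
    children <- edge[edge[, 1] %in% frontier, 2]
    nodes <- c(nodes, children)
    frontier <- children
  }
  nodes
}

#' Paint selective regimes onto a tree
#'
#' Each clade in `clade_map` must be monophyletic; all edges inside the clade
#' plus its stem edge receive the clade's regime label. The clades must
#' jointly cover every edge of the tree (e.g. two suborders attached at the
#' root). The root node itself carries `root_regime` as a label only.
#'
#' @param tree A `phylo` object.
#' @param clade_map Named list `regime -> tips` or data frame with columns
#'   `species` and `group`.
#' @param root_regime Label for the root node (default `"root"`).
#' @return The tree with class `painted_phylo` and attributes `edge_regime`
#'   (regime per edge), `regime_map`, and `root_regime`.
#' @export
paint_regimes <- function(tree, clade_map, root_regime = "root") {
  stopifnot(inherits(tree, "phylo"))
  tree <- unclass_painted(tree)
  cm <- as_group_map(clade_map)
  root_regime <- root_regime %||% "root"
  tips <- tree$tip.label
  all_assigned <- unlist(cm)
  if (anyDuplicated(all_assigned)) {
    abort("Clades in `clade_map` must be disjoint.")
  }
  if (!setequal(all_assigned, tips)) {
    abort("Clades in `clade_map` must jointly cover all tips.")
  }
  ntip <- ape::Ntip(tree)
  edge <- tree$edge
  edge_regime <- rep(NA_character_, nrow(edge))
  for (regime in names(cm)) {
    clade_tips <- cm[[regime]]
    idx <- match(clade_tips, tips)
    if (length(idx) == 1) {
      nodes <- idx
    } else {
      mrca <- ape::getMRCA(tree, idx)
      nodes <- subtree_nodes(tree, mrca)
      clade_of_mrca <- tips[nodes[nodes <= ntip]]
      if (!setequal(clade_of_mrca, clade_tips)) {
        abort(sprintf("Tip set for regime '%s' is not monophyletic.", regime))
      }
    }
    sel <- edge[, 2] %in% nodes
    if (any(!is.na(edge_regime[sel]))) {
      abort("Regime paintings overlap; clades must be disjoint subtrees.")
    }
    edge_regime[sel] <- regime
  }
  if (anyNA(edge_regime)) {
    abort("Painting leaves some edges without a regime; clades plus their stems must cover every edge.")
  }
  attr(tree, "edge_regime") <- edge_regime
  attr(tree, "regime_map") <- cm
  attr(tree, "root_regime") <- root_regime
  class(tree) <- c("painted_phylo", "phylo")
  tree
}

#' Regime label of each edge of a painted tree
#'
#' @param tree A painted tree from [paint_regimes()].
#' @return Character vector parallel to `tree$edge` rows.
#' @export
edge_regimes <- function(tree) {
  er <- attr(tree, "edge_regime")
  if (is.null(er)) {
    abort("Tree is not painted; call paint_regimes() first.")
  }
  er
}

#' @export
print.painted_phylo <- function(x, ...) {
  NextMethod()
  cm <- attr(x, "regime_map")
  cat(sprintf("Painted regimes: %s (root: %s)\n",
              paste(sprintf("%s (%d tips)", names(cm),
                            vapply(cm, length, integer(1))), collapse = ", "),
              attr(x, "root_regime")))
  invisible(x)
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the shared root-to-tip path length of tips i and j; the
#' diagonal equals the tree depth for an ultrametric tree. This is the base
#' covariance of a unit-rate Brownian motion on the tree.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A symmetric positive semi-definite species-by-species matrix.
#' @export
tree_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::vcv(unclass_painted(tree))
}

# For each tip, the root-to-tip lineage as a data frame of segments:
# start/end depths and the regime of each edge, ordered root -> tip.
tip_lineages <- function(tree) {
  er <- edge_regimes(tree)
  edge <- tree$edge
  depths <- node_depths(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  parent_of <- integer(max(edge))
  edge_to <- integer(max(edge)) # edge row ending at node
  parent_of[edge[, 2]] <- edge[, 1]
  edge_to[edge[, 2]] <- seq_len(nrow(edge))
  lapply(seq_len(ntip), function(tip) {
    node <- tip
    rows <- integer(0)
    while (node != root) {
      rows <- c(edge_to[node], rows)
      node <- parent_of[node]
    }
    data.frame(
      t0 = depths[edge[rows, 1]],
      t1 = depths[edge[rows, 2]],
      regime = er[rows],
      stringsAsFactors = FALSE
    )
  })
}
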