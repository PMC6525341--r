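# Seeded generators for trees, gene-count tables, trait vectors, and planted
# category enrichment. Defaults emulate the scale of the beetle study: two
# suborder clades of nine species each on a 250 My ultrametric tree, a few
# thousand families evolving at gain/loss rates of about 0.002 events per
# gene per My, and eight candidate categories totalling 91 families.

FIXTURE_NEWICK <- paste0(
  "(((CHYBR:120,(CFRIG:70,EAURE:70):50):80,",
  "((DINEU:60,GMARI:60):110,",
  "(((CLATE:80,SWRAS:80):30,HFLUV:110):30,NCLAV:140):30):30):50,",
  "((ACURT:160,OTAUR:160):45,",
  "(APLAN:190,((TCAST:130,MVIOL:130):30,",
  "(AGLAB:140,((DPOND:60,LTESS:60):30,LDECE:90):50):20):30):15):45);"
)

ADEPHAGA_TIPS <- c("CHYBR", "CFRIG", "EAURE", "NCLAV", "HFLUV", "CLATE",
                   "SWRAS", "DINEU", "GMARI")
POLYPHAGA_TIPS <- c("ACURT", "AGLAB", "APLAN", "DPOND", "LDECE", "LTESS",
                    "MVIOL", "OTAUR", "TCAST")

#' Deterministic 18-species two-clade fixture tree
#'
#' An ultrametric tree of nine Adephaga and nine Polyphaga species (short
#' names) with a 250 My root depth, painted with one regime per suborder and
#' a root regime label. Node ages are synthetic, chosen so the node-age
#' distributions of the two suborders are similar.
#'
#' @return A painted tree (see [paint_regimes()]).
#' @examples
#' validate_ultrametric(fixture_tree())
#' @export
fixture_tree <- function() {
  tree <- read_newick(FIXTURE_NEWICK)
  paint_regimes(tree,
                list(Adephaga = ADEPHAGA_TIPS, Polyphaga = POLYPHAGA_TIPS),
                root_regime = "root")
}

#' Random two-clade ultrametric tree
#'
#' Each clade's labelled topology is drawn from the Markov branching
#' (Yule-type) distribution and rescaled so the clade crowns sit at 80% of
#' the total depth; the two clades join at the root.
#'
#' @param tips_per_group Number of tips in each of the two clades (>= 2).
#' @param depth Root-to-tip depth (e.g. My).
#' @param seed Integer seed; same seed, same newick.
#' @param regimes Names of the two regimes.
#' @return A painted tree.
#' @export
random_tree <- function(tips_per_group = 9, depth = 250, seed = 1,
                        regimes = c("A", "B")) {
  assert_scalar_number(tips_per_group, "tips_per_group", min = 2)
  assert_scalar_number(depth, "depth", min = 1e-9)
  stopifnot(length(regimes) == 2)
  crown <- 0.8 * depth
  clades <- with_seed(seed, {
    lapply(1:2, function(g) {
      cl <- ape::rcoal(tips_per_group,
                       tip.label = sprintf("%s%02d", regimes[g], seq_len(tips_per_group)))
      cl$edge.length <- cl$edge.length * (crown / max(node_depths(cl)))
      cl
    })
  })
  stem <- depth - crown
  newick <- sprintf("(%s:%.10f,%s:%.10f);",
                    sub(";$", "", write_newick(clades[[1]])), stem,
                    sub(";$", "", write_newick(clades[[2]])), stem)
  tree <- read_newick(newick)
  # newick serialization rounds branch lengths; restore the exact depth
  tree <- scale_tree_depth(tree, depth)
  paint_regimes(tree,
                setNames(list(clades[[1]]$tip.label, clades[[2]]$tip.label), regimes),
                root_regime = "root")
}

#' Simulate a gene-family count table under the birth-death model
#'
#' Each family draws a root size and then evolves down the tree, each branch
#' sampling the child count from the linear birth-death transition law (the
#' same law [bd_transition_prob()] evaluates; an independent event-by-event
#' simulator is available as [simulate_counts_gillespie()] for cross-checks).
#'
#' @param tree Ultrametric `phylo` (painting ignored).
#' @param lambda Gain rate (events/gene/My), default 0.002.
#' @param mu Loss rate (events/gene/My), default 0.0018.
#' @param n_families Number of families, default 2000.
#' @param root_max Root sizes are uniform on `1..root_max` (default 10); pass
#'   `root_sizes` to fix them instead.
#' @param root_sizes Optional explicit root sizes (recycled to `n_families`).
#' @param seed Integer seed.
#' @return A count table tibble (`family` column, then one column per tip).
#' @export
simulate_count_table <- function(tree, lambda = 0.002, mu = 0.0018,
                                 n_families = 2000, root_max = 10,
                                 root_sizes = NULL, seed = 1) {
  assert_scalar_number(lambda, "lambda", min = 0)
  assert_scalar_number(mu, "mu", min = 0)
  assert_scalar_number(n_families, "n_families", min = 1)
  m <- with_seed(seed, {
    roots <- if (is.null(root_sizes)) {
      sample.int(as.integer(root_max), n_families, replace = TRUE)
    } else {
      rep_len(as.integer(root_sizes), n_families)
    }
    bd_simulate_tips(tree, roots, lambda, mu)
  })
  tibble::as_tibble(cbind(
    tibble::tibble(family = sprintf("OG%05d", seq_len(nrow(m)))),
    tibble::as_tibble(m)
  ))
}

#' Event-by-event birth-death simulator (cross-check oracle)
#'
#' Simulates every duplication and loss event explicitly with exponential
#' waiting times instead of sampling from the transition law; slower, but an
#' independent check of the distributional machinery.
#'
#' @inheritParams simulate_count_table
#' @return A count table tibble.
#' @export
simulate_counts_gillespie <- function(tree, lambda = 0.002, mu = 0.0018,
                                      n_families = 100, root_max = 10,
                                      root_sizes = NULL, seed = 1) {
  tree_u <- unclass_painted(tree)
  edge <- tree_u$edge
  elen <- tree_u$edge.length
  ntip <- ape::Ntip(tree_u)
  ord <- order(node_depths(tree_u)[edge[, 2]])
  evolve <- function(s, t_total) {
    t <- 0
    repeat {
      if (s == 0) return(0L)
      rate <- s * (lambda + mu)
      if (rate == 0) return(s)
      t <- t + rexp(1, rate)
      if (t > t_total) return(s)
      s <- if (runif(1) < lambda / (lambda + mu)) s + 1L else s - 1L
    }
  }
  with_seed(seed, {
    roots <- if (is.null(root_sizes)) {
      sample.int(as.integer(root_max), n_families, replace = TRUE)
    } else {
      rep_len(as.integer(root_sizes), n_families)
    }
    m <- matrix(0L, n_families, ntip, dimnames = list(NULL, tree_u$tip.label))
    for (f in seq_len(n_families)) {
      states <- integer(max(edge))
      states[ntip + 1L] <- roots[f]
      for (k in ord) {
        states[edge[k, 2]] <- evolve(states[edge[k, 1]], elen[k])
      }
      m[f, ] <- states[seq_len(ntip)]
    }
    tibble::as_tibble(cbind(
      tibble::tibble(family = sprintf("OG%05d", seq_len(n_families))),
      tibble::as_tibble(m)
    ))
  })
}

#' Simulate a continuous trait under a BM or OU regime model
#'
#' Recursive simulation from root to tips using exact branch transitions:
#' Gaussian increments with variance `sigma2 * length` for Brownian motion,
#' and `y_child ~ N(theta + (y_parent - theta) e^(-a l),
#' sigma2 (1 - e^(-2 a l)) / (2 a))` for OU, with regime-specific `theta`
#' and/or `sigma2` where the model calls for them.
#'
#' @param tree Painted ultrametric tree.
#' @param model One of `"BM1"`, `"BMS"`, `"OU1"`, `"OUM"`, `"OUMV"`.
#' @param params List with `sigma2` (scalar or regime-named), `alpha` and
#'   `theta` (regime-named) for OU models, and optional `root_value`
#'   (defaults to the mean of `theta` for OU models, 0 for BM).
#' @param n Number of independent replicate traits.
#' @param seed Integer seed.
#' @return A tibble `rep`, `species`, `value`.
#' @export
simulate_trait <- function(tree, model, params, n = 1, seed = 1) {
  model <- match.arg(model, REGIME_MODELS)
  er <- edge_regimes(tree)
  edge <- tree$edge
  elen <- tree$edge.length
  ntip <- ape::Ntip(tree)
  ord <- order(node_depths(tree)[edge[, 2]])
  s2 <- edge_sigma2(tree, params$sigma2)
  is_ou <- model %in% c("OU1", "OUM", "OUMV")
  alpha <- if (is_ou) params$alpha else 0
  theta_edge <- if (is_ou) {
    th <- params$theta
    if (length(th) == 1 && is.null(names(th))) {
      rep(as.numeric(th), length(er))
    } else {
      as.numeric(th[er])
    }
  } else {
    numeric(length(er))
  }
  root_value <- params$root_value %||% if (is_ou) mean(unlist(params$theta)) else 0
  with_seed(seed, {
    states <- matrix(0, max(edge), n)
    states[ntip + 1L, ] <- root_value
    for (k in ord) {
      y0 <- states[edge[k, 1], ]
      l <- elen[k]
      if (!is_ou || alpha < 1e-12) {
        states[edge[k, 2], ] <- y0 + rnorm(n, 0, sqrt(s2[k] * l))
      } else {
        decay <- exp(-alpha * l)
        v <- s2[k] * (-expm1(-2 * alpha * l)) / (2 * alpha)
        states[edge[k, 2], ] <- theta_edge[k] + (y0 - theta_edge[k]) * decay +
          rnorm(n, 0, sqrt(v))
      }
    }
    tibble::tibble(
      rep = rep(seq_len(n), each = ntip),
      species = rep(tree$tip.label, n),
      value = as.vector(states[seq_len(ntip), , drop = FALSE])
    )
  })
}

#' Plant positive families in background and candidate categories
#'
#' Draws Bernoulli positive flags for a background set and for each candidate
#' category at its own rate, the harness used to exercise the enrichment
#' stage end to end.
#'
#' @param n_background Number of background families.
#' @param background_positive_rate Positive probability in the background
#'   (default 0.009, the order of the beetle study's background rate).
#' @param category_spec Data frame `name`, `n`, `positive_rate`; defaults to
#'   the eight candidate categories at their studied sizes with a planted
#'   tenfold-elevated rate.
#' @param seed Integer seed.
#' @return A tibble `family`, `category` (`"background"` or a category name),
#'   `positive`.
#' @export
plant_categories <- function(n_background = 9629,
                             background_positive_rate = 0.009,
                             category_spec = default_category_spec(),
                             seed = 1) {
  assert_scalar_number(background_positive_rate, "background_positive_rate",
                       min = 0, max = 1)
  if (any(category_spec$positive_rate < 0 | category_spec$positive_rate > 1)) {
    abort("Category positive rates must lie in [0, 1].")
  }
  with_seed(seed, {
    bg <- tibble::tibble(
      family = sprintf("BG%05d", seq_len(n_background)),
      category = "background",
      positive = runif(n_background) < background_positive_rate
    )
    cats <- purrr::pmap(category_spec, function(name, n, positive_rate) {
      tibble::tibble(
        family = sprintf("%s%03d", name, seq_len(n)),
        category = name,
        positive = runif(n) < positive_rate
      )
    })
    dplyr::bind_rows(bg, dplyr::bind_rows(cats))
  })
}

#' Default planted-category specification
#'
#' The eight candidate categories at their studied sizes (91 families in
#' total) with a positive rate ten times the 0.009 background rate.
#'
#' @return A tibble `name`, `n`, `positive_rate`.
#' @export
default_category_spec <- function() {
  tibble::tibble(
    name = c("UGT", "P450", "CE", "GST", "SER", "CYS", "ABC", "GH"),
    n = c(4L, 22L, 19L, 6L, 4L, 7L, 28L, 1L),
    positive_rate = 0.09
  )
}
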