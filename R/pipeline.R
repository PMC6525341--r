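# Full analysis orchestration: shared-family filter -> global gain/loss
# rates and LRT -> per-family Monte Carlo screening -> five-model regime
# comparison on screened families -> direction calls -> per-direction
# category enrichment.

#' Run the full adaptive-expansion analysis
#'
#' Stages are executed in the study's order; the regime models are fitted
#' only to families whose gain/loss p-value falls below `p_threshold`, and
#' enrichment is computed per direction (each regime's positive calls against
#' the full background) and per candidate category.
#'
#' @param counts Count table (tibble, `family` column first).
#' @param tree Painted ultrametric tree with two clade regimes
#'   ([paint_regimes()]; the regimes must match `groups`).
#' @param groups Named list `group -> species` or species/group data frame
#'   with the same two groups as the painting.
#' @param candidates Optional `family`/`category` assignment
#'   ([select_candidate_ogs()]); enables category enrichment and the
#'   candidates-only node-change summary.
#' @param p_threshold Family screening threshold (default 0.01).
#' @param n_sim Simulations per family p-value (default 1000).
#' @param n_draws Draws for the enrichment resampling (default 100,000).
#' @param seed Integer seed driving every stochastic stage.
#' @param epsilon Tip observation-error weight (default 0).
#' @param quiet Suppress progress messages.
#' @return An object of class `lse_report`; see [write_results()].
#' @export
run_pipeline <- function(counts, tree, groups, candidates = NULL,
                         p_threshold = 0.01, n_sim = 1000, n_draws = 1e5,
                         seed = 1, epsilon = 0, quiet = FALSE) {
  if (p_threshold <= 0 || p_threshold >= 1) {
    abort("`p_threshold` must lie in (0, 1).")
  }
  gm <- as_group_map(groups)
  if (!setequal(names(gm), names(attr(tree, "regime_map") %||% list()))) {
    abort("`groups` must name the same regimes as the tree painting.")
  }
  say <- function(...) if (!quiet) inform(sprintf(...))
  counts <- validate_count_table(counts)
  n_input <- nrow(counts)
  counts <- filter_shared_families(counts, gm)
  say("Filtered to %d of %d families shared by both groups.", nrow(counts), n_input)

  say("Fitting global gain/loss rates (single and distinct modes)...")
  fit_distinct <- fit_global_rates(counts, tree, mode = "distinct", epsilon = epsilon)
  fit_single <- fit_global_rates(counts, tree, mode = "single", epsilon = epsilon,
                                 root_prior_max = fit_distinct$root_prior_max)
  lrt <- likelihood_ratio_test(fit_single, fit_distinct)
  fit <- if (lrt$p_value < 0.05) fit_distinct else fit_single
  say("lambda = %.5g, mu = %.5g (%s rates; LRT p = %.3g).",
      fit$lambda, fit$mu, fit$mode, lrt$p_value)

  say("Computing per-family Monte Carlo p-values (n_sim = %d)...", n_sim)
  fam <- family_p_values(counts, tree, fit, n_sim = n_sim,
                         seed = derive_seed(seed, 1), epsilon = epsilon)
  fam$screened <- fam$p_value < p_threshold
  say("%d of %d families (%.1f%%) below the %.3g screen.",
      sum(fam$screened), nrow(fam),
      percent_of(sum(fam$screened), nrow(fam)), p_threshold)

  say("Reconstructing ancestral counts...")
  calls <- reconstruct_families(counts, tree, fit$lambda, fit$mu, epsilon)
  node_changes <- list(all = summarize_node_changes(calls))
  if (!is.null(candidates)) {
    node_changes$candidates <- summarize_node_changes(
      calls, only_families = candidates$family)
  }

  screened_ids <- fam$family[fam$screened]
  say("Fitting regime models to %d screened families...", length(screened_ids))
  m <- count_matrix(counts)
  ctx <- regime_context(tree)
  selection <- purrr::map(screened_ids, function(f) {
    trait <- setNames(as.numeric(m[f, ]), colnames(m))
    fits <- fit_regime_models(trait, tree, ctx = ctx)
    means <- group_means(trait, gm)
    sel <- select_model(fits, means = means)
    aiccs <- vapply(fits, function(x) x$aicc, numeric(1))
    dplyr::bind_cols(
      tibble::tibble(family = f),
      tibble::as_tibble(as.list(setNames(aiccs, paste0("aicc_", tolower(names(aiccs)))))),
      sel,
      tibble::as_tibble(as.list(setNames(means, paste0("mean_", names(means)))))
    )
  }) |> dplyr::bind_rows()
  if (nrow(selection) == 0) {
    selection <- empty_selection(names(gm))
  }

  say("Testing category enrichment per direction (n_draws = %d)...", as.integer(n_draws))
  total <- nrow(fam)
  enrichment <- list()
  comparisons <- list()
  pos_by_regime <- setNames(integer(length(gm)), names(gm))
  for (regime in names(gm)) {
    pos_ids <- selection$family[selection$positive & selection$direction == regime]
    pos_by_regime[regime] <- length(pos_ids)
    if (!is.null(candidates)) {
      cats <- candidates |>
        dplyr::filter(.data$family %in% fam$family) |>
        dplyr::group_by(.data$category) |>
        dplyr::summarise(n = dplyr::n(),
                         k = sum(.data$family %in% pos_ids), .groups = "drop")
      if (nrow(cats) > 0) {
        enrichment[[regime]] <- enrichment_table(
          total, length(pos_ids), cats,
          n_draws = n_draws, seed = derive_seed(seed, 2))
      }
      n_cand <- sum(candidates$family %in% fam$family)
      k_cand <- sum(candidates$family %in% pos_ids)
      comparisons[[paste0("candidates_vs_background_", regime)]] <-
        permutation_enrichment(
          total, length(pos_ids),
          tibble::tibble(category = "candidates", n = n_cand, k = k_cand),
          n_draws = n_draws, seed = derive_seed(seed, 3))
    }
  }
  if (length(gm) == 2 && sum(pos_by_regime) > 0) {
    comparisons$regimes_equal_proportions <- prop_test_2x2(
      pos_by_regime[1], total, pos_by_regime[2], total)
  }

  structure(list(
    config = list(p_threshold = p_threshold, n_sim = n_sim, n_draws = n_draws,
                  seed = seed, epsilon = epsilon, groups = gm,
                  n_input_families = n_input),
    tree = tree,
    global = list(single = fit_single, distinct = fit_distinct, lrt = lrt,
                  selected = fit$mode),
    family_results = fam,
    node_changes = node_changes,
    selection = selection,
    positives_by_regime = pos_by_regime,
    enrichment = enrichment,
    comparisons = comparisons,
    candidates = candidates
  ), class = "lse_report")
}

empty_selection <- function(regimes) {
  tibble::tibble(
    family = character(),
    aicc_bm1 = numeric(), aicc_bms = numeric(), aicc_ou1 = numeric(),
    aicc_oum = numeric(), aicc_oumv = numeric(),
    best_h0 = character(), best_h0_aicc = numeric(),
    best_h1 = character(), best_h1_aicc = numeric(),
    delta_aicc = numeric(), positive = logical(), direction = character()
  ) |>
    dplyr::bind_cols(tibble::as_tibble(
      setNames(rep(list(numeric()), length(regimes)), paste0("mean_", regimes))))
}

#' @export
print.lse_report <- function(x, ...) {
  cat("Adaptive lineage-specific expansion report\n")
  cat(sprintf("  Families analyzed: %d (of %d input)\n",
              nrow(x$family_results), x$config$n_input_families))
  cat(sprintf("  Rates (%s): lambda = %.5g, mu = %.5g; LRT p = %.3g\n",
              x$global$selected, x$global[[x$global$selected]]$lambda,
              x$global[[x$global$selected]]$mu, x$global$lrt$p_value))
  scr <- sum(x$family_results$screened)
  cat(sprintf("  Screened families (p < %.3g): %d (%.1f%%)\n",
              x$config$p_threshold, scr,
              percent_of(scr, nrow(x$family_results))))
  for (r in names(x$positives_by_regime)) {
    cat(sprintf("  Positive adaptive expansions toward %s: %d\n",
                r, x$positives_by_regime[[r]]))
  }
  invisible(x)
}

#' Write a report bundle to TSV and a structured summary
#'
#' Emits per-family results, selection calls, node-change tallies, enrichment
#' tables, and a machine-readable JSON run summary with deterministic column
#' order.
#'
#' @param report An `lse_report` from [run_pipeline()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(report, out_dir) {
  stopifnot(inherits(report, "lse_report"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory '%s'.", out_dir))
  }
  paths <- character()
  wr <- function(tbl, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(tbl, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$family_results, "family_results.tsv")
  wr(report$selection, "selection.tsv")
  wr(report$node_changes$all, "node_changes_all.tsv")
  if (!is.null(report$node_changes$candidates)) {
    wr(report$node_changes$candidates, "node_changes_candidates.tsv")
  }
  if (length(report$enrichment) > 0) {
    enr <- dplyr::bind_rows(report$enrichment, .id = "direction")
    wr(enr, "enrichment.tsv")
  }
  summary <- list(
    config = report$config[c("p_threshold", "n_sim", "n_draws", "seed", "epsilon")],
    rates = list(
      mode = report$global$selected,
      lambda = report$global[[report$global$selected]]$lambda,
      mu = report$global[[report$global$selected]]$mu,
      logLik_single = report$global$single$logLik,
      logLik_distinct = report$global$distinct$logLik,
      lrt_statistic = report$global$lrt$statistic,
      lrt_p = report$global$lrt$p_value
    ),
    n_families = nrow(report$family_results),
    n_screened = sum(report$family_results$screened),
    positives_by_regime = as.list(report$positives_by_regime),
    comparisons = lapply(report$comparisons, function(x) as.list(x))
  )
  p <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
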