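# ggplot2 views of the main result tables.

#' Plot per-node expansion and contraction counts
#'
#' @param node_changes Tibble from [summarize_node_changes()] (or the
#'   `node_changes$all` element of a report).
#' @return A ggplot object: diverging bars, expansions up, contractions down.
#' @export
plot_node_changes <- function(node_changes) {
  stopifnot(all(c("node", "n_expanding", "n_contracting") %in% names(node_changes)))
  df <- node_changes |>
    tidyr::pivot_longer(c("n_expanding", "n_contracting"),
                        names_to = "change", values_to = "n") |>
    dplyr::mutate(
      change = dplyr::if_else(.data$change == "n_expanding", "expansion", "contraction"),
      n = dplyr::if_else(.data$change == "contraction", -.data$n, as.integer(.data$n))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$n, fill = .data$change)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(expansion = "#2e7d32", contraction = "#212121")) +
    ggplot2::labs(x = NULL, y = "families", fill = NULL,
                  title = "Gene-family expansions and contractions per node") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a category enrichment table
#'
#' @param enrichment Tibble from [enrichment_table()] (columns `category`,
#'   `n`, `k`, `fdr`).
#' @param fdr_threshold Reference line (default 0.05).
#' @return A ggplot object of -log10 FDR per category.
#' @export
plot_enrichment <- function(enrichment, fdr_threshold = 0.05) {
  stopifnot(all(c("category", "fdr") %in% names(enrichment)))
  df <- dplyr::mutate(enrichment,
                      fdr_floor = pmax(.data$fdr, 1e-6),
                      label = sprintf("%d/%d", .data$k, .data$n))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$category, -.data$fdr_floor),
                                   y = -log10(.data$fdr_floor))) +
    ggplot2::geom_col(fill = "#1565c0") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.4, size = 3) +
    ggplot2::geom_hline(yintercept = -log10(fdr_threshold), linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ FDR),
                  title = "Category enrichment among adaptive expansions") +
    ggplot2::theme_minimal()
}

#' Plot selection calls against regime means
#'
#' @param selection Selection table from a report (needs `delta_aicc`,
#'   `positive`, and two `mean_*` columns).
#' @return A ggplot object: per-family delta AICc against the mean ratio.
#' @export
plot_selection <- function(selection) {
  mean_cols <- grep("^mean_", names(selection), value = TRUE)
  if (length(mean_cols) != 2) {
    abort("`selection` must have exactly two mean_<regime> columns.")
  }
  df <- dplyr::mutate(
    selection,
    log2_ratio = log2((.data[[mean_cols[2]]] + 0.5) / (.data[[mean_cols[1]]] + 0.5))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_ratio, y = .data$delta_aicc,
                                   colour = .data$positive)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 2, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c62828", `FALSE` = "grey55")) +
    ggplot2::labs(
      x = sprintf("log2 mean ratio (%s / %s)",
                  sub("^mean_", "", mean_cols[2]), sub("^mean_", "", mean_cols[1])),
      y = expression(Delta ~ AICc ~ (H[0] - H[1])),
      colour = "positive",
      title = "Adaptive-expansion calls"
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot method for pipeline reports
#'
#' @param object An `lse_report`.
#' @param type One of `"node_changes"`, `"enrichment"`, `"selection"`.
#' @param ... Passed to the underlying `plot_*` function.
#' @return A ggplot object.
#' @export
autoplot.lse_report <- function(object, type = c("node_changes", "enrichment", "selection"),
                                ...) {
  type <- match.arg(type)
  switch(type,
    node_changes = plot_node_changes(object$node_changes$all, ...),
    enrichment = {
      if (length(object$enrichment) == 0) {
        abort("Report has no enrichment tables (no candidates supplied).")
      }
      plot_enrichment(dplyr::bind_rows(object$enrichment, .id = "direction"), ...)
    },
    selection = plot_selection(object$selection, ...)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
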