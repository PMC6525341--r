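#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a birth-death rate fit
#'
#' @param x A `bd_fit` from [fit_global_rates()].
#' @param ... Unused.
#' @return A tibble with one row per rate parameter.
#' @export
tidy.bd_fit <- function(x, ...) {
  tibble::tibble(
    term = c("lambda", "mu"),
    estimate = c(x$lambda, x$mu),
    units = "events/gene/My"
  )
}

#' One-row summary of a birth-death fit
#'
#' @inheritParams tidy.bd_fit
#' @return A one-row tibble: `mode`, `logLik`, `n_params`, `n_families`.
#' @export
glance.bd_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    logLik = x$logLik,
    n_params = x$n_params,
    n_families = x$n_families
  )
}

#' Tidy a trait-model fit
#'
#' @param x A `regime_fit` from [fit_trait_model()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `regime`, `estimate`).
#' @export
tidy.regime_fit <- function(x, ...) {
  rows <- list()
  s2 <- x$sigma2
  rows$sigma2 <- tibble::tibble(
    term = "sigma2",
    regime = if (is.null(names(s2))) NA_character_ else names(s2),
    estimate = unname(s2)
  )
  if (!is.null(x$alpha)) {
    rows$alpha <- tibble::tibble(term = "alpha", regime = NA_character_,
                                 estimate = x$alpha)
  }
  if (!is.null(x$theta)) {
    rows$theta <- tibble::tibble(term = "theta", regime = names(x$theta),
                                 estimate = unname(x$theta))
  }
  if (!is.null(x$root_state)) {
    rows$root <- tibble::tibble(term = "root_state", regime = NA_character_,
                                estimate = x$root_state)
  }
  dplyr::bind_rows(rows)
}

#' One-row summary of a trait-model fit
#'
#' @inheritParams tidy.regime_fit
#' @return A one-row tibble: `model`, `logLik`, `k`, `n`, `AICc`.
#' @export
glance.regime_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$lnL, k = x$k, n = x$n, AICc = x$aicc)
}

#' Tidy the per-family results of a pipeline run
#'
#' @param x An `lse_report` from [run_pipeline()].
#' @param ... Unused.
#' @return The per-family selection table joined with screening p-values.
#' @export
tidy.lse_report <- function(x, ...) {
  dplyr::left_join(x$family_results, x$selection, by = "family")
}

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.lse_report
#' @return A one-row tibble with rates, LRT, and headline counts.
#' @export
glance.lse_report <- function(x, ...) {
  fit <- x$global[[x$global$selected]]
  out <- tibble::tibble(
    mode = fit$mode,
    lambda = fit$lambda,
    mu = fit$mu,
    lrt_statistic = x$global$lrt$statistic,
    lrt_p = x$global$lrt$p_value,
    n_families = nrow(x$family_results),
    n_screened = sum(x$family_results$screened)
  )
  for (r in names(x$positives_by_regime)) {
    out[[paste0("positive_", r)]] <- x$positives_by_regime[[r]]
  }
  out
}
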