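#' @importFrom rlang abort warn inform %||%
#' @importFrom stats optim optimize pchisq phyper p.adjust prop.test rbinom
#'   rnbinom rnorm runif rexp setNames
#' @importFrom utils head tail
NULL

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded helpers do not disturb the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Sub-seed derivation keeping values well inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(min), format(max)))
  }
  invisible(x)
}

# Format a count as "k/n (xx.x%)", used in run summaries.
percent_of <- function(k, n, digits = 1) {
  assert_scalar_number(k, "k", min = 0)
  assert_scalar_number(n, "n", min = 1)
  round(100 * k / n, digits)
}

# Standardize a species -> group mapping given either a named list
# (group -> character vector of species) or a data frame with columns
# species and group. Returns a named list group -> species.
as_group_map <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("species", "group") %in% names(groups))) {
      abort("`groups` data frame must have columns `species` and `group`.")
    }
    return(split(as.character(groups$species), as.character(groups$group)))
  }
  if (is.list(groups) && !is.null(names(groups))) {
    return(lapply(groups, as.character))
  }
  abort("`groups` must be a named list or a data frame with columns species/group.")
}
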