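#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a correlation matrix into its unordered pairs
#'
#' @param x a `correlation_matrix` (see [curve_similarity_matrix()],
#'   [strain_similarity_matrix()]).
#' @param ... unused.
#' @return tibble `helmet_a, helmet_b, r, p, band, level, location, metric`
#'   with one row per unordered helmet pair.
#' @export
tidy.correlation_matrix <- function(x, ...) {
  k <- length(x$labels)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    helmet_a = x$labels[idx[, 1]],
    helmet_b = x$labels[idx[, 2]],
    r = x$r[idx],
    p = x$p[idx],
    band = correlation_band(x$r[idx]),
    level = x$context$level,
    location = x$context$location,
    metric = x$context$metric
  )
}

#' Summarise a correlation matrix
#'
#' @param x a `correlation_matrix`.
#' @param ... unused.
#' @return one-row tibble with pair count, r range and band counts.
#' @export
glance.correlation_matrix <- function(x, ...) {
  pairs <- tidy(x)
  tibble(
    n_helmets = length(x$labels),
    n_pairs = nrow(pairs),
    r_min = min(pairs$r),
    r_max = max(pairs$r),
    n_weak = sum(pairs$band == "weak"),
    n_moderate = sum(pairs$band == "moderate"),
    n_strong = sum(pairs$band == "strong")
  )
}

#' Tidy a helmet ranking
#'
#' @param x a [helmet_ranking()].
#' @param ... unused.
#' @return tibble `helmet_id, metric, value, rank`.
#' @export
tidy.helmet_ranking <- function(x, ...) {
  x$values |> inner_join(x$ranks, by = c("helmet_id", "metric"))
}

#' Summarise ranking agreement across metrics
#'
#' @param x a [helmet_ranking()].
#' @param ... unused.
#' @return one-row tibble with helmet/metric counts and the Kendall tau-b
#'   range over metric pairs.
#' @export
glance.helmet_ranking <- function(x, ...) {
  tau <- kendall_tau_matrix(x)
  lower <- tau[lower.tri(tau)]
  tibble(
    n_helmets = length(unique(x$ranks$helmet_id)),
    n_metrics = ncol(tau),
    n_tau_pairs = length(lower),
    tau_min = min(lower),
    tau_max = max(lower)
  )
}
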