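#' Average strain summaries across impact locations
#'
#' Arithmetic mean of the per-location percentile summaries for each
#' (helmet, metric); every helmet must have all locations.
#'
#' @param summaries tibble `helmet_id, location, metric, value`.
#' @param locations required locations (default the three canonical ones).
#' @return tibble `helmet_id, metric, value`.
#' @export
average_across_locations <- function(summaries,
                                     locations = c("XRot", "YRot", "ZRot")) {
  chk <- summaries |>
    filter(location %in% locations) |>
    count(helmet_id, metric)
  bad <- chk |> filter(n != length(locations))
  if (nrow(bad) > 0 || nrow(chk) == 0) {
    stop_data(sprintf(
      "missing location(s) for helmet(s): %s",
      paste(unique(bad$helmet_id), collapse = ", ")
    ))
  }
  summaries |>
    filter(location %in% locations) |>
    group_by(helmet_id, metric) |>
    summarise(value = mean(value), .groups = "drop")
}

#' Rank helmets from summary values
#'
#' Ascending ranks (smaller strain = better = rank 1), ties averaged.
#'
#' @param values numeric vector of per-helmet summary values.
#' @return numeric ranks.
#' @export
rank_helmets <- function(values) {
  if (any(!is.finite(values))) stop_data("non-finite summary value")
  rank(values, ties.method = "average")
}

#' Helmet ranking across strain metrics
#'
#' Ranks the helmets per strain metric from location-averaged percentile
#' summaries. The result is a `helmet_ranking` object with [tidy()]/
#' [glance()] methods and an `autoplot()` bump chart.
#'
#' @param summaries tibble `helmet_id, location, metric, value` (per-location
#'   summaries, see [strain_summary()]), or the output of
#'   [average_across_locations()] (no `location` column).
#' @return a `helmet_ranking`: list with tibbles `values` and `ranks`
#'   (`helmet_id, metric, value/rank`).
#' @export
helmet_ranking <- function(summaries) {
  avg <- if ("location" %in% names(summaries)) {
    average_across_locations(summaries)
  } else {
    summaries
  }
  ranks <- avg |>
    group_by(metric) |>
    mutate(rank_value = rank_helmets(value)) |>
    ungroup() |>
    select(helmet_id, metric, rank = rank_value)
  structure(list(values = avg, ranks = ranks), class = "helmet_ranking")
}

#' @export
print.helmet_ranking <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$ranks, names_from = metric, values_from = rank)
  cat(sprintf(
    "<helmet_ranking> %d helmets, %d metrics (rank 1 = lowest strain)\n",
    nrow(wide), ncol(wide) - 1
  ))
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' Kendall's Tau agreement between metric rankings
#'
#' Tau-b (tie-corrected) rank correlation for every unordered pair of strain
#' metrics (10 pairs for 5 metrics); diagonal 1.
#'
#' @param ranking a [helmet_ranking()] (or a tibble like its `ranks` field).
#' @return a symmetric matrix of tau-b coefficients.
#' @export
kendall_tau_matrix <- function(ranking) {
  ranks <- if (inherits(ranking, "helmet_ranking")) ranking$ranks else ranking
  wide <- tidyr::pivot_wider(ranks, names_from = metric, values_from = rank)
  if (anyNA(wide)) stop_data("helmet sets differ between metric rankings")
  m <- as.matrix(wide[setdiff(names(wide), "helmet_id")])
  cor(m, method = "kendall")
}

#' Cross-metric Pearson correlations over all impacts
#'
#' Pearson r and p for every kinematic-by-strain metric pair (7 x 5 = 35
#' tests) and every strain-by-strain pair (10 tests), pooled over all
#' (helmet, location) observations. Coefficients with `|r| > 0.7` are
#' flagged strong.
#'
#' @param table a [metric_table()] with the five strain summary columns
#'   (`MPS, MTON, MTPN, MTOS, MTPS`) appended, one row per
#'   (helmet, location).
#' @param strong_threshold threshold for the strong-correlation flag.
#' @return tibble `metric_a, metric_b, block, r, p, strong` with `block` in
#'   `kinematic_strain` / `strain_strain`.
#' @export
metric_correlations <- function(table, strong_threshold = 0.7) {
  kin <- c("PLA", "HIC", "PAA", "PAV", "BrIC", "UBrIC", "DAMAGE")
  strn <- names(strain_metric_cols())
  missing <- setdiff(c(kin, strn), names(table))
  if (length(missing) > 0) {
    stop_data(paste0(
      "metric table incomplete; missing column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  one <- function(a, b, block) {
    ct <- cor.test(table[[a]], table[[b]], method = "pearson")
    tibble(
      metric_a = a, metric_b = b, block = block,
      r = unname(ct$estimate), p = ct$p.value,
      strong = abs(unname(ct$estimate)) > strong_threshold
    )
  }
  ks <- purrr::map_dfr(
    kin,
    function(a) purrr::map_dfr(strn, function(b) one(a, b, "kinematic_strain"))
  )
  ss <- purrr::map_dfr(
    utils::combn(strn, 2, simplify = FALSE),
    function(pr) one(pr[1], pr[2], "strain_strain")
  )
  bind_rows(ks, ss)
}

#' Join strain summaries onto the kinematic metric table
#'
#' Produces the full 12-column metric table (7 kinematic + 5 strain
#' summaries) with one row per (helmet, location).
#'
#' @param kin_table a [metric_table()].
#' @param summaries tibble `helmet_id, location, metric, value`.
#' @return the joined wide tibble.
#' @export
full_metric_table <- function(kin_table, summaries) {
  wide <- summaries |>
    tidyr::pivot_wider(names_from = metric, values_from = value)
  out <- kin_table |> inner_join(wide, by = c("helmet_id", "location"))
  if (nrow(out) != nrow(kin_table)) {
    stop_data("strain summaries do not cover every (helmet, location)")
  }
  out
}
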