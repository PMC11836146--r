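#' Correlation band labels
#'
#' Bands a Pearson coefficient magnitude into the conventional strength
#' classes: 0-0.3 weak, 0.3-0.7 moderate, 0.7-1 strong.
#'
#' @param r numeric vector of correlation coefficients.
#' @return factor with levels `weak`, `moderate`, `strong`.
#' @export
correlation_band <- function(r) {
  cut(abs(r),
    breaks = c(-Inf, 0.3, 0.7, Inf),
    labels = c("weak", "moderate", "strong")
  )
}

#' Curve-level similarity between two impacts
#'
#' Concatenates the three directional angular-velocity curves of each record
#' (x, then y, then z; 600 samples each on the canonical grid) into one
#' 1800-sample vector and reports the Pearson correlation between the two
#' vectors.
#'
#' @param recA,recB [kin_record()]s at the same impact location, on the same
#'   time grid.
#' @return tibble `r, p, n`.
#' @export
curve_similarity <- function(recA, recB) {
  if (!identical(attr(recA, "location"), attr(recB, "location"))) {
    stop_data("records are from different impact locations")
  }
  if (nrow(recA) != nrow(recB) || max(abs(recA$t - recB$t)) > 1e-9) {
    stop_data("records are not on the same time grid")
  }
  a <- c(recA$wx, recA$wy, recA$wz)
  b <- c(recB$wx, recB$wy, recB$wz)
  ct <- cor.test(a, b, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

new_correlation_matrix <- function(labels, r, p, context) {
  labels <- unname(labels)
  dimnames(r) <- dimnames(p) <- list(labels, labels)
  structure(
    list(labels = labels, r = r, p = p, context = context),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  ctx <- x$context
  cat(sprintf(
    "<correlation_matrix> %s-level, location %s, metric %s: %d helmets, %d pairs\n",
    ctx$level, ctx$location, ctx$metric,
    length(x$labels), choose(length(x$labels), 2)
  ))
  print(round(x$r, 3))
  invisible(x)
}

pairwise_matrix <- function(labels, pair_fun) {
  k <- length(labels)
  r <- diag(1, k)
  p <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      res <- pair_fun(i, j)
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p
    }
  }
  list(r = r, p = p)
}

#' Helmet-pair curve-similarity heatmap for one location
#'
#' All unordered helmet pairs at one impact location (136 for 17 helmets);
#' with three locations the full ensemble yields 408 curve-level
#' correlations.
#'
#' @param records list of [kin_record()]s (the whole ensemble; filtered by
#'   location internally).
#' @param location impact location label.
#' @param helmets optional character vector of required helmet ids (defaults
#'   to all present, sorted).
#' @return a `correlation_matrix`.
#' @export
curve_similarity_matrix <- function(records, location, helmets = NULL) {
  locs <- vapply(records, function(r) attr(r, "location"), character(1))
  recs <- records[locs == location]
  ids <- vapply(recs, function(r) attr(r, "helmet_id"), character(1))
  names(recs) <- ids
  if (is.null(helmets)) helmets <- sort(ids)
  missing <- setdiff(helmets, ids)
  if (length(missing) > 0) {
    stop_data(sprintf(
      "missing helmet(s) at %s: %s", location, paste(missing, collapse = ", ")
    ))
  }
  recs <- recs[helmets]
  m <- pairwise_matrix(helmets, function(i, j) {
    curve_similarity(recs[[i]], recs[[j]])
  })
  new_correlation_matrix(
    helmets, m$r, m$p,
    context = list(level = "curve", location = location,
                   metric = "angular velocity")
  )
}

#' Element-wise strain-distribution correlation between two simulations
#'
#' Pearson correlation over paired per-element strain peaks from two
#' simulations at the same impact location, over the metric's eligible
#' element set (whole brain for MPS, white matter for tract metrics).
#'
#' @param tableA,tableB [strain_peak_table()]s.
#' @param metric one of `"MPS", "MTON", "MTPN", "MTOS", "MTPS"`.
#' @return tibble `r, p, n`.
#' @export
elementwise_distribution_correlation <- function(tableA, tableB,
                                                 metric = "MPS") {
  col <- strain_metric_cols()[[match.arg(metric, names(strain_metric_cols()))]]
  a <- tableA[eligible_rows(tableA, metric), c("element_id", col)]
  b <- tableB[eligible_rows(tableB, metric), c("element_id", col)]
  n_diff <- length(union(
    setdiff(a$element_id, b$element_id),
    setdiff(b$element_id, a$element_id)
  ))
  if (n_diff > 0) {
    stop_data(sprintf(
      "element id sets differ for %s (%d elements not shared)", metric, n_diff
    ))
  }
  b <- b[match(a$element_id, b$element_id), ]
  ct <- cor.test(a[[col]], b[[col]], method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = nrow(a))
}

#' Element-wise strain-correlation heatmap for one location and metric
#'
#' @param peak_tables named list of [strain_peak_table()]s (names or
#'   attributes carry helmet/location).
#' @param location impact location label.
#' @param metric strain metric.
#' @param helmets optional required helmet ids.
#' @return a `correlation_matrix`.
#' @export
strain_similarity_matrix <- function(peak_tables, location, metric = "MPS",
                                     helmets = NULL) {
  locs <- vapply(peak_tables, function(x) attr(x, "location"), character(1))
  tabs <- peak_tables[locs == location]
  ids <- vapply(tabs, function(x) attr(x, "helmet_id"), character(1))
  names(tabs) <- ids
  if (is.null(helmets)) helmets <- sort(ids)
  missing <- setdiff(helmets, ids)
  if (length(missing) > 0) {
    stop_data(sprintf(
      "missing helmet(s) at %s: %s", location, paste(missing, collapse = ", ")
    ))
  }
  tabs <- tabs[helmets]
  m <- pairwise_matrix(helmets, function(i, j) {
    elementwise_distribution_correlation(tabs[[i]], tabs[[j]], metric)
  })
  new_correlation_matrix(
    helmets, m$r, m$p,
    context = list(level = "element", location = location, metric = metric)
  )
}

#' High-strain element set
#'
#' The ids of the `ceiling(fraction * n)` elements with the largest peaks of
#' one metric, within that metric's eligible set. Ties are broken by element
#' id (deterministic).
#'
#' @param peaks a [strain_peak_table()].
#' @param metric strain metric.
#' @param fraction fraction of elements to keep, in (0, 1); default 0.05
#'   (top 5%).
#' @return sorted integer vector of element ids.
#' @export
top_fraction_elements <- function(peaks, metric = "MPS", fraction = 0.05) {
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    stop_parameter("fraction must lie in (0, 1)")
  }
  col <- strain_metric_cols()[[match.arg(metric, names(strain_metric_cols()))]]
  sub <- peaks[eligible_rows(peaks, metric), ]
  k <- ceiling(fraction * nrow(sub))
  ord <- order(-sub[[col]], sub$element_id)
  sort(sub$element_id[ord[seq_len(k)]])
}

#' Jaccard overlap of two element sets
#' @param a,b id vectors.
#' @return scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Normalise an element strain field by its simulation summary
#'
#' Divides each element's peak by the same simulation's percentile summary
#' (default the 95th percentile) of the same metric, so roughly the top 5%
#' of eligible elements exceed 1.
#'
#' @param peaks a [strain_peak_table()].
#' @param metric strain metric.
#' @param summary95 the per-simulation summary value; computed from `peaks`
#'   when `NULL`.
#' @param q percentile used when computing the summary.
#' @return tibble `element_id, region, value` over the eligible set.
#' @export
normalize_field <- function(peaks, metric = "MPS", summary95 = NULL, q = 95) {
  col <- strain_metric_cols()[[match.arg(metric, names(strain_metric_cols()))]]
  mask <- eligible_rows(peaks, metric)
  if (is.null(summary95)) {
    summary95 <- percentile_summary(peaks[[col]], q = q, mask = mask)
  }
  if (!is.finite(summary95) || summary95 <= 0) {
    stop_data("degenerate simulation: percentile summary is not positive")
  }
  tibble(
    element_id = peaks$element_id[mask],
    region = peaks$region[mask],
    value = peaks[[col]][mask] / summary95
  )
}

#' Paired location-effect test on strain summaries
#'
#' Two-sided Wilcoxon matched-pairs signed-rank tests comparing each pair of
#' impact locations on per-helmet summary values of one metric. Pairs are
#' matched by helmet. Zero differences are discarded (standard signed-rank
#' convention; identical samples give p = 1); the exact distribution is used
#' for up to 25 non-zero pairs, the normal approximation above.
#'
#' @param summaries tibble `helmet_id, location, metric, value` (one metric
#'   or several; tested per metric).
#' @param alpha significance threshold recorded in the output.
#' @return tibble `metric, location_a, location_b, n_pairs, statistic, p,
#'   significant, direction` where `direction` names the location with the
#'   larger median difference.
#' @export
location_effect_test <- function(summaries, alpha = 0.05) {
  combos <- summaries |> distinct(metric)
  purrr::map_dfr(combos$metric, function(met) {
    sub <- summaries |> filter(metric == met)
    wide <- sub |>
      select(helmet_id, location, value) |>
      tidyr::pivot_wider(names_from = location, values_from = value)
    locs <- setdiff(names(wide), "helmet_id")
    if (anyNA(wide[locs])) {
      stop_data(sprintf("unmatched helmet sets across locations for %s", met))
    }
    pairs <- utils::combn(sort(locs), 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(pr) {
      d <- wide[[pr[2]]] - wide[[pr[1]]]
      nz <- d[d != 0]
      if (length(nz) == 0) {
        stat <- 0
        pval <- 1
      } else {
        wt <- suppressWarnings(wilcox.test(
          nz,
          alternative = "two.sided",
          exact = length(nz) <= 25, correct = TRUE
        ))
        stat <- unname(wt$statistic)
        pval <- wt$p.value
      }
      tibble(
        metric = met,
        location_a = pr[1], location_b = pr[2],
        n_pairs = length(nz),
        statistic = stat, p = pval,
        significant = pval < alpha,
        direction = if (median(d) > 0) pr[2] else if (median(d) < 0) pr[1] else NA_character_
      )
    })
  })
}
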