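#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a helmet-pair correlation matrix
#'
#' @param object a `correlation_matrix`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.correlation_matrix <- function(object, ...) {
  df <- as_tibble(object$r, rownames = "helmet_a") |>
    tidyr::pivot_longer(-"helmet_a", names_to = "helmet_b", values_to = "r") |>
    mutate(
      helmet_a = factor(helmet_a, levels = object$labels),
      helmet_b = factor(helmet_b, levels = rev(object$labels))
    )
  ggplot(df, aes(x = helmet_a, y = helmet_b, fill = r)) +
    geom_tile() +
    scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b",
      midpoint = 0, limits = c(-1, 1)
    ) +
    coord_fixed() +
    labs(
      x = NULL, y = NULL, fill = "Pearson r",
      title = sprintf(
        "%s-level similarity, %s (%s)",
        object$context$level, object$context$location, object$context$metric
      )
    ) +
    theme_minimal()
}

#' Bump chart of helmet ranks across strain metrics
#'
#' Rank 1 (lowest strain, best helmet) is drawn at the top.
#'
#' @param object a [helmet_ranking()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.helmet_ranking <- function(object, ...) {
  df <- object$ranks
  ggplot(df, aes(
    x = metric, y = rank, group = helmet_id, colour = helmet_id
  )) +
    geom_line(alpha = 0.6) +
    geom_point() +
    scale_y_reverse(breaks = seq_len(max(df$rank))) +
    labs(
      x = NULL, y = "rank (1 = lowest strain)", colour = "helmet",
      title = "Helmet ranking by strain metric"
    ) +
    theme_minimal()
}

#' Time-history panel of one kinematics record
#'
#' @param object a [kin_record()].
#' @param ... unused.
#' @return a ggplot faceted by channel group.
#' @export
autoplot.kin_record <- function(object, ...) {
  df <- as_tibble(object) |>
    select(any_of(c("t", "ax", "ay", "az", "wx", "wy", "wz"))) |>
    tidyr::pivot_longer(-"t", names_to = "channel", values_to = "value") |>
    mutate(group = ifelse(
      startsWith(channel, "a"), "linear acceleration [g]",
      "angular velocity [rad/s]"
    ))
  ggplot(df, aes(x = t, y = value, colour = channel)) +
    geom_line() +
    facet_wrap(~group, scales = "free_y", ncol = 1) +
    labs(
      x = "time [ms]", y = NULL,
      title = sprintf(
        "Helmet %s, %s", attr(object, "helmet_id"), attr(object, "location")
      )
    ) +
    theme_minimal()
}
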