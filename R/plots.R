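#' Plot daily rank trajectories
#'
#' One line per animal across baseline days, colored by final
#' (cumulative) rank and faceted by sex — the standard view of
#' hierarchy stability.
#'
#' @param trajectories Output of [daily_trajectories()].
#' @return A ggplot object.
#' @export
plot_rank_trajectories <- function(trajectories) {
  df <- tibble::as_tibble(trajectories)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$day, y = .data$daily_norm_ds,
    group = .data$individual_id,
    colour = factor(.data$final_rank)
  )) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::stat_summary(
      ggplot2::aes(group = factor(.data$final_rank)),
      fun = mean, geom = "line", linewidth = 1.2
    ) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "Baseline day", y = "Normalized David's Score",
                  colour = "Final rank") +
    ggplot2::theme_minimal()
}

#' Plot rank-maintenance odds against chance
#'
#' @param maintenance Output of [maintenance_counts()].
#' @return A ggplot object; the dashed line marks chance-level odds.
#' @export
plot_maintenance <- function(maintenance) {
  df <- tibble::as_tibble(maintenance)
  df$odds <- (df$k / df$n) / (1 - df$k / df$n)
  chance_odds <- df$p0[1] / (1 - df$p0[1])
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$final_rank), y = .data$odds, fill = .data$sex
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = chance_odds, linetype = 2) +
    ggplot2::labs(x = "Final rank (1 = alpha)",
                  y = "Rank maintenance odds", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scree / score plots for an outcome PCA
#'
#' @param object An `outcome_pca`.
#' @param type `"scree"` (variance explained per component) or
#'   `"scores"` (PC1 vs PC2).
#' @param colour Optional vector used to colour score points.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.outcome_pca <- function(object, type = c("scree", "scores"),
                                 colour = NULL, ...) {
  type <- match.arg(type)
  if (type == "scree") {
    df <- tidy(object, "eigenvalues")
    ggplot2::ggplot(utils::head(df, 10), ggplot2::aes(
      x = .data$component, y = 100 * .data$var_explained
    )) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "Component", y = "% variance explained") +
      ggplot2::theme_minimal()
  } else {
    df <- tidy(object, "scores")
    if (!is.null(colour)) df$colour <- colour
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$PC1, y = .data$PC2
    ))
    if (!is.null(colour)) {
      p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour))
    } else {
      p <- p + ggplot2::geom_point()
    }
    p + ggplot2::theme_minimal()
  }
}

#' Plot the dominance-by-sex interaction on an outcome
#'
#' Scatter of an outcome (e.g. PC1 score) against normalized dominance
#' with per-sex OLS fits, faceted by condition — the display that
#' makes an opposite-slopes interaction visible.
#'
#' @param data Data frame with the plotted columns.
#' @param score,dominance,sex,condition Column names.
#' @return A ggplot object.
#' @export
plot_ds_interaction <- function(data, score = "PC1",
                                dominance = "dominance", sex = "sex",
                                condition = "condition") {
  df <- tibble::as_tibble(data)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[dominance]], y = .data[[score]],
    colour = .data[[sex]]
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(stats::as.formula(paste("~", condition))) +
    ggplot2::labs(x = "Normalized David's Score", y = score,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
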