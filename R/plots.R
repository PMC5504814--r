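#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_vline geom_segment labs theme_minimal scale_y_continuous coord_flip
#' @export
ggplot2::autoplot

#' Plot a treatment ranking
#'
#' Horizontal bars of expected value, ordered by rank, shaded by the
#' confidence index so weakly supported options are visually discounted.
#'
#' @param object A ranking from [rank_options()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hopt_ranking
#' @export
autoplot.hopt_ranking <- function(object, ...) {
  df <- as_tibble(object)
  df$option_id <- stats::reorder(df$option_id, -df$rank)
  ggplot(df, aes(x = .data$option_id, y = .data$expected_value,
                 fill = .data$confidence_index)) +
    geom_col() +
    coord_flip() +
    scale_y_continuous(limits = c(0, 100)) +
    labs(x = NULL, y = "Expected value (0-100)", fill = "Confidence",
         title = "Preference-weighted treatment ranking") +
    theme_minimal()
}

#' Plot a what-if ranking comparison
#'
#' Slope chart of each option's rank under the base and the modified
#' preference weights (rank 1 at the top).
#'
#' @param object A comparison from [what_if()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hopt_whatif
#' @export
autoplot.hopt_whatif <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df) +
    geom_segment(aes(x = 1, xend = 2, y = .data$old_rank, yend = .data$new_rank,
                     colour = .data$option_id)) +
    geom_point(aes(x = 1, y = .data$old_rank, colour = .data$option_id)) +
    geom_point(aes(x = 2, y = .data$new_rank, colour = .data$option_id)) +
    scale_y_continuous(trans = "reverse", breaks = seq_len(nrow(df))) +
    labs(x = NULL, y = "Rank (1 = best)", colour = "Option",
         title = "Ranking under base vs. modified preferences") +
    theme_minimal()
}

#' Plot a daily timeline
#'
#' Line of the daily outcome rating with treatment-plan switch markers and
#' life events; the visual-inspection companion to the single-subject
#' statistics.
#'
#' @param object A timeline from [timeline_export()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hopt_timeline
#' @export
autoplot.hopt_timeline <- function(object, ...) {
  df <- as_tibble(object)
  switches <- df$date[c(FALSE, df$plan_id[-1] != df$plan_id[-nrow(df)])]
  p <- ggplot(df, aes(x = .data$date, y = .data$rating)) +
    geom_line(na.rm = TRUE) +
    geom_point(data = df[!is.na(df$events), ], na.rm = TRUE, colour = "red") +
    labs(x = NULL, y = "Rating (0-100)", title = "Outcome over time",
         subtitle = "Red points mark days with life events; dashed lines mark plan switches") +
    theme_minimal()
  if (length(switches) > 0) {
    p <- p + geom_vline(xintercept = as.numeric(stats::na.omit(switches)),
                        linetype = "dashed", colour = "grey50")
  }
  p
}
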