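# ggplot2 views of the three result types.

#' Plot cumulative prospect values per scheme
#'
#' Bar chart of the cumulative prospect value of each scheme, the selected
#' scheme highlighted; negative values indicate schemes perceived as losses
#' relative to the reference point.
#'
#' @param object A `prospect_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prospect_result <- function(object, ...) {
  df <- mutate(object$utilities,
               selected = .data$scheme == object$selected)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$scheme, -.data$utility),
    y = .data$utility, fill = .data$selected)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#1b7837",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = "scheme", y = "cumulative prospect value",
                  title = "Scheme ranking under cumulative prospect theory")
}

#' Plot decision rules in support/coverage space
#'
#' One point per extracted rule; rules in the upper right match many
#' objects and dominate their decision class, so they rank first during
#' classification.
#'
#' @param object A `rule_list`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rule_list <- function(object, ...) {
  df <- tibble(rank = object$rank, support = object$support,
               coverage = object$coverage,
               decision_label = object$decision_label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$support, y = .data$coverage,
                                   colour = .data$decision_label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$rank), nudge_y = 0.03,
                       size = 3, show.legend = FALSE) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1.05)) +
    ggplot2::labs(x = "support", y = "coverage", colour = "decision",
                  title = "Decision rules (labelled by rank)")
}

#' Plot department weights and group utilities
#'
#' Two-panel view of a group aggregation: department weights (left) and
#' scheme utilities under the comprehensive group matrix (right),
#' faceted into a single figure.
#'
#' @param object A `group_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_result <- function(object, ...) {
  df <- bind_rows(
    tibble(panel = "department weights",
           item = names(object$weights), value = unname(object$weights)),
    tibble(panel = "scheme utility",
           item = object$utilities$scheme,
           value = object$utilities$utility))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item, y = .data$value)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Multi-department aggregation")
}
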