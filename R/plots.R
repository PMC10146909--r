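# ggplot2 displays for the main result types.

#' Plot per-column conservation ranks
#'
#' Columns colored by conservation class, with the class boundaries (0.33,
#' 0.50, 0.66) drawn as reference lines.
#'
#' @param profiles A `column_profiles` tibble from [column_profile()].
#' @return A ggplot object.
#' @export
plot_conservation <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$column, y = .data$rank,
                               color = .data$class)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = c(0.33, 0.50, 0.66),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(
      ultra = "#1b7837", conservative = "#5aae61",
      weak = "#fdb863", excluded = "grey70")) +
    ggplot2::labs(x = "alignment column", y = "top-residue rank",
                  color = "class") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.column_profiles <- function(object, ...) {
  plot_conservation(object)
}

#' Plot a cysteine report
#'
#' Conservation calls of each reference cysteine at the three grouping
#' levels, with basic-flanked cysteines marked.
#'
#' @param report A `cysteine_report` from [build_cysteine_report()].
#' @return A ggplot object.
#' @export
plot_cysteine_report <- function(report) {
  long <- tidyr::pivot_longer(
    report$cysteines,
    c("in_reference_group", "in_clade", "in_family"),
    names_to = "level", values_to = "call")
  long$level <- factor(long$level,
                       levels = c("in_reference_group", "in_clade", "in_family"),
                       labels = c("reference group", "clade", "family"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$position),
                                     y = .data$level, fill = .data$call)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_point(
      data = dplyr::filter(long, .data$basic_flank,
                           .data$level == "reference group"),
      ggplot2::aes(y = 0.4), shape = 8, size = 1.5, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(
      Yes = "#1b7837", Partially = "#a6dba0", No = "#c2a5cf",
      NotAlignable = "grey80")) +
    ggplot2::labs(x = "reference cysteine position", y = NULL,
                  fill = "conserved") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @exportS3Method ggplot2::autoplot
autoplot.cysteine_report <- function(object, ...) {
  plot_cysteine_report(object)
}

#' Plot penalty scores per sequence
#'
#' @param penalties Tibble from [penalty_score()] (both modes may be mixed;
#'   they are faceted).
#' @return A ggplot object.
#' @export
plot_penalties <- function(penalties) {
  ggplot2::ggplot(penalties,
                  ggplot2::aes(x = stats::reorder(.data$id, .data$penalty),
                               y = .data$penalty)) +
    ggplot2::geom_col(fill = "#5aae61") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~mode, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "frequency-weighted penalty") +
    ggplot2::theme_minimal()
}
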