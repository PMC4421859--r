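# ggplot2 views of screen and trait-profile results.

#' Plot a functional-category screen
#'
#' Horizontal bar chart of the body-mass-controlled partial correlation of
#' each category with the response, coloured by retention at the screen's
#' alpha.
#'
#' @param screen A screen tibble from [correlation_screen()].
#' @param top_n Show at most this many categories (by |partial r|).
#' @return A ggplot object.
#' @export
plot_screen <- function(screen, top_n = 15L) {
  dat <- screen |>
    dplyr::arrange(dplyr::desc(abs(.data$r_s_partial))) |>
    head(top_n)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$r_s_partial,
    y = stats::reorder(.data$category, .data$r_s_partial),
    fill = .data$retained
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey70"),
      name = "p < alpha"
    ) +
    ggplot2::labs(
      x = "Partial Spearman r (body-mass-controlled)",
      y = NULL,
      title = "Functional categories vs response"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a trait against the oxic gene proportion
#'
#' @param data Joined trait/profile tibble with an `Oxic metabolism` (or
#'   `oxic_proportion`) column.
#' @param y Trait column to plot (default `"q_W_per_g"`).
#' @param log_y Use a log10 y axis (appropriate for rates and lifespans).
#' @return A ggplot object.
#' @export
plot_oxic_scatter <- function(data, y = "q_W_per_g", log_y = TRUE) {
  ox <- if ("oxic_proportion" %in% names(data)) {
    "oxic_proportion"
  } else {
    "Oxic metabolism"
  }
  p <- ggplot2::ggplot(data, ggplot2::aes(
    x = .data[[ox]], y = .data[[y]],
    colour = log10(.data$mass_g)
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(name = "log10 mass (g)") +
    ggplot2::labs(x = "Proportion of oxic genes", y = y) +
    ggplot2::theme_minimal()
  if (isTRUE(log_y)) {
    p <- p + ggplot2::scale_y_log10()
  }
  p
}
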