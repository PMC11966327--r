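#' Tornado diagram
#'
#' Horizontal bars of incremental NMB swings, widest at the top.
#'
#' @param torn Ordered data frame from [tornado()].
#' @param top Show at most this many parameters.
#' @return A ggplot object.
#' @export
plot_tornado <- function(torn, top = 15) {
  torn <- utils::head(torn, top)
  torn$parameter <- factor(torn$parameter, levels = rev(torn$parameter))
  ggplot2::ggplot(torn) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$nmb_low, xend = .data$nmb_high,
                                       y = .data$parameter, yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$nmb_base[1]),
                        linetype = "dashed") +
    ggplot2::labs(x = "Incremental net monetary benefit (USD)", y = NULL,
                  title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' @param ceac_df Data frame from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df) {
  ggplot2::ggplot(ceac_df,
                  ggplot2::aes(x = .data$wtp, y = .data$acceptability,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
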