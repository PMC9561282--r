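#' Scatter of per-site fold changes with classification
#'
#' Control-arm vs knockdown-arm damaged/undamaged log2 fold change per site,
#' coloured by class, with the identity line and the +/- tau classification
#' band.
#'
#' @param quants A classified site table from [classify_sites()].
#' @param tau Band half-width; defaults to the value stored at classification.
#' @return A ggplot object.
#' @export
plot_site_classes <- function(quants, tau = NULL) {
  assert_data_frame(quants, "quants", c("log2fc_ctrl", "log2fc_kd", "class"))
  tau <- tau %||% attr(quants, "tau") %||% 0.5
  ggplot2::ggplot(quants,
                  ggplot2::aes(.data$log2fc_ctrl, .data$log2fc_kd,
                               colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 1,
                         colour = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = c(-tau, tau), linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      dependent = "#1f4e9c", independent = "#7fa8d9", increased = "grey55"
    )) +
    ggplot2::labs(
      x = "log2 FC damaged/undamaged (control siRNA)",
      y = "log2 FC damaged/undamaged (knockdown siRNA)",
      colour = "site class"
    ) +
    ggplot2::theme_classic()
}

#' Break-centred metagene profile
#'
#' @param profile A [metagene_profile()] (or several row-bound, with an extra
#'   grouping column passed as `colour`).
#' @param colour Optional name of a column to colour profiles by.
#' @return A ggplot object.
#' @export
plot_metagene <- function(profile, colour = NULL) {
  assert_data_frame(profile, "profile", c("bin_center", "mean_log2fc"))
  mapping <- if (is.null(colour)) {
    ggplot2::aes(.data$bin_center, .data$mean_log2fc)
  } else {
    ggplot2::aes(.data$bin_center, .data$mean_log2fc,
                 colour = .data[[colour]])
  }
  ggplot2::ggplot(profile, mapping) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from cut site (bp)",
                  y = "mean log2 FC damaged/undamaged") +
    ggplot2::theme_classic()
}

#' Pre-existing hybrid level vs induced fold change
#'
#' The correlation plot behind the control-arm / knockdown-arm switch: one
#' point per site, pre-existing (undamaged) hybrid signal on x, the chosen
#' arm's damaged/undamaged log2 fold change on y, with a least-squares line.
#'
#' @param quants A `site_quant` table.
#' @param arm `"ctrl"` or `"kd"`.
#' @return A ggplot object.
#' @export
plot_hybrid_correlation <- function(quants, arm = c("ctrl", "kd")) {
  arm <- rlang::arg_match(arm)
  col <- paste0("log2fc_", arm)
  assert_data_frame(quants, "quants", c("preexisting", col))
  ggplot2::ggplot(quants, ggplot2::aes(.data$preexisting, .data[[col]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#1f4e9c") +
    ggplot2::labs(
      x = "pre-existing DNA:RNA-hybrid level (normalized signal, -OHT ctrl)",
      y = paste0("log2 FC damaged/undamaged (", arm, " siRNA)")
    ) +
    ggplot2::theme_classic()
}

#' Histogram of cross-study identification frequency
#'
#' @param table A [frequency_table()], optionally annotated; when `flag` is
#'   given, bars are filled by that logical column (e.g. hybrid interactors).
#' @param flag Optional annotation column name.
#' @param kmin Only show proteins identified in at least this many studies.
#' @return A ggplot object.
#' @export
plot_hit_frequency <- function(table, flag = NULL, kmin = 1) {
  assert_data_frame(table, "table", c("protein", "k"))
  df <- dplyr::filter(tibble::as_tibble(table), .data$k >= kmin)
  df$protein <- factor(df$protein,
                       levels = rev(df$protein[order(-df$k, df$protein)]))
  mapping <- if (is.null(flag)) {
    ggplot2::aes(.data$protein, .data$k)
  } else {
    ggplot2::aes(.data$protein, .data$k, fill = .data[[flag]])
  }
  p <- ggplot2::ggplot(df, mapping) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "studies identifying the protein") +
    ggplot2::theme_classic()
  if (!is.null(flag)) {
    p <- p + ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                                   `TRUE` = "#18b5c4"))
  }
  p
}
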