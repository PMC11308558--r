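#' Histogram break points for screening displays
#'
#' High-resolution equal-width binning (100 bins by default) or the
#' Freedman-Diaconis rule.
#'
#' @param x Numeric values (missing dropped).
#' @param rule `"equal"` (default, `bins` equal-width bins) or `"fd"`.
#' @param bins Number of bins for the equal-width rule.
#' @return Numeric vector of break points.
#' @export
histogram_breaks <- function(x, rule = c("equal", "fd"), bins = 100L) {
  rule <- match.arg(rule)
  x <- x[!is.na(x)]
  if (rule == "equal") {
    return(seq(min(x), max(x), length.out = bins + 1L))
  }
  h <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (h <= 0) {
    return(seq(min(x), max(x), length.out = bins + 1L))
  }
  seq(min(x), max(x) + h, by = h)
}

#' Combo plot of a continuous variable
#'
#' High-resolution histogram with a quartile/extreme strip and a data rug:
#' the standard univariate screening display, optionally on the selected
#' transformed scale. Requires ggplot2.
#'
#' @param ds An `ida_dataset`.
#' @param var Variable name.
#' @param decisions Optional transformation decisions from
#'   [select_transformations()]; when the variable has a chosen transform
#'   the plot is drawn on that scale (axis labelled `t_<var>`).
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
ida_combo_plot <- function(ds, var, decisions = NULL, bins = 100L) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting.")
  }
  x <- display_values(ds, var, decisions)
  transformed <- !is.null(decisions) &&
    var %in% decisions$variable[decisions$chosen %in% c("pseudolog", "cuberoot")]
  lab <- if (transformed) paste0("t_", var) else var
  df <- data.frame(x = x[!is.na(x)])
  q <- quantile(df$x, c(0, 0.25, 0.5, 0.75, 1), type = 7)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60", colour = NA) +
    ggplot2::geom_vline(xintercept = q, linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_rug(alpha = 0.2, length = ggplot2::unit(0.02, "npc")) +
    ggplot2::labs(x = lab, y = "count") +
    ggplot2::theme_minimal()
}
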