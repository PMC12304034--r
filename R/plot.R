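# Optional figure layer (off the critical path).

#' Scatter of a physiological response with post-inflection regressions
#'
#' Plots the per-individual points of a response against air temperature
#' for one or two groups, overlaying each group's fitted segmented line
#' above its breakpoint (the conventional presentation of heat-response
#' data). Requires ggplot2.
#'
#' @param points data.frame with `ta`, the response column and a grouping
#'   column.
#' @param response name of the response column.
#' @param fits named list of [fit_segmented_lmm()] objects, one per group
#'   level (entries may be `NULL` for linear groups).
#' @param group name of the grouping column (default `"group"`).
#' @return a ggplot object.
#' @export
plot_response <- function(points, response, fits = list(), group = "group") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plot_response() needs the ggplot2 package")
  stopifnot(all(c("ta", response, group) %in% names(points)))
  p <- ggplot2::ggplot(points, ggplot2::aes(
    x = .data[["ta"]], y = .data[[response]],
    shape = .data[[group]], colour = .data[[group]]))
  p <- p + ggplot2::geom_point(alpha = 0.7)
  for (g in names(fits)) {
    f <- fits[[g]]
    if (is.null(f)) next
    ta_max <- max(points$ta[points[[group]] == g])
    seg <- data.frame(ta = seq(f$psi, ta_max, length.out = 50))
    seg$y <- f$intercept + f$slope_below * seg$ta +
      (f$slope_above - f$slope_below) * (seg$ta - f$psi)
    seg[[group]] <- g
    p <- p + ggplot2::geom_line(
      data = seg, ggplot2::aes(x = .data[["ta"]], y = .data[["y"]],
                               colour = .data[[group]]),
      inherit.aes = FALSE, linewidth = 0.8)
  }
  p + ggplot2::labs(x = "Air temperature (degC)", y = response)
}
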