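#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's result
#' objects: the similarity curve over the shift axis, the sarcomere
#' length / shortening-rate trace, the ROI-placement sensitivity map
#' (invalid centers blank), and the orientation sweep with its fitted
#' `P / cos(alpha - alpha0)` curve.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name sarclen-autoplot
NULL

#' @rdname sarclen-autoplot
#' @param step Shift grid step used to draw the curve.
#' @export
autoplot.similarity_curve <- function(object, step = 0.01, ...) {
  df <- tidy(object, step = step)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shift, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "shift (px)", y = "similarity measure",
                  title = sprintf("%s similarity measure", object$method)) +
    ggplot2::theme_minimal()
}

#' @rdname sarclen-autoplot
#' @export
autoplot.sarcomere_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[c("time_s", "sl_um", "rate_um_s")],
    c("sl_um", "rate_um_s"),
    names_to = "quantity", values_to = "value")
  df$quantity <- factor(df$quantity, c("sl_um", "rate_um_s"),
                        c("sarcomere length (μm)",
                          "shortening rate (μm/s)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~quantity, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname sarclen-autoplot
#' @export
autoplot.sl_map <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$center_col, y = .data$center_row,
                               fill = .data$sl_px)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "ROI center column", y = "ROI center row",
                  fill = "SL (px)") +
    ggplot2::theme_minimal()
}

#' @rdname sarclen-autoplot
#' @export
autoplot.orientation_scan <- function(object, ...) {
  df <- object$samples[object$samples$valid, ]
  a <- seq(min(df$angle_deg), max(df$angle_deg), length.out = 200L)
  fitted <- tibble(
    angle_deg = a,
    sl_px = object$corrected_sl_px /
      cos((a - object$alpha0_deg) * pi / 180))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle_deg, y = .data$sl_px)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fitted, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$alpha0_deg, linetype = 2) +
    ggplot2::labs(x = "ROI angle (deg)", y = "estimated period (px)") +
    ggplot2::theme_minimal()
}
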