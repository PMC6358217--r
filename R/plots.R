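#' Plot the along-membrane intensity profile
#'
#' Intensity against arc position around the membrane, coloured by domain —
#' the standard way to show posterior exclusion or accumulation at a glance.
#'
#' @param x An `oocyte_quantification` or its `$profile` tibble.
#' @return A ggplot.
#' @export
plot_membrane_profile <- function(x) {
  profile <- if (inherits(x, "oocyte_quantification")) x$profile else x
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$arc_position, y = .data$intensity,
                               colour = .data$domain)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      anterior = "#d62728", lateral1 = "#2ca02c",
      lateral2 = "#98df8a", posterior = "#1f77b4"
    )) +
    ggplot2::labs(x = "Arc position (px)", y = "Membrane intensity",
                  colour = "Domain") +
    ggplot2::theme_minimal()
}

#' @rdname plot_membrane_profile
#' @param object An `oocyte_quantification`.
#' @param ... Unused.
#' @export
autoplot.oocyte_quantification <- function(object, ...) {
  plot_membrane_profile(object)
}

#' Plot FRAP recovery curves
#'
#' One panel per normalisation: the rebased curves (post-bleach, starting at
#' 0) and the pre-bleach-normalised curves (pre-bleach level 1).
#'
#' @param result A `frap_result` from [frap_analyze()].
#' @return A ggplot.
#' @export
plot_frap_curves <- function(result) {
  stopifnot(inherits(result, "frap_result"))
  long <- tidy(result)
  d <- dplyr::bind_rows(
    dplyr::transmute(long, .data$time_s, .data$domain,
                     value = .data$rebased, normalisation = "rebased to 0"),
    dplyr::transmute(long, .data$time_s, .data$domain,
                     value = .data$prebleach_normalized,
                     normalisation = "pre-bleach = 1")
  )
  ggplot2::ggplot(dplyr::filter(d, !is.na(.data$value)),
                  ggplot2::aes(.data$time_s, .data$value, colour = .data$domain)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(
      xintercept = result$series$data$time_s[result$bleach_index],
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::facet_wrap(~normalisation, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Quantity", colour = "Domain") +
    ggplot2::theme_minimal()
}

#' @rdname plot_frap_curves
#' @param object A `frap_result`.
#' @param ... Unused.
#' @export
autoplot.frap_result <- function(object, ...) plot_frap_curves(object)

#' Tukey box plot of a per-oocyte metric across groups
#'
#' Boxes span the quartiles with whiskers at the most extreme data within
#' 1.5 IQR (Tukey variation); individual oocytes are overplotted.
#'
#' @param data Data frame of per-oocyte metrics.
#' @param value Metric column (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @return A ggplot.
#' @export
plot_group_box <- function(data, value, group) {
  ggplot2::ggplot(data, ggplot2::aes({{ group }}, {{ value }})) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, size = 1, alpha = 0.7) +
    ggplot2::theme_minimal()
}
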