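# ggplot2 visualisations of the main result types.

#' Plot a spectral fit
#'
#' Log-log plot of the rotationally averaged power spectrum with the fitted
#' line over the fit range.
#'
#' @param object A `spectral_fit` from [spectral_slope()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectral_fit
#' @export
autoplot.spectral_fit <- function(object, ...) {
  df <- tibble(freq = object$radial_freqs, power = object$radial_power) |>
    filter(.data$power > 0)
  in_range <- df$freq >= object$fit_range[1] & df$freq <= object$fit_range[2]
  ggplot2::ggplot(df, ggplot2::aes(log10(.data$freq), log10(.data$power))) +
    ggplot2::geom_point(ggplot2::aes(colour = in_range), size = 0.8,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "steelblue")) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2, colour = "deeppink3") +
    ggplot2::labs(
      x = "log10 frequency (cycles/image)", y = "log10 power",
      title = sprintf("Spectral slope = %.3f", object$slope)
    ) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a preference model fit
#'
#' Fixed-effect estimates with 95% Wald intervals, intercept omitted.
#'
#' @param object A `prefeat_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prefeat_fit
#' @export
autoplot.prefeat_fit <- function(object, ...) {
  df <- object$coefficients |>
    filter(.data$term != "(Intercept)") |>
    mutate(term = stats::reorder(.data$term, .data$estimate),
           lo = .data$estimate - 1.96 * .data$std_error,
           hi = .data$estimate + 1.96 * .data$std_error)
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::labs(x = "coefficient (z-scored predictors)", y = NULL,
                  title = sprintf("%s mixed model (%d obs, %d participants)",
                                  object$family, object$n_observations,
                                  object$n_participants)) +
    ggplot2::theme_minimal()
}

#' Feature-by-model coefficient grid
#'
#' Tile grid of fixed-effect estimates across several fits (e.g. one per
#' sample or category), annotated with the coefficient value and
#' significance stars -- the standard summary layout for multi-sample
#' feature--preference analyses.
#'
#' @param fits A named list of `prefeat_fit` objects; names label the
#'   columns.
#' @param drop_intercept Omit the intercept row (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_coefficient_grid <- function(fits, drop_intercept = TRUE) {
  stopifnot(length(fits) > 0, !is.null(names(fits)))
  df <- purrr::imap_dfr(fits, ~ mutate(tidy(.x), model = .y))
  if (drop_intercept) df <- filter(df, .data$term != "(Intercept)")
  df <- df |>
    mutate(stars = dplyr::case_when(
      .data$p_value < 0.001 ~ "***",
      .data$p_value < 0.01 ~ "**",
      .data$p_value < 0.05 ~ "*",
      TRUE ~ ""
    ))
  ggplot2::ggplot(df, ggplot2::aes(.data$model, .data$term,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%s", .data$estimate, .data$stars)
    ), size = 3) +
    ggplot2::scale_fill_gradient2(low = "mediumpurple4", mid = "white",
                                  high = "palevioletred3", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "estimate") +
    ggplot2::theme_minimal()
}
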