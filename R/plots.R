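#' Plot a diagnostic-accuracy report as a confusion heatmap
#'
#' @param object A `breslow_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot breslow_eval
#' @export
autoplot.breslow_eval <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object$confusion)))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$predicted, y = .data$true, fill = .data$count
  )) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev(breslow_levels())) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(
      x = "Predicted category", y = "Histological category",
      title = sprintf(
        "kappa = %.3f (%.3f-%.3f)",
        object$kappa, object$kappa_low, object$kappa_high
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot fitted versus observed thickness for a regression fit
#'
#' @param object A `breslow_lm` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot breslow_lm
#' @export
autoplot.breslow_lm <- function(object, ...) {
  df <- augment(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$observed_mm, y = .data$fitted_mm
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "Histological Breslow thickness (mm)",
      y = "Model-fitted thickness (mm)",
      title = sprintf("Multivariate fit, r = %.3f", object$r)
    ) +
    ggplot2::theme_minimal()
}

#' Scatter of simulated ultrasound readings against true thickness
#'
#' @param cohort A cohort tibble holding `true_breslow_mm` and
#'   `hfus_measured_mm` (from [simulate_hfus()]).
#' @return A ggplot object.
#' @export
plot_hfus_agreement <- function(cohort) {
  r <- pearson_r(cohort$hfus_measured_mm, cohort$true_breslow_mm)$r
  ggplot2::ggplot(cohort, ggplot2::aes(
    x = .data$true_breslow_mm, y = .data$hfus_measured_mm
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "Histological Breslow thickness (mm)",
      y = "Simulated ultrasound thickness (mm)",
      title = sprintf("Ultrasound agreement, r = %.3f", r)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
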