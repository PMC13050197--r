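#' Plot phased against unphased predictions
#'
#' Scatter of the two closed-form predictions across crosses; points off
#' the identity line show variance contributed (or removed) by linkage
#' phase between loci.
#'
#' @param object A `seg_prediction` tibble with both `sigma2_phased` and
#'   `sigma2_unphased`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seg_prediction <- function(object, ...) {
  if (!all(c("sigma2_phased", "sigma2_unphased") %in% names(object))) {
    abort("need both `sigma2_phased` and `sigma2_unphased` columns.")
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$sigma2_unphased,
                               y = .data$sigma2_phased)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = expression(sigma[unphased]^2),
      y = expression(sigma[phased]^2),
      title = "Segregation variance: phased vs unphased prediction"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-run agreement metrics of a scenario
#'
#' Boxplots of the per-run PCC (or RMSD) for each comparison between
#' progeny-based estimates and closed-form predictions.
#'
#' @param object A `seg_scenario`.
#' @param metric `"pcc"` or `"rmsd"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seg_scenario <- function(object, metric = c("pcc", "rmsd"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object$runs,
                  ggplot2::aes(x = .data$comparison,
                               y = .data[[metric]])) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(
      x = NULL, y = toupper(metric),
      title = sprintf(
        "Family size %g (%s), %d crosses, %d runs",
        object$config$family_size_mean, object$config$size_distribution,
        object$config$n_cross, object$config$n_runs)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot the gamete probability table against c
#'
#' Class probabilities of the 36 two-locus gametes as a function of the
#' recombination fraction.
#'
#' @param c_grid Recombination fractions to evaluate.
#' @return A ggplot object.
#' @export
plot_gamete_classes <- function(c_grid = seq(0, 0.5, by = 0.01)) {
  df <- purrr::map_dfr(c_grid, function(cc) {
    gamete_probabilities(cc) |>
      dplyr::distinct(.data$type, .data$probability) |>
      dplyr::mutate(c = cc)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$c, y = .data$probability,
                                   colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "recombination fraction c",
                  y = "per-gamete probability",
                  colour = "gamete class") +
    ggplot2::theme_minimal()
}
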