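#' Plot methods
#'
#' ggplot2 visualisations of the main result types: the k_obs titration
#' curve with its Henderson-Hasselbalch fit, the competition titration
#' with the fitted binding model, and the protection-versus-spacer trend.
#'
#' @param object,x The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name zincys_plots
NULL

#' @rdname zincys_plots
#' @method autoplot titration_curve
#' @export
autoplot.titration_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ph_final,
                                       y = .data$kobs_mean)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$kobs_mean - .data$sem,
                   ymax = .data$kobs_mean + .data$sem),
      width = 0.1, na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "final pH", y = expression(k[obs] ~ (min^-1))) +
    ggplot2::theme_minimal()
}

#' @rdname zincys_plots
#' @method autoplot pka_fit
#' @export
autoplot.pka_fit <- function(object, ...) {
  grid <- tibble(ph = seq(min(object$data$ph), max(object$data$ph),
                          length.out = 200))
  grid$kobs <- hh_rate_model(grid$ph, object)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ph, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$ph, y = .data$kobs),
                       colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$pka, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "final pH", y = expression(k[obs] ~ (min^-1)),
                  title = sprintf("%d-site fit", object$n_sites)) +
    ggplot2::theme_minimal()
}

#' @rdname zincys_plots
#' @method autoplot binding_fit
#' @export
autoplot.binding_fit <- function(object, ...) {
  zn <- seq(0, max(object$data$zn_total_um), length.out = 150)
  m <- object$model
  line <- bind_rows(
    tibble(curve_id = "no_protein", zn_total_um = zn,
           a620 = predict_absorbance(
             solve_species(zn, m, object$zincon_total, 0), m)),
    tibble(curve_id = "with_protein", zn_total_um = zn,
           a620 = predict_absorbance(
             solve_species(zn, m, object$zincon_total,
                           object$protein_total), m))
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$zn_total_um, y = .data$a620,
                               colour = .data$curve_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line) +
    ggplot2::labs(x = "total Zn (uM)", y = "A620 (AU)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname zincys_plots
#' @method autoplot spacer_trend
#' @export
autoplot.spacer_trend <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$spacer_arm_a,
                               y = .data$percent_inhibition)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_line(linetype = "dotted") +
    ggplot2::labs(x = "spacer arm (Å)", y = "inhibition (%)",
                  title = sprintf("Spearman rho = %s (%s)",
                                  format(object$rho, digits = 3),
                                  object$trend)) +
    ggplot2::theme_minimal()
}

#' @rdname zincys_plots
#' @export
plot_protection <- function(x, ...) {
  stopifnot(inherits(x, "protection_result") || is.data.frame(x))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$agent,
                                  y = .data$percent_inhibition,
                                  fill = factor(.data$salt_conc_um))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "inhibition (%)", fill = "salt (uM)") +
    ggplot2::theme_minimal()
}
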