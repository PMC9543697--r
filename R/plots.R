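#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a radial profile
#'
#' Net OD against radius with a one-standard-deviation ribbon.
#'
#' @param object A [radial_rebin()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot radial_profile
#' @export
autoplot.radial_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r_mm, y = .data$od_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$od_mean - .data$od_std,
                                      ymax = .data$od_mean + .data$od_std),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "radius r (mm)", y = "net optical density")
}

#' Plot a fitted calibration curve
#'
#' Net OD as a function of reconstructed dose over the valid OD range,
#' with the training plateau points overlaid when the fit stored them.
#'
#' @param object A fit from [fit_ratio_method()] or
#'   [fit_standard_method()].
#' @param measurements Optional measurement tibble whose plateau points
#'   are drawn over the curve.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot calibration_fit
#' @export
autoplot.calibration_fit <- function(object, measurements = NULL, ...) {
  cal <- object$cal
  o <- seq(cal$valid_od_range[1], cal$valid_od_range[2], length.out = 200)
  curve <- tibble::tibble(net_od = o, dose = inverse_dose(cal, o))
  p <- ggplot2::ggplot(curve,
                       ggplot2::aes(x = .data$dose, y = .data$net_od)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "dose (Gy)", y = "net optical density",
                  title = paste(object$method, "method,", cal$family,
                                "family"))
  if (!is.null(measurements)) {
    tab <- measurement_table(measurements)
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(dose = tab$k, net_od = tab$plateau_od),
      shape = 5)
  }
  p
}

#' Plot the RMSD distributions of a split experiment
#'
#' Violin plots of the per-repeat test RMSD by method, the summary view
#' used to compare calibration strategies.
#'
#' @param object An [split_experiment()] result.
#' @param which `"test"` or `"train"` RMSD.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot experiment_summary
#' @export
autoplot.experiment_summary <- function(object, which = c("test", "train"),
                                        ...) {
  which <- match.arg(which)
  col <- paste0("rmsd_", which)
  dat <- object$repeats
  dat <- dat[!dat$failed & !dat$skipped & !is.na(dat[[col]]), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$method,
                                    y = .data[[col]])) +
    ggplot2::geom_violin() +
    ggplot2::stat_summary(fun = stats::median, geom = "point") +
    ggplot2::labs(x = NULL, y = sprintf("%s RMSD (%%)", which),
                  title = sprintf("%d training levels, %d repeats",
                                  object$n_train, object$n_repeats))
}

#' Plot a two-level ratio sweep
#'
#' Median test RMSD (with interquartile band) against the training dose
#' ratio.
#'
#' @param object A [ratio_sweep()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_ratio_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ratio,
                                       y = .data$rmsd_median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rmsd_q25,
                                      ymax = .data$rmsd_q75),
                         alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "train dose ratio k_max / k_min",
                  y = "test RMSD (%)")
}
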