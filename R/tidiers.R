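#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration fit
#'
#' @param x A fit returned by [fit_ratio_method()] or
#'   [fit_standard_method()].
#' @param ... Unused.
#' @return One row per model parameter with the normalized and
#'   physical-unit estimate.
#' @method tidy calibration_fit
#' @export
tidy.calibration_fit <- function(x, ...) {
  cal <- x$cal
  terms <- if (cal$family == "bimolecular") {
    c("theta1_saturation_od", "theta2_half_saturation_dose",
      "theta3_shape")
  } else {
    paste0("theta", seq_along(cal$theta) - 1L)
  }
  tibble::tibble(term = terms, estimate = physical_theta(cal),
                 estimate_normalized = cal$theta)
}

#' Glance at a calibration fit
#'
#' @inheritParams tidy.calibration_fit
#' @return A one-row tibble with the fit-level summary: cost split,
#'   bookkeeping counts and convergence flags.
#' @method glance calibration_fit
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, family = x$cal$family,
    final_cost = x$final_cost, chi_a = x$chi_a, chi_b = x$chi_b,
    n_pairs = x$n_pairs %||% NA_integer_,
    n_positions = x$n_positions %||% NA_integer_,
    w_b = x$w_b %||% NA_real_,
    n_iterations = x$n_iterations,
    n_restarts_used = x$n_restarts_used,
    rejected_starts = x$rejected_starts,
    converged = x$converged,
    od_min = x$cal$valid_od_range[1], od_max = x$cal$valid_od_range[2],
    dose_scale = x$cal$dose_scale
  )
}

#' @importFrom rlang %||% .data
NULL
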