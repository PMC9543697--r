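#' Calibration function families
#'
#' A calibration function is a bijective map between the net optical density
#' (net OD) of a scanned film and the absorbed dose in Gy. Two families are
#' supported:
#'
#' * `"bimolecular"`: a three-parameter saturation model. The OD-to-dose
#'   direction is `d = theta2 * (o / (theta1 - o))^(1/theta3)`, where
#'   `theta1` is the saturation net OD, `theta2` the dose (Gy) at
#'   half-saturation and `theta3` a shape exponent. Its inverse (dose to OD)
#'   is the sigmoid `o = theta1 * (d/theta2)^theta3 / (1 + (d/theta2)^theta3)`.
#' * `"polynomial"`: a power series in net OD,
#'   `d = sum_m theta_m * o^m`, default degree 4 (five coefficients). The
#'   dose-to-OD direction has no closed form and is obtained by bracketed
#'   monotone root finding.
#'
#' All evaluation happens in normalized coordinates `o / od_scale` and
#' `d / dose_scale`; `theta` is stored in this normalized space so that the
#' same parameter magnitudes are meaningful across film batches and dose
#' ranges. [physical_theta()] converts to physical units.
#'
#' The map is only trusted between the lowest and highest net OD actually
#' measured (`valid_od_range`, physical units); no extrapolation below or
#' above that window is performed.
#'
#' @param family `"bimolecular"` or `"polynomial"`.
#' @param theta Numeric parameter vector in normalized coordinates: length 3
#'   for the bimolecular family, `degree + 1` for the polynomial family
#'   (constant term first).
#' @param od_scale Positive normalization divisor for net OD (typically the
#'   maximum net OD in the training data).
#' @param dose_scale Positive normalization divisor for dose, Gy.
#' @param valid_od_range Length-2 numeric, physical net OD bounds
#'   `(o_min, o_max)` with `0 < o_min < o_max`, outside which evaluation is
#'   refused.
#' @param degree Polynomial degree; ignored for the bimolecular family.
#'
#' @return An object of class `calibration_function`.
#' @examples
#' cal <- calibration_function("bimolecular", theta = c(0.55, 3, 1.2),
#'                             valid_od_range = c(0.01, 0.5))
#' inverse_dose(cal, 0.3)
#' forward_od(cal, 2)
#' @export
calibration_function <- function(family = c("bimolecular", "polynomial"),
                                 theta,
                                 od_scale = 1,
                                 dose_scale = 1,
                                 valid_od_range,
                                 degree = 4L) {
  family <- match.arg(family)
  theta <- as.numeric(theta)
  if (!all(is.finite(theta))) {
    stop("`theta` must be finite", call. = FALSE)
  }
  if (family == "bimolecular") {
    if (length(theta) != 3L) stop("bimolecular family needs 3 parameters", call. = FALSE)
    degree <- NA_integer_
  } else {
    degree <- length(theta) - 1L
    if (degree < 1L) stop("polynomial family needs at least 2 coefficients", call. = FALSE)
  }
  stopifnot(is.numeric(od_scale), od_scale > 0,
            is.numeric(dose_scale), dose_scale > 0)
  valid_od_range <- as.numeric(valid_od_range)
  if (length(valid_od_range) != 2L || !all(is.finite(valid_od_range)) ||
      valid_od_range[1] <= 0 || valid_od_range[1] >= valid_od_range[2]) {
    stop("`valid_od_range` must satisfy 0 < o_min < o_max", call. = FALSE)
  }
  structure(
    list(family = family, theta = theta, degree = degree,
         od_scale = as.numeric(od_scale), dose_scale = as.numeric(dose_scale),
         valid_od_range = valid_od_range),
    class = "calibration_function"
  )
}

#' @export
print.calibration_function <- function(x, ...) {
  cat("<calibration_function> family:", x$family, "\n")
  cat("  theta (normalized):", format(x$theta, digits = 6), "\n")
  cat("  od_scale:", x$od_scale, " dose_scale:", x$dose_scale, "Gy\n")
  cat("  valid net OD range: [", x$valid_od_range[1], ",",
      x$valid_od_range[2], "]\n")
  invisible(x)
}

n_params <- function(cal) length(cal$theta)

check_od_range <- function(cal, o, allow_outside = FALSE) {
  if (allow_outside) return(invisible(TRUE))
  lo <- cal$valid_od_range[1]
  hi <- cal$valid_od_range[2]
  tol <- 1e-12 * max(abs(hi), 1)
  bad <- !is.finite(o) | o < lo - tol | o > hi + tol
  if (any(bad)) {
    stop(sprintf("%d net OD value(s) outside the valid range [%g, %g]",
                 sum(bad), lo, hi), call. = FALSE)
  }
  invisible(TRUE)
}

# OD -> dose in normalized coordinates; returns NaN where the map is
# undefined (bimolecular o >= theta1 or o <= 0)
.inverse_dose_norm <- function(family, theta, o) {
  if (family == "bimolecular") {
    u <- o / (theta[1] - o)
    u[!is.finite(u) | u <= 0] <- NaN
    theta[2] * u^(1 / theta[3])
  } else {
    d <- rep(theta[1], length(o))
    op <- rep(1, length(o))
    for (m in seq_along(theta)[-1]) {
      op <- op * o
      d <- d + theta[m] * op
    }
    d
  }
}

# d(f^-1)/d(theta_m) in normalized coordinates: matrix length(o) x n_params
.param_grad_norm <- function(family, theta, o) {
  if (family == "bimolecular") {
    u <- o / (theta[1] - o)
    u[!is.finite(u) | u <= 0] <- NaN
    d <- theta[2] * u^(1 / theta[3])
    cbind(-d / (theta[3] * (theta[1] - o)),
          u^(1 / theta[3]),
          -d * log(u) / theta[3]^2)
  } else {
    matrix(vapply(seq_along(theta) - 1L, function(m) o^m,
                  numeric(length(o))),
           nrow = length(o))
  }
}

#' Reconstruct dose from net optical density
#'
#' Evaluates the OD-to-dose direction of a calibration function,
#' elementwise over `o`.
#'
#' @param cal A [calibration_function()].
#' @param o Net optical density, scalar or vector, physical units.
#' @param allow_outside If `TRUE`, skip the valid-range check (used
#'   internally during optimization, where out-of-range samples are
#'   penalized rather than refused).
#' @return Dose in Gy, same length as `o`. `NaN` where the bimolecular map
#'   is undefined (`o >= theta1` in normalized units).
#' @export
inverse_dose <- function(cal, o, allow_outside = FALSE) {
  stopifnot(inherits(cal, "calibration_function"))
  check_od_range(cal, o, allow_outside)
  on <- o / cal$od_scale
  .inverse_dose_norm(cal$family, cal$theta, on) * cal$dose_scale
}

#' Predict net optical density from dose
#'
#' Evaluates the dose-to-OD direction. For the bimolecular family this is
#' the closed-form saturation sigmoid; for the polynomial family the
#' monotone OD-to-dose map is inverted by bracketed root finding over
#' `valid_od_range` (tolerance 1e-12 on normalized OD).
#'
#' @inheritParams inverse_dose
#' @param d Dose in Gy, scalar or vector; must be strictly positive.
#' @return Net OD, physical units, same length as `d`.
#' @export
forward_od <- function(cal, d) {
  stopifnot(inherits(cal, "calibration_function"))
  if (any(!is.finite(d) | d <= 0)) {
    stop("dose must be finite and > 0", call. = FALSE)
  }
  dn <- d / cal$dose_scale
  th <- cal$theta
  if (cal$family == "bimolecular") {
    v <- (dn / th[2])^th[3]
    on <- th[1] * v / (1 + v)
    return(on * cal$od_scale)
  }
  # polynomial: invert numerically on the valid bracket
  lo <- cal$valid_od_range[1] / cal$od_scale
  hi <- cal$valid_od_range[2] / cal$od_scale
  dlo <- .inverse_dose_norm(cal$family, th, lo)
  dhi <- .inverse_dose_norm(cal$family, th, hi)
  if (!is.finite(dlo) || !is.finite(dhi) || dlo >= dhi) {
    stop("polynomial is not increasing over valid_od_range; cannot invert",
         call. = FALSE)
  }
  out <- vapply(dn, function(di) {
    if (di < dlo - 1e-9 * max(abs(dlo), 1) ||
        di > dhi + 1e-9 * max(abs(dhi), 1)) {
      stop(sprintf("dose %g Gy outside the calibrated dose range [%g, %g] Gy",
                   di * cal$dose_scale, dlo * cal$dose_scale,
                   dhi * cal$dose_scale), call. = FALSE)
    }
    di <- min(max(di, dlo), dhi)
    stats::uniroot(function(o) .inverse_dose_norm(cal$family, th, o) - di,
                   lower = lo, upper = hi, tol = 1e-12)$root
  }, numeric(1))
  out * cal$od_scale
}

#' Parameter gradient of the reconstructed dose
#'
#' Partial derivatives of the OD-to-dose map with respect to each model
#' parameter, as needed by gradient-based fitting. Derivatives are taken in
#' normalized coordinates (normalized dose with respect to the normalized
#' `theta`), the space in which fitting is carried out. For the polynomial
#' family component `m` is simply `o_norm^m`; for the bimolecular family
#' the analytic partials of `theta2 * (o/(theta1-o))^(1/theta3)` are used.
#'
#' @inheritParams inverse_dose
#' @return Numeric matrix, `length(o)` rows by `length(cal$theta)` columns.
#' @export
parameter_gradient <- function(cal, o, allow_outside = FALSE) {
  stopifnot(inherits(cal, "calibration_function"))
  check_od_range(cal, o, allow_outside)
  .param_grad_norm(cal$family, cal$theta, o / cal$od_scale)
}

#' Check that a calibration function is bijective over its valid range
#'
#' Samples the OD-to-dose map on a dense grid over `valid_od_range` and
#' verifies that the reconstructed dose is finite, strictly positive and
#' strictly increasing. A fit is only accepted if this check passes.
#'
#' @inheritParams inverse_dose
#' @param n_grid Number of grid points (default 512).
#' @return `TRUE` or `FALSE`; on failure the attribute `"diagnostic"`
#'   carries the first violating OD interval.
#' @export
check_bijective <- function(cal, n_grid = 512L) {
  o <- seq(cal$valid_od_range[1], cal$valid_od_range[2], length.out = n_grid)
  d <- suppressWarnings(inverse_dose(cal, o, allow_outside = TRUE))
  ok_finite <- all(is.finite(d))
  ok_pos <- ok_finite && all(d > 0)
  dd <- diff(d)
  ok_mono <- ok_finite && all(dd > 0)
  ok <- ok_finite && ok_pos && ok_mono
  if (!ok) {
    if (!ok_finite) {
      i <- which(!is.finite(d))[1]
    } else if (!ok_mono) {
      i <- which(dd <= 0)[1]
    } else {
      i <- which(d <= 0)[1]
    }
    attr(ok, "diagnostic") <- c(o[max(i - 1, 1)], o[min(i + 1, n_grid)])
  }
  ok
}

#' Convert normalized parameters to physical units
#'
#' For the polynomial family `theta_m_phys = theta_m_norm * dose_scale /
#' od_scale^m`, so that `d_Gy = sum theta_m_phys * o^m` with `o` in physical
#' net OD. For the bimolecular family `theta1` scales with OD, `theta2`
#' with dose and the exponent `theta3` is dimensionless.
#'
#' @inheritParams inverse_dose
#' @return Numeric vector of parameters in physical units.
#' @export
physical_theta <- function(cal) {
  th <- cal$theta
  if (cal$family == "bimolecular") {
    c(th[1] * cal$od_scale, th[2] * cal$dose_scale, th[3])
  } else {
    m <- seq_along(th) - 1L
    th * cal$dose_scale / cal$od_scale^m
  }
}

# inverse of physical_theta(); used when reading serialized calibrations
normalized_theta <- function(family, theta_phys, od_scale, dose_scale) {
  if (family == "bimolecular") {
    c(theta_phys[1] / od_scale, theta_phys[2] / dose_scale, theta_phys[3])
  } else {
    m <- seq_along(theta_phys) - 1L
    theta_phys * od_scale^m / dose_scale
  }
}
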