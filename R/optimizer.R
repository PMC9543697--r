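#' Fit configuration
#'
#' @param family Calibration family, `"polynomial"` (default, avoids any
#'   a-priori knowledge of the film batch) or `"bimolecular"`.
#' @param degree Polynomial degree (default 4).
#' @param n_restarts Number of random start vectors per fit.
#' @param start_scale Standard deviation of the normal start-value draws in
#'   normalized coordinates. Small values keep polynomial fits from starting
#'   in oscillatory configurations.
#' @param seed Integer seed for the start draws; `NULL` leaves the RNG
#'   state alone (non-reproducible starts).
#' @param grad_tol Gradient-norm convergence tolerance (normalized
#'   coordinates).
#' @param max_iter Maximum optimizer iterations per restart.
#' @param require_highest_dose If `TRUE` (default), fitting errors when the
#'   data set's highest dose level is known and absent from the training
#'   measurements; `FALSE` downgrades this to a warning. Omitting the
#'   highest level would require extrapolating above the largest trained
#'   OD, which the validity range forbids.
#' @param engine `"lm"` (Levenberg-Marquardt on the weighted residual
#'   vector, default) or `"bfgs"` (quasi-Newton on the scalar cost). Both
#'   use the analytic gradient; the choice is configuration, not semantics.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(family = c("polynomial", "bimolecular"),
                       degree = 4L, n_restarts = 20L, start_scale = 0.1,
                       seed = NULL, grad_tol = 1e-10, max_iter = 1000L,
                       require_highest_dose = TRUE,
                       engine = c("lm", "bfgs")) {
  family <- match.arg(family)
  engine <- match.arg(engine)
  structure(list(family = family, degree = as.integer(degree),
                 n_restarts = as.integer(n_restarts),
                 start_scale = start_scale, seed = seed,
                 grad_tol = grad_tol, max_iter = as.integer(max_iter),
                 require_highest_dose = require_highest_dose,
                 engine = engine),
            class = "fit_config")
}

#' Random start vector
#'
#' I.i.d. normal(0, scale^2) draws, deterministic for a given seed and
#' independent of the global RNG state.
#'
#' @param n_params Number of parameters.
#' @param seed Integer seed; `NULL` draws from the current RNG stream.
#' @param scale Standard deviation.
#' @return Numeric vector of length `n_params`.
#' @export
random_start <- function(n_params, seed = NULL, scale = 0.1) {
  stopifnot(n_params >= 1, scale >= 0)
  if (is.null(seed)) return(stats::rnorm(n_params, 0, scale))
  withr::with_seed(seed, stats::rnorm(n_params, 0, scale))
}

# Offsets added to the raw normal draws. The polynomial family starts
# around zero; the bimolecular saturation OD must exceed the largest
# normalized OD (= 1) for the start to be physically meaningful, so its
# draws are centred in the valid region instead.
start_center <- function(family, n_par) {
  if (family == "bimolecular") c(1.5, 0.5, 1.0) else rep(0, n_par)
}

# Multi-restart gradient-based minimization of a sum-of-squares cost given
# by residual_fn(theta) -> list(res, jac). Starts whose cost is non-finite
# are rejected ("physically meaningful start parameters"); fits failing
# the bijectivity check afterwards are rejected too.
fit_with_restarts <- function(residual_fn, n_par, family, fit_cfg,
                              make_cal, starts = NULL) {
  n_restarts <- if (is.null(starts)) fit_cfg$n_restarts else nrow(starts)
  center <- start_center(family, n_par)
  seed0 <- fit_cfg$seed
  rows <- vector("list", n_restarts)
  rejected <- 0L
  for (s in seq_len(n_restarts)) {
    start <- if (is.null(starts)) {
      center + random_start(n_par, if (is.null(seed0)) NULL else seed0 + s,
                            fit_cfg$start_scale)
    } else {
      center + starts[s, ]
    }
    r0 <- residual_fn(start, jacobian = FALSE)
    if (!all(is.finite(r0$raw))) {
      rejected <- rejected + 1L
      next
    }
    if (fit_cfg$engine == "lm") {
      fit <- minpack.lm::nls.lm(
        par = start,
        fn = function(p) residual_fn(p, jacobian = FALSE)$res,
        jac = function(p) residual_fn(p, jacobian = TRUE)$jac,
        control = minpack.lm::nls.lm.control(
          maxiter = min(fit_cfg$max_iter, 1024L),
          ftol = 1e-15, ptol = 1e-15, gtol = 1e-15))
      theta <- fit$par
      n_iter <- fit$niter
      conv_engine <- fit$info %in% 1:4
    } else {
      fit <- stats::optim(
        start,
        fn = function(p) sum(residual_fn(p, jacobian = FALSE)$res^2),
        gr = function(p) {
          rr <- residual_fn(p, jacobian = TRUE)
          as.vector(2 * crossprod(rr$jac, rr$res))
        },
        method = "BFGS",
        control = list(maxit = fit_cfg$max_iter, reltol = 1e-15))
      theta <- fit$par
      n_iter <- fit$counts[["function"]]
      conv_engine <- fit$convergence == 0
    }
    rf <- residual_fn(theta, jacobian = TRUE)
    chi <- sum(rf$res^2)
    gnorm <- sqrt(sum(as.vector(2 * crossprod(rf$jac, rf$res))^2))
    cal <- make_cal(theta)
    accepted <- is.finite(chi) && isTRUE(check_bijective(cal))
    if (!accepted) rejected <- rejected + 1L
    rows[[s]] <- tibble::tibble(
      restart = s, cost = chi, grad_norm = gnorm,
      n_iterations = n_iter, accepted = accepted,
      converged = conv_engine, theta = list(theta), start = list(start))
  }
  diag <- dplyr::bind_rows(rows)
  acc <- diag[diag$accepted, , drop = FALSE]
  if (nrow(acc) == 0L) {
    stop("no restart produced an accepted (finite, bijective) fit; ",
         "per-restart diagnostics attached",
         call. = FALSE)
  }
  best <- acc[which.min(acc$cost), ]
  theta <- best$theta[[1]]
  rf <- residual_fn(theta, jacobian = TRUE)
  gnorm <- sqrt(sum(as.vector(2 * crossprod(rf$jac, rf$res))^2))
  list(
    theta = theta,
    final_cost = best$cost,
    chi_a = rf$chi_a, chi_b = rf$chi_b,
    n_iterations = best$n_iterations,
    n_restarts_used = n_restarts,
    rejected_starts = rejected,
    start = best$start[[1]],
    converged = gnorm <= fit_cfg$grad_tol || isTRUE(best$converged),
    diagnostics = diag
  )
}

check_highest_dose <- function(train_k, dataset_max_k, fit_cfg) {
  if (is.null(dataset_max_k)) return(invisible(TRUE))
  if (max(train_k) < dataset_max_k - 1e-12) {
    msg <- sprintf(paste0(
      "highest dose level of the data set (%g Gy) is not among the ",
      "training measurements (max %g Gy); the calibration would require ",
      "extrapolation above the trained OD range"),
      dataset_max_k, max(train_k))
    if (fit_cfg$require_highest_dose) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit a calibration function by the dose-ratio method
#'
#' Minimizes the total cost (ratio part over the gradient region plus the
#' absolute side objective on the plateau of the selected levels) with a
#' gradient-based unconstrained optimizer, multiple random normal starts,
#' and rejection of unphysical starts and non-bijective fits. Net OD and
#' dose are normalized to \[0, 1\] by their training maxima before fitting.
#'
#' @param measurements Training film measurement tibble; needs at least two
#'   distinct dose levels.
#' @param cfg An [objective_config()].
#' @param fit_cfg A [fit_config()].
#' @param starts Optional matrix of raw start offsets (one row per
#'   restart), overriding random generation — used to share identical start
#'   values between methods in comparison experiments.
#' @param dataset_max_k Highest dose level (Gy) of the full data set, if
#'   the training measurements are a subset; used to enforce the
#'   highest-dose rule.
#' @return An object of class `c("ratio_fit", "calibration_fit")`: the
#'   accepted `cal` ([calibration_function()]), `final_cost`, `chi_a`,
#'   `chi_b`, iteration/restart counters, `converged`, and a per-restart
#'   `diagnostics` tibble.
#' @export
fit_ratio_method <- function(measurements, cfg = objective_config(),
                             fit_cfg = fit_config(), starts = NULL,
                             dataset_max_k = NULL) {
  measurements <- as_film_measurements(measurements)
  tab <- measurement_table(measurements)
  if (length(unique(tab$level_id)) < 2L) {
    stop("the ratio method needs at least two distinct dose levels",
         call. = FALSE)
  }
  check_highest_dose(tab$k, dataset_max_k, fit_cfg)

  used <- measurements |>
    dplyr::filter((.data$region == "gradient" & .data$r_mm >= cfg$r_lb &
                     .data$r_mm <= cfg$r_ub) |
                    (.data$region == "plateau" &
                       .data$r_mm <= cfg$plateau_r_max))
  od_scale <- max(used$net_od)
  dose_scale <- max(tab$k)
  od_range <- range(used$net_od)
  obj <- prepare_objective_data(measurements, cfg, od_scale, dose_scale)

  n_par <- if (fit_cfg$family == "bimolecular") 3L else fit_cfg$degree + 1L
  make_cal <- function(theta) {
    calibration_function(fit_cfg$family, theta, od_scale = od_scale,
                         dose_scale = dose_scale, valid_od_range = od_range,
                         degree = fit_cfg$degree)
  }
  residual_fn <- function(theta, jacobian = TRUE) {
    cr <- cost_residuals(theta, fit_cfg$family, obj, jacobian = jacobian)
    # raw: residuals before penalty substitution, for start rejection
    cr$raw <- if (cr$n_bad > 0) NaN else cr$res
    cr
  }
  out <- fit_with_restarts(residual_fn, n_par, fit_cfg$family, fit_cfg,
                           make_cal, starts)
  out$cal <- make_cal(out$theta)
  out$method <- "ratio"
  out$start_seed <- fit_cfg$seed
  out$n_pairs <- obj$n_pairs
  out$n_positions <- obj$n_pos
  out$w_b <- obj$w_b
  class(out) <- c("ratio_fit", "calibration_fit")
  out
}

#' Fit a calibration function by the standard method
#'
#' Ordinary least squares of the reconstructed plateau dose against the
#' reference dose, `sum_i (f^-1(plateau_od_i) - d_i)^2`, using only the
#' homogeneous plateau statistic of each measurement — the conventional
#' film-calibration procedure. Shares the normalization, restart and
#' acceptance machinery of [fit_ratio_method()].
#'
#' @inheritParams fit_ratio_method
#' @return An object of class `c("standard_fit", "calibration_fit")`.
#' @export
fit_standard_method <- function(measurements, fit_cfg = fit_config(),
                                starts = NULL, dataset_max_k = NULL) {
  tab <- measurement_table(as_film_measurements(measurements))
  tab <- tab[is.finite(tab$plateau_od) & !is.na(tab$reference_dose), ]
  n_par <- if (fit_cfg$family == "bimolecular") 3L else fit_cfg$degree + 1L
  if (nrow(tab) <= n_par) {
    stop(sprintf(paste0("the standard method needs strictly more (plateau ",
                        "OD, reference dose) points (%d) than free ",
                        "parameters (%d)"), nrow(tab), n_par),
         call. = FALSE)
  }
  check_highest_dose(tab$k, dataset_max_k, fit_cfg)
  od_scale <- max(tab$plateau_od)
  dose_scale <- max(tab$reference_dose)
  od_range <- range(tab$plateau_od)
  on <- tab$plateau_od / od_scale
  dn <- tab$reference_dose / dose_scale

  make_cal <- function(theta) {
    calibration_function(fit_cfg$family, theta, od_scale = od_scale,
                         dose_scale = dose_scale, valid_od_range = od_range,
                         degree = fit_cfg$degree)
  }
  residual_fn <- function(theta, jacobian = TRUE) {
    D <- .inverse_dose_norm(fit_cfg$family, theta, on)
    res <- D - dn
    bad <- !is.finite(res)
    raw <- if (any(bad)) NaN else res
    res[bad] <- 1e3
    out <- list(res = res, raw = raw, chi_a = 0, chi_b = sum(res^2),
                n_bad = sum(bad))
    if (jacobian) {
      J <- .param_grad_norm(fit_cfg$family, theta, on)
      J[bad, ] <- 0
      J[!is.finite(J)] <- 0
      out$jac <- J
    }
    out
  }
  out <- fit_with_restarts(residual_fn, n_par, fit_cfg$family, fit_cfg,
                           make_cal, starts)
  out$cal <- make_cal(out$theta)
  out$method <- "standard"
  out$start_seed <- fit_cfg$seed
  class(out) <- c("standard_fit", "calibration_fit")
  out
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit> method:", x$method, " family:", x$cal$family, "\n")
  cat("  final cost:", format(x$final_cost, digits = 8),
      " converged:", x$converged, "\n")
  cat("  restarts:", x$n_restarts_used, " rejected:", x$rejected_starts,
      "\n")
  print(x$cal)
  invisible(x)
}
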