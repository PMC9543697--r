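#' Configuration of the dose-ratio objective
#'
#' Collects the region bounds and weights that define the cost function.
#' Defaults follow the measurement geometry of a 67 mm film piece with a
#' ~15 mm radius dose plateau: gradient samples between 15 and 27 mm feed
#' the ratio cost, the central region up to 7.8 mm radius supplies the
#' plateau statistic used for absolute anchoring.
#'
#' @param r_lb,r_ub Lower/upper radius of the gradient region, mm.
#' @param plateau_r_max Maximum radius of the plateau region, mm.
#' @param w_r Default per-position weight in the ratio cost.
#' @param w_s Side-objective weight; the effective per-point weight is
#'   `w_b = w_s * (Nr * n_pairs) / N_d`, balancing the number of summands
#'   in the ratio cost against the number of absolute anchor points.
#' @param side_objective Which dose levels anchor the fit absolutely:
#'   `"highest"` (default; only the highest dose level, the recommended
#'   choice since extrapolation above the largest measured OD is never
#'   valid), `"all"`, or a character vector of `level_id`s.
#' @return An object of class `objective_config`.
#' @export
objective_config <- function(r_lb = 15, r_ub = 27, plateau_r_max = 7.8,
                             w_r = 1, w_s = 10, side_objective = "highest") {
  if (!(r_lb < r_ub)) stop("`r_lb` must be < `r_ub`", call. = FALSE)
  if (w_s <= 0) stop("`w_s` must be > 0", call. = FALSE)
  structure(list(r_lb = r_lb, r_ub = r_ub, plateau_r_max = plateau_r_max,
                 w_r = w_r, w_s = w_s, side_objective = side_objective),
            class = "objective_config")
}

#' Enumerate the measurement pairs entering the ratio cost
#'
#' All unordered pairs of measurements are formed, excluding pairs that
#' share a dose level (their ratio carries no calibration information).
#' For N dose levels measured in triplicate this yields `9 * N * (N-1) / 2`
#' pairs; generally `reps^2 * N * (N-1) / 2`.
#'
#' @param measurements A film measurement tibble (or its
#'   [measurement_table()]).
#' @return A tibble with one row per pair: integer indices `i < j` into the
#'   measurement order, plus ids, levels and scalings of both members;
#'   ordered lexicographically by `(i, j)`.
#' @export
enumerate_pairs <- function(measurements) {
  tab <- if (all(c("plateau_od", "n_gradient") %in% names(measurements))) {
    measurements
  } else {
    measurement_table(measurements)
  }
  if (nrow(tab) < 2L || length(unique(tab$level_id)) < 2L) {
    stop("at least two measurements at two distinct dose levels are required",
         call. = FALSE)
  }
  idx <- utils::combn(nrow(tab), 2L)
  keep <- tab$level_id[idx[1, ]] != tab$level_id[idx[2, ]]
  tibble::tibble(
    i = idx[1, keep], j = idx[2, keep],
    measurement_i = tab$measurement_id[idx[1, keep]],
    measurement_j = tab$measurement_id[idx[2, keep]],
    level_i = tab$level_id[idx[1, keep]],
    level_j = tab$level_id[idx[2, keep]],
    k_i = tab$k[idx[1, keep]], k_j = tab$k[idx[2, keep]]
  )
}

# Assemble the matrices the cost kernel works on, in normalized
# coordinates. All measurements must share one radius grid over
# [r_lb, r_ub]; profiles are expected to have been rebinned onto a common
# grid upstream.
prepare_objective_data <- function(measurements, cfg, od_scale, dose_scale) {
  measurements <- as_film_measurements(measurements)
  tab <- measurement_table(measurements)

  grad <- measurements |>
    dplyr::filter(.data$region == "gradient",
                  .data$r_mm >= cfg$r_lb, .data$r_mm <= cfg$r_ub) |>
    dplyr::arrange(match(.data$measurement_id, tab$measurement_id),
                   .data$r_mm)
  if (nrow(grad) == 0L) {
    stop("no gradient samples inside [r_lb, r_ub]", call. = FALSE)
  }
  by_m <- split(grad, factor(grad$measurement_id, levels = tab$measurement_id))
  r0 <- by_m[[1]]$r_mm
  same <- vapply(by_m, function(g) {
    length(g$r_mm) == length(r0) && all(abs(g$r_mm - r0) < 1e-9)
  }, logical(1))
  if (!all(same)) {
    stop("measurements are not sampled on a common radius grid; ",
         "rebin profiles onto a shared grid first", call. = FALSE)
  }
  O <- vapply(by_m, function(g) g$net_od, numeric(length(r0))) / od_scale
  O <- matrix(O, nrow = length(r0))
  w_r <- by_m[[1]]$weight * cfg$w_r

  pairs <- enumerate_pairs(tab)
  n_pairs <- nrow(pairs)
  n_pos <- length(r0)

  side_levels <- if (identical(cfg$side_objective, "highest")) {
    tab$level_id[which.max(tab$k)]
  } else if (identical(cfg$side_objective, "all")) {
    unique(tab$level_id)
  } else {
    cfg$side_objective
  }
  sel <- which(tab$level_id %in% side_levels & !is.na(tab$reference_dose) &
                 is.finite(tab$plateau_od))
  if (length(sel) == 0L) {
    stop("no measurement with a plateau OD and reference dose is available ",
         "for the side objective", call. = FALSE)
  }
  n_d <- length(sel)
  w_b <- cfg$w_s * (n_pos * n_pairs) / n_d

  list(
    O = O, r = r0, w_r = w_r,
    kn = tab$k / dose_scale,
    pairs = cbind(pairs$i, pairs$j),
    o_plat = tab$plateau_od[sel] / od_scale,
    d_ref = tab$reference_dose[sel] / dose_scale,
    w_b = w_b, n_pairs = n_pairs, n_pos = n_pos, n_d = n_d,
    tab = tab
  )
}

# Weighted residual vector and Jacobian of the total cost in normalized
# coordinates: chi = sum(res^2), grad = 2 t(J) %*% res. Samples at which
# the model is undefined get a large finite penalty residual with zero
# derivative so line searches stay well defined.
cost_residuals <- function(theta, family, obj, penalty = 1e3,
                           jacobian = TRUE) {
  Nr <- nrow(obj$O); M <- ncol(obj$O)
  np <- length(theta)
  D <- .inverse_dose_norm(family, theta, as.vector(obj$O))
  D <- matrix(D, nrow = Nr)
  pi <- obj$pairs[, 1]; pj <- obj$pairs[, 2]
  ki <- obj$kn[pi]; kj <- obj$kn[pj]
  invkk <- 1 / (ki * kj)
  sw <- sqrt(obj$w_r)
  Rm <- sweep(D[, pi, drop = FALSE], 2, kj, `*`) -
    sweep(D[, pj, drop = FALSE], 2, ki, `*`)
  Rm <- sweep(Rm, 2, invkk, `*`) * sw
  bad_a <- !is.finite(Rm)
  Rm[bad_a] <- penalty

  Dp <- .inverse_dose_norm(family, theta, obj$o_plat)
  res_b <- sqrt(obj$w_b) * (Dp - obj$d_ref)
  bad_b <- !is.finite(res_b)
  res_b[bad_b] <- penalty

  res <- c(as.vector(Rm), res_b)
  out <- list(res = res,
              chi_a = sum(Rm^2), chi_b = sum(res_b^2),
              n_bad = sum(bad_a) + sum(bad_b))
  if (jacobian) {
    G <- .param_grad_norm(family, theta, as.vector(obj$O))
    Gp <- .param_grad_norm(family, theta, obj$o_plat)
    J <- matrix(0, nrow = length(res), ncol = np)
    na <- length(Rm)
    for (m in seq_len(np)) {
      Gm <- matrix(G[, m], nrow = Nr)
      Jm <- sweep(Gm[, pi, drop = FALSE], 2, kj, `*`) -
        sweep(Gm[, pj, drop = FALSE], 2, ki, `*`)
      Jm <- sweep(Jm, 2, invkk, `*`) * sw
      Jm[bad_a] <- 0
      J[seq_len(na), m] <- as.vector(Jm)
      gb <- sqrt(obj$w_b) * Gp[, m]
      gb[bad_b] <- 0
      J[na + seq_along(res_b), m] <- gb
    }
    J[!is.finite(J)] <- 0
    out$jac <- J
  }
  out
}

#' Per-pair dose-ratio cost
#'
#' For each admissible measurement pair `(i, j)` computes the summed
#' squared helper residual over the gradient region,
#' `sum_r w_r * h_{i,j,r}^2` with
#' `h = (k_i k_j)^-1 (k_j f^-1(o_i,r) - k_i f^-1(o_j,r))`:
#' when the calibration function is correct, `f^-1(o_i,r) = k_i d(r)` so
#' every `h` vanishes identically, whatever the (unknown) relative profile
#' `d(r)`.
#'
#' @param measurements A film measurement tibble; all measurements must be
#'   sampled on one common radius grid.
#' @param cal A [calibration_function()]; costs are computed in its
#'   normalized coordinates.
#' @param cfg An [objective_config()].
#' @return The pair tibble of [enumerate_pairs()] with an extra `cost`
#'   column.
#' @export
pair_costs <- function(measurements, cal, cfg = objective_config()) {
  obj <- prepare_objective_data(measurements, cfg, cal$od_scale,
                                cal$dose_scale)
  check_od_range(cal, as.vector(obj$O) * cal$od_scale)
  cr <- cost_residuals(cal$theta, cal$family, obj, jacobian = FALSE)
  na <- obj$n_pos * obj$n_pairs
  Rm <- matrix(cr$res[seq_len(na)], nrow = obj$n_pos)
  out <- enumerate_pairs(obj$tab)
  out$cost <- colSums(Rm^2)
  out
}

#' Ratio part of the cost function
#'
#' Sums the per-pair cost over all admissible pairs. Scales as `c^-2` when
#' every dose-level scaling is multiplied by `c` (so the minimiser is
#' unaffected by the unit of `k`), and is zero exactly when all dose-ratio
#' residuals vanish.
#'
#' @inheritParams pair_costs
#' @return A scalar (normalized-coordinate) cost with attributes `n_pairs`
#'   and `n_positions`.
#' @export
cost_ratio <- function(measurements, cal, cfg = objective_config()) {
  pc <- pair_costs(measurements, cal, cfg)
  out <- sum(pc$cost)
  attr(out, "n_pairs") <- nrow(pc)
  out
}

#' Absolute-dose side objective
#'
#' Quadratic penalty tying the reconstructed plateau dose of the selected
#' measurements to their reference doses,
#' `chi_b = sum_i w_b (f^-1(plateau_od_i) - d_i)^2`, with `w_b` balancing
#' the summand counts of the two cost parts (see [objective_config()]). On
#' its own (applied to all levels) this is the standard calibration
#' objective for spatially homogeneous exposures.
#'
#' @inheritParams pair_costs
#' @return A scalar normalized cost with attribute `w_b`.
#' @export
cost_side <- function(measurements, cal, cfg = objective_config()) {
  obj <- prepare_objective_data(measurements, cfg, cal$od_scale,
                                cal$dose_scale)
  check_od_range(cal, obj$o_plat * cal$od_scale)
  cr <- cost_residuals(cal$theta, cal$family, obj, jacobian = FALSE)
  out <- cr$chi_b
  attr(out, "w_b") <- obj$w_b
  out
}

#' Total cost and analytic gradient
#'
#' Computes the full objective `chi = chi_a + chi_b` and its analytic
#' gradient with respect to the (normalized) model parameters, the
#' quantities driving the gradient-based fit.
#'
#' @inheritParams pair_costs
#' @return A list of class `cost_breakdown`: `chi_a`, `chi_b`, `chi`,
#'   `grad` (length `length(cal$theta)`), `n_pairs`, `n_positions`, `w_b`.
#' @export
total_cost <- function(measurements, cal, cfg = objective_config()) {
  obj <- prepare_objective_data(measurements, cfg, cal$od_scale,
                                cal$dose_scale)
  check_od_range(cal, c(as.vector(obj$O), obj$o_plat) * cal$od_scale)
  cr <- cost_residuals(cal$theta, cal$family, obj, jacobian = TRUE)
  structure(
    list(chi_a = cr$chi_a, chi_b = cr$chi_b, chi = cr$chi_a + cr$chi_b,
         grad = as.vector(2 * crossprod(cr$jac, cr$res)),
         n_pairs = obj$n_pairs, n_positions = obj$n_pos, w_b = obj$w_b),
    class = "cost_breakdown"
  )
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("<cost_breakdown> chi =", format(x$chi, digits = 8),
      "(chi_a =", format(x$chi_a, digits = 8),
      ", chi_b =", format(x$chi_b, digits = 8), ")\n")
  cat("  pairs:", x$n_pairs, " positions:", x$n_positions,
      " w_b:", format(x$w_b, digits = 6), "\n")
  cat("  |grad|:", format(sqrt(sum(x$grad^2)), digits = 6), "\n")
  invisible(x)
}
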