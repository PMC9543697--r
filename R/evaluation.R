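#' Relative dose deviations on held-out plateau points
#'
#' Reconstructs the plateau dose of each test measurement through the
#' calibration and reports the relative deviation from the reference dose
#' in percent. Points above the trained OD range (`above_max`) cannot be
#' evaluated meaningfully — beyond the largest trained OD a saturating
#' film curve has no usable inverse — and are flagged for exclusion from
#' RMSD (never silently dropped). Points below the trained range are
#' evaluated by downward extrapolation and flagged `below_min`; their
#' residuals show what calibrating without low dose levels costs.
#'
#' @param cal A [calibration_function()].
#' @param test_measurements Film measurement tibble (or its
#'   [measurement_table()]) with reference doses.
#' @return A tibble with one row per test measurement: `measurement_id`,
#'   `level_id`, `k`, `plateau_od`, `reference_dose`, `dose_est`,
#'   `residual_pct`, `in_range`, `below_min`, `above_max`.
#' @export
dose_residuals <- function(cal, test_measurements) {
  tab <- if (all(c("plateau_od") %in% names(test_measurements))) {
    test_measurements
  } else {
    measurement_table(test_measurements)
  }
  if (any(is.na(tab$reference_dose))) {
    stop("every test measurement needs a reference dose", call. = FALSE)
  }
  lo <- cal$valid_od_range[1]
  hi <- cal$valid_od_range[2]
  tol <- 1e-9 * max(hi, 1)
  below <- tab$plateau_od < lo - tol
  above <- tab$plateau_od > hi + tol
  dose_est <- suppressWarnings(
    inverse_dose(cal, tab$plateau_od, allow_outside = TRUE))
  dose_est[!is.finite(dose_est)] <- NA_real_
  tibble::tibble(
    measurement_id = tab$measurement_id, level_id = tab$level_id,
    k = tab$k, plateau_od = tab$plateau_od,
    reference_dose = tab$reference_dose, dose_est = dose_est,
    residual_pct = 100 * (dose_est - tab$reference_dose) /
      tab$reference_dose,
    in_range = !below & !above, below_min = below, above_max = above
  )
}

#' Root-mean-square deviation of percent residuals
#'
#' @param residuals Numeric vector of percent deviations (NA entries are
#'   not allowed; exclude out-of-range points explicitly first).
#' @return `sqrt(mean(residuals^2))`, percent.
#' @export
rmsd <- function(residuals) {
  residuals <- as.numeric(residuals)
  if (length(residuals) == 0L) {
    stop("cannot compute the RMSD of zero residuals", call. = FALSE)
  }
  if (any(is.na(residuals))) {
    stop("residuals contain NA; exclude out-of-range points first",
         call. = FALSE)
  }
  sqrt(mean(residuals^2))
}

# RMSD over evaluable points: above-range points are excluded (counted by
# the caller); below-range points enter via extrapolation
rmsd_of <- function(res_tbl) {
  r <- res_tbl$residual_pct[!res_tbl$above_max]
  r <- r[!is.na(r)]
  if (length(r) == 0L) return(NA_real_)
  rmsd(r)
}

fit_one_method <- function(method, train, fit_cfg1, cfg, starts) {
  if (method == "ratio") {
    fit_ratio_method(train, cfg = cfg, fit_cfg = fit_cfg1, starts = starts)
  } else {
    fit_standard_method(train, fit_cfg = fit_cfg1, starts = starts)
  }
}

#' Random train/test split experiment
#'
#' Repeatedly splits the dose levels of a data set at random into
#' `n_train` training levels (a level travels with all its repetitions)
#' and the remaining test levels, fits a calibration per repeat from a
#' fresh random start, and collects train and test RMSD over the plateau
#' points. With `method = "both"` the ratio and the standard method are
#' fitted per repeat from the identical split and identical start vector,
#' making their RMSD distributions directly comparable. The standard
#' method is skipped (flagged, not failed) on splits where its
#' `(plateau OD, dose)` point count does not exceed the parameter count.
#'
#' @param measurements Full film measurement tibble.
#' @param n_train Number of training dose levels (e.g. 2, 4, 6, 8).
#' @param n_repeats Number of random splits (default 200).
#' @param seed Integer seed; repeat `t` uses `seed + t` for both the split
#'   and the start vector, so any single repeat is reproducible in
#'   isolation.
#' @param method `"ratio"`, `"standard"`, or `"both"`.
#' @param cfg An [objective_config()].
#' @param fit_cfg A [fit_config()]; one start vector per repeat is used
#'   (`n_restarts` is ignored here).
#' @return An object of class `experiment_summary`: `summary` (percentile
#'   tibble per method) and `repeats` (per-repeat records: chosen levels,
#'   start-vector hash, RMSDs, excluded test points).
#' @export
split_experiment <- function(measurements, n_train, n_repeats = 200L,
                             seed = 1L, method = c("ratio", "standard",
                                                   "both"),
                             cfg = objective_config(),
                             fit_cfg = fit_config()) {
  method <- match.arg(method)
  measurements <- as_film_measurements(measurements)
  tab <- measurement_table(measurements)
  levels_all <- unique(tab$level_id)
  if (length(levels_all) < n_train + 1L) {
    stop("the data set needs at least n_train + 1 dose levels",
         call. = FALSE)
  }
  methods <- if (method == "both") c("ratio", "standard") else method
  n_par <- if (fit_cfg$family == "bimolecular") 3L else fit_cfg$degree + 1L

  rows <- vector("list", n_repeats * length(methods))
  ri <- 0L
  for (t in seq_len(n_repeats)) {
    seed_t <- seed + t
    train_levels <- withr::with_seed(seed_t,
                                     sample(levels_all, n_train))
    start <- random_start(n_par, seed = seed_t + 10000000L,
                          scale = fit_cfg$start_scale)
    starts <- matrix(start, nrow = 1)
    train <- measurements[measurements$level_id %in% train_levels, ]
    test_tab <- tab[!tab$level_id %in% train_levels, ]
    train_tab <- tab[tab$level_id %in% train_levels, ]
    fit_cfg1 <- fit_cfg
    fit_cfg1$n_restarts <- 1L
    fit_cfg1$seed <- NULL
    fit_cfg1$require_highest_dose <- FALSE
    for (mth in methods) {
      ri <- ri + 1L
      skipped <- mth == "standard" && nrow(train_tab) <= n_par
      rec <- tibble::tibble(
        repeat_id = t, method = mth, seed = seed_t,
        train_levels = paste(sort(train_levels), collapse = ","),
        start_hash = rlang::hash(start),
        rmsd_train = NA_real_, rmsd_test = NA_real_,
        n_test_excluded = NA_integer_, converged = NA, failed = FALSE,
        skipped = skipped)
      if (!skipped) {
        fit <- tryCatch(
          fit_one_method(mth, train, fit_cfg1, cfg, starts),
          error = function(e) NULL)
        if (is.null(fit)) {
          rec$failed <- TRUE
        } else {
          res_tr <- dose_residuals(fit$cal, train_tab)
          res_te <- dose_residuals(fit$cal, test_tab)
          rec$rmsd_train <- rmsd_of(res_tr)
          rec$rmsd_test <- rmsd_of(res_te)
          rec$n_test_excluded <- sum(res_te$above_max)
          rec$converged <- fit$converged
        }
      }
      rows[[ri]] <- rec
    }
  }
  repeats <- dplyr::bind_rows(rows)
  summary <- repeats |>
    dplyr::filter(!.data$failed, !.data$skipped) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_train = n_train, n_repeats = dplyr::n(),
      rmsd_train_q25 = stats::quantile(.data$rmsd_train, 0.25,
                                       na.rm = TRUE, names = FALSE),
      rmsd_train_median = stats::median(.data$rmsd_train, na.rm = TRUE),
      rmsd_train_q75 = stats::quantile(.data$rmsd_train, 0.75,
                                       na.rm = TRUE, names = FALSE),
      rmsd_test_q25 = stats::quantile(.data$rmsd_test, 0.25,
                                      na.rm = TRUE, names = FALSE),
      rmsd_test_median = stats::median(.data$rmsd_test, na.rm = TRUE),
      rmsd_test_q75 = stats::quantile(.data$rmsd_test, 0.75,
                                      na.rm = TRUE, names = FALSE),
      .groups = "drop")
  summary$n_failed <- vapply(summary$method, function(m) {
    sum(repeats$failed[repeats$method == m])
  }, integer(1))
  summary$n_skipped <- vapply(summary$method, function(m) {
    sum(repeats$skipped[repeats$method == m])
  }, integer(1))
  structure(list(summary = summary, repeats = repeats,
                 n_train = n_train, n_repeats = n_repeats, seed = seed),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat("<experiment_summary> n_train =", x$n_train, ", repeats =",
      x$n_repeats, "\n")
  print(x$summary)
  invisible(x)
}

#' Two-level dose-ratio sweep
#'
#' The special case of training on a single dose ratio: for each pair of
#' dose levels that includes the highest level (`pairs = "highest"`,
#' keeping the anchor inside the training set; `pairs = "all"` sweeps
#' every pair, flagging those without the highest level), the fit is
#' repeated with fresh random starts and the test RMSD distribution is
#' recorded as a function of the train dose ratio `k_max / k_min`.
#'
#' @inheritParams split_experiment
#' @param n_repeats Fits per pair.
#' @param pairs `"highest"` or `"all"`.
#' @return A tibble with one row per pair: `level_lo`, `level_hi`,
#'   `k_lo`, `k_hi`, `ratio`, RMSD percentiles, `n_failed`,
#'   `includes_highest`.
#' @export
ratio_sweep <- function(measurements, n_repeats = 50L, seed = 1L,
                        cfg = objective_config(),
                        fit_cfg = fit_config(), pairs = c("highest",
                                                          "all")) {
  pairs <- match.arg(pairs)
  measurements <- as_film_measurements(measurements)
  tab <- measurement_table(measurements)
  lv <- unique(tab[c("level_id", "k")])
  if (nrow(lv) < 3L) stop("need at least three dose levels", call. = FALSE)
  k_max <- max(lv$k)
  idx <- utils::combn(nrow(lv), 2L)
  out <- vector("list", ncol(idx))
  fit_cfg1 <- fit_cfg
  fit_cfg1$n_restarts <- 1L
  fit_cfg1$seed <- NULL
  fit_cfg1$require_highest_dose <- FALSE
  n_par <- if (fit_cfg$family == "bimolecular") 3L else fit_cfg$degree + 1L
  cell <- 0L
  for (p in seq_len(ncol(idx))) {
    a <- idx[1, p]; b <- idx[2, p]
    klo <- min(lv$k[a], lv$k[b]); khi <- max(lv$k[a], lv$k[b])
    includes_highest <- abs(khi - k_max) < 1e-12
    if (pairs == "highest" && !includes_highest) next
    cell <- cell + 1L
    train_levels <- c(lv$level_id[a], lv$level_id[b])
    train <- measurements[measurements$level_id %in% train_levels, ]
    test_tab <- tab[!tab$level_id %in% train_levels, ]
    rmsds <- rep(NA_real_, n_repeats)
    for (t in seq_len(n_repeats)) {
      start <- random_start(n_par, seed = seed + 1000L * cell + t,
                            scale = fit_cfg$start_scale)
      fit <- tryCatch(
        suppressWarnings(
          fit_ratio_method(train, cfg = cfg, fit_cfg = fit_cfg1,
                           starts = matrix(start, nrow = 1))),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rmsds[t] <- rmsd_of(dose_residuals(fit$cal, test_tab))
      }
    }
    ok <- rmsds[!is.na(rmsds)]
    lo_i <- if (lv$k[a] <= lv$k[b]) a else b
    hi_i <- if (lv$k[a] <= lv$k[b]) b else a
    out[[p]] <- tibble::tibble(
      level_lo = lv$level_id[lo_i],
      level_hi = lv$level_id[hi_i],
      k_lo = klo, k_hi = khi, ratio = khi / klo,
      rmsd_q25 = stats::quantile(ok, 0.25, names = FALSE),
      rmsd_median = stats::median(ok),
      rmsd_q75 = stats::quantile(ok, 0.75, names = FALSE),
      n_failed = sum(is.na(rmsds)),
      includes_highest = includes_highest)
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$ratio)
}

#' Full calibration from one four-field measurement
#'
#' End-to-end pipeline for the single-exposure layout: compute the net OD
#' map, crop a window around each field's nominal centre, refine the
#' centre on the 50% ring, rebin radially, extract plateau and gradient
#' regions, and fit the ratio method using the four dose levels of the
#' manifest. Residuals are reported on all four plateau points.
#'
#' @param image A four-field `film_image` (see [make_multifield_image()])
#'   or a list with `before`, `after`, `pixel_size`, `manifest`.
#' @param manifest Field manifest (tibble with `field`, `level`, `cx_mm`,
#'   `cy_mm`); defaults to `image$manifest`.
#' @param cfg An [objective_config()].
#' @param fit_cfg A [fit_config()].
#' @param window_half Half-size of the per-field crop window, mm.
#' @param bin_width Radial bin width, mm (default one pixel).
#' @return A list of class `single_measurement_result`: `fit`,
#'   `residuals` (plateau residual tibble), `centers` (nominal and
#'   refined, mm), `measurements`.
#' @export
single_measurement_calibration <- function(image, manifest = image$manifest,
                                           cfg = objective_config(),
                                           fit_cfg = fit_config(),
                                           window_half = 33,
                                           bin_width = image$pixel_size) {
  stopifnot(!is.null(manifest), nrow(manifest) >= 2L)
  full <- net_optical_density(image$before, image$after,
                              pixel_size = image$pixel_size)
  px <- image$pixel_size
  meas <- list()
  centers <- vector("list", nrow(manifest))
  for (f in seq_len(nrow(manifest))) {
    cx <- manifest$cx_mm[f]; cy <- manifest$cy_mm[f]
    cols <- which(abs((seq_len(ncol(full$values)) - 1) * px - cx) <=
                    window_half)
    rows <- which(abs((seq_len(nrow(full$values)) - 1) * px - cy) <=
                    window_half)
    sub <- od_map(full$values[rows, cols], pixel_size = px,
                  channel = full$channel)
    # crop origin in full-image mm coordinates
    ox <- (min(cols) - 1) * px
    oy <- (min(rows) - 1) * px
    ctr <- find_center(sub, start = c(cx - ox, cy - oy))
    prof <- radial_rebin(sub, ctr, bin_width = bin_width)
    meas[[f]] <- profile_to_measurement(
      prof, measurement_id = manifest$field[f],
      level_id = manifest$field[f], k = manifest$level[f],
      reference_dose = manifest$level[f], cfg = cfg)
    centers[[f]] <- tibble::tibble(
      field = manifest$field[f], cx_nominal = cx, cy_nominal = cy,
      cx_found = ctr[1] + ox, cy_found = ctr[2] + oy)
  }
  measurements <- dplyr::bind_rows(meas)
  fit <- fit_ratio_method(measurements, cfg = cfg, fit_cfg = fit_cfg)
  res <- dose_residuals(fit$cal, measurements)
  structure(list(fit = fit, residuals = res,
                 centers = dplyr::bind_rows(centers),
                 measurements = measurements),
            class = "single_measurement_result")
}
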