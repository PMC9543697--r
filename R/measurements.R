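#' Film measurement sets
#'
#' A film measurement set is a long-format tibble with one row per sampled
#' profile position per film exposure. Columns:
#'
#' * `measurement_id`: identifies one film exposure (repetitions of the same
#'   dose level are distinct measurements).
#' * `level_id`: groups repetitions of the same dose level; ratios are never
#'   formed between measurements that share a `level_id`.
#' * `k`: the dose-level scaling of this exposure, Gy at the plateau centre
#'   (or any linear monitor-unit scaling).
#' * `r_mm`: radial (or axial) position of the sample, mm.
#' * `net_od`: net optical density at that position.
#' * `region`: `"gradient"` (dose-falloff samples used by the ratio
#'   objective) or `"plateau"` (central homogeneous samples used for
#'   absolute anchoring and verification).
#' * `weight`: optional nonnegative per-position weight `w_r` (default 1).
#' * `reference_dose`: absolute reference dose in Gy for plateau rows, `NA`
#'   where no reference measurement exists.
#'
#' @param x A data frame with the columns above (`weight` and
#'   `reference_dose` are optional and default to 1 and `NA`).
#' @return `x` validated, with class `film_measurements` prepended.
#' @export
as_film_measurements <- function(x) {
  x <- tibble::as_tibble(x)
  req <- c("measurement_id", "level_id", "k", "r_mm", "net_od", "region")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop("missing measurement columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"weight" %in% names(x)) x$weight <- 1
  if (!"reference_dose" %in% names(x)) x$reference_dose <- NA_real_
  if (!all(x$region %in% c("gradient", "plateau"))) {
    stop("`region` must be 'gradient' or 'plateau'", call. = FALSE)
  }
  if (any(!is.finite(x$net_od) | x$net_od <= 0)) {
    stop("all net OD values must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(x$k) | x$k <= 0)) {
    stop("all dose-level scalings `k` must be finite and > 0", call. = FALSE)
  }
  if (any(x$weight < 0)) stop("weights must be nonnegative", call. = FALSE)
  class(x) <- unique(c("film_measurements", class(x)))
  x
}

#' Per-measurement summary of a film measurement set
#'
#' Collapses a long measurement set to one row per film exposure, with the
#' mean plateau net OD (the statistic used for absolute anchoring and for
#' verification) and the number of gradient samples.
#'
#' @param measurements A [as_film_measurements()] tibble.
#' @return A tibble with columns `measurement_id`, `level_id`, `k`,
#'   `plateau_od`, `reference_dose`, `n_gradient`, in order of first
#'   appearance.
#' @export
measurement_table <- function(measurements) {
  measurements <- as_film_measurements(measurements)
  measurements |>
    dplyr::mutate(.order = match(.data$measurement_id,
                                 unique(.data$measurement_id))) |>
    dplyr::group_by(.data$.order, .data$measurement_id, .data$level_id,
                    .data$k) |>
    dplyr::summarise(
      plateau_od = mean(.data$net_od[.data$region == "plateau"]),
      reference_dose = if (any(!is.na(.data$reference_dose))) {
        mean(.data$reference_dose, na.rm = TRUE)
      } else NA_real_,
      n_gradient = sum(.data$region == "gradient"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$.order) |>
    dplyr::select(-".order")
}

#' Write / read a measurement set as CSV with a JSON manifest
#'
#' The CSV holds the long table; the JSON sidecar records the dose levels
#' and reference doses so a run can be reproduced from files alone.
#'
#' @param measurements A film measurement tibble.
#' @param csv_path Path to the CSV file. The manifest is written next to it
#'   with extension `.json` unless `manifest_path` is given.
#' @param manifest_path Optional explicit manifest path.
#' @return `csv_path`, invisibly.
#' @export
write_measurements <- function(measurements, csv_path, manifest_path = NULL) {
  measurements <- as_film_measurements(measurements)
  readr::write_csv(measurements, csv_path)
  if (is.null(manifest_path)) {
    manifest_path <- sub("\\.csv$", ".json", csv_path)
  }
  tab <- measurement_table(measurements)
  manifest <- list(
    levels = unique(tab[c("level_id", "k")]),
    measurements = tab[c("measurement_id", "level_id", "k", "reference_dose")]
  )
  jsonlite::write_json(manifest, manifest_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(csv_path) {
  x <- readr::read_csv(csv_path, show_col_types = FALSE)
  as_film_measurements(x)
}
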