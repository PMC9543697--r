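#' Serialize a calibration function to JSON
#'
#' The document stores the parameters in physical units together with the
#' normalization scales and validity range, so the calibration can be
#' applied elsewhere without the training data. Reading inverts the
#' normalization exactly.
#'
#' @param cal A [calibration_function()].
#' @param path Output path (`.json`).
#' @param provenance Optional named list of provenance metadata merged
#'   into the document.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(cal, path, provenance = list()) {
  doc <- list(
    family = cal$family,
    degree = if (is.na(cal$degree)) NULL else cal$degree,
    theta = physical_theta(cal),
    od_scale = cal$od_scale,
    dose_scale = cal$dose_scale,
    valid_od_range = cal$valid_od_range,
    provenance = c(list(package = "filmratio",
                        version = as.character(
                          utils::packageVersion("filmratio"))),
                   provenance)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$family) || is.null(doc$theta) || is.null(doc$od_scale)) {
    stop("not a calibration document: ", path, call. = FALSE)
  }
  theta <- normalized_theta(doc$family, as.numeric(doc$theta),
                            doc$od_scale, doc$dose_scale)
  calibration_function(doc$family, theta, od_scale = doc$od_scale,
                       dose_scale = doc$dose_scale,
                       valid_od_range = as.numeric(doc$valid_od_range))
}

#' Apply a calibration to net OD values
#'
#' Converts an OD map, matrix or vector to dose. Out-of-range ODs are
#' masked to `NA` (with a warning) rather than extrapolated; the masked
#' fraction is attached as attribute `"masked_fraction"`.
#'
#' @param cal A [calibration_function()].
#' @param od An [od_map()], matrix or numeric vector of net OD.
#' @return Dose in Gy with the shape of the input.
#' @export
apply_calibration <- function(cal, od) {
  v <- if (inherits(od, "od_map")) od$values else od
  lo <- cal$valid_od_range[1]; hi <- cal$valid_od_range[2]
  out_of_range <- !is.finite(v) | v < lo | v > hi
  frac <- mean(out_of_range)
  if (frac > 0) {
    warning(sprintf("%.2f%% of OD values outside the valid range were masked",
                    100 * frac), call. = FALSE)
  }
  d <- v
  d[] <- NA_real_
  d[!out_of_range] <- inverse_dose(cal, v[!out_of_range])
  attr(d, "masked_fraction") <- frac
  d
}

#' Read and write film scans as 16-bit TIFF
#'
#' Thin wrappers around the tiff package keeping intensities in 16-bit
#' counts (0--65535) as delivered by flatbed scanners.
#'
#' @param path TIFF path.
#' @return `read_film_scan`: a numeric matrix (grayscale) or array (RGB)
#'   of counts.
#' @export
read_film_scan <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  img
}

#' @rdname read_film_scan
#' @param image Numeric matrix or array of counts in \[0, 65535\].
#' @export
write_film_scan <- function(image, path) {
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a delimited-text OD map
#'
#' Alternative to TIFF input: a plain-text matrix of net OD values
#' (whitespace-, comma- or tab-separated, one image row per line).
#'
#' @param path Text file path.
#' @param pixel_size Pixel side length, mm.
#' @param channel Label recorded in the map.
#' @return An [od_map()].
#' @export
read_od_map <- function(path, pixel_size = 25.4 / 300, channel = "red") {
  v <- as.matrix(utils::read.table(path, header = FALSE,
                                   sep = "", comment.char = "#"))
  dimnames(v) <- NULL
  od_map(v, pixel_size = pixel_size, channel = channel)
}

#' Write a radial profile as CSV with a JSON sidecar
#'
#' @param profile A [radial_rebin()] tibble.
#' @param csv_path Output CSV; the sidecar (centre, bin width) is written
#'   next to it with extension `.json`.
#' @return `csv_path`, invisibly.
#' @export
write_radial_profile <- function(profile, csv_path) {
  readr::write_csv(profile, csv_path)
  sidecar <- list(center = attr(profile, "center"),
                  bin_width = attr(profile, "bin_width"))
  jsonlite::write_json(sidecar, sub("\\.csv$", ".json", csv_path),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
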