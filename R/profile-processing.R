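#' Net optical density map
#'
#' Container for a 2D net-OD image. Coordinates are in mm with the origin
#' at the centre of the top-left pixel, x rightward, y downward.
#'
#' @param values Numeric matrix of net OD (rows = y, columns = x).
#' @param pixel_size Pixel side length, mm. The default corresponds to a
#'   300 dpi scan.
#' @param channel Colour channel the map was derived from.
#' @return An object of class `od_map`.
#' @export
od_map <- function(values, pixel_size = 25.4 / 300, channel = "red") {
  stopifnot(is.matrix(values), pixel_size > 0)
  structure(list(values = values, pixel_size = pixel_size,
                 channel = channel),
            class = "od_map")
}

#' @export
print.od_map <- function(x, ...) {
  cat("<od_map>", nrow(x$values), "x", ncol(x$values), "px @",
      format(x$pixel_size, digits = 4), "mm,", x$channel, "channel\n")
  cat("  OD range:", format(range(x$values, na.rm = TRUE), digits = 4),
      "\n")
  invisible(x)
}

select_channel <- function(img, channel) {
  if (length(dim(img)) == 3L) {
    ch <- match(channel, c("red", "green", "blue"))
    if (is.na(ch)) stop("unknown channel: ", channel, call. = FALSE)
    img[, , ch]
  } else {
    as.matrix(img)
  }
}

#' Compute the net optical density from a before/after scan pair
#'
#' `OD(x, y) = log10(mean(I_before) / I_after(x, y))` on the selected
#' colour channel: the film-wide mean of the unirradiated scan over the
#' pixel-wise irradiated intensities. Optionally (`per_pixel_before`)
#' divides by the before-scan pixel-wise instead.
#'
#' Zero and saturated after-pixels cannot carry an OD value; they are
#' masked (`NA` in the map, logical mask in attribute `"flagged"`), and
#' more than 1% flagged pixels is an error.
#'
#' @param before,after Intensity images of identical shape: numeric
#'   matrices or 3-channel arrays (16-bit counts).
#' @param channel Colour channel (default `"red"`, the channel used for
#'   dose response).
#' @param pixel_size Pixel side length, mm.
#' @param per_pixel_before Divide by the before image pixel-wise rather
#'   than by its mean.
#' @param saturation Intensity treated as saturated (default `2^16 - 1`).
#' @return An [od_map()] with the flagged-pixel mask attached to
#'   `values` as attribute `"flagged"`.
#' @export
net_optical_density <- function(before, after, channel = "red",
                                pixel_size = 25.4 / 300,
                                per_pixel_before = FALSE,
                                saturation = 65535) {
  b <- select_channel(before, channel)
  a <- select_channel(after, channel)
  if (!all(dim(b) == dim(a))) {
    stop("before and after images must have the same shape", call. = FALSE)
  }
  flagged <- a <= 0 | a >= saturation
  if (mean(flagged) > 0.01) {
    stop(sprintf("%.1f%% of after-pixels are zero or saturated",
                 100 * mean(flagged)), call. = FALSE)
  }
  denom <- a
  denom[flagged] <- NA_real_
  num <- if (per_pixel_before) b else mean(b)
  v <- log10(num / denom)
  attr(v, "flagged") <- flagged
  od_map(v, pixel_size = pixel_size, channel = channel)
}

pixel_coords <- function(od) {
  list(x = (seq_len(ncol(od$values)) - 1) * od$pixel_size,
       y = (seq_len(nrow(od$values)) - 1) * od$pixel_size)
}

#' Find the centre of a radially symmetric OD distribution
#'
#' The centre is the point minimizing the standard deviation of the OD
#' along a ring of constant radius (a symmetric field has constant OD on
#' any circle around its true centre). The ring radius is taken where the
#' dose reaches 50% of the plateau, the steepest part of the falloff. The
#' search is a two-stage grid scan: a coarse grid around the geometric
#' image centre, then a fine grid around the coarse minimum; ties are
#' broken by the first candidate in row-major scan order.
#'
#' @param od An [od_map()].
#' @param r50 Ring radius, mm (default: the 50% radius of the default
#'   phantom profile).
#' @param coarse_extent,coarse_step Coarse grid half-extent and step, mm.
#' @param fine_extent,fine_step Fine grid half-extent and step, mm.
#' @param annulus_half Half-thickness of the ring, mm (default half a
#'   pixel).
#' @param start Centre of the coarse grid, mm; default the geometric image
#'   centre.
#' @return Numeric `c(cx, cy)` in mm with attribute `"sigma"` (the
#'   minimized ring standard deviation).
#' @export
find_center <- function(od, r50 = r50_radius(), coarse_extent = 5,
                        coarse_step = 1, fine_extent = 1, fine_step = 0.1,
                        annulus_half = od$pixel_size / 2, start = NULL) {
  co <- pixel_coords(od)
  if (is.null(start)) {
    start <- c(mean(range(co$x)), mean(range(co$y)))
  }
  v <- od$values
  scan_grid <- function(center, extent, step) {
    gx <- center[1] + seq(-extent, extent, by = step)
    gy <- center[2] + seq(-extent, extent, by = step)
    sig <- matrix(NA_real_, nrow = length(gy), ncol = length(gx))
    for (iy in seq_along(gy)) {
      dy2 <- (co$y - gy[iy])^2
      for (ix in seq_along(gx)) {
        r <- sqrt(outer(dy2, (co$x - gx[ix])^2, `+`))
        ring <- abs(r - r50) <= annulus_half
        sig[iy, ix] <- stats::sd(v[ring], na.rm = TRUE)
      }
    }
    # row-major: scan rows (y) first, columns (x) within a row
    flat <- as.vector(t(sig))
    i <- which.min(flat)
    iy <- (i - 1) %/% length(gx) + 1
    ix <- (i - 1) %% length(gx) + 1
    list(center = c(gx[ix], gy[iy]), sigma = sig)
  }
  coarse <- scan_grid(start, coarse_extent, coarse_step)
  rng <- range(coarse$sigma, na.rm = TRUE)
  if (!all(is.finite(rng)) || diff(rng) < 1e-12 * max(abs(rng), 1)) {
    stop("OD map shows no radial structure at r50 (flat ring standard ",
         "deviation); cannot locate a centre", call. = FALSE)
  }
  fine <- scan_grid(coarse$center, fine_extent, fine_step)
  out <- fine$center
  attr(out, "sigma") <- min(fine$sigma, na.rm = TRUE)
  out
}

#' Rebin an OD map into a radial profile
#'
#' Pixels are assigned to half-open annular bins
#' `[b * bin_width, (b+1) * bin_width)` by their distance from `center`;
#' per-bin mean, standard deviation and pixel count are reported. Bins
#' without pixels are dropped.
#'
#' @param od An [od_map()].
#' @param center Numeric `c(cx, cy)`, mm.
#' @param bin_width Bin width, mm (default one pixel).
#' @param r_max Largest radius retained, mm.
#' @return A tibble of class `radial_profile` with columns `r_mm` (bin
#'   centres), `od_mean`, `od_std`, `count`; attributes `center` and
#'   `bin_width`.
#' @export
radial_rebin <- function(od, center, bin_width = od$pixel_size,
                         r_max = 30) {
  co <- pixel_coords(od)
  if (center[1] < min(co$x) || center[1] > max(co$x) ||
      center[2] < min(co$y) || center[2] > max(co$y)) {
    stop("`center` lies outside the image", call. = FALSE)
  }
  r <- sqrt(outer((co$y - center[2])^2, (co$x - center[1])^2, `+`))
  keep <- r < r_max & is.finite(od$values)
  bin <- floor(r[keep] / bin_width)
  v <- od$values[keep]
  agg <- tibble::tibble(bin = bin, od = v) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(od_mean = mean(.data$od),
                     od_std = if (dplyr::n() > 1) stats::sd(.data$od) else 0,
                     count = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$bin)
  out <- tibble::tibble(r_mm = (agg$bin + 0.5) * bin_width,
                        od_mean = agg$od_mean, od_std = agg$od_std,
                        count = agg$count)
  attr(out, "center") <- as.numeric(center)
  attr(out, "bin_width") <- bin_width
  class(out) <- c("radial_profile", class(out))
  out
}

#' Average an OD map along one symmetry axis
#'
#' For an axially symmetric field: the profile along `axis` is the mean
#' across the perpendicular direction, restricted to within `half_width`
#' of the symmetry axis (default 1 cm) to stay inside the homogeneous
#' band.
#'
#' @param od An [od_map()].
#' @param axis `"x"` (profile along x, averaging over y) or `"y"`.
#' @param half_width Half-width of the averaging band, mm; 0 keeps the
#'   single centre row/column.
#' @param center Numeric `c(cx, cy)`, mm; default the geometric image
#'   centre.
#' @return A tibble with `pos_mm`, `od_mean`, `od_std`, `count`.
#' @export
axial_profile <- function(od, axis = c("x", "y"), half_width = 10,
                          center = NULL) {
  axis <- match.arg(axis)
  co <- pixel_coords(od)
  if (is.null(center)) center <- c(mean(range(co$x)), mean(range(co$y)))
  if (half_width > max(co$x) - min(co$x) ||
      half_width > max(co$y) - min(co$y)) {
    stop("`half_width` exceeds the image extent", call. = FALSE)
  }
  v <- od$values
  if (axis == "x") {
    rows <- abs(co$y - center[2]) <= half_width + 1e-9
    sub <- v[rows, , drop = FALSE]
    pos <- co$x
  } else {
    cols <- abs(co$x - center[1]) <= half_width + 1e-9
    sub <- t(v[, cols, drop = FALSE])
    pos <- co$y
  }
  tibble::tibble(
    pos_mm = pos,
    od_mean = colMeans(sub, na.rm = TRUE),
    od_std = apply(sub, 2, function(z) {
      z <- z[is.finite(z)]
      if (length(z) > 1) stats::sd(z) else 0
    }),
    count = colSums(is.finite(sub))
  )
}

#' Split a radial profile into plateau statistic and gradient samples
#'
#' The central plateau (`r <= plateau_r_max`) is collapsed to its mean OD,
#' the absolute-anchor/verification statistic; the gradient annulus
#' (`r_lb <= r <= r_ub`) supplies the per-position samples for the ratio
#' objective. The plateau is deliberately not fed to the ratio cost: its
#' positions all see the same dose, so ratios there carry no shape
#' information.
#'
#' @param profile A [radial_rebin()] tibble.
#' @param cfg An [objective_config()].
#' @return A list with `plateau` (one-row tibble: `plateau_od`,
#'   `plateau_std`, `n_bins`) and `gradient` (tibble `r_mm`, `net_od`,
#'   `od_std`, `count`).
#' @export
extract_regions <- function(profile, cfg = objective_config()) {
  plat <- profile[profile$r_mm <= cfg$plateau_r_max, ]
  grad <- profile[profile$r_mm >= cfg$r_lb & profile$r_mm <= cfg$r_ub, ]
  if (nrow(plat) == 0L) {
    stop("no profile bins inside the plateau region", call. = FALSE)
  }
  if (nrow(grad) == 0L) {
    stop("no profile bins inside the gradient region [r_lb, r_ub]",
         call. = FALSE)
  }
  list(
    plateau = tibble::tibble(
      plateau_od = mean(plat$od_mean),
      plateau_std = if (nrow(plat) > 1) stats::sd(plat$od_mean) else 0,
      n_bins = nrow(plat)),
    gradient = tibble::tibble(r_mm = grad$r_mm, net_od = grad$od_mean,
                              od_std = grad$od_std, count = grad$count)
  )
}

#' Assemble a film measurement from a radial profile
#'
#' Binds the plateau and gradient rows of one processed film into the long
#' measurement format used by the fitting functions.
#'
#' @param profile A [radial_rebin()] tibble.
#' @param measurement_id,level_id Identifiers.
#' @param k Dose-level scaling, Gy.
#' @param reference_dose Absolute reference dose at the plateau, Gy
#'   (`NA` if none).
#' @param cfg An [objective_config()].
#' @return A [as_film_measurements()] tibble for this single film.
#' @export
profile_to_measurement <- function(profile, measurement_id, level_id, k,
                                   reference_dose = NA_real_,
                                   cfg = objective_config()) {
  plat <- profile[profile$r_mm <= cfg$plateau_r_max, ]
  grad <- profile[profile$r_mm >= cfg$r_lb & profile$r_mm <= cfg$r_ub, ]
  if (nrow(plat) == 0L || nrow(grad) == 0L) {
    stop("profile does not span both the plateau and gradient regions",
         call. = FALSE)
  }
  as_film_measurements(dplyr::bind_rows(
    tibble::tibble(measurement_id = measurement_id, level_id = level_id,
                   k = k, r_mm = plat$r_mm, net_od = plat$od_mean,
                   region = "plateau", weight = 1, count = plat$count,
                   reference_dose = reference_dose),
    tibble::tibble(measurement_id = measurement_id, level_id = level_id,
                   k = k, r_mm = grad$r_mm, net_od = grad$od_mean,
                   region = "gradient", weight = 1, count = grad$count,
                   reference_dose = NA_real_)
  ))
}
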