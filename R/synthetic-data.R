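#' Phantom specification for the synthetic dose profile
#'
#' Describes the radially symmetric relative dose profile the generator
#' emulates: a homogeneous central plateau, a linear 80--20% falloff, and a
#' smooth tail. Defaults mirror a pencil-beam-scanned proton field on a
#' 67 mm film piece: plateau of 15 mm radius, falloff from 80% at 17 mm to
#' 20% at 26 mm, and samples below 5% of the central dose excluded from
#' analysis.
#'
#' @param plateau_radius Radius up to which the relative dose is 1, mm.
#' @param falloff_start,falloff_end Radii of the 80% and 20% points of the
#'   linear falloff, mm.
#' @param falloff_hi,falloff_lo Relative dose at `falloff_start` /
#'   `falloff_end`.
#' @param cutoff_fraction Relative dose below which samples are flagged
#'   excluded (must lie in (0, 0.2)).
#' @param film_size Side length of the square film piece, mm.
#' @param pixel_size Pixel side length, mm. The default 0.4 mm is a
#'   coarsened scan resolution used for fast simulation; 300 dpi scanning
#'   corresponds to 25.4/300 = 0.0847 mm.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(plateau_radius = 15, falloff_start = 17,
                         falloff_end = 26, falloff_hi = 0.8,
                         falloff_lo = 0.2, cutoff_fraction = 0.05,
                         film_size = 67, pixel_size = 0.4) {
  stopifnot(plateau_radius < falloff_start, falloff_start < falloff_end,
            falloff_hi > falloff_lo, falloff_lo > 0,
            cutoff_fraction > 0, cutoff_fraction < 0.2,
            film_size > 0, pixel_size > 0)
  structure(list(plateau_radius = plateau_radius,
                 falloff_start = falloff_start, falloff_end = falloff_end,
                 falloff_hi = falloff_hi, falloff_lo = falloff_lo,
                 cutoff_fraction = cutoff_fraction, film_size = film_size,
                 pixel_size = pixel_size),
            class = "phantom_spec")
}

#' Noise specification for synthetic measurements
#'
#' Two stochastic components emulate the repeatability of film/scanner
#' measurements: a per-film multiplicative response factor (films of one
#' batch differ by a fraction of a percent in sensitivity) and additive
#' per-pixel OD noise with a relative part and an absolute floor. Rebinned
#' profile values inherit the pixel noise scaled by `1/sqrt(count)`.
#'
#' @param od_sigma_rel Relative per-pixel OD noise (default 1%).
#' @param od_sigma_abs Absolute per-pixel OD noise floor.
#' @param interfilm_sigma_rel Standard deviation of the per-film
#'   multiplicative response factor.
#' @param seed Integer seed making every generated data set reproducible.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(od_sigma_rel = 0.01, od_sigma_abs = 0.002,
                       interfilm_sigma_rel = 0.005, seed = 1L) {
  stopifnot(od_sigma_rel >= 0, od_sigma_abs >= 0, interfilm_sigma_rel >= 0)
  structure(list(od_sigma_rel = od_sigma_rel, od_sigma_abs = od_sigma_abs,
                 interfilm_sigma_rel = interfilm_sigma_rel,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Zero-noise specification (noise-free generation)
#' @param seed Seed (irrelevant for the values, kept for reproducibility
#'   bookkeeping).
#' @return A [noise_spec()] with all components zero.
#' @export
noise_free <- function(seed = 1L) {
  noise_spec(0, 0, 0, seed = seed)
}

#' Default synthetic ground-truth calibration
#'
#' A bimolecular calibration resembling the red-channel response of EBT3
#' film over 0.25--12 Gy: saturation net OD 0.70, half-saturation dose
#' 8 Gy, and the classical bimolecular shape exponent 1 (net OD linear in
#' dose at the low-dose end, as measured film response is). These values
#' are synthetic defaults, not fitted batch parameters; see the methods
#' vignette for how they were chosen.
#'
#' @param theta Length-3 physical parameter vector.
#' @return A [calibration_function()] in physical units (unit scales).
#' @export
default_truth <- function(theta = c(0.70, 8.0, 1.0)) {
  calibration_function("bimolecular", theta, od_scale = 1, dose_scale = 1,
                       valid_od_range = c(1e-5, theta[1] * (1 - 1e-9)))
}

#' The twelve-level dose schedule of the sequential proton session
#' @return Numeric vector of plateau doses, Gy.
#' @export
p1_levels <- function() {
  c(0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 5, 7.5, 10, 12)
}

#' Relative radial dose profile
#'
#' Evaluates the phantom's normalized dose profile `d(r)` in \[0, 1\]:
#' 1 on the plateau, a monotone cubic shoulder joining the plateau to the
#' linear 80--20% falloff, and an exponential tail continuing the falloff
#' slope smoothly below 20%. The profile is nonincreasing everywhere.
#'
#' @param spec A [phantom_spec()].
#' @param r Radius grid, mm; default bin centres at `pixel_size` spacing up
#'   to 30 mm.
#' @return A tibble with `r_mm`, `dose_rel`, and `excluded` (samples below
#'   `cutoff_fraction`).
#' @export
make_dose_profile <- function(spec = phantom_spec(), r = NULL) {
  if (is.null(r)) {
    r <- seq(spec$pixel_size / 2, 30, by = spec$pixel_size)
  }
  d <- relative_dose(spec, r)
  tibble::tibble(r_mm = r, dose_rel = d,
                 excluded = d < spec$cutoff_fraction)
}

# vectorized relative dose; C1-smooth, monotone nonincreasing
relative_dose <- function(spec, r) {
  r1 <- spec$plateau_radius; r2 <- spec$falloff_start
  r3 <- spec$falloff_end
  v2 <- spec$falloff_hi; v3 <- spec$falloff_lo
  slope <- (v3 - v2) / (r3 - r2)
  lambda <- -v3 / slope  # tail length matching the falloff slope at r3
  d <- numeric(length(r))
  d[r <= r1] <- 1
  sh <- r > r1 & r < r2
  if (any(sh)) {
    # cubic Hermite from (r1, 1, slope 0) to (r2, v2, slope of the falloff)
    t <- (r[sh] - r1) / (r2 - r1)
    h00 <- 2 * t^3 - 3 * t^2 + 1
    h01 <- -2 * t^3 + 3 * t^2
    h11 <- t^3 - t^2
    d[sh] <- h00 * 1 + h01 * v2 + h11 * (r2 - r1) * slope
  }
  lin <- r >= r2 & r <= r3
  d[lin] <- v2 + slope * (r[lin] - r2)
  tail <- r > r3
  d[tail] <- v3 * exp(-(r[tail] - r3) / lambda)
  d
}

# radius at which the relative dose falls to `frac`
cutoff_radius <- function(spec, frac = spec$cutoff_fraction) {
  slope <- (spec$falloff_lo - spec$falloff_hi) /
    (spec$falloff_end - spec$falloff_start)
  lambda <- -spec$falloff_lo / slope
  if (frac >= spec$falloff_lo) {
    spec$falloff_start + (frac - spec$falloff_hi) / slope
  } else {
    spec$falloff_end + lambda * log(spec$falloff_lo / frac)
  }
}

# radius of 50% relative dose, the default annulus for centre finding
r50_radius <- function(spec = phantom_spec()) cutoff_radius(spec, 0.5)

# expected pixels per radial bin after rebinning at this bin width
bin_pixel_count <- function(r, bin_width, pixel_size) {
  pmax(1, round(2 * pi * r * bin_width / pixel_size^2))
}

#' Simulate a set of film measurements
#'
#' Generates rebinned radial net-OD profiles for each dose level and
#' repetition, as produced by the image pipeline, without rendering
#' images: `o(r) = f(k d(r) | theta_true) * (1 + delta_film) + eps(r)`,
#' with per-bin noise scaled by `1/sqrt(count)` to emulate pixel averaging
#' over annuli. Plateau rows carry the dose level as reference dose.
#'
#' @param levels Dose levels, Gy (default the twelve-level schedule
#'   0.25--12 Gy).
#' @param reps Repetitions per level (default 3).
#' @param truth Ground-truth [calibration_function()] (physical units).
#' @param noise A [noise_spec()]; use [noise_free()] for exact closure
#'   tests.
#' @param spec A [phantom_spec()].
#' @param cfg An [objective_config()]; defines which radii become plateau
#'   and gradient rows.
#' @param bin_width Radial bin width, mm (default `spec$pixel_size`).
#' @return A [as_film_measurements()] tibble, deterministic given
#'   `noise$seed`.
#' @export
simulate_measurement_set <- function(levels = p1_levels(), reps = 3L,
                                     truth = default_truth(),
                                     noise = noise_spec(),
                                     spec = phantom_spec(),
                                     cfg = objective_config(),
                                     bin_width = spec$pixel_size) {
  stopifnot(all(levels > 0), reps >= 1)
  prof <- make_dose_profile(spec,
                            r = seq(bin_width / 2, 30, by = bin_width))
  keep <- (prof$r_mm <= cfg$plateau_r_max) |
    (prof$r_mm >= cfg$r_lb & prof$r_mm <= cfg$r_ub)
  prof <- prof[keep & !prof$excluded, ]
  counts <- bin_pixel_count(prof$r_mm, bin_width, spec$pixel_size)
  region <- ifelse(prof$r_mm <= cfg$plateau_r_max, "plateau", "gradient")

  withr::with_seed(noise$seed, {
    rows <- list()
    m <- 0L
    for (li in seq_along(levels)) {
      k <- levels[li]
      for (rep_i in seq_len(reps)) {
        m <- m + 1L
        delta <- stats::rnorm(1, 0, noise$interfilm_sigma_rel)
        o_clean <- forward_od(truth, k * prof$dose_rel)
        sigma <- (noise$od_sigma_abs + noise$od_sigma_rel * o_clean) /
          sqrt(counts)
        o <- o_clean * (1 + delta) + stats::rnorm(length(o_clean), 0, sigma)
        o <- pmax(o, 1e-6)
        rows[[m]] <- tibble::tibble(
          measurement_id = sprintf("L%02d_rep%d", li, rep_i),
          level_id = sprintf("L%02d", li),
          k = k, r_mm = prof$r_mm, net_od = o,
          region = region, weight = 1, count = counts,
          reference_dose = ifelse(region == "plateau", k, NA_real_)
        )
      }
    }
    as_film_measurements(dplyr::bind_rows(rows))
  })
}

# dose -> OD that tolerates doses below/at zero (renders to OD 0) and, for
# truths whose forward map is only defined on a bracket, ramps linearly
# below the lowest invertible dose
render_od_from_dose <- function(truth, dose) {
  od <- numeric(length(dose))
  pos <- dose > 0
  if (truth$family == "bimolecular") {
    od[pos] <- forward_od(truth, dose[pos])
    return(od)
  }
  o_min <- truth$valid_od_range[1]
  d_min <- inverse_dose(truth, o_min)
  hi <- pos & dose >= d_min
  lo <- pos & dose < d_min
  if (any(hi)) od[hi] <- forward_od(truth, dose[hi])
  if (any(lo)) od[lo] <- o_min * dose[lo] / d_min
  od
}

#' Render a synthetic scanner image pair for one film
#'
#' Produces a uniform 16-bit "before" scan and an "after" scan whose
#' intensities encode the phantom's dose profile through the ground-truth
#' calibration: `I_after = I_before_mean * 10^-OD(x, y)`. The pair is
#' invertible by [net_optical_density()] up to the pixel noise.
#'
#' @inheritParams simulate_measurement_set
#' @param k Plateau dose of the exposure, Gy.
#' @param center_offset Length-2 offset (mm) of the field centre from the
#'   geometric film centre.
#' @param before_mean Mean before-scan intensity (16-bit counts).
#' @param pixel_size Rendered pixel size, mm.
#' @return A list of class `film_image`: integer matrices `before` and
#'   `after`, `pixel_size`, true `center` (mm, x/y from the top-left pixel
#'   centre), and `k`.
#' @export
render_film_image <- function(spec = phantom_spec(), k,
                              truth = default_truth(),
                              center_offset = c(0, 0),
                              noise = noise_spec(),
                              before_mean = 40000,
                              pixel_size = spec$pixel_size) {
  stopifnot(k > 0, length(center_offset) == 2)
  n <- round(spec$film_size / pixel_size)
  geom <- (n - 1) / 2 * pixel_size
  center <- c(geom + center_offset[1], geom + center_offset[2])
  # the 50% ring (used for centre finding) must stay on the film; the
  # far tail may be clipped by the film edge
  if (r50_radius(spec) + max(abs(center_offset)) > spec$film_size / 2) {
    stop("field does not fit the film at this centre offset (the 50% dose ",
         "ring would leave the film)", call. = FALSE)
  }
  x <- (seq_len(n) - 1) * pixel_size
  y <- (seq_len(n) - 1) * pixel_size
  R <- sqrt(outer((y - center[2])^2, (x - center[1])^2, `+`))
  od <- render_od_from_dose(truth, k * relative_dose(spec, as.vector(R)))
  od <- matrix(od, nrow = n)
  withr::with_seed(noise$seed, {
    delta <- stats::rnorm(1, 0, noise$interfilm_sigma_rel)
    sigma <- noise$od_sigma_abs + noise$od_sigma_rel * od
    od_noisy <- od * (1 + delta) +
      matrix(stats::rnorm(n * n, 0, 1), n, n) * sigma
  })
  after <- before_mean * 10^(-od_noisy)
  if (any(after < 1)) {
    stop("net OD too high for the 16-bit intensity range (after-scan ",
         "underflow)", call. = FALSE)
  }
  before <- matrix(as.integer(round(before_mean)), n, n)
  structure(list(before = before,
                 after = matrix(as.integer(round(after)), n, n),
                 pixel_size = pixel_size, center = center, k = k),
            class = "film_image")
}

#' Render a four-field single-exposure image
#'
#' One large scan containing four radial fields in quadrant layout
#' (I upper right, II upper left, III lower left, IV lower right), centres
#' spaced `spacing` mm apart, allowing a full calibration from a single
#' measurement. An optional uniform cross-scatter dose (a fraction of the
#' lowest plateau dose) can be added to study the perturbation from
#' neighbouring fields.
#'
#' @inheritParams render_film_image
#' @param levels Plateau doses of quadrants I--IV, Gy.
#' @param spacing Distance between adjacent field centres, mm.
#' @param scatter_fraction Uniform scatter dose as a fraction of
#'   `min(levels)`; 0 disables it.
#' @param margin Extra image margin around the outermost field centres,
#'   mm.
#' @return A list of class `film_image` with an additional `manifest`
#'   tibble (field, level, nominal centre in mm) and `scatter_fraction`.
#' @export
make_multifield_image <- function(spec = phantom_spec(),
                                  levels = c(4, 12, 2, 0.75),
                                  spacing = 120,
                                  truth = default_truth(),
                                  noise = noise_spec(),
                                  scatter_fraction = 0,
                                  before_mean = 40000,
                                  pixel_size = spec$pixel_size,
                                  margin = spec$film_size / 2) {
  if (length(levels) != 4L) stop("exactly four dose levels are required",
                                 call. = FALSE)
  r_cut <- cutoff_radius(spec)
  if (spacing < 2 * r_cut) {
    stop(sprintf("fields overlap above the cutoff: spacing %g mm < 2 x ",
                 spacing) |> paste0(sprintf("cutoff radius %.1f mm", r_cut)),
         call. = FALSE)
  }
  half <- spacing / 2
  size <- spacing + 2 * margin
  n <- round(size / pixel_size)
  mid <- (n - 1) / 2 * pixel_size
  # x rightward, y downward: quadrant I is +x, -y
  manifest <- tibble::tibble(
    field = c("I", "II", "III", "IV"),
    level = levels,
    cx_mm = mid + c(half, -half, -half, half),
    cy_mm = mid + c(-half, -half, half, half)
  )
  x <- (seq_len(n) - 1) * pixel_size
  y <- (seq_len(n) - 1) * pixel_size
  dose <- matrix(0, n, n)
  for (f in seq_len(4)) {
    R <- sqrt(outer((y - manifest$cy_mm[f])^2,
                    (x - manifest$cx_mm[f])^2, `+`))
    dose <- dose + levels[f] *
      matrix(relative_dose(spec, as.vector(R)), n, n)
  }
  if (scatter_fraction > 0) {
    dose <- dose + scatter_fraction * min(levels)
  }
  od <- matrix(render_od_from_dose(truth, as.vector(dose)), n, n)
  withr::with_seed(noise$seed, {
    delta <- stats::rnorm(1, 0, noise$interfilm_sigma_rel)
    sigma <- noise$od_sigma_abs + noise$od_sigma_rel * od
    od_noisy <- od * (1 + delta) +
      matrix(stats::rnorm(n * n, 0, 1), n, n) * sigma
  })
  after <- before_mean * 10^(-od_noisy)
  if (any(after < 1)) {
    stop("net OD too high for the 16-bit intensity range", call. = FALSE)
  }
  structure(list(before = matrix(as.integer(round(before_mean)), n, n),
                 after = matrix(as.integer(round(after)), n, n),
                 pixel_size = pixel_size, manifest = manifest,
                 scatter_fraction = scatter_fraction),
            class = "film_image")
}
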