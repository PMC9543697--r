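# Shared fixtures, generated once per test run and memoised. Everything is
# built in code from the synthetic generator; no data files.

fr_cache <- new.env(parent = emptyenv())

# noise-free 12-level x 3-rep measurement set from the default truth
nf_dataset <- function() {
  if (is.null(fr_cache$nf)) {
    fr_cache$nf <- simulate_measurement_set(noise = noise_free())
  }
  fr_cache$nf
}

# default-noise 12-level x 3-rep measurement set
noisy_dataset <- function() {
  if (is.null(fr_cache$noisy)) {
    fr_cache$noisy <- simulate_measurement_set(noise = noise_spec(seed = 3))
  }
  fr_cache$noisy
}

# central finite differences of a scalar function
fd_gradient <- function(f, x, h = 1e-7) {
  vapply(seq_along(x), function(m) {
    xp <- x; xm <- x
    xp[m] <- xp[m] + h
    xm[m] <- xm[m] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# total cost chi as a function of (normalized) theta for a fixed dataset
chi_of_theta <- function(measurements, family, cfg, od_scale, dose_scale) {
  obj <- filmratio:::prepare_objective_data(measurements, cfg, od_scale,
                                            dose_scale)
  function(theta) {
    sum(filmratio:::cost_residuals(theta, family, obj,
                                   jacobian = FALSE)$res^2)
  }
}

grad_of_theta <- function(measurements, family, cfg, od_scale, dose_scale) {
  obj <- filmratio:::prepare_objective_data(measurements, cfg, od_scale,
                                            dose_scale)
  function(theta) {
    cr <- filmratio:::cost_residuals(theta, family, obj, jacobian = TRUE)
    as.vector(2 * crossprod(cr$jac, cr$res))
  }
}
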