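test_that("inverse_dose evaluates both families on hand-checked cases", {
  # identity polynomial: d = o
  cal <- calibration_function("polynomial", c(0, 1, 0, 0, 0),
                              valid_od_range = c(0.01, 1))
  expect_equal(inverse_dose(cal, 0.5), 0.5)

  # at o = theta1/2 the ratio term is 1, so d = theta2 for any theta3
  calb <- calibration_function("bimolecular", c(0.8, 3, 1.2),
                               valid_od_range = c(0.01, 0.79))
  expect_equal(inverse_dose(calb, 0.4), 3)

  # theta = (1,1,1): d = o/(1-o); hand value at o = 0.25 confirmed by a
  # numerical root-find of the forward map
  cal1 <- calibration_function("bimolecular", c(1, 1, 1),
                               valid_od_range = c(0.01, 0.99))
  expect_equal(inverse_dose(cal1, 0.25), 1 / 3, tolerance = 1e-12)
  root <- uniroot(function(d) forward_od(cal1, d) - 0.25,
                  c(1e-6, 10), tol = 1e-14)$root
  expect_equal(inverse_dose(cal1, 0.25), root, tolerance = 1e-9)

  # out-of-range OD is refused
  expect_error(inverse_dose(cal, 1.5), "outside the valid range")
})

test_that("forward_od inverts the dose map for both families", {
  cal1 <- calibration_function("bimolecular", c(1, 1, 1),
                               valid_od_range = c(0.001, 0.999))
  expect_equal(forward_od(cal1, 1), 0.5)         # symmetric midpoint
  expect_lt(forward_od(cal1, 1e-9), 1e-8)        # o -> 0 with d -> 0
  expect_equal(forward_od(cal1, 1e9), 1, tolerance = 1e-8)  # saturation

  # polynomial d = 2o inverts to o = d/2 by root finding
  cal2 <- calibration_function("polynomial", c(0, 2, 0, 0, 0),
                               valid_od_range = c(0.01, 1))
  expect_equal(forward_od(cal2, 1), 0.5, tolerance = 1e-10)

  # non-monotone polynomial over the bracket cannot be inverted
  bad <- calibration_function("polynomial", c(0, -1, 0, 0, 0),
                              valid_od_range = c(0.01, 1))
  expect_error(forward_od(bad, 0.5), "not increasing")
})

test_that("bimolecular round trip is exact to 1e-9 over 0.1-15 Gy", {
  set.seed(42)
  for (i in 1:10) {
    th <- c(1 + abs(rnorm(1, 0, 0.5)), abs(rnorm(1, 5, 2)) + 0.5,
            rnorm(1, 1, 0.15))
    cal <- calibration_function("bimolecular", th,
                                valid_od_range = c(1e-6, th[1] * (1 - 1e-9)))
    d <- exp(seq(log(0.1), log(15), length.out = 40))
    d2 <- inverse_dose(cal, forward_od(cal, d), allow_outside = TRUE)
    expect_lt(max(abs(d2 - d) / d), 1e-9)
  }
})

test_that("parameter_gradient matches the trivial closed forms", {
  cal <- calibration_function("polynomial", c(0, 1, 0, 0, 0),
                              valid_od_range = c(0.01, 1))
  expect_equal(as.vector(parameter_gradient(cal, 0.5)),
               c(1, 0.5, 0.25, 0.125, 0.0625))
  # d(f^-1)/d(theta2) = d / theta2 for the bimolecular family
  calb <- calibration_function("bimolecular", c(1.2, 4, 1.1),
                               valid_od_range = c(0.01, 1.19))
  o <- c(0.1, 0.4, 0.9)
  g <- parameter_gradient(calb, o)
  expect_equal(g[, 2], inverse_dose(calb, o) / 4, tolerance = 1e-12)
})

test_that("parameter gradients agree with central finite differences", {
  set.seed(7)
  n_checked <- 0L
  while (n_checked < 100L) {
    family <- if (n_checked %% 2 == 0) "bimolecular" else "polynomial"
    if (family == "bimolecular") {
      th <- c(1 + abs(rnorm(1, 0, 0.4)), abs(rnorm(1, 0.6, 0.3)) + 0.05,
              rnorm(1, 1, 0.1))
    } else {
      th <- rnorm(5, 0, 0.5)
    }
    o <- runif(1, 0.05, 0.9)
    if (family == "bimolecular" && o >= th[1] * 0.95) next
    g <- filmratio:::.param_grad_norm(family, th, o)
    fd <- fd_gradient(function(t)
      filmratio:::.inverse_dose_norm(family, t, o), th, h = 1e-6)
    expect_lt(max(abs(as.vector(g) - fd)),
              1e-5 * (sqrt(sum(fd^2)) + 1e-8))
    n_checked <- n_checked + 1L
  }
})

test_that("check_bijective accepts monotone maps and localizes violations", {
  ok <- calibration_function("polynomial", c(0, 1, 0, 0, 0),
                             valid_od_range = c(0.01, 1))
  expect_true(check_bijective(ok))
  dec <- calibration_function("polynomial", c(0, -1, 0, 0, 0),
                              valid_od_range = c(0.01, 1))
  expect_false(check_bijective(dec))
  # d = o - 5 o^4 turns over at o = (1/20)^(1/3) ~ 0.368
  turn <- calibration_function("polynomial", c(0, 1, 0, 0, -5),
                               valid_od_range = c(0.01, 1))
  res <- check_bijective(turn)
  expect_false(res)
  expect_true(all(abs(attr(res, "diagnostic") - (1 / 20)^(1 / 3)) < 0.05))
})

test_that("normalized and physical parameterizations give identical doses", {
  set.seed(3)
  th <- rnorm(5, 0, 0.4)
  od_scale <- 0.47
  dose_scale <- 12
  cal <- calibration_function("polynomial", th, od_scale = od_scale,
                              dose_scale = dose_scale,
                              valid_od_range = c(0.01, 0.45))
  o <- seq(0.02, 0.44, length.out = 30)
  d_norm_path <- inverse_dose(cal, o)
  thp <- physical_theta(cal)
  d_phys_path <- as.vector(outer(o, 0:4, `^`) %*% thp)
  expect_equal(d_norm_path, d_phys_path, tolerance = 1e-12)
})

test_that("calibrations survive a JSON round trip exactly", {
  cal <- calibration_function("bimolecular", c(1.3, 0.62, 1.05),
                              od_scale = 0.44, dose_scale = 12,
                              valid_od_range = c(0.012, 0.43))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  cal2 <- read_calibration(path)
  expect_equal(cal2$family, cal$family)
  expect_equal(cal2$theta, cal$theta, tolerance = 1e-14)
  o <- seq(0.013, 0.42, length.out = 20)
  expect_equal(inverse_dose(cal2, o), inverse_dose(cal, o),
               tolerance = 1e-12)
})
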