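two_level_pair <- function() {
  # two single-position measurements with known reconstructed doses under
  # the identity calibration: f^-1(o) = o
  tibble::tibble(
    measurement_id = c("a", "a", "b", "b"),
    level_id = c("A", "A", "B", "B"),
    k = c(1, 1, 2, 2),
    r_mm = c(20, 3, 20, 3),
    net_od = c(1.0, 0.9, 1.5, 1.8),
    region = c("gradient", "plateau", "gradient", "plateau"),
    reference_dose = c(NA, 1, NA, 2)
  )
}

test_that("pair enumeration excludes same-level pairs and counts 9N(N-1)/2", {
  for (n_levels in c(2L, 4L)) {
    m <- simulate_measurement_set(levels = p1_levels()[seq_len(n_levels)],
                                  reps = 3, noise = noise_free())
    expect_identical(nrow(enumerate_pairs(m)),
                     as.integer(9 * n_levels * (n_levels - 1) / 2))
  }
  one_level <- simulate_measurement_set(levels = 2, reps = 3,
                                        noise = noise_free())
  expect_error(enumerate_pairs(one_level), "two distinct dose levels")
  # brute-force cross-check at 4 levels: C(12,2) minus 12 same-level pairs
  expect_identical(nrow(enumerate_pairs(
    simulate_measurement_set(levels = c(1, 2, 5, 12), reps = 3,
                             noise = noise_free()))),
    as.integer(choose(12, 2) - 4 * choose(3, 2)))
})

test_that("pair cost reproduces the hand-evaluated single-position value", {
  m <- two_level_pair()
  cal <- calibration_function("polynomial", c(0, 1, 0, 0, 0),
                              valid_od_range = c(0.5, 2))
  pc <- pair_costs(m, cal, objective_config(r_lb = 15, r_ub = 27))
  # h^2 = (1*2)^-2 * (2*1.0 - 1*1.5)^2 = 0.25 * 0.25 = 0.0625 with
  # reconstructed doses f^-1(1.0) = 1.0 and f^-1(1.5) = 1.5
  expect_equal(pc$cost, 0.25 * (2 * 1.0 - 1 * 1.5)^2)
  expect_equal(pc$cost, 0.0625)
  # swapping the pair order leaves the cost unchanged (squared
  # antisymmetric difference)
  m2 <- m[c(3, 4, 1, 2), ]
  pc2 <- pair_costs(m2, cal, objective_config(r_lb = 15, r_ub = 27))
  expect_equal(pc2$cost, pc$cost)
})

test_that("the ratio cost vanishes at the generating parameters", {
  m <- simulate_measurement_set(levels = c(0.75, 12), reps = 1,
                                noise = noise_free())
  truth <- default_truth()
  cal <- calibration_function("bimolecular", truth$theta,
                              valid_od_range = range(m$net_od))
  expect_lt(cost_ratio(m, cal), 1e-20)
  cb <- total_cost(m, cal)
  expect_lt(sqrt(sum(cb$grad^2)), 1e-9)
})

test_that("chi_a scales exactly as c^-2 under uniform k scaling", {
  m <- simulate_measurement_set(levels = c(1, 3, 12), reps = 2,
                                noise = noise_spec(seed = 5))
  cal <- calibration_function("polynomial", c(0.01, 0.8, 0.4, -0.1, 0.05),
                              od_scale = max(m$net_od), dose_scale = 12,
                              valid_od_range = range(m$net_od))
  chi1 <- cost_ratio(m, cal)
  m2 <- dplyr::mutate(m, k = 2 * k,
                      reference_dose = 2 * reference_dose)
  chi2 <- cost_ratio(m2, cal)
  expect_equal(as.numeric(chi2), as.numeric(chi1) / 4, tolerance = 1e-12)
})

test_that("chi is invariant under permutation of measurement input order", {
  m <- simulate_measurement_set(levels = c(1, 3, 12), reps = 2,
                                noise = noise_spec(seed = 5))
  cal <- calibration_function("polynomial", c(0.01, 0.8, 0.4, -0.1, 0.05),
                              od_scale = max(m$net_od), dose_scale = 12,
                              valid_od_range = range(m$net_od))
  ids <- unique(m$measurement_id)
  set.seed(1)
  perm <- sample(ids)
  m2 <- dplyr::arrange(m, match(measurement_id, perm))
  expect_equal(as.numeric(cost_ratio(m2, cal)),
               as.numeric(cost_ratio(m, cal)), tolerance = 1e-12)
})

test_that("side objective anchors the highest level and w_s -> Inf pins it", {
  m <- simulate_measurement_set(levels = c(0.75, 12), reps = 3,
                                noise = noise_spec(seed = 2))
  truth <- default_truth()
  cal <- calibration_function("bimolecular", truth$theta,
                              valid_od_range = range(m$net_od))
  # exact calibration on noise-free data: chi_b = 0
  mf <- simulate_measurement_set(levels = c(0.75, 12), reps = 3,
                                 noise = noise_free())
  calf <- calibration_function("bimolecular", truth$theta,
                               valid_od_range = range(mf$net_od))
  expect_lt(as.numeric(cost_side(mf, calf)), 1e-18)

  # a huge side weight forces the fit through the highest-dose point
  fit <- fit_ratio_method(m, cfg = objective_config(w_s = 1e8),
                          fit_cfg = fit_config(family = "bimolecular",
                                               seed = 4, n_restarts = 5))
  tab <- measurement_table(m)
  anchor <- tab[tab$k == 12, ]
  res <- dose_residuals(fit$cal, anchor)
  expect_lt(abs(mean(res$residual_pct)), 1e-3)
})

test_that("total cost decomposes as chi = chi_a + chi_b with bookkeeping", {
  m <- noisy_dataset()
  cal <- calibration_function("polynomial", c(0.02, 0.7, 0.3, 0, 0.05),
                              od_scale = max(m$net_od), dose_scale = 12,
                              valid_od_range = range(m$net_od))
  cb <- total_cost(m, cal)
  expect_identical(cb$chi, cb$chi_a + cb$chi_b)
  expect_identical(cb$n_pairs, as.integer(9 * 12 * 11 / 2))
  expect_equal(cb$w_b, 10 * cb$n_positions * cb$n_pairs / 3)
  expect_equal(as.numeric(cost_ratio(m, cal)), cb$chi_a, tolerance = 1e-12)
  expect_equal(as.numeric(cost_side(m, cal)), cb$chi_b, tolerance = 1e-12)
})

test_that("analytic cost gradient matches finite differences", {
  set.seed(11)
  cfg <- objective_config()
  for (family in c("polynomial", "bimolecular")) {
    m <- simulate_measurement_set(levels = c(0.75, 3, 12), reps = 2,
                                  noise = noise_spec(seed = 8))
    od_scale <- max(m$net_od)
    chi_f <- chi_of_theta(m, family, cfg, od_scale, 12)
    grad_f <- grad_of_theta(m, family, cfg, od_scale, 12)
    for (i in 1:10) {
      th <- if (family == "bimolecular") {
        c(1 + abs(rnorm(1, 0.3, 0.2)), abs(rnorm(1, 0.5, 0.2)) + 0.1,
          rnorm(1, 1, 0.1))
      } else {
        rnorm(5, 0, 0.3)
      }
      g <- grad_f(th)
      fd <- fd_gradient(chi_f, th)
      expect_lt(max(abs(g - fd)), 1e-5 * (sqrt(sum(fd^2)) + 1e-6))
    }
  }
})

test_that("mismatched radius grids are rejected", {
  m <- two_level_pair()
  m$r_mm[3] <- 21
  cal <- calibration_function("polynomial", c(0, 1, 0, 0, 0),
                              valid_od_range = c(0.5, 2))
  expect_error(pair_costs(m, cal, objective_config()), "common radius grid")
})

test_that("measurement sets survive a CSV round trip", {
  m <- simulate_measurement_set(levels = c(1, 12), reps = 2,
                                noise = noise_spec(seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(m, path)
  m2 <- read_measurements(path)
  expect_equal(m2$net_od, m$net_od, tolerance = 1e-12)
  expect_identical(m2$level_id, m$level_id)
  expect_true(file.exists(sub("\\.csv$", ".json", path)))
})
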