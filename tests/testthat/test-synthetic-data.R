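test_that("the relative dose profile is normalized, monotone and linear in
          the falloff window", {
  prof <- make_dose_profile()
  expect_equal(prof$dose_rel[1], 1)
  expect_true(all(diff(prof$dose_rel) <= 1e-12))
  spec <- phantom_spec()
  mid <- (spec$falloff_start + spec$falloff_end) / 2
  expect_equal(filmratio:::relative_dose(spec, mid),
               (spec$falloff_hi + spec$falloff_lo) / 2, tolerance = 1e-12)
  expect_true(all(prof$excluded == (prof$dose_rel < 0.05)))
  expect_true(all(prof$dose_rel[prof$r_mm <= 14.9] == 1))
})

test_that("measurement simulation is seeded and exact when noise-free", {
  m1 <- simulate_measurement_set(levels = c(1, 12), reps = 2,
                                 noise = noise_spec(seed = 7))
  m2 <- simulate_measurement_set(levels = c(1, 12), reps = 2,
                                 noise = noise_spec(seed = 7))
  expect_identical(m1$net_od, m2$net_od)
  m3 <- simulate_measurement_set(levels = c(1, 12), reps = 2,
                                 noise = noise_spec(seed = 8))
  expect_false(identical(m1$net_od, m3$net_od))

  nf <- simulate_measurement_set(levels = c(1, 12), reps = 1,
                                 noise = noise_free())
  truth <- default_truth()
  grad <- nf[nf$region == "gradient" & nf$k == 12, ]
  o_expect <- forward_od(truth,
                         12 * filmratio:::relative_dose(phantom_spec(),
                                                        grad$r_mm))
  expect_equal(grad$net_od, o_expect, tolerance = 1e-12)
})

test_that("plateau repeatability reflects the inter-film noise scale", {
  m <- simulate_measurement_set(levels = 2, reps = 30,
                                noise = noise_spec(seed = 12))
  tab <- measurement_table(m)
  cv <- sd(tab$plateau_od) / mean(tab$plateau_od)
  expect_gt(cv, 0.005 / 3)
  expect_lt(cv, 0.005 * 3)
})

test_that("generator and fit close the loop on noise-free data", {
  full <- nf_dataset()
  train <- full[full$level_id %in% c("L02", "L07", "L12"), ]
  fit <- fit_ratio_method(train,
                          fit_cfg = fit_config(family = "bimolecular",
                                               seed = 2, n_restarts = 5))
  res <- dose_residuals(fit$cal, measurement_table(full))
  expect_lt(max(abs(res$residual_pct)) / 100, 1e-6)
})

test_that("per-bin profile noise shrinks as 1/sqrt(count) with radius", {
  # many repetitions at one level with only the absolute pixel-noise
  # component: the across-repetition spread of each bin estimates the
  # per-bin noise, which must scale with the annulus pixel count
  m <- simulate_measurement_set(levels = 2, reps = 60,
                                noise = noise_spec(0, 0.004, 0, seed = 3))
  spread <- m |>
    dplyr::group_by(r_mm, count) |>
    dplyr::summarise(sd = sd(net_od), .groups = "drop")
  fitlm <- lm(log(sd) ~ log(count), data = spread)
  expect_equal(unname(coef(fitlm)[2]), -0.5, tolerance = 0.1)
})

test_that("the four-field image matches its manifest and single-field
          renders", {
  img <- make_multifield_image(noise = noise_free())
  expect_identical(nrow(img$manifest), 4L)
  expect_identical(img$manifest$level, c(4, 12, 2, 0.75))
  sp <- diff(sort(unique(c(img$manifest$cx_mm))))
  expect_equal(sp, 120)
  # cropping a quadrant reproduces the single-field render of its level
  full <- net_optical_density(img$before, img$after,
                              pixel_size = img$pixel_size)
  f <- 2  # 12 Gy quadrant
  px <- img$pixel_size
  cx <- img$manifest$cx_mm[f]; cy <- img$manifest$cy_mm[f]
  cols <- which(abs((seq_len(ncol(full$values)) - 1) * px - cx) <= 33)
  rows <- which(abs((seq_len(nrow(full$values)) - 1) * px - cy) <= 33)
  sub <- od_map(full$values[rows, cols], pixel_size = px)
  ctr <- c(cx - (min(cols) - 1) * px, cy - (min(rows) - 1) * px)
  prof <- radial_rebin(sub, ctr, r_max = 28)
  truth_o <- forward_od(default_truth(),
                        pmax(12 * filmratio:::relative_dose(phantom_spec(),
                                                            prof$r_mm),
                             1e-9))
  expect_lt(max(abs(prof$od_mean - truth_o)), 0.002)
})

test_that("overlapping fields above the cutoff are rejected", {
  expect_error(make_multifield_image(spacing = 40, noise = noise_free()),
               "overlap")
})

test_that("uniform cross-scatter biases the lowest plateau by its nominal
          fraction before refitting", {
  img0 <- make_multifield_image(noise = noise_free())
  img1 <- make_multifield_image(noise = noise_free(),
                                scatter_fraction = 0.01)
  full0 <- net_optical_density(img0$before, img0$after,
                               pixel_size = img0$pixel_size)
  full1 <- net_optical_density(img1$before, img1$after,
                               pixel_size = img1$pixel_size)
  truth <- default_truth()
  f <- 4  # 0.75 Gy quadrant
  px <- img0$pixel_size
  cx <- img0$manifest$cx_mm[f]; cy <- img0$manifest$cy_mm[f]
  cols <- which(abs((seq_len(ncol(full0$values)) - 1) * px - cx) <= 7)
  rows <- which(abs((seq_len(nrow(full0$values)) - 1) * px - cy) <= 7)
  d0 <- mean(inverse_dose(truth, full0$values[rows, cols],
                          allow_outside = TRUE))
  d1 <- mean(inverse_dose(truth, full1$values[rows, cols],
                          allow_outside = TRUE))
  expect_equal((d1 - d0) / d0, 0.01 * 0.75 / 0.75, tolerance = 0.15)
})
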