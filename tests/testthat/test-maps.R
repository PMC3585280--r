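# tiny synthetic series: linear warming with a vertical gradient
make_tiny_series <- function() {
  dims <- c(6, 5, 3); times <- seq(0, 30, by = 5)
  maps <- array(NA_real_, c(dims, length(times)))
  for (it in seq_along(times))
    maps[, , , it] <- 4 + 0.2 * times[it] + 0.1 * (1:6)
  temperature_series(maps, times, 4, 21.25, voxel_mm = c(2, 2, 5))
}

test_that("mean temperature respects the mask contract", {
  ser <- make_tiny_series()
  mask <- array(TRUE, dim(ser$maps)[1:3])
  uniform <- temperature_series(array(5, c(2, 2, 1, 3)), c(0, 3, 6), 4, 21,
                                voxel_mm = c(1, 1, 1))
  expect_equal(mean_temperature(uniform, array(TRUE, c(2, 2, 1))), rep(5, 3))

  two <- temperature_series(array(c(4, 6, 99, 99), c(2, 2, 1, 1)), 0, 4, 21,
                            voxel_mm = c(1, 1, 1))
  m2 <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  expect_equal(mean_temperature(two, m2), 5)
  expect_error(mean_temperature(ser, array(FALSE, dim(ser$maps)[1:3])),
               "empty")
})

test_that("geometry summary computes volumes and central-slice extents", {
  mask <- array(TRUE, c(10, 10, 7))
  g <- geometry_summary(mask, mask, voxel_mm = c(1.1, 1.1, 7.5))
  expect_equal(g$rbc_volume_ml, 10 * 10 * 7 * 1.1 * 1.1 * 7.5 / 1000)
  expect_equal(g$height_cm, 10 * 1.1 / 10)
  expect_equal(g$width_cm, 10 * 1.1 / 10)
  expect_equal(g$wh_ratio, 1)
  expect_equal(unname(g$center["slice"]), 4)
  expect_error(geometry_summary(array(FALSE, c(3, 3, 3)),
                                voxel_mm = c(1, 1, 1)), "empty")

  # synthetic default phantom hits the target RBC volume within 2%
  spec <- pouch_phantom_spec()
  ph <- make_pouch_phantom(spec)
  g2 <- geometry_summary(ph$rbc_mask, ph$pouch_mask, spec$voxel_mm)
  expect_rel_error(g2$rbc_volume_ml, 255, 0.02)
  expect_rel_error(g2$pouch_volume_ml, 287, 0.02)
  expect_lte(g2$rbc_volume_ml, g2$pouch_volume_ml)
  expect_rel_error(g2$height_cm, 13.1, 0.05)
  expect_rel_error(g2$width_cm, 3.4, 0.05)
})

test_that("volume fractions count voxels above threshold", {
  ser <- make_tiny_series()
  mask <- array(TRUE, dim(ser$maps)[1:3])
  vf_all <- volume_fraction(ser, mask, 0)
  expect_true(all(vf_all$fractions == 1))
  vf_none <- volume_fraction(ser, mask, 100)
  expect_true(all(vf_none$fractions == 0))

  # exactly half the voxels above threshold
  half <- array(rep(c(2, 8), each = 4), c(2, 2, 2, 1))
  ser_h <- temperature_series(half, 0, 1, 21, voxel_mm = c(1, 1, 1))
  vf_h <- volume_fraction(ser_h, array(TRUE, c(2, 2, 2)), 5)
  expect_equal(vf_h$fractions, 0.5)

  # non-increasing in threshold, non-decreasing in time for warming fields
  f10 <- volume_fraction(ser, mask, 6)$fractions
  f12 <- volume_fraction(ser, mask, 8)$fractions
  expect_true(all(f12 <= f10))
  expect_true(all(diff(f10) >= 0))
})

test_that("tangent crossing times match closed forms", {
  # exact linear ramp: the tangent is the line itself
  t <- seq(0, 40, by = 0.5)
  ramp <- pmin(pmax((t - 10) / 20, 0), 1)
  cur <- structure(list(threshold_T = 10, times = t, fractions = ramp),
                   class = "volume_fraction_curve")
  cr <- crossing_times(cur)
  expect_equal(unname(cr["t_surface_reach"]), 10, tolerance = 0.05)
  expect_equal(unname(cr["t_core_reach"]), 30, tolerance = 0.05)

  # logistic: slope 1/40 at half maximum -> crossings at 30 and 70
  t2 <- seq(0, 100, by = 0.5)
  lg <- 1 / (1 + exp(-(t2 - 50) / 10))
  cur2 <- structure(list(threshold_T = 10, times = t2, fractions = lg),
                    class = "volume_fraction_curve")
  cr2 <- crossing_times(cur2)
  expect_equal(unname(cr2["t_surface_reach"]), 30, tolerance = 0.05)
  expect_equal(unname(cr2["t_core_reach"]), 70, tolerance = 0.05)

  # saturating below 0.5: reported as skipped, not an error
  cur3 <- structure(list(threshold_T = 10, times = t2,
                         fractions = 0.4 * lg), class = "volume_fraction_curve")
  expect_message(res <- crossing_times(cur3), "skipped")
  expect_null(res)
})

test_that("surface/core extraction on a simulation is physically ordered", {
  rep <- default_unit_report()
  cur <- rep$curves
  # tangent geometry: surface reaches a threshold before the core does
  common <- intersect(cur$surface$T_celsius, cur$core$T_celsius)
  expect_gt(length(common), 3)
  for (T in common) {
    expect_lt(cur$surface$t_min[cur$surface$T_celsius == T],
              cur$core$t_min[cur$core$T_celsius == T])
  }
  # interpolated to a common time grid: T_surface >= T_mean >= T_core
  tg <- seq(max(min(cur$surface$t_min), min(cur$core$t_min), min(cur$times)),
            min(max(cur$surface$t_min), max(cur$core$t_min), max(cur$times)),
            length.out = 15)
  Ts <- stats::approx(cur$surface$t_min, cur$surface$T_celsius, tg)$y
  Tc <- stats::approx(cur$core$t_min, cur$core$T_celsius, tg)$y
  Tm <- stats::approx(cur$times, cur$t_mean, tg)$y
  expect_true(all(Ts >= Tm - 0.25))
  expect_true(all(Tm >= Tc - 0.25))

  # model fits of the extracted curves describe them well
  expect_gt(rep$fit$r2_mean, 0.999)
  expect_gt(rep$fit$r2_surface, 0.98)
  expect_gt(rep$fit$r2_core, 0.99)
})

test_that("extraction errors and skips follow the preconditions", {
  ser <- make_tiny_series()
  mask <- array(TRUE, dim(ser$maps)[1:3])
  short <- temperature_series(ser$maps[, , , 1:4, drop = FALSE],
                              ser$times[1:4], 4, 21.25, c(2, 2, 5))
  expect_error(surface_core_curves(short, mask), "5 time points")
  narrow <- temperature_series(ser$maps, ser$times, 4, 6.5, c(2, 2, 5))
  expect_error(surface_core_curves(narrow, mask), "thresholds")
})

test_that("thermal core localization and tie-breaking", {
  # uniform field: centroid voxel wins the tie-break
  uni <- temperature_series(array(5, c(5, 5, 3, 2)), c(0, 3), 4, 21,
                            voxel_mm = c(1, 1, 1))
  mask <- array(TRUE, c(5, 5, 3))
  expect_equal(thermal_core_position(uni, mask),
               c(row = 3, col = 3, slice = 2))

  # unique coldest voxel is found
  maps <- array(10, c(5, 5, 3, 2)); maps[4, 2, 3, ] <- 7
  ser <- temperature_series(maps, c(0, 3), 4, 21, voxel_mm = c(1, 1, 1))
  expect_equal(thermal_core_position(ser, mask),
               c(row = 4, col = 2, slice = 3))

  # diffusion phantom: with the SAGM layer warming like RBC, the coldest
  # region sits at the pouch centre, vertically displaced from the centre of
  # the RBC volume toward the SAGM boundary (sign check only)
  rep <- default_unit_report()
  spec <- pouch_phantom_spec()
  ph <- make_pouch_phantom(spec)
  rbc_centre_row <- mean(range(which(apply(ph$rbc_mask, 1, any))))
  pouch_centre_row <- mean(range(which(apply(ph$pouch_mask, 1, any))))
  expect_lt(rep$core_position[["row"]], rbc_centre_row)
  expect_lt(abs(rep$core_position[["row"]] - pouch_centre_row), 4)
})
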