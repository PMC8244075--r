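# Scaled-down walker counts keep the suite fast; the Monte Carlo standard
# error is reported by the simulator and used in the assertions.

test_that("free diffusion calibration: ln(S/S0) = -b D0 without boundaries", {
  ens <- walker_ensemble(n_walkers = 2000, seed = 11)
  # effectively unbounded cylinder, several waveforms and orientations
  sub <- cylinder_substrate(100, 0.5, axis = c(0, 0, 1))
  for (w in list(scale_waveform_to_b(stejskal_tanner_waveform(8, 20, 40, c(0, 0, 1)), 1),
                 scale_waveform_to_b(bipolar_press_waveform(45, 59, 14, 40, c(0, 0, 1)), 2),
                 scale_waveform_to_b(bipolar_press_waveform(53, 65, 12, 40, c(0, 0, 1)), 1))) {
    r <- simulate_restricted_signal(sub, w, ens)
    expect_lt(abs(r$S_ratio - exp(-r$b * 0.5)), 3 * r$SE + 1e-4)
  }
})

test_that("axial mean-squared displacement grows as 2 D0 t", {
  w <- stejskal_tanner_waveform(5, 10, 30, c(1, 0, 0))
  s <- simulate_restricted_signal(cylinder_substrate(1, 0.5, c(0, 0, 1)), w,
                                  walker_ensemble(n_walkers = 4e4, seed = 3))
  expect_lt(max(abs(s$msd_z / (2 * 0.5 * s$msd_t) - 1)), 0.05)
  # final time within 2%
  nf <- length(s$msd_z)
  expect_lt(abs(s$msd_z[nf] / (2 * 0.5 * s$msd_t[nf]) - 1), 0.02)
})

test_that("vanishing restrictions kill perpendicular attenuation", {
  w <- scale_waveform_to_b(bipolar_press_waveform(53, 65, 12, 40, c(1, 0, 0)),
                           14.5)
  expect_warning(
    s <- simulate_restricted_signal(cylinder_substrate(0.1, 0.5, c(0, 0, 1)), w,
                                    walker_ensemble(2000, seed = 4)),
    "under-resolved")
  expect_lt(1 - s$S_ratio, 1e-4)
})

test_that("restricted perpendicular signal matches the Gaussian-phase oracle", {
  w <- scale_waveform_to_b(bipolar_press_waveform(53, 65, 12, 40, c(1, 0, 0)),
                           14.5)
  sub <- cylinder_substrate(1, 0.5, axis = c(0, 0, 1))
  s <- simulate_restricted_signal(sub, w, walker_ensemble(4000, seed = 5))
  dt_mc <- apparent_transverse_diffusivity(s$S_ratio, s$b)
  dt_gpd <- -gpd_cylinder_lnS(w, 1, 0.5) / s$b
  expect_lt(abs(dt_mc - dt_gpd) / dt_gpd, 0.15)
})

test_that("results are invariant under joint rotation of substrate and gradient", {
  w0 <- scale_waveform_to_b(stejskal_tanner_waveform(10, 20, 40, c(1, 0, 0)), 3)
  base <- simulate_restricted_signal(cylinder_substrate(2, 0.5, c(0, 0, 1)),
                                     w0, walker_ensemble(2000, seed = 6))
  Rots <- uniform_rotations(3, seed = 12)
  for (m in 1:3) {
    R <- Rots[, , m]
    wr <- scale_waveform_to_b(
      stejskal_tanner_waveform(10, 20, 40, as.numeric(R %*% c(1, 0, 0))), 3)
    rot <- simulate_restricted_signal(
      cylinder_substrate(2, 0.5, as.numeric(R %*% c(0, 0, 1))),
      wr, walker_ensemble(2000, seed = 6))
    expect_lt(abs(rot$S_ratio - base$S_ratio), 3 * (rot$SE + base$SE) + 1e-4)
  }
})

test_that("halving the time step leaves the attenuation unchanged", {
  w <- scale_waveform_to_b(stejskal_tanner_waveform(10, 20, 40, c(1, 0, 0)), 5)
  sub <- cylinder_substrate(1, 0.5, c(0, 0, 1))
  a <- simulate_restricted_signal(sub, w, walker_ensemble(4000, dt = 0.0064, seed = 7))
  b <- simulate_restricted_signal(sub, w, walker_ensemble(4000, dt = 0.0032, seed = 7))
  expect_lt(abs(a$S_ratio - b$S_ratio), a$SE + b$SE + 1e-4)
})

test_that("apparent transverse diffusivity readout is exact for exponentials", {
  expect_equal(apparent_transverse_diffusivity(1, 5), 0)
  expect_equal(apparent_transverse_diffusivity(exp(-5 * 0.12), 5), 0.12)
  expect_error(apparent_transverse_diffusivity(0, 5), "positive")
  expect_error(apparent_transverse_diffusivity(0.5, 0), "positive")
})

test_that("deviation from the matched stick grows with radius and at lower D0", {
  w <- scale_waveform_to_b(bipolar_press_waveform(53, 65, 12, 40, c(1, 0, 0)),
                           14.5)
  ens <- walker_ensemble(1500, seed = 8)
  radii <- c(0.5, 1, 1.5, 2, 3)
  dev <- vapply(radii, function(r)
    powder_stick_deviation(cylinder_substrate(r, 0.5), w, ens,
                           n_dirs = 16)$deviation, 1)
  # monotone trend over the sweep (allowing MC noise at the small end)
  expect_true(all(diff(dev[-1]) > 0))
  expect_gt(dev[5], dev[1])
  expect_lt(dev[1], 0.01)
  # lower intrinsic diffusivity -> larger deviation at fixed radius
  d_lo <- powder_stick_deviation(cylinder_substrate(2, 0.25), w, ens,
                                 n_dirs = 16)$deviation
  d_hi <- powder_stick_deviation(cylinder_substrate(2, 2), w, ens,
                                 n_dirs = 16)$deviation
  expect_gt(d_lo, d_hi)
})
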