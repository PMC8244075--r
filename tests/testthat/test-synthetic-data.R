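test_that("fiber orientation sampling matches the prescribed angular spread", {
  # perfect alignment
  f0 <- sample_fiber_orientations(0, 100, seed = 1)
  expect_equal(abs(f0[, 3]), rep(1, 100))
  # magic angle: isotropic second moment
  fm <- sample_fiber_orientations(54.7356, 1e5, seed = 2)
  expect_lt(abs(mean(fm[, 3]^2) - 1 / 3), 0.01)
  # aligned-substrate spread
  f31 <- sample_fiber_orientations(31, 1e5, seed = 3)
  expect_lt(abs(mean(f31[, 3]^2) - cos(31 * pi / 180)^2), 0.005)
  # girdle side of the magic angle
  f70 <- sample_fiber_orientations(70, 1e5, seed = 4)
  expect_lt(abs(mean(f70[, 3]^2) - cos(70 * pi / 180)^2), 0.005)
  # mean-axis rotation preserves the spread
  fr <- sample_fiber_orientations(31, 1e5, seed = 3, mean_axis = c(1, 0, 0))
  expect_lt(abs(mean(fr[, 1]^2) - cos(31 * pi / 180)^2), 0.005)
  expect_error(sample_fiber_orientations(95, 10), "degrees")
})

test_that("generated datasets follow the dispersed-compartment forward model", {
  pre <- scenario_preset("PWM")
  pre$SNR <- Inf
  sc <- preset_scheme(pre, seed = 0)
  # full dispersion: every direction sees the analytic powder value
  pre$theta <- "uniform"
  ds <- generate_dataset(pre, sc, K = 20000, seed = 5)
  ana <- stick_powder_signal(max(sc$b_values), 1, 0.5)
  expect_lt(max(abs(ds$amplitudes[, 5, 1] - ana)), 4 / sqrt(20000))
  # perfect alignment along a gradient direction
  pre$theta <- 0
  e1 <- sc$directions[1, ]
  ds0 <- generate_dataset(pre, sc, K = 8, seed = 6, mean_axis = e1)
  b <- sc$b_values
  expect_equal(ds0$amplitudes[1, , 1], exp(-b * 0.5), tolerance = 1e-12)
  # a direction nearly perpendicular to the fibers keeps full signal
  perp_idx <- which.min(abs(as.numeric(sc$directions %*% e1)))
  c2 <- as.numeric(sc$directions[perp_idx, ] %*% e1)^2
  expect_equal(ds0$amplitudes[perp_idx, , 1], exp(-b * 0.5 * c2),
               tolerance = 1e-12)
  # seeded reproducibility
  expect_identical(generate_dataset(scenario_preset("CC"), sc, seed = 9)$amplitudes,
                   generate_dataset(scenario_preset("CC"), sc, seed = 9)$amplitudes)
})

test_that("repetition noise scales so the averaged amplitude has sd S0/SNR", {
  sc <- gradient_scheme(diag(3), c(0, 5), n_reps = 12)
  pre <- list(theta = "uniform", D_L = 0, D_T = 0, S0 = 1, SNR = 40)
  devs <- vapply(1:300, function(s) {
    ds <- generate_dataset(pre, sc, K = 4, seed = s)
    mean(ds$amplitudes[1, 1, ]) - 1
  }, 1)
  expect_lt(abs(stats::sd(devs) - 1 / 40) / (1 / 40), 0.15)
})

test_that("noise-free pipeline recovers D_L regardless of orientation dispersion", {
  for (th in list(31, 46, "uniform")) {
    pre <- scenario_preset("PWM")
    pre$SNR <- Inf
    pre$theta <- th
    ds <- generate_dataset(pre, preset_scheme(pre, seed = 0), seed = 4)
    fit <- fit_powder_model(powder_average(ds), "stick")
    expect_lt(abs(fit$D_L - 0.5) / 0.5, 0.01)
  }
  # perfectly aligned substrates carry rotational variance from the
  # 12-direction sampling at high b; the orientation-averaged estimate
  # still recovers the truth
  pre <- scenario_preset("PWM")
  pre$SNR <- Inf
  pre$theta <- 0
  sc <- preset_scheme(pre, seed = 0)
  axes <- uniform_rotations(96, seed = 13)
  dls <- vapply(1:96, function(m) {
    ds <- generate_dataset(pre, sc, K = 16, seed = m,
                           mean_axis = as.numeric(axes[, , m] %*% c(0, 0, 1)))
    fit_powder_model(powder_average(ds), "stick")$D_L
  }, 1)
  expect_lt(abs(mean(dls) - 0.5) / 0.5, 0.01)
})

test_that("macroscopic pipeline recovers the angular spread within 2 degrees", {
  for (th in c(20, 35, 50)) {
    pre <- scenario_preset("PWM")
    pre$SNR <- Inf
    pre$theta <- th
    ds <- generate_dataset(pre, preset_scheme(pre, seed = 0), seed = 4)
    res <- suppressWarnings(run_full_pipeline(ds))
    expect_lt(abs(res$theta_deg - th), 2)
  }
})

test_that("aligned substrates show larger directional spread than dispersed ones", {
  # high alignment (CC-like) versus dispersed (PWM-like) at their max b
  spread <- function(preset_name, seed) {
    pre <- scenario_preset(preset_name)
    pre$SNR <- Inf
    ds <- generate_dataset(pre, preset_scheme(pre, seed = 0), seed = seed)
    a <- ds$amplitudes[, 5, 1]
    stats::sd(a) / mean(a)
  }
  wins <- vapply(1:20, function(s) spread("CC", s) > spread("PWM", s),
                 logical(1))
  expect_true(all(wins))
})

test_that("null datasets yield near-zero fitted diffusivities", {
  sc <- preset_scheme(scenario_preset("PWM"), seed = 0)
  nd <- generate_null_dataset(sc, S0 = 1, SNR = Inf, seed = 1)
  expect_true(all(nd$amplitudes == 1))
  # with noise: powder-point sd is S0/(SNR sqrt(n_dir)); fitted MD stays
  # within a few multiples of that sensitivity scale
  dls <- vapply(1:20, function(s) {
    nd <- generate_null_dataset(sc, S0 = 1, SNR = 50, seed = s)
    suppressWarnings(fit_powder_model(powder_average(nd), "stick")$D_L)
  }, 1)
  expect_true(all(dls < 0.01))
  expect_identical(generate_null_dataset(sc, 1, 50, seed = 3)$amplitudes,
                   generate_null_dataset(sc, 1, 50, seed = 3)$amplitudes)
})
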