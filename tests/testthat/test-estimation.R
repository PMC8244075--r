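make_scheme <- function(n_dir = 12, b_max = 14.5, n_b = 5, n_reps = 1,
                        seed = 0) {
  electrostatic_directions(n_dir, seed = seed,
                           b_values = b_max * (seq(0, n_b - 1) / (n_b - 1))^2,
                           n_reps = n_reps)
}

test_that("powder averaging is the unweighted direction mean after repetition averaging", {
  sc <- make_scheme(n_dir = 6, n_reps = 3)
  # constant amplitudes pass through unchanged
  ds <- directional_dataset(sc, array(2.5, c(6, 5, 3)))
  pd <- powder_average(ds)
  expect_equal(pd$amplitude, rep(2.5, 5))
  expect_equal(pd$sd, rep(0, 5))
  # discrete forward model: the average equals the direction mean exactly
  axis <- c(0, 0, 1)
  c2 <- as.numeric((sc$directions %*% axis)^2)
  amp <- vapply(sc$b_values, function(b) exp(-b * 0.5 * c2), numeric(6))
  ds2 <- directional_dataset(sc, array(rep(amp, 3), c(6, 5, 3)))
  expect_equal(powder_average(ds2)$amplitude, colMeans(amp))
  # repetitions averaged first: unbalanced rep noise cancels in the mean
  amp3 <- array(rep(amp, 3), c(6, 5, 3))
  amp3[, , 1] <- amp3[, , 1] + 0.1
  amp3[, , 2] <- amp3[, , 2] - 0.1
  ds3 <- suppressWarnings(directional_dataset(sc, amp3))
  expect_equal(powder_average(ds3)$amplitude, colMeans(amp))
})

test_that("constrained fits recover exact-model data to machine tolerance", {
  b <- c(0, 2, 4, 6, 9.4)
  fs <- fit_powder_model(powder_decay(b, stick_powder_signal(b, 1, 0.5)),
                         "stick")
  expect_lt(abs(fs$D_L - 0.5) / 0.5, 1e-6)
  expect_equal(fs$MD, fs$D_L / 3)
  ft <- fit_powder_model(powder_decay(b, tensor_powder_signal(b, 1, 0.5, 0.05)),
                         "tensor")
  expect_lt(abs(ft$D_L - 0.5) / 0.5, 1e-6)
  expect_lt(abs(ft$D_T - 0.05) / 0.05, 1e-6)
  expect_true(ft$converged)
  expect_true(ft$D_L >= ft$D_T && ft$D_T >= 0)
  # S0 is a fitted parameter, not pinned to the b = 0 point
  noisy0 <- stick_powder_signal(b, 1, 0.5) + c(0.01, 0, 0, 0, 0)
  f0 <- fit_powder_model(powder_decay(b, noisy0), "stick")
  expect_lt(f0$S0, 1.01)
  expect_error(fit_powder_model(powder_decay(0, 1), "stick"), "at least 2")
  expect_error(fit_powder_model(powder_decay(c(0, 5), c(1, 0.5)), "tensor"),
               "at least 3")
})

test_that("two-point stick design has the exact constrained solution", {
  # interior: interpolates both points
  f <- fit_powder_model(powder_decay(c(0, 4.57),
                                     c(1.02, stick_powder_signal(4.57, 1.02, 0.5))),
                        "stick")
  expect_equal(f$S0, 1.02)
  expect_equal(f$D_L, 0.5, tolerance = 1e-9)
  # boundary: no attenuation -> D_L = 0, S0 the mean
  f0 <- fit_powder_model(powder_decay(c(0, 4.57), c(0.98, 1.02)), "stick")
  expect_equal(f0$D_L, 0)
  expect_equal(f0$S0, 1.0)
  # non-physical point flagged, not silently absorbed
  fneg <- fit_powder_model(powder_decay(c(0, 4.57), c(1, -0.01)), "stick")
  expect_false(fneg$converged)
})

test_that("asymptote rescaling flags the high-b regime of stick data", {
  b <- c(0, 1, 2, 4.57, 9.14, 18.28, 36.56)  # bDL up to ~18
  dec <- powder_decay(b, stick_powder_signal(b, 1, 0.5))
  fit <- fit_powder_model(dec, "stick")
  tab <- asymptote_check(dec, fit)
  expect_false(tab$asymptotic[1])            # b = 0 excluded
  hi <- tab$asymptotic
  expect_true(all(tab$inv_sqrt_bDL[hi] < 0.5))
  # on the asymptote within 0.5% in the flagged regime
  expect_true(all(abs(tab$deviation[hi]) / tab$asymptote[hi] < 0.005))
  # transverse diffusivity pulls the curve below the asymptote
  dec_t <- powder_decay(b, tensor_powder_signal(b, 1, 0.5, 0.05))
  tab_t <- asymptote_check(dec_t, fit)
  expect_true(all(tab_t$deviation[tab_t$b >= 9.14] < 0))
})

test_that("gamma decay fit returns the initial-slope diffusivity", {
  b <- 14.5 * (0:4 / 4)^2
  # monoexponential limit
  g <- directional_adc_gamma(b, exp(-0.3 * b))
  expect_lt(abs(g$mu - 0.3) / 0.3, 1e-6)
  expect_lt(g$var, 1e-6)
  # stick powder data at low b: initial slope D_L/3
  bl <- 0.3 * (0:4 / 4)^2  # b_max * D_L = 0.3 for D_L = 1
  gl <- directional_adc_gamma(bl, stick_powder_signal(bl, 1, 1))
  expect_lt(abs(gl$mu - 1 / 3) / (1 / 3), 0.01)
  # two-exponential mixture: initial slope is the mixture mean
  gm <- directional_adc_gamma(b, 0.5 * exp(-0.2 * b) + 0.5 * exp(-0.8 * b))
  expect_lt(abs(gm$mu - 0.5), 0.01)
  expect_error(directional_adc_gamma(c(0, 5), c(1, 0.5)), "at least 3")
})

test_that("macroscopic tensor is recovered from directional diffusivities", {
  sc <- make_scheme(12)
  D <- matrix(c(0.40, 0.02, 0.01,
                0.02, 0.12, 0.03,
                0.01, 0.03, 0.09), 3, 3)
  D_i <- rowSums((sc$directions %*% D) * sc$directions)
  mt <- solve_macro_tensor(D_i, sc)
  expect_lt(max(abs(mt$tensor - D)), 1e-10)
  expect_equal(mt$MD, mean(eigen(D)$values))
  # printed-eigenvalue arithmetic
  ev <- c(0.42, 0.08, 0.08)
  md <- mean(ev)
  fa <- sqrt(1.5 * sum((ev - md)^2) / sum(ev^2))
  expect_equal(round(fa, 2), 0.78)
  # isotropic input
  iso <- solve_macro_tensor(rep(0.3, 12), sc)
  expect_equal(iso$FA, 0, tolerance = 1e-12)
  expect_equal(iso$MD, 0.3, tolerance = 1e-12)
  # rank deficiency: coplanar directions cannot determine 6 components
  th <- seq(0, pi, length.out = 8)[-8]
  plane <- cbind(cos(th), sin(th), 0)
  expect_error(solve_macro_tensor(rep(0.3, 7), plane), "rank-deficient")
})

test_that("dispersion angle reproduces the printed macro-tensor summaries", {
  expect_equal(round(dispersion_angle(0.19, 0.42)), 31)
  expect_equal(round(dispersion_angle(0.20, 0.29)), 46)
  # isotropic tensor: magic angle
  expect_equal(dispersion_angle(0.2, 0.2), 54.7356, tolerance = 1e-4)
  expect_error(dispersion_angle(0.1, 0.4), "inconsistent")
  expect_error(dispersion_angle(0.2, 0.1), "at least")
})

test_that("region comparison is a symmetric two-tailed t-test per metric", {
  set.seed(7)
  A <- data.frame(D_L = rnorm(5, 0.5, 0.05), MD = rnorm(5, 0.17, 0.01))
  expect_equal(region_compare(A, A)$p, c(1, 1))
  B <- data.frame(D_L = rnorm(5, 0.9, 0.05), MD = rnorm(5, 0.17, 0.01))
  ab <- region_compare(A, B)
  ba <- region_compare(B, A)
  expect_equal(ab$p, ba$p)
  expect_true(ab$significant[ab$metric == "D_L"])
  # power: groups 5 SD apart are detected in >= 99% of draws
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    a <- rnorm(5, 0, 1)
    b <- rnorm(5, 5, 1)
    region_compare(data.frame(m = a), data.frame(m = b))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
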