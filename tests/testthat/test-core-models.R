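test_that("stick powder signal matches its closed form and limits", {
  expect_equal(stick_powder_signal(0, 1, 0.5), 1.0)
  # frozen from the closed form; cross-checked against the spherical
  # average below
  expect_equal(stick_powder_signal(4.57, 1, 0.5), 0.5672, tolerance = 1e-4)
  orc <- spherical_average_oracle(4.57, 0.5, 0, n = 1e6, seed = 11)
  expect_lt(abs(stick_powder_signal(4.57, 1, 0.5) - orc$mean), 3 * orc$se)
  # high-b asymptote S0 (sqrt(pi)/2) (bDL)^(-1/2): erf(5) ~ 1
  expect_equal(stick_powder_signal(50, 1, 0.5), sqrt(pi) / 2 / 5,
               tolerance = 1e-10)
  # continuity through the series switch
  x <- c(1e-9, 1e-7, 9.9e-7, 1.01e-6, 1e-5)
  s <- stick_powder_signal(x, 1, 1)
  expect_true(all(diff(s) < 0))
  expect_error(stick_powder_signal(-1, 1, 0.5), "nonnegative")
  expect_error(stick_powder_signal(1, 1, -0.5), "nonnegative")
})

test_that("tensor powder signal reduces correctly and matches the spherical average", {
  # isotropic limit
  expect_equal(tensor_powder_signal(5, 1, 0.2, 0.2), exp(-1), tolerance = 1e-12)
  # stick reduction
  b <- c(0.5, 2, 7, 20)
  expect_equal(tensor_powder_signal(b, 1, 0.6, 0),
               stick_powder_signal(b, 1, 0.6), tolerance = 1e-12)
  # micro_domain argument
  expect_equal(tensor_powder_signal(5, 1, micro_domain(0.5, 0.05)),
               tensor_powder_signal(5, 1, 0.5, 0.05))
  # spherical-average oracle, 20 random draws
  set.seed(42)
  for (i in 1:20) {
    b <- runif(1, 0.5, 15)
    D_L <- runif(1, 0.1, 1)
    D_T <- runif(1, 0, 1) * D_L
    orc <- spherical_average_oracle(b, D_L, D_T, n = 1e6, seed = i)
    expect_lt(abs(tensor_powder_signal(b, 1, D_L, D_T) - orc$mean),
              3 * orc$se)
  }
  expect_error(tensor_powder_signal(5, 1, 0.2, 0.5), "planar")
})

test_that("powder signals are monotone and bounded", {
  bs <- seq(0, 20, by = 0.5)
  for (pars in list(c(0.5, 0), c(0.5, 0.1), c(1, 1))) {
    s <- tensor_powder_signal(bs, 1, pars[1], pars[2])
    expect_true(all(diff(s) < 0))
    expect_true(all(s > 0 & s <= 1))
  }
  # decreasing in D_L and D_T at fixed b
  dl <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(vapply(dl, function(d)
    stick_powder_signal(5, 1, d), 1)) < 0))
  dt <- seq(0, 0.4, by = 0.05)
  expect_true(all(diff(vapply(dt, function(d)
    tensor_powder_signal(5, 1, 0.5, d), 1)) < 0))
})

test_that("initial slope of the powder signal equals the compartment MD", {
  for (pars in list(c(0.5, 0), c(0.5, 0.05), c(0.9, 0.3))) {
    md <- compartment_md(pars[1], pars[2])
    b <- 1e-3 / pars[1]
    s <- tensor_powder_signal(b, 1, pars[1], pars[2])
    expect_lt(abs(s - (1 - b * md)), 1e-5)
  }
})

test_that("uFA and compartment MD reproduce the group-mean arithmetic", {
  expect_equal(mufa(1.0, 0.0), 1.0)
  expect_equal(mufa(0.3, 0.3), 0.0)
  expect_equal(round(mufa(0.50, 0.011), 2), 0.98)
  expect_equal(round(compartment_md(0.51, 0.024), 2), 0.19)
  expect_equal(compartment_md(0.6, 0), 0.2)
  expect_equal(compartment_md(0.37, 0.37), 0.37)
  # scale covariance
  expect_equal(mufa(3 * 0.5, 3 * 0.05), mufa(0.5, 0.05))
  expect_error(mufa(0, 0), "undefined")
  expect_error(mufa(0.1, 0.2), "planar")
})

test_that("asymptote deviation follows 1 - erf(sqrt(bDL))", {
  expect_lt(asymptote_deviation(4), 0.005)
  expect_equal(asymptote_deviation(4), 0.004678, tolerance = 1e-3)
  expect_equal(asymptote_deviation(1), 0.15730, tolerance = 1e-4)
  expect_lt(asymptote_deviation(100), 1e-10)
  expect_error(asymptote_deviation(0), "positive")
})

test_that("sensitivity optimum agrees with a dense grid search of the analytic derivative", {
  prof <- optimal_sensitivity_point()
  # brute-force oracle: |x A'(x)| on a 1e-4 grid
  g <- seq(1e-4, 20, by = 1e-4)
  sens <- g * abs(pamrs:::.stick_kernel_d1(g))
  expect_lt(abs(prof$argmax - g[which.max(sens)]), 2e-4)
  # scale invariance: optimal acquisition b for D_L = 0.5
  expect_equal(prof$argmax / 0.5, 2 * prof$argmax)
  expect_true(all(prof$sensitivity >= 0))
})

test_that("micro_domain validates and derives its summary metrics", {
  d <- micro_domain(0.5, 0.011)
  expect_equal(d$MD, compartment_md(0.5, 0.011))
  expect_equal(d$uFA, mufa(0.5, 0.011))
  expect_error(micro_domain(0.1, 0.2), "planar")
  expect_error(micro_domain(-0.1), "nonnegative")
  # (MD, uFA) -> (D_L, D_T) inversion round-trips
  for (ufa in c(0.3, 0.6, 0.9, 0.98)) {
    dom <- domain_from_md_mufa(0.17, ufa)
    expect_equal(dom$MD, 0.17, tolerance = 1e-9)
    expect_equal(dom$uFA, ufa, tolerance = 1e-9)
  }
  expect_equal(domain_from_md_mufa(0.2, 1)$D_L, 0.6)
  expect_equal(domain_from_md_mufa(0.2, 0)$D_T, 0.2)
})
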