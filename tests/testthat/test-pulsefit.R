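test_that("noise-free two-harmonic series is fitted exactly", {
  s <- make_series()
  f <- fit_harmonic_regression(s, order = 1)
  expect_equal(f$a0, 5, tolerance = 1e-8)
  expect_equal(f$a_n1, 2, tolerance = 1e-8)
  expect_equal(f$b_n1, -1, tolerance = 1e-8)
  expect_equal(f$rho, 0)
  expect_true(f$converged)

  # coefficients agree with ordinary least squares on the same design
  X <- cbind(1, cos(2 * pi * s$t), sin(2 * pi * s$t), s$t,
             pmax(s$t - 1, 0), pmax(s$t - 2, 0))
  beta_ols <- qr.solve(X, s$intensity)
  expect_equal(unname(f$coefficients), unname(beta_ols), tolerance = 1e-8)
})

test_that("the spline absorbs a linear drift without touching the harmonics", {
  f0 <- fit_harmonic_regression(make_series(), order = 1)
  f1 <- fit_harmonic_regression(make_series(drift = 0.5), order = 1)
  expect_equal(f1$a_n1, f0$a_n1, tolerance = 1e-6)
  expect_equal(f1$b_n1, f0$b_n1, tolerance = 1e-6)
  expect_equal(f1$hrwa, f0$hrwa, tolerance = 1e-6)
  # and the amplitude ignores a0 and trend entirely
  f2 <- fit_harmonic_regression(make_series(a0 = 50, drift = 3), order = 1)
  expect_equal(f2$hrwa, f0$hrwa, tolerance = 1e-6)
})

test_that("coefficients are recovered under AR(1) noise (Monte Carlo)", {
  set.seed(42)
  errs <- replicate(200, {
    s <- make_noisy_series()
    f <- fit_harmonic_regression(s, order = 2)
    mean(abs(c(f$a_n1 - 2, f$b_n1 + 1, f$a_n2 - 0.4, f$b_n2 - 0.3)))
  })
  expect_lt(mean(errs), 0.1)
})

test_that("degenerate series are rejected", {
  s <- make_series(n = 40, cycles = 1.5)
  expect_error(fit_harmonic_regression(s, order = 1), "3 cardiac cycles")
  s2 <- make_series(n = 12)
  expect_error(fit_harmonic_regression(s2, order = 4), "too few samples")
  s3 <- make_series()
  s3$t <- rev(s3$t)
  expect_error(fit_harmonic_regression(s3, order = 1), "increasing")
})

test_that("AR(1) estimation matches the lag-1 ratio", {
  x <- as.numeric(0.9^(0:30))
  expect_equal(estimate_ar1(x), 0.9, tolerance = 1e-9)
  set.seed(8)
  expect_lt(abs(estimate_ar1(rnorm(10000))), 0.03)
  expect_error(estimate_ar1(c(1, 2)), "at least 3")
  expect_error(estimate_ar1(rep(1, 10)), "degenerate")
})

test_that("pulse amplitude matches closed forms and the dense-grid oracle", {
  expect_equal(compute_hrwa(list(a_n1 = 3, b_n1 = 4)), 10)
  expect_equal(compute_hrwa(list(a_n1 = 0, b_n1 = 0, a_n2 = 0, b_n2 = 0)), 0)
  expect_equal(compute_hrwa(list(a_n1 = 1, b_n1 = 0, a_n2 = 0.5, b_n2 = 0)),
               2.25, tolerance = 1e-6)
  set.seed(77)
  for (i in seq_len(1000)) {
    co <- stats::rnorm(4, sd = 2)
    got <- compute_hrwa(list(a_n1 = co[1], b_n1 = co[2],
                             a_n2 = co[3], b_n2 = co[4]))
    want <- grid_peak_to_trough(co[1], co[2], co[3], co[4])
    expect_lt(abs(got - want), 1e-6)
    expect_gte(got, 0)
  }
})

test_that("waveform reconstruction is exact and linear in the coefficients", {
  s <- make_series(a2 = 0.4, b2 = 0.3)
  f <- fit_harmonic_regression(s, order = 2)
  expect_equal(reconstruct_waveform(f, s$t), s$intensity, tolerance = 1e-8)

  tg <- seq(0, 2, length.out = 101)
  base <- reconstruct_waveform(f, tg, include_trend = FALSE)
  f2 <- f
  for (nm in c("a_n1", "b_n1", "a_n2", "b_n2")) f2[[nm]] <- 2 * f2[[nm]]
  expect_equal(reconstruct_waveform(f2, tg, include_trend = FALSE),
               2 * base, tolerance = 1e-10)

  fz <- f
  for (nm in c("a_n1", "b_n1", "a_n2", "b_n2")) fz[[nm]] <- 0
  got <- reconstruct_waveform(fz, tg, include_trend = FALSE)
  expect_equal(got, rep(0, length(tg)))
})

test_that("AIC arithmetic holds for nested fits of a first-order signal", {
  set.seed(17)
  s <- make_noisy_series(a2 = 0, b2 = 0, rho = 0, sigma = 0.2)
  f1 <- fit_harmonic_regression(s, order = 1)
  f2 <- fit_harmonic_regression(s, order = 2)
  # order 2 nests order 1 and fits no better: its AIC can exceed the
  # order-1 AIC by at most 2 * (number of extra parameters), up to the
  # small wobble of the separately estimated AR(1) terms
  expect_lte(f2$aic, f1$aic + 2 * 2 + 0.1)
})

test_that("AIC selects the generating harmonic order at high SNR", {
  # A present second harmonic well above the noise floor is detected
  # essentially always.
  set.seed(314)
  hits2 <- sum(replicate(100, {
    s <- make_noisy_series(a1 = 3, b1 = -2, a2 = 1.2, b2 = 0.8,
                           rho = 0, sigma = 0.15)
    select_harmonic_order(s, max_order = 3) >= 2
  }))
  expect_gte(hits2, 90)

  # For a pure first-harmonic signal, AIC is not a consistent order
  # selector: each extra candidate order is preferred with asymptotic
  # probability P(chisq_2 > 4) ~= 13.5% regardless of SNR (worse in finite
  # samples). Order 1 is therefore the clear modal choice but not a >= 90%
  # one; assert the modal property and that overfitting stays within the
  # theoretically expected band.
  set.seed(315)
  picks <- replicate(100, {
    s <- make_noisy_series(a1 = 3, b1 = -2, a2 = 0, b2 = 0,
                           rho = 0, sigma = 0.15)
    select_harmonic_order(s, max_order = 3)
  })
  expect_gte(mean(picks == 1), 0.55)
  expect_gt(sum(picks == 1), max(sum(picks == 2), sum(picks == 3)))

  expect_equal(select_harmonic_order(make_series(), max_order = 1), 1L)
})

test_that("fit_cohort_pixels maps over a long table", {
  des <- small_design(seed = 31)
  sim <- simulate_cohort(des)
  set.seed(99)
  series <- simulate_cohort_series(sim$truth, des,
                                   pixels = sim$truth$pixel_id[1:4])
  fits <- fit_cohort_pixels(series, select_order = TRUE)
  expect_equal(nrow(fits), 4)
  expect_true(all(fits$order <= 2))
  expect_true(all(fits$hrwa >= 0))
})
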