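make_grouped_data <- function(n_groups = 50, n_rep = 20, sd_group = 1,
                              sd_resid = 2, beta = 0, seed = 1) {
  set.seed(seed)
  g <- rep(sprintf("g%02d", seq_len(n_groups)), each = n_rep)
  x <- rnorm(n_groups * n_rep)
  u <- rnorm(n_groups, 0, sd_group)[rep(seq_len(n_groups), each = n_rep)]
  tibble::tibble(
    subject_id = g, eye = "right", hemiretina = "superior",
    x = x, y = beta * x + u + rnorm(n_groups * n_rep, 0, sd_resid)
  )
}

test_that("model collapses to OLS when no random factor is identifiable", {
  d <- make_grouped_data(n_groups = 1, n_rep = 60, sd_group = 0, beta = 0.7)
  expect_warning(
    fit <- fit_pulse_lmm(d, "y", predictors = "x", random_factors = "subject_id"),
    "dropped"
  )
  expect_false(fit$is_mixed)
  ols <- stats::lm(y ~ x, data = d)
  expect_equal(fit$coefficients$estimate, unname(stats::coef(ols)),
               tolerance = 1e-6)
})

test_that("variance components match the balanced-ANOVA closed form", {
  d <- make_grouped_data(seed = 2)
  fit <- fit_pulse_lmm(d, "y", predictors = "x",
                       random_factors = "subject_id")
  vg <- fit$varcor$variance[fit$varcor$group != "Residual"]
  ve <- fit$varcor$variance[fit$varcor$group == "Residual"]
  expect_lt(abs(vg - 1), 0.3)
  expect_lt(abs(ve - 4), 0.3)
  # method-of-moments oracle from the one-way ANOVA mean squares
  aovt <- stats::anova(stats::aov(y ~ subject_id, data = d))
  msb <- aovt$`Mean Sq`[1]; msw <- aovt$`Mean Sq`[2]
  expect_lt(abs(vg - (msb - msw) / 20), 0.15)
})

test_that("noise-free distance decay is recovered exactly", {
  set.seed(3)
  d <- tibble::tibble(
    subject_id = rep(c("a", "b", "c"), each = 40),
    eye = rep(c("right", "left"), 60),
    hemiretina = rep(c("superior", "inferior"), each = 2, length.out = 120),
    v_dist_mm = runif(120, 0, 5),
    iop_i_mmHg = runif(120, 10, 40),
    icp_cmH2O = runif(120, 5, 50)
  )
  d$y <- 1.4823 - 0.07 * d$v_dist_mm
  fits <- suppressWarnings(
    univariate_effects(d, "y", predictors = "v_dist_mm")
  )
  slopes <- attr(fits, "slopes")
  expect_equal(slopes$estimate, -0.07, tolerance = 1e-6)
})

test_that("generated cohort fixed effects are recovered within 2 SE", {
  des <- cohort_design(seed = 2718)
  sim <- simulate_cohort(des)
  vein <- sim$table[sim$table$vessel == "vein", ]
  expect_gte(nrow(vein), 2000)
  fit <- fit_pulse_lmm(vein, "hrwa_yjt")
  truth <- unname(vein_interaction_coefs())
  expect_true(all(abs(fit$coefficients$estimate - truth) <
                    2 * fit$coefficients$std_error))
})

test_that("univariate IOP slope sign matches the generator", {
  # positive induced-IOP effect for veins at typical distances: the
  # composite IOP coefficient 0.00091 + 0.0071 * V_Dist + ... is positive
  signs <- vapply(1:20, function(s) {
    des <- cohort_design(n_subjects = 10, odf_levels_per_eye = 5,
                         pixels_per_vessel = 3, seed = 5000 + s)
    sim <- simulate_cohort(des)
    vein <- sim$table[sim$table$vessel == "vein", ]
    fits <- univariate_effects(vein, "hrwa_yjt", predictors = "iop_i_mmHg")
    sign(attr(fits, "slopes")$estimate)
  }, numeric(1))
  expect_gte(mean(signs > 0), 0.95)
})

test_that("R-squared pair: bounds, OLS reduction and plug-in values", {
  # reduction to the classical R-squared without random factors
  d <- make_grouped_data(n_groups = 1, n_rep = 200, sd_group = 0,
                         beta = 1, seed = 4)
  fit <- suppressWarnings(
    fit_pulse_lmm(d, "y", predictors = "x", random_factors = "subject_id")
  )
  r2 <- r2_nakagawa(fit)
  expect_equal(r2$marginal, r2$conditional)
  expect_equal(r2$marginal, summary(stats::lm(y ~ x, data = d))$r.squared,
               tolerance = 1e-8)

  # zero fixed effects give zero marginal R-squared (up to sampling noise)
  d0 <- make_grouped_data(beta = 0, seed = 5)
  f0 <- fit_pulse_lmm(d0, "y", predictors = "x",
                      random_factors = "subject_id")
  expect_lt(r2_nakagawa(f0)$marginal, 0.01)

  # plug-in case: var(fixed) = 1, var(random) = 1, var(resid) = 2
  dp <- make_grouped_data(n_groups = 200, n_rep = 100, sd_group = 1,
                          sd_resid = sqrt(2), beta = 1, seed = 6)
  fp <- fit_pulse_lmm(dp, "y", predictors = "x",
                      random_factors = "subject_id")
  r2p <- r2_nakagawa(fp)
  expect_lt(abs(r2p$marginal - 0.25), 0.03)
  expect_lt(abs(r2p$conditional - 0.5), 0.03)
})

test_that("R-squared bounds hold on every converged fit", {
  for (s in 1:5) {
    sim <- simulate_cohort(small_design(seed = 100 + s))
    for (vt in c("vein", "artery")) {
      fit <- fit_pulse_lmm(sim$table[sim$table$vessel == vt, ], "hrwa_yjt")
      r2 <- r2_nakagawa(fit)
      expect_gte(r2$marginal, 0)
      expect_lte(r2$marginal, r2$conditional)
      expect_lte(r2$conditional, 1)
    }
  }
})

test_that("standardised betas: correlation identity and scale invariance", {
  d <- make_grouped_data(n_groups = 1, n_rep = 300, sd_group = 0,
                         beta = 0.5, seed = 7)
  fit <- suppressWarnings(
    fit_pulse_lmm(d, "y", predictors = "x", random_factors = "subject_id")
  )
  b <- standardized_betas(fit)
  expect_equal(b$beta, stats::cor(d$x, d$y), tolerance = 1e-6)

  d10 <- d
  d10$x <- d10$x * 10
  f10 <- suppressWarnings(
    fit_pulse_lmm(d10, "y", predictors = "x", random_factors = "subject_id")
  )
  expect_equal(standardized_betas(f10)$beta, b$beta, tolerance = 1e-9)
})

test_that("mixed-model fits are invariant to row order", {
  sim <- simulate_cohort(small_design(seed = 77))
  vein <- sim$table[sim$table$vessel == "vein", ]
  f1 <- fit_pulse_lmm(vein, "hrwa_yjt")
  set.seed(1)
  f2 <- fit_pulse_lmm(vein[sample.int(nrow(vein)), ], "hrwa_yjt")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("effect grid evaluates the fixed-effect surface", {
  co <- vein_interaction_coefs()
  g0 <- effect_grid(co, v_dist = 0, iop_i = 0, icp = 0)
  expect_equal(g0$estimate, 1.69)

  # hand-computed composite slope at IOP_i = 20, ICP = 40
  g <- effect_grid(co, v_dist = c(1, 2), iop_i = 20, icp = 40)
  slope <- diff(g$estimate)
  expect_equal(slope, -0.3638 + 0.0071 * 20 + 0.0085 * 40 -
                 0.0001612 * 20 * 40, tolerance = 1e-10)

  # predictions are linear in distance within each facet
  gl <- effect_grid(co, v_dist = seq(0, 4, by = 0.5),
                    iop_i = c(15, 45), icp = c(10, 40))
  gl |>
    dplyr::group_by(.data$iop_i_mmHg, .data$icp_cmH2O) |>
    dplyr::group_walk(function(d, key) {
      expect_lt(max(abs(diff(diff(d$estimate)))), 1e-10)
    })

  # fitted-model version carries SEs and extrapolation flags
  sim <- simulate_cohort(small_design(seed = 55))
  fit <- fit_pulse_lmm(sim$table[sim$table$vessel == "vein", ], "hrwa_yjt")
  gf <- effect_grid(fit, v_dist = c(0, 2, 10), iop_i = 20, icp = 20)
  expect_true(all(gf$std_error > 0))
  expect_true(gf$extrapolated[gf$v_dist_mm == 10])
})

test_that("tidiers expose coefficients and fit summaries", {
  sim <- simulate_cohort(small_design(seed = 66))
  fit <- fit_pulse_lmm(sim$table[sim$table$vessel == "vein", ], "hrwa_yjt")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "p_value") %in% names(td)))
  gl <- glance(fit)
  expect_true(gl$is_mixed)
  expect_lte(gl$r2_marginal, gl$r2_conditional)

  f <- fit_harmonic_regression(make_series(), order = 1)
  expect_equal(glance(f)$hrwa, f$hrwa)
  expect_equal(nrow(tidy(f)), length(f$coefficients))
})
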