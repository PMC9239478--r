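# Shared fixtures for the test suite.

# Noise-free two-harmonic series on a cycle-fraction grid.
make_series <- function(n = 75, cycles = 3, a0 = 5, a1 = 2, b1 = -1,
                        a2 = 0, b2 = 0, drift = 0) {
  t <- seq(0, cycles, length.out = n)
  y <- a0 + a1 * cos(2 * pi * t) + b1 * sin(2 * pi * t) +
    a2 * cos(4 * pi * t) + b2 * sin(4 * pi * t) + drift * t
  list(t = t, intensity = y)
}

# Noisy series with AR(1) errors built independently of the generator.
make_noisy_series <- function(n = 75, cycles = 3, a0 = 5, a1 = 2, b1 = -1,
                              a2 = 0.4, b2 = 0.3, rho = 0.5, sigma = 0.2) {
  s <- make_series(n, cycles, a0, a1, b1, a2, b2)
  e <- if (rho == 0) {
    stats::rnorm(n, sd = sigma)
  } else {
    as.numeric(stats::arima.sim(list(ar = rho), n, sd = sigma))
  }
  s$intensity <- s$intensity + e
  s
}

# Small, fast cohort design for structural tests.
small_design <- function(seed = 11, ...) {
  cohort_design(n_subjects = 6, eyes_per_subject = 2, odf_levels_per_eye = 4,
                pixels_per_vessel = 2, seed = seed, ...)
}

# Deterministic design: no random effects, no residual noise.
noise_free_design <- function(seed = 1, ...) {
  cohort_design(
    re_sd = list(vein = c(subject = 0, eye = 0, hemiretina = 0),
                 artery = c(subject = 0, eye = 0, hemiretina = 0)),
    resid_sd = c(vein = 0, artery = 0),
    seed = seed, ...
  )
}

# Dense-grid peak-to-trough oracle for the periodic component.
grid_peak_to_trough <- function(a1, b1, a2 = 0, b2 = 0, n = 1e5) {
  t <- seq(0, 1, length.out = n)
  v <- a1 * cos(2 * pi * t) + b1 * sin(2 * pi * t) +
    a2 * cos(4 * pi * t) + b2 * sin(4 * pi * t)
  max(v) - min(v)
}
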