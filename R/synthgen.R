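# Synthetic cohort generator. Emulates the modified-photoplethysmography
# study design: ~21 subjects split by intracranial pressure at 25 cm water,
# two eyes per subject, ~10 ophthalmodynamometric force levels per eye, and
# per-pixel pulse amplitudes generated from the published interaction-model
# fixed effects on the Yeo-Johnson-transformed scale, with nested
# subject/eye/hemiretina random intercepts and Gaussian residual noise.

#' Default generating fixed effects for the transformed pulse amplitude
#'
#' The venous and arterial interaction-model coefficients (intercept,
#' V_Dist, IOP_i, ICP, the three two-way products and the three-way
#' product) on the Yeo-Johnson-transformed amplitude scale, used as the
#' generator's defaults.
#'
#' @return Named numeric vector of length 8.
#' @export
vein_interaction_coefs <- function() {
  c(intercept = 1.69, v_dist_mm = -0.3638, iop_i_mmHg = 0.00091,
    icp_cmH2O = -0.01149, `v_dist_mm:iop_i_mmHg` = 0.0071,
    `v_dist_mm:icp_cmH2O` = 0.0085, `iop_i_mmHg:icp_cmH2O` = 0.000094,
    `v_dist_mm:iop_i_mmHg:icp_cmH2O` = -0.0001612)
}

#' @rdname vein_interaction_coefs
#' @export
artery_interaction_coefs <- function() {
  c(intercept = 1.50, v_dist_mm = -0.2374, iop_i_mmHg = -0.00038,
    icp_cmH2O = -0.00708, `v_dist_mm:iop_i_mmHg` = 0.0089,
    `v_dist_mm:icp_cmH2O` = 0.00376, `iop_i_mmHg:icp_cmH2O` = 0.000188,
    `v_dist_mm:iop_i_mmHg:icp_cmH2O` = -0.0002)
}

interaction_model_matrix <- function(v_dist, iop_i, icp) {
  cbind(intercept = 1, v_dist_mm = v_dist, iop_i_mmHg = iop_i,
        icp_cmH2O = icp, `v_dist_mm:iop_i_mmHg` = v_dist * iop_i,
        `v_dist_mm:icp_cmH2O` = v_dist * icp,
        `iop_i_mmHg:icp_cmH2O` = iop_i * icp,
        `v_dist_mm:iop_i_mmHg:icp_cmH2O` = v_dist * iop_i * icp)
}

#' Describe a synthetic photoplethysmography cohort
#'
#' Collects all knobs of the synthetic-data generator into a validated
#' design object. Defaults mirror the study conditions: 21 subjects split
#' evenly between normal (<= 25 cm water) and high intracranial pressure,
#' 2 eyes per subject, 10 ophthalmodynamometric force levels per eye,
#' recordings of 3 cardiac cycles at 25 frames/s, and per-vessel variance
#' components calibrated so that the fixed effects explain roughly 9%
#' (vein) and 6% (artery) of the transformed-amplitude variance, with all
#' random plus fixed effects explaining roughly 40%.
#'
#' @param n_subjects Number of subjects.
#' @param eyes_per_subject 1 or 2 eyes imaged per subject.
#' @param prop_high_icp Proportion of subjects in the high-ICP group.
#' @param icp_normal_range_cmH2O,icp_high_range_cmH2O Uniform ranges the
#'   intracranial pressure is drawn from in each group (cm water).
#' @param odf_levels_per_eye Number of ophthalmodynamometric force levels.
#' @param odf_range_mu Uniform range of the applied force (Meditron units).
#' @param iop_b_mean_mmHg,iop_b_sd_mmHg Baseline intraocular pressure
#'   distribution per eye (mmHg).
#' @param pixels_per_vessel Pixels sampled per vessel per force level.
#' @param v_dist_range_mm Uniform range of distance along the vessel from
#'   the optic-disc centre (mm).
#' @param frame_rate_hz Video frame rate (default 25 frames/s).
#' @param n_cycles Cardiac cycles recorded per pixel (default 3).
#' @param heart_rate_bpm Heart rate used to convert frames to cycle
#'   fractions.
#' @param fixed_effects Named list with elements `vein` and `artery`, each
#'   a length-8 coefficient vector (intercept, V_Dist, IOP_i, ICP and the
#'   three two-way and one three-way products) on the transformed scale.
#' @param lambda Named vector of Yeo-Johnson exponents used to
#'   back-transform amplitudes (`artery`, `vein`).
#' @param re_sd Named list (`vein`, `artery`) of length-3 vectors: SDs of
#'   the subject, eye and hemiretina random intercepts.
#' @param resid_sd Named vector (`vein`, `artery`) of residual SDs on the
#'   transformed scale.
#' @param zeta Fraction of the peak-to-trough amplitude carried by the
#'   first harmonic (default 0.8; the first two harmonics dominate the
#'   pulse waveform).
#' @param rho AR(1) coefficient of the intensity noise, `|rho| < 1`.
#' @param noise_sd Innovation SD of the intensity noise (green-channel
#'   units).
#' @param a0_mean,a0_sd Mean green-channel intensity level distribution.
#' @param trend_slope_sd SD of the per-cycle linear trend slopes
#'   (intensity units per cycle).
#' @param seed Integer seed; mandatory for reproducible generation.
#' @return A `cohort_design` object (validated list).
#' @export
cohort_design <- function(n_subjects = 21L,
                          eyes_per_subject = 2L,
                          prop_high_icp = 0.5,
                          icp_normal_range_cmH2O = c(9.5, 24),
                          icp_high_range_cmH2O = c(25.5, 68),
                          odf_levels_per_eye = 10L,
                          odf_range_mu = c(0, 30),
                          iop_b_mean_mmHg = 16,
                          iop_b_sd_mmHg = 2.5,
                          pixels_per_vessel = 5L,
                          v_dist_range_mm = c(0.2, 4.5),
                          frame_rate_hz = 25,
                          n_cycles = 3,
                          heart_rate_bpm = 70,
                          fixed_effects = list(
                            vein = vein_interaction_coefs(),
                            artery = artery_interaction_coefs()
                          ),
                          lambda = c(artery = -0.0635, vein = -0.1684),
                          re_sd = list(
                            vein = c(subject = 0.18, eye = 0.12, hemiretina = 0.09),
                            artery = c(subject = 0.34, eye = 0.22, hemiretina = 0.16)
                          ),
                          resid_sd = c(vein = 0.338, artery = 0.552),
                          zeta = 0.8,
                          rho = 0.3,
                          noise_sd = 0.4,
                          a0_mean = 120,
                          a0_sd = 10,
                          trend_slope_sd = 0.5,
                          seed = 1L) {
  counts <- c(n_subjects = n_subjects, eyes_per_subject = eyes_per_subject,
              odf_levels_per_eye = odf_levels_per_eye,
              pixels_per_vessel = pixels_per_vessel)
  if (any(counts < 1)) {
    bad <- names(counts)[counts < 1]
    stop("design counts must be >= 1: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (eyes_per_subject > 2L) {
    stop("`eyes_per_subject` must be 1 or 2", call. = FALSE)
  }
  if (is.null(seed) || !is.finite(seed)) {
    stop("`seed` is mandatory for the synthetic generator", call. = FALSE)
  }
  cycle_dur_s <- 60 / heart_rate_bpm
  if (frame_rate_hz * cycle_dur_s < 2) {
    stop("sampling violates the Nyquist condition: fewer than 2 samples ",
         "per cardiac cycle", call. = FALSE)
  }
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (zeta < 0 || zeta > 1) stop("`zeta` must be in [0, 1]", call. = FALSE)
  for (v in c("vein", "artery")) {
    if (length(fixed_effects[[v]]) != 8L) {
      stop("`fixed_effects$", v, "` must have 8 coefficients", call. = FALSE)
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      eyes_per_subject = as.integer(eyes_per_subject),
      prop_high_icp = prop_high_icp,
      icp_normal_range_cmH2O = icp_normal_range_cmH2O,
      icp_high_range_cmH2O = icp_high_range_cmH2O,
      odf_levels_per_eye = as.integer(odf_levels_per_eye),
      odf_range_mu = odf_range_mu,
      iop_b_mean_mmHg = iop_b_mean_mmHg,
      iop_b_sd_mmHg = iop_b_sd_mmHg,
      pixels_per_vessel = as.integer(pixels_per_vessel),
      v_dist_range_mm = v_dist_range_mm,
      frame_rate_hz = frame_rate_hz,
      n_cycles = n_cycles,
      heart_rate_bpm = heart_rate_bpm,
      fixed_effects = fixed_effects,
      lambda = lambda,
      re_sd = re_sd,
      resid_sd = resid_sd,
      zeta = zeta,
      rho = rho,
      noise_sd = noise_sd,
      a0_mean = a0_mean,
      a0_sd = a0_sd,
      trend_slope_sd = trend_slope_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_design"
  )
}

# Upper end of the transformed scale reachable by non-negative amplitudes
# under Yeo-Johnson with exponent lambda (Inf when lambda >= 0).
yj_upper_bound <- function(lambda) {
  if (lambda < 0) -1 / lambda else Inf
}

# Split a raw peak-to-trough amplitude across two harmonics with random
# phases so that the combined periodic waveform has exactly that
# peak-to-trough range.
split_amplitude <- function(amplitude, zeta, phases) {
  r <- c(zeta, 1 - zeta)
  a <- r * cos(phases)
  b <- -r * sin(phases)
  if (amplitude == 0) {
    return(list(a = c(0, 0), b = c(0, 0)))
  }
  unit_ptt <- if (r[2] == 0) {
    2 * r[1]
  } else if (r[1] == 0) {
    2 * r[2]
  } else {
    rg <- periodic_range(list(a = a, b = b))
    rg[2] - rg[1]
  }
  s <- amplitude / unit_ptt
  list(a = a * s, b = b * s)
}

#' Simulate a synthetic photoplethysmography cohort
#'
#' Draws the full cohort: subjects with intracranial pressure split at
#' 25 cm water, eyes with baseline intraocular pressure, force levels,
#' and per-pixel predictors. The transformed pulse amplitude of each pixel
#' is the vessel-specific fixed-effect linear predictor plus nested
#' subject/eye/hemiretina random intercepts and Gaussian residual noise;
#' the raw amplitude is its inverse Yeo-Johnson transform at the vessel's
#' exponent. Residual draws that would leave the attainable transformed
#' range (possible for negative exponents) are redrawn; a pixel that
#' cannot be placed in-range is an error.
#'
#' @param design A [cohort_design()] object.
#' @return List with `table` (tibble, one row per pixel, the cohort
#'   analysis table including the realised `hrwa`, Fourier coefficients
#'   and `hrwa_yjt`) and `truth` (tibble of per-pixel generating values:
#'   fixed linear predictor, realised transformed amplitude, exponent,
#'   waveform coefficients, trend slopes, `rho`, `sigma`).
#' @examples
#' sim <- simulate_cohort(cohort_design(n_subjects = 4, pixels_per_vessel = 2,
#'                                      odf_levels_per_eye = 3, seed = 7))
#' dplyr::count(sim$table, vessel, icp_group)
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  d <- design

  n_high <- round(d$prop_high_icp * d$n_subjects)
  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(d$n_subjects)),
    icp_high = seq_len(d$n_subjects) <= n_high,
    icp_cmH2O = ifelse(
      icp_high,
      stats::runif(d$n_subjects, d$icp_high_range_cmH2O[1], d$icp_high_range_cmH2O[2]),
      stats::runif(d$n_subjects, d$icp_normal_range_cmH2O[1], d$icp_normal_range_cmH2O[2])
    ),
    age_years = round(stats::runif(d$n_subjects, 17, 47)),
    gender = ifelse(stats::runif(d$n_subjects) < 0.952, "female", "male")
  )

  eyes <- tidyr::expand_grid(
    subjects,
    eye = c("right", "left")[seq_len(d$eyes_per_subject)]
  )
  eyes$iop_b_mmHg <- pmax(stats::rnorm(nrow(eyes), d$iop_b_mean_mmHg,
                                       d$iop_b_sd_mmHg), 0)

  grid <- tidyr::expand_grid(
    eyes,
    odf_level = seq_len(d$odf_levels_per_eye),
    vessel = c("artery", "vein"),
    pixel = seq_len(d$pixels_per_vessel)
  )
  n <- nrow(grid)
  grid$odf_mu <- stats::runif(n, d$odf_range_mu[1], d$odf_range_mu[2])
  grid$v_dist_mm <- stats::runif(n, d$v_dist_range_mm[1], d$v_dist_range_mm[2])
  grid$hemiretina <- sample(c("superior", "inferior"), n, replace = TRUE)
  grid$iop_i_mmHg <- odf_to_iop(grid$odf_mu, grid$iop_b_mmHg)
  grid$icp_group <- assign_icp_group(grid$icp_cmH2O)
  grid$pixel_id <- sprintf("px%06d", seq_len(n))

  # Nested random intercepts, drawn per vessel system (the downstream
  # models are fitted to each vessel separately).
  re_key <- function(level) {
    switch(level,
      subject = grid$subject_id,
      eye = paste(grid$subject_id, grid$eye, sep = ":"),
      hemiretina = paste(grid$subject_id, grid$eye, grid$hemiretina, sep = ":")
    )
  }
  re_total <- numeric(n)
  for (level in c("subject", "eye", "hemiretina")) {
    key <- paste(grid$vessel, re_key(level), sep = "@")
    u <- unique(key)
    sds <- ifelse(startsWith(u, "vein@"),
                  d$re_sd$vein[[level]], d$re_sd$artery[[level]])
    draw <- stats::setNames(stats::rnorm(length(u), 0, sds), u)
    re_total <- re_total + unname(draw[key])
  }

  is_vein <- grid$vessel == "vein"
  X <- interaction_model_matrix(grid$v_dist_mm, grid$iop_i_mmHg, grid$icp_cmH2O)
  lp <- numeric(n)
  lp[is_vein] <- as.numeric(X[is_vein, , drop = FALSE] %*% d$fixed_effects$vein)
  lp[!is_vein] <- as.numeric(X[!is_vein, , drop = FALSE] %*% d$fixed_effects$artery)

  sd_resid <- ifelse(is_vein, d$resid_sd[["vein"]], d$resid_sd[["artery"]])
  lambda_px <- ifelse(is_vein, d$lambda[["vein"]], d$lambda[["artery"]])
  upper <- vapply(lambda_px, yj_upper_bound, numeric(1)) - 1e-9

  z <- lp + re_total + stats::rnorm(n, 0, sd_resid)
  out_of_range <- function(z) z < 0 | z >= upper
  bad <- which(out_of_range(z))
  tries <- 0L
  while (length(bad) > 0 && tries < 200L) {
    if (all(sd_resid[bad] == 0)) break
    z[bad] <- lp[bad] + re_total[bad] + stats::rnorm(length(bad), 0, sd_resid[bad])
    bad <- which(out_of_range(z))
    tries <- tries + 1L
  }
  if (length(bad) > 0) {
    stop("generated transformed amplitude outside the attainable ",
         "Yeo-Johnson range for pixel(s) ",
         paste(utils::head(grid$pixel_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }

  hrwa <- vapply(seq_len(n), function(i) {
    invert_yeo_johnson(z[i], lambda_px[i])
  }, numeric(1))

  phases <- matrix(stats::runif(2 * n, 0, 2 * pi), ncol = 2)
  ab <- lapply(seq_len(n), function(i) {
    split_amplitude(hrwa[i], d$zeta, phases[i, ])
  })
  a_n1 <- vapply(ab, function(x) x$a[1], numeric(1))
  b_n1 <- vapply(ab, function(x) x$b[1], numeric(1))
  a_n2 <- vapply(ab, function(x) x$a[2], numeric(1))
  b_n2 <- vapply(ab, function(x) x$b[2], numeric(1))

  a0 <- stats::rnorm(n, d$a0_mean, d$a0_sd)
  n_cyc <- ceiling(d$n_cycles)
  trend <- matrix(stats::rnorm(n * n_cyc, 0, d$trend_slope_sd), nrow = n)

  table <- tibble::tibble(
    subject_id = grid$subject_id,
    age_years = grid$age_years,
    gender = grid$gender,
    eye = grid$eye,
    hemiretina = grid$hemiretina,
    vessel = grid$vessel,
    pixel_id = grid$pixel_id,
    v_dist_mm = grid$v_dist_mm,
    odf_mu = grid$odf_mu,
    iop_b_mmHg = grid$iop_b_mmHg,
    iop_i_mmHg = grid$iop_i_mmHg,
    icp_cmH2O = grid$icp_cmH2O,
    icp_group = grid$icp_group,
    hrwa = hrwa,
    a_n1 = a_n1, b_n1 = b_n1, a_n2 = a_n2, b_n2 = b_n2,
    hrwa_yjt = z
  )
  truth <- tibble::tibble(
    pixel_id = grid$pixel_id,
    vessel = grid$vessel,
    v_dist_mm = grid$v_dist_mm,
    true_fixed_predictor = lp,
    true_yj_amplitude = z,
    true_lambda = lambda_px,
    true_hrwa = hrwa,
    a0 = a0,
    a_n1 = a_n1, b_n1 = b_n1, a_n2 = a_n2, b_n2 = b_n2,
    trend_slopes = lapply(seq_len(n), function(i) trend[i, ]),
    rho = d$rho,
    sigma = d$noise_sd
  )
  list(table = table, truth = truth)
}

#' Simulate one pixel's intensity time-series
#'
#' Builds the cardiac-cycle-fraction time grid implied by the design's
#' frame rate, heart rate and number of cycles, and evaluates the pixel's
#' generating waveform: mean level + two-harmonic periodic component +
#' piecewise-linear trend + AR(1) noise (stationary start). The
#' peak-to-trough of the noise-free periodic part equals the pixel's raw
#' amplitude by construction.
#'
#' @param truth One row of the `truth` tibble from [simulate_cohort()]
#'   (or a list with fields `a0`, `a_n1`, `b_n1`, `a_n2`, `b_n2`,
#'   `trend_slopes`, `rho`, `sigma`, `pixel_id`).
#' @param design A [cohort_design()] object (frame rate, cycles, heart
#'   rate).
#' @return A `pulse_series` object: list with `t` (cycle fractions),
#'   `intensity`, and the pixel metadata.
#' @export
simulate_pixel_series <- function(truth, design) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.data.frame(truth)) {
    stopifnot(nrow(truth) == 1L)
    truth <- as.list(truth)
    if (is.list(truth$trend_slopes)) truth$trend_slopes <- truth$trend_slopes[[1]]
  }
  if (abs(truth$rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (truth$sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  cycle_dur_s <- 60 / design$heart_rate_bpm
  spc <- design$frame_rate_hz * cycle_dur_s
  if (spc < 2) {
    stop("sampling violates the Nyquist condition: fewer than 2 samples ",
         "per cardiac cycle", call. = FALSE)
  }
  n <- ceiling(design$n_cycles * spc) + 1L
  t <- (seq_len(n) - 1L) / spc

  periodic <- truth$a_n1 * cos(2 * pi * t) + truth$b_n1 * sin(2 * pi * t) +
    truth$a_n2 * cos(4 * pi * t) + truth$b_n2 * sin(4 * pi * t)

  slopes <- truth$trend_slopes
  n_seg <- ceiling(max(t))
  if (length(slopes) < n_seg) slopes <- rep_len(slopes, n_seg)
  seg <- pmin(floor(t) + 1L, n_seg)
  seg_start <- cumsum(c(0, slopes))[seg]
  trend <- seg_start + slopes[seg] * (t - (seg - 1L))

  noise <- numeric(n)
  if (truth$sigma > 0) {
    innov <- stats::rnorm(n, 0, truth$sigma)
    init <- stats::rnorm(1, 0, truth$sigma / sqrt(1 - truth$rho^2))
    noise <- as.numeric(stats::filter(innov, truth$rho, method = "recursive",
                                      init = init))
  }

  structure(
    list(
      pixel_id = truth$pixel_id %||% "px000001",
      vessel = truth$vessel %||% NA_character_,
      v_dist_mm = truth$v_dist_mm %||% NA_real_,
      t = t,
      intensity = truth$a0 + periodic + trend + noise
    ),
    class = "pulse_series"
  )
}

#' @export
print.pulse_series <- function(x, ...) {
  cat(sprintf("Pulse series %s (%s): %d samples over %.2f cycles\n",
              x$pixel_id, x$vessel %||% "?", length(x$t), max(x$t)))
  invisible(x)
}

#' Simulate the long-format time-series table for a cohort
#'
#' Convenience wrapper mapping [simulate_pixel_series()] over (a subset
#' of) the pixels of a simulated cohort.
#'
#' @param truth The `truth` tibble from [simulate_cohort()].
#' @param design The [cohort_design()] used.
#' @param pixels Optional character vector of `pixel_id`s to simulate
#'   (default: all).
#' @return Tibble with columns `pixel_id`, `t`, `intensity`.
#' @export
simulate_cohort_series <- function(truth, design, pixels = NULL) {
  if (!is.null(pixels)) {
    truth <- truth[truth$pixel_id %in% pixels, , drop = FALSE]
  }
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    s <- simulate_pixel_series(truth[i, ], design)
    tibble::tibble(pixel_id = s$pixel_id, t = s$t, intensity = s$intensity)
  })
}

#' Cell-mean pattern of the vessel-by-ICP interaction plots
#'
#' The transformed-scale cell means used to emulate the study's interaction
#' plots: the pulse amplitude shows a cross-over (disordinal) interaction
#' between vessel type and ICP group (venous means 1.502 / 1.368 and
#' arterial means 1.435 / 1.466 in the normal / high groups), the first
#' cosine coefficient shows a main effect with no interaction, the second
#' cosine coefficient an ordinal interaction, the first sine coefficient an
#' interaction with loss of the main effect in the high-ICP group, and the
#' second sine coefficient an ordinal interaction with loss of the main
#' effect in the high-ICP group.
#'
#' @return Tibble with columns `parameter`, `vessel`, `icp_group`, `mean`.
#' @export
interaction_cell_pattern <- function() {
  tibble::tribble(
    ~parameter,  ~vessel,  ~icp_group, ~mean,
    "hrwa_yjt",  "artery", "normal",    1.435,
    "hrwa_yjt",  "artery", "high",      1.466,
    "hrwa_yjt",  "vein",   "normal",    1.502,
    "hrwa_yjt",  "vein",   "high",      1.368,
    "a_n1_yjt",  "artery", "normal",    0.10,
    "a_n1_yjt",  "artery", "high",      0.15,
    "a_n1_yjt",  "vein",   "normal",    0.40,
    "a_n1_yjt",  "vein",   "high",      0.45,
    "b_n1_yjt",  "artery", "normal",   -1.00,
    "b_n1_yjt",  "artery", "high",     -1.02,
    "b_n1_yjt",  "vein",   "normal",   -1.33,
    "b_n1_yjt",  "vein",   "high",     -1.02,
    "a_n2_yjt",  "artery", "normal",    0.00,
    "a_n2_yjt",  "artery", "high",      0.00,
    "a_n2_yjt",  "vein",   "normal",   -0.30,
    "a_n2_yjt",  "vein",   "high",     -0.10,
    "b_n2_yjt",  "artery", "normal",    0.05,
    "b_n2_yjt",  "artery", "high",      0.06,
    "b_n2_yjt",  "vein",   "normal",    0.35,
    "b_n2_yjt",  "vein",   "high",      0.06
  )
}

#' Simulate a cohort with a prescribed vessel-by-ICP cell-mean structure
#'
#' Generates Gaussian values around the given cell means for each
#' parameter, for validating the interaction-plot classifier against a
#' known pattern.
#'
#' @param pattern Tibble as returned by [interaction_cell_pattern()].
#' @param n_per_cell Observations per (vessel, ICP group) cell.
#' @param sd Common within-cell standard deviation.
#' @param seed Integer seed.
#' @return Tibble with columns `vessel`, `icp_group`, and one column per
#'   parameter in `pattern`.
#' @export
simulate_cell_cohort <- function(pattern = interaction_cell_pattern(),
                                 n_per_cell = 2000L, sd = 0.3, seed = 1L) {
  stopifnot(n_per_cell >= 2L, sd >= 0)
  set.seed(seed)
  cells <- tidyr::expand_grid(
    vessel = c("artery", "vein"),
    icp_group = c("normal", "high"),
    row = seq_len(n_per_cell)
  )
  out <- cells[, c("vessel", "icp_group")]
  for (p in unique(pattern$parameter)) {
    pp <- pattern[pattern$parameter == p, ]
    mu <- pp$mean[match(paste(out$vessel, out$icp_group),
                        paste(pp$vessel, pp$icp_group))]
    out[[p]] <- stats::rnorm(nrow(out), mu, sd)
  }
  tibble::as_tibble(out)
}
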