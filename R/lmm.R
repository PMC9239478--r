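# Hierarchical linear mixed-effects models of the transformed pulse
# amplitude on distance along the vessel, induced intraocular pressure and
# intracranial pressure, with nested random intercepts
# subject -> eye -> hemiretina. Age and gender are subject-level
# attributes, available as optional fixed covariates.

default_random_factors <- c("subject_id", "eye", "hemiretina")

build_fixed_formula <- function(response, predictors, interactions) {
  rhs <- if (interactions && length(predictors) > 1) {
    paste(predictors, collapse = " * ")
  } else {
    paste(predictors, collapse = " + ")
  }
  stats::as.formula(paste(response, "~", rhs))
}

# Nested random-intercept terms; factors with < 2 observed levels are
# dropped (with a warning) since their variance is unidentifiable.
nested_random_terms <- function(table, random_factors) {
  keys <- character(0)
  terms <- character(0)
  path <- character(0)
  for (f in random_factors) {
    path <- c(path, f)
    key <- do.call(paste, c(unname(table[path]), list(sep = ":")))
    if (length(unique(key)) < 2L) {
      warning("random factor `", f,
              "` has fewer than 2 levels and was dropped", call. = FALSE)
      next
    }
    terms <- c(terms, paste0("(1 | ", paste(path, collapse = ":"), ")"))
  }
  terms
}

#' Fit a hierarchical mixed-effects pulse-amplitude model
#'
#' Fits a Gaussian random-intercept model of a (typically Yeo-Johnson
#' transformed) pulse parameter on distance along the vessel, induced
#' intraocular pressure and intracranial pressure, optionally with all
#' two-way and the three-way interaction. Random intercepts are nested
#' subject, eye-within-subject and hemiretina-within-eye; grouping factors
#' with fewer than two observed levels are dropped with a warning, and if
#' none remain the model collapses to ordinary least squares. Estimation is
#' REML by default (set `REML = FALSE` when comparing fixed-effect
#' structures); p-values are Wald z tests on coefficient / SE.
#'
#' @param table Cohort data frame (typically one vessel's rows).
#' @param response Name of the response column.
#' @param predictors Fixed-effect columns (default `v_dist_mm`,
#'   `iop_i_mmHg`, `icp_cmH2O`).
#' @param interactions Include all interaction products? Default `TRUE`.
#' @param random_factors Nested grouping columns, outermost first.
#' @param REML Use restricted maximum likelihood? Default `TRUE`.
#' @return A `pulse_lmm` object: list with `model` (a `lmerMod` or `lm`),
#'   `coefficients` (tibble: term, estimate, std_error, statistic,
#'   p_value), `varcor` (tibble: group, variance, sd), `loglik`,
#'   `converged`, `is_mixed`, `response`, `predictors`, `data`.
#' @examples
#' sim <- simulate_cohort(cohort_design(n_subjects = 6, pixels_per_vessel = 2,
#'                                      odf_levels_per_eye = 3, seed = 3))
#' fit <- fit_pulse_lmm(dplyr::filter(sim$table, vessel == "vein"),
#'                      response = "hrwa_yjt")
#' tidy(fit)
#' @export
fit_pulse_lmm <- function(table, response,
                          predictors = c("v_dist_mm", "iop_i_mmHg", "icp_cmH2O"),
                          interactions = TRUE,
                          random_factors = default_random_factors,
                          REML = TRUE) {
  stopifnot(is.data.frame(table))
  needed <- c(response, predictors, random_factors)
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0) {
    stop("columns not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  table <- as.data.frame(table)
  fixed <- build_fixed_formula(response, predictors, interactions)
  re_terms <- if (length(random_factors) > 0) {
    nested_random_terms(table, random_factors)
  } else {
    character(0)
  }

  if (length(re_terms) == 0) {
    model <- stats::lm(fixed, data = table)
    est <- stats::coef(model)
    se <- sqrt(diag(stats::vcov(model)))
    varcor <- tibble::tibble(group = "Residual",
                             variance = sum(stats::residuals(model)^2) /
                               (nrow(table) - 1),
                             sd = sqrt(variance))
    converged <- TRUE
    ll <- as.numeric(stats::logLik(model))
    is_mixed <- FALSE
  } else {
    form <- stats::as.formula(
      paste(response, "~", as.character(fixed)[3], "+",
            paste(re_terms, collapse = " + "))
    )
    model <- lme4::lmer(
      form, data = table, REML = REML,
      control = lme4::lmerControl(optimizer = "bobyqa",
                                  optCtrl = list(maxfun = 1e5))
    )
    est <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
    vc <- as.data.frame(lme4::VarCorr(model))
    varcor <- tibble::tibble(group = vc$grp, variance = vc$vcov,
                             sd = vc$sdcor)
    singular <- lme4::isSingular(model, tol = 1e-5)
    if (singular) {
      warning("one or more variance components estimated at the boundary ",
              "(reported as 0)", call. = FALSE)
    }
    msgs <- model@optinfo$conv$lme4$messages
    converged <- is.null(msgs) || length(msgs) == 0
    if (!converged) {
      warning("mixed-model fit flagged: ",
              paste(unlist(msgs), collapse = "; "), call. = FALSE)
    }
    ll <- as.numeric(stats::logLik(model))
    is_mixed <- TRUE
  }

  z <- est / se
  coefficients <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    statistic = unname(z),
    p_value = 2 * stats::pnorm(-abs(unname(z)))
  )
  structure(
    list(
      model = model,
      coefficients = coefficients,
      varcor = varcor,
      loglik = ll,
      converged = converged,
      is_mixed = is_mixed,
      response = response,
      predictors = predictors,
      interactions = interactions,
      data = table
    ),
    class = "pulse_lmm"
  )
}

#' @export
print.pulse_lmm <- function(x, ...) {
  cat(sprintf("Pulse-amplitude %s model: %s ~ %s%s\n",
              if (x$is_mixed) "mixed-effects" else "linear",
              x$response, paste(x$predictors, collapse = " + "),
              if (x$interactions) " (with interactions)" else ""))
  print(x$coefficients)
  if (x$is_mixed) {
    cat("Variance components:\n")
    print(x$varcor)
  }
  invisible(x)
}

#' Single-predictor mixed-model effects
#'
#' Fits one random-intercept model per predictor (same random structure),
#' reporting each slope. These are the univariate decay/amplification
#' effects of distance, induced intraocular pressure and intracranial
#' pressure on the transformed amplitude.
#'
#' @inheritParams fit_pulse_lmm
#' @return Named list of `pulse_lmm` fits, one per predictor, with a
#'   `slopes` attribute (tibble: predictor, estimate, std_error, p_value).
#' @export
univariate_effects <- function(table, response,
                               predictors = c("v_dist_mm", "iop_i_mmHg", "icp_cmH2O"),
                               random_factors = default_random_factors,
                               REML = TRUE) {
  fits <- lapply(predictors, function(p) {
    fit_pulse_lmm(table, response, predictors = p, interactions = FALSE,
                  random_factors = random_factors, REML = REML)
  })
  names(fits) <- predictors
  slopes <- purrr::map_dfr(predictors, function(p) {
    cf <- fits[[p]]$coefficients
    row <- cf[cf$term == p, ]
    tibble::tibble(predictor = p, estimate = row$estimate,
                   std_error = row$std_error, p_value = row$p_value)
  })
  attr(fits, "slopes") <- slopes
  fits
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-partition R-squared for Gaussian random-intercept models:
#' marginal = var(fixed predictor) / (var(fixed predictor) + sum of random
#' intercept variances + residual variance); conditional adds the random
#' intercept variances to the numerator. With no random factors both equal
#' the classical R-squared.
#'
#' @param fit A `pulse_lmm` object.
#' @return List with `marginal` and `conditional`, each in `[0, 1]`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "pulse_lmm"))
  if (fit$is_mixed) {
    X <- lme4::getME(fit$model, "X")
    lp <- as.numeric(X %*% lme4::fixef(fit$model))
    var_f <- stats::var(lp)
    vc <- fit$varcor
    var_r <- sum(vc$variance[vc$group != "Residual"])
    var_e <- vc$variance[vc$group == "Residual"]
  } else {
    lp <- stats::fitted(fit$model)
    var_f <- stats::var(lp)
    var_r <- 0
    var_e <- sum(stats::residuals(fit$model)^2) /
      (length(lp) - 1)
  }
  denom <- var_f + var_r + var_e
  if (denom <= 0) stop("zero total variance", call. = FALSE)
  list(marginal = var_f / denom, conditional = (var_f + var_r) / denom)
}

#' Standardised (weighted beta) coefficients
#'
#' Rescales each fixed-effect coefficient by sd(predictor column) /
#' sd(response), with interaction columns standardised as the constructed
#' product variables, so that effect sizes are comparable across
#' predictors with different units. Standard errors are scaled
#' identically. For a single-predictor model the beta equals the Pearson
#' correlation between predictor and response.
#'
#' @param fit A `pulse_lmm` object.
#' @return Tibble: term, beta, std_error, p_value.
#' @export
standardized_betas <- function(fit) {
  stopifnot(inherits(fit, "pulse_lmm"))
  X <- if (fit$is_mixed) {
    as.matrix(lme4::getME(fit$model, "X"))
  } else {
    stats::model.matrix(fit$model)
  }
  y <- fit$data[[fit$response]]
  sdy <- stats::sd(y)
  cf <- fit$coefficients
  out <- cf[cf$term != "(Intercept)", ]
  sdx <- vapply(out$term, function(tm) stats::sd(X[, tm]), numeric(1))
  if (any(sdx == 0)) {
    stop("zero-variance predictor column(s): ",
         paste(out$term[sdx == 0], collapse = ", "), call. = FALSE)
  }
  scale <- unname(sdx) / sdy
  tibble::tibble(term = out$term,
                 beta = out$estimate * scale,
                 std_error = out$std_error * scale,
                 p_value = out$p_value)
}

predict_fixed_terms <- function(coefs, newdata) {
  lp <- numeric(nrow(newdata))
  X <- matrix(0, nrow(newdata), length(coefs))
  colnames(X) <- names(coefs)
  for (j in seq_along(coefs)) {
    nm <- names(coefs)[j]
    if (nm %in% c("(Intercept)", "intercept")) {
      X[, j] <- 1
    } else {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      if (!all(parts %in% names(newdata))) {
        stop("cannot evaluate term `", nm, "` on the prediction grid",
             call. = FALSE)
      }
      X[, j] <- Reduce(`*`, lapply(parts, function(p) newdata[[p]]))
    }
  }
  list(X = X, lp = as.numeric(X %*% coefs))
}

#' Fixed-effect prediction grid for trellis interaction displays
#'
#' Evaluates the fixed-effect surface (random effects at zero) over a grid
#' of distances along the vessel, faceted by ICP level (columns) and
#' induced IOP level (rows), with Wald standard-error bands. Grid points
#' outside the observed predictor ranges are flagged as extrapolation, not
#' forbidden (boundary regions of the interaction surface can produce
#' spurious slope reversals).
#'
#' @param fit A `pulse_lmm` object, or a named coefficient vector (names
#'   `intercept`/`(Intercept)`, `v_dist_mm`, `iop_i_mmHg`, `icp_cmH2O` and
#'   their `:` products).
#' @param v_dist Numeric grid of distances (mm).
#' @param iop_i Numeric vector of induced IOP facet levels (mmHg).
#' @param icp Numeric vector of ICP facet levels (cm water).
#' @return Tibble: `v_dist_mm`, `iop_i_mmHg`, `icp_cmH2O`, `estimate`,
#'   `std_error` (NA for bare coefficient vectors), `extrapolated`.
#' @examples
#' effect_grid(vein_interaction_coefs(), v_dist = 0, iop_i = 0, icp = 0)
#' @export
effect_grid <- function(fit,
                        v_dist = seq(0, 5, by = 0.25),
                        iop_i = c(15, 25, 35, 45),
                        icp = c(10, 20, 30, 40)) {
  grid <- tidyr::expand_grid(v_dist_mm = v_dist, iop_i_mmHg = iop_i,
                             icp_cmH2O = icp)
  if (inherits(fit, "pulse_lmm")) {
    coefs <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
    pr <- predict_fixed_terms(coefs, grid)
    V <- as.matrix(stats::vcov(fit$model))
    se <- sqrt(rowSums((pr$X %*% V) * pr$X))
    obs <- fit$data
    extrap <- grid$v_dist_mm < min(obs$v_dist_mm) |
      grid$v_dist_mm > max(obs$v_dist_mm) |
      grid$iop_i_mmHg < min(obs$iop_i_mmHg) |
      grid$iop_i_mmHg > max(obs$iop_i_mmHg) |
      grid$icp_cmH2O < min(obs$icp_cmH2O) |
      grid$icp_cmH2O > max(obs$icp_cmH2O)
  } else {
    stopifnot(is.numeric(fit), !is.null(names(fit)))
    pr <- predict_fixed_terms(fit, grid)
    se <- rep(NA_real_, nrow(grid))
    extrap <- rep(NA, nrow(grid))
  }
  dplyr::mutate(grid, estimate = pr$lp, std_error = se,
                extrapolated = extrap)
}
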