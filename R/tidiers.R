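# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a harmonic regression fit
#'
#' @param x A `harmonic_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `term`, `estimate`.
#' @export
tidy.harmonic_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' One-row summary of a harmonic regression fit
#'
#' @param x A `harmonic_fit` object.
#' @param ... Unused.
#' @return Tibble: `order`, `hrwa`, `rho`, `sigma2`, `aic`, `loglik`,
#'   `converged`, `nobs`.
#' @export
glance.harmonic_fit <- function(x, ...) {
  tibble::tibble(order = x$order, hrwa = x$hrwa, rho = x$rho,
                 sigma2 = x$sigma2, aic = x$aic, loglik = x$loglik,
                 converged = x$converged, nobs = length(x$t))
}

#' Tidy a pulse mixed-model fit
#'
#' @param x A `pulse_lmm` object.
#' @param effects `"fixed"` (default) for the coefficient table or
#'   `"ran_pars"` for the variance components.
#' @param ... Unused.
#' @return Tibble of fixed-effect coefficients (term, estimate,
#'   std_error, statistic, p_value) or variance components (group,
#'   variance, sd).
#' @export
tidy.pulse_lmm <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") x$coefficients else x$varcor
}

#' One-row summary of a pulse mixed-model fit
#'
#' @param x A `pulse_lmm` object.
#' @param ... Unused.
#' @return Tibble: `r2_marginal`, `r2_conditional`, `loglik`, `converged`,
#'   `nobs`, `is_mixed`.
#' @export
glance.pulse_lmm <- function(x, ...) {
  r2 <- r2_nakagawa(x)
  tibble::tibble(r2_marginal = r2$marginal,
                 r2_conditional = r2$conditional,
                 loglik = x$loglik, converged = x$converged,
                 nobs = nrow(x$data), is_mixed = x$is_mixed)
}

#' Tidy a Yeo-Johnson lambda fit
#'
#' @param x A `lambda_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `lambda`, `stat_before`, `stat_after`.
#' @export
tidy.lambda_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, stat_before = x$stat_before,
                 stat_after = x$stat_after)
}
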