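#' Yeo-Johnson power transformation
#'
#' Applies the Yeo-Johnson transformation \eqn{\psi(\lambda, y)}, a power
#' transformation defined for both negative and positive values. For
#' non-negative `y` it equals the Box-Cox transformation of `y + 1`; for
#' negative `y` it equals the Box-Cox transformation of `-y + 1` with power
#' `2 - lambda`, negated. The transformation is strictly increasing in `y`
#' and continuous in `lambda` at 0 and 2.
#'
#' @param y Numeric vector of finite values.
#' @param lambda Single numeric exponent \eqn{\lambda}.
#' @return Numeric vector of transformed values, same length as `y`.
#' @examples
#' yeo_johnson(c(-2, 0, 3.2), lambda = 1)
#' yeo_johnson(exp(1) - 1, lambda = 0) # log branch -> 1
#' @seealso [invert_yeo_johnson()], [estimate_lambda()]
#' @export
yeo_johnson <- function(y, lambda) {
  stopifnot(is.numeric(y), is.numeric(lambda), length(lambda) == 1L)
  if (!all(is.finite(y))) {
    stop("`y` must be finite", call. = FALSE)
  }
  if (!is.finite(lambda)) {
    stop("`lambda` must be finite", call. = FALSE)
  }
  out <- numeric(length(y))
  pos <- y >= 0
  if (any(pos)) {
    out[pos] <- if (abs(lambda) < .Machine$double.eps^0.5) {
      log1p(y[pos])
    } else {
      (exp(lambda * log1p(y[pos])) - 1) / lambda
    }
  }
  if (any(!pos)) {
    tl <- 2 - lambda
    out[!pos] <- if (abs(tl) < .Machine$double.eps^0.5) {
      -log1p(-y[!pos])
    } else {
      -(exp(tl * log1p(-y[!pos])) - 1) / tl
    }
  }
  out
}

#' Invert the Yeo-Johnson transformation
#'
#' Recovers `y` such that `yeo_johnson(y, lambda) == z`. Because the
#' transformation preserves sign, non-negative `z` is inverted through the
#' positive branch and negative `z` through the negative branch. The
#' transformed scale is bounded for some `lambda`: for `lambda < 0` the
#' positive branch is bounded above by `-1 / lambda`, and for `lambda > 2`
#' the negative branch is bounded below by `-1 / (lambda - 2)`. Values
#' outside the attainable range raise a domain error.
#'
#' @param z Numeric vector of transformed values.
#' @param lambda Single numeric exponent \eqn{\lambda}.
#' @return Numeric vector `y` with `yeo_johnson(y, lambda) == z` to
#'   round-off accuracy.
#' @examples
#' invert_yeo_johnson(yeo_johnson(2.5, -0.17), -0.17)
#' @export
invert_yeo_johnson <- function(z, lambda) {
  stopifnot(is.numeric(z), is.numeric(lambda), length(lambda) == 1L)
  if (!all(is.finite(z))) {
    stop("`z` must be finite", call. = FALSE)
  }
  out <- numeric(length(z))
  pos <- z >= 0
  if (any(pos)) {
    zp <- z[pos]
    if (abs(lambda) < .Machine$double.eps^0.5) {
      out[pos] <- expm1(zp)
    } else {
      arg <- lambda * zp + 1
      if (any(arg <= 0)) {
        stop(
          "transformed value outside the range of the positive branch for lambda = ",
          lambda,
          call. = FALSE
        )
      }
      out[pos] <- exp(log(arg) / lambda) - 1
    }
  }
  if (any(!pos)) {
    zn <- z[!pos]
    tl <- 2 - lambda
    if (abs(tl) < .Machine$double.eps^0.5) {
      out[!pos] <- -expm1(-zn)
    } else {
      arg <- -tl * zn + 1
      if (any(arg <= 0)) {
        stop(
          "transformed value outside the range of the negative branch for lambda = ",
          lambda,
          call. = FALSE
        )
      }
      out[!pos] <- 1 - exp(log(arg) / tl)
    }
  }
  out
}

#' Pearson chi-squared normality statistic (P/df)
#'
#' Computes the Pearson goodness-of-fit statistic of a sample against the
#' normal distribution with estimated mean and standard deviation, using
#' `ceiling(2 * n^0.4)` equiprobable classes by default, and divides it by
#' its degrees of freedom (classes minus 3, accounting for the two estimated
#' moments). Lower values indicate closer agreement with normality; the
#' statistic is the criterion used to choose the Yeo-Johnson exponent.
#'
#' @param y Numeric vector, `length(y) >= 20`, non-degenerate.
#' @param n_classes Number of equiprobable classes, at least 4. Default
#'   `NULL` uses `ceiling(2 * length(y)^0.4)`. Fixing the class count makes
#'   the statistic scale exactly with replication of the sample.
#' @return Single numeric value, the Pearson statistic divided by df.
#' @examples
#' set.seed(1)
#' pearson_normality(rnorm(500))
#' @seealso [estimate_lambda()]
#' @export
pearson_normality <- function(y, n_classes = NULL) {
  stopifnot(is.numeric(y))
  y <- y[is.finite(y)]
  n <- length(y)
  if (n < 20L) {
    stop("`y` must contain at least 20 finite values", call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("`y` has zero variance", call. = FALSE)
  }
  k <- if (is.null(n_classes)) ceiling(2 * n^0.4) else as.integer(n_classes)
  if (k < 4L) {
    stop("`n_classes` must be at least 4", call. = FALSE)
  }
  pt <- nortest::pearson.test(y, n.classes = k, adjust = TRUE)
  unname(pt$statistic) / (k - 3)
}

#' Choose the Yeo-Johnson exponent by the Pearson P/df criterion
#'
#' Searches a grid of \eqn{\lambda} values and returns the one whose
#' Yeo-Johnson transform of `y` minimises [pearson_normality()]. Ties on the
#' criterion are broken in favour of the \eqn{\lambda} closest to 1 (the
#' identity), so an already-normal sample is not transformed needlessly.
#'
#' @param y Numeric vector to normalise (at least 20 finite values).
#' @param grid Numeric vector of candidate \eqn{\lambda} values. Default
#'   `seq(-5, 5, by = 0.01)`.
#' @param n_classes Optional fixed Pearson class count, passed to
#'   [pearson_normality()].
#' @return A `lambda_fit` object: a list with elements `lambda`,
#'   `stat_before` (Pearson P/df of the raw data), `stat_after` (of the
#'   transformed data), and `grid_stats` (a tibble of the profiled
#'   criterion).
#' @examples
#' set.seed(1)
#' y <- invert_yeo_johnson(rnorm(2000), lambda = 0.5)
#' estimate_lambda(y, grid = seq(-2, 2, by = 0.05))$lambda
#' @export
estimate_lambda <- function(y, grid = seq(-5, 5, by = 0.01),
                            n_classes = NULL) {
  stopifnot(is.numeric(y), is.numeric(grid), length(grid) >= 1L)
  y <- y[is.finite(y)]
  stat_before <- pearson_normality(y, n_classes = n_classes)
  stats_grid <- vapply(
    grid,
    function(l) pearson_normality(yeo_johnson(y, l), n_classes = n_classes),
    numeric(1)
  )
  best <- min(stats_grid)
  cand <- which(stats_grid <= best + .Machine$double.eps^0.5 * max(1, best))
  lambda <- grid[cand[which.min(abs(grid[cand] - 1))]]
  structure(
    list(
      lambda = lambda,
      stat_before = stat_before,
      stat_after = stats_grid[which(grid == lambda)[1L]],
      grid_stats = tibble::tibble(lambda = grid, stat = stats_grid)
    ),
    class = "lambda_fit"
  )
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("Yeo-Johnson lambda fit\n")
  cat(sprintf("  lambda      : %.4f\n", x$lambda))
  cat(sprintf("  Pearson P/df: %.4f (raw) -> %.4f (transformed)\n",
              x$stat_before, x$stat_after))
  invisible(x)
}

#' Yeo-Johnson normalisation report for a cohort table
#'
#' For each pulse parameter column and vessel type, estimates the
#' Yeo-Johnson exponent on the pooled pixel values, appends `<column>_yjt`
#' transformed columns to the table, and reports the normality statistic
#' before and after transformation.
#'
#' @param table A cohort data frame with a `vessel` column.
#' @param parameters Character vector of columns to normalise. Defaults to
#'   the amplitude and the four Fourier coefficients.
#' @param grid Candidate \eqn{\lambda} grid passed to [estimate_lambda()].
#' @return A list with `table` (the input plus `*_yjt` columns) and
#'   `report` (tibble: vessel, parameter, lambda, stat_before, stat_after).
#' @export
transform_cohort <- function(table,
                             parameters = c("hrwa", "a_n1", "b_n1", "a_n2", "b_n2"),
                             grid = seq(-5, 5, by = 0.01)) {
  stopifnot(is.data.frame(table), "vessel" %in% names(table))
  missing_cols <- setdiff(parameters, names(table))
  if (length(missing_cols) > 0) {
    stop("columns not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  report <- list()
  table <- tibble::as_tibble(table)
  for (vt in unique(table$vessel)) {
    idx <- table$vessel == vt
    for (p in parameters) {
      fit <- estimate_lambda(table[[p]][idx], grid = grid)
      col <- paste0(p, "_yjt")
      if (!col %in% names(table)) table[[col]] <- NA_real_
      table[[col]][idx] <- yeo_johnson(table[[p]][idx], fit$lambda)
      report[[length(report) + 1L]] <- tibble::tibble(
        vessel = vt, parameter = p, lambda = fit$lambda,
        stat_before = fit$stat_before, stat_after = fit$stat_after
      )
    }
  }
  list(table = table, report = dplyr::bind_rows(report))
}
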