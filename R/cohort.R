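# Cohort assembly, pressure conversions and the descriptive / univariate
# statistics reported for each pulse parameter by vessel and ICP group.

#' Convert ophthalmodynamometric force to induced intraocular pressure
#'
#' `IOP_i = 0.89 * ODF + IOP_b`, with the force in Meditron units and both
#' pressures in mmHg.
#'
#' @param odf_mu Non-negative force in Meditron units.
#' @param iop_b Baseline intraocular pressure (mmHg).
#' @return Induced intraocular pressure (mmHg).
#' @examples
#' odf_to_iop(10, 15) # 23.9
#' @export
odf_to_iop <- function(odf_mu, iop_b) {
  stopifnot(is.numeric(odf_mu), is.numeric(iop_b))
  if (any(odf_mu < 0, na.rm = TRUE)) {
    stop("ophthalmodynamometric force must be >= 0", call. = FALSE)
  }
  0.89 * odf_mu + iop_b
}

#' Classify intracranial pressure into the study groups
#'
#' An ICP of 25 cm water is the upper normal limit: values at or below 25
#' are `"normal"`, values above 25 are `"high"`.
#'
#' @param icp_cmH2O Non-negative intracranial pressure (cm water).
#' @return Character vector, `"normal"` or `"high"`.
#' @examples
#' assign_icp_group(c(9.5, 25, 25.5))
#' @export
assign_icp_group <- function(icp_cmH2O) {
  stopifnot(is.numeric(icp_cmH2O))
  if (any(icp_cmH2O < 0, na.rm = TRUE)) {
    stop("intracranial pressure must be >= 0", call. = FALSE)
  }
  ifelse(icp_cmH2O > 25, "high", "normal")
}

#' Descriptive statistics per parameter, vessel and ICP group
#'
#' Medians with interquartile ranges and ranges for each pulse parameter,
#' split by vessel type and ICP group, together with rank-sum comparisons:
#' within-group (artery vs vein at the same ICP level) and between-group
#' (normal vs high ICP for the same vessel) Wilcoxon tests with Bonferroni
#' adjustment over all comparisons performed in the call. Quartiles use
#' linear interpolation (type 7).
#'
#' @param table Cohort data frame with `vessel`, `icp_group` and the
#'   parameter columns.
#' @param parameters Character vector of columns to summarise.
#' @return A list with `summary` (tibble: parameter, vessel, icp_group, n,
#'   median, iqr, min, max, range) and `tests` (tibble: parameter,
#'   comparison, p_value, p_adjusted, m).
#' @export
summarize_cohort <- function(table,
                             parameters = c("hrwa", "a_n1", "b_n1", "a_n2", "b_n2")) {
  stopifnot(is.data.frame(table),
            all(c("vessel", "icp_group") %in% names(table)))
  parameters <- intersect(parameters, names(table))
  if (length(parameters) == 0) {
    stop("none of the requested parameter columns are present", call. = FALSE)
  }
  long <- table |>
    dplyr::select(dplyr::all_of(c("vessel", "icp_group", parameters))) |>
    tidyr::pivot_longer(dplyr::all_of(parameters),
                        names_to = "parameter", values_to = "value") |>
    dplyr::filter(is.finite(.data$value))

  summary <- long |>
    dplyr::group_by(.data$parameter, .data$vessel, .data$icp_group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$value),
      iqr = stats::IQR(.data$value, type = 7),
      min = min(.data$value),
      max = max(.data$value),
      range = max(.data$value) - min(.data$value),
      .groups = "drop"
    )

  empty <- tidyr::expand_grid(parameter = parameters,
                              vessel = unique(long$vessel),
                              icp_group = unique(long$icp_group)) |>
    dplyr::anti_join(summary, by = c("parameter", "vessel", "icp_group"))
  if (nrow(empty) > 0) {
    warning("empty summary cells omitted: ",
            paste(empty$parameter, empty$vessel, empty$icp_group,
                  sep = "/", collapse = ", "), call. = FALSE)
  }

  tests <- list()
  for (p in parameters) {
    lv <- long[long$parameter == p, ]
    grab <- function(vessel, group) {
      lv$value[lv$vessel == vessel & lv$icp_group == group]
    }
    cmp <- list(
      within_normal = list(grab("artery", "normal"), grab("vein", "normal")),
      within_high = list(grab("artery", "high"), grab("vein", "high")),
      between_artery = list(grab("artery", "normal"), grab("artery", "high")),
      between_vein = list(grab("vein", "normal"), grab("vein", "high"))
    )
    for (nm in names(cmp)) {
      x <- cmp[[nm]][[1]]; y <- cmp[[nm]][[2]]
      if (length(x) == 0 || length(y) == 0) next
      tests[[length(tests) + 1L]] <- tibble::tibble(
        parameter = p, comparison = nm, p_value = wilcoxon_test(x, y)
      )
    }
  }
  tests <- dplyr::bind_rows(tests)
  if (nrow(tests) > 0) {
    m <- nrow(tests)
    tests$p_adjusted <- bonferroni_adjust(tests$p_value, m)
    tests$m <- m
  }
  list(summary = summary, tests = tests)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided rank-sum p-value. For small samples (`n_x + n_y <= 12`) the
#' exact permutation distribution of the rank sum is enumerated (valid with
#' ties); otherwise the normal approximation with tie and continuity
#' corrections is used.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return Two-sided p-value.
#' @examples
#' wilcoxon_test(c(1, 2, 3), c(4, 5, 6)) # 0.1
#' @export
wilcoxon_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  if (nx + ny <= 12L) {
    r <- rank(c(x, y))
    obs <- sum(r[seq_len(nx)])
    idx <- utils::combn(nx + ny, nx)
    sums <- colSums(matrix(r[idx], nrow = nx))
    mu <- nx * (nx + ny + 1) / 2
    p <- mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
    return(min(p, 1))
  }
  stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` elementwise, for a family of `m` comparisons.
#'
#' @param p Numeric vector of p-values.
#' @param m Family size, at least `length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m) {
  stopifnot(is.numeric(p), m >= length(p))
  pmin(1, m * p)
}

#' Median-centred Levene (Brown-Forsythe) test for equal variances
#'
#' One-way ANOVA F statistic on the absolute deviations of each
#' observation from its group median, with the p-value from the F
#' distribution. Robust to the heavy-tailed amplitude distributions seen
#' in pulse data.
#'
#' @param groups List of at least 2 numeric vectors, each with at least 2
#'   values.
#' @return List with `statistic` (W) and `p_value`.
#' @examples
#' levene_test(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
levene_test <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  res <- car::leveneTest(y, g, center = stats::median)
  W <- res[["F value"]][1]
  p <- res[["Pr(>F)"]][1]
  if (is.na(W)) {
    # Degenerate deviations (all zero spread): no evidence against equality.
    W <- 0; p <- 1
  }
  list(statistic = unname(W), p_value = unname(p))
}
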