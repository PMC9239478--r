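# Vessel-by-ICP-group interaction plots: cell means and the
# main-effect / ordinal / disordinal classification of the pattern.

#' Cell means for a vessel-by-ICP interaction plot
#'
#' Arithmetic mean, standard error and count of a (transformed) pulse
#' parameter in each of the four (vessel, ICP group) cells.
#'
#' @param table Cohort data frame with `vessel`, `icp_group` and the
#'   parameter column.
#' @param parameter Name of the column to summarise.
#' @return An `interaction_cells` object: tibble with `vessel`,
#'   `icp_group`, `n`, `mean`, `se` and a `parameter` attribute.
#' @export
cell_means <- function(table, parameter) {
  stopifnot(is.data.frame(table),
            all(c("vessel", "icp_group") %in% names(table)))
  if (!parameter %in% names(table)) {
    stop("column `", parameter, "` not in table", call. = FALSE)
  }
  cells <- table |>
    dplyr::filter(is.finite(.data[[parameter]])) |>
    dplyr::group_by(.data$vessel, .data$icp_group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[parameter]]),
      se = stats::sd(.data[[parameter]]) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  expected <- tidyr::expand_grid(vessel = c("artery", "vein"),
                                 icp_group = c("normal", "high"))
  missing_cells <- dplyr::anti_join(expected, cells,
                                    by = c("vessel", "icp_group"))
  if (nrow(missing_cells) > 0) {
    stop("missing interaction cell(s): ",
         paste(missing_cells$vessel, missing_cells$icp_group,
               sep = "/", collapse = ", "), call. = FALSE)
  }
  if (any(cells$n < 2)) {
    stop("every interaction cell needs at least 2 observations",
         call. = FALSE)
  }
  structure(cells, class = c("interaction_cells", class(cells)),
            parameter = parameter)
}

# Welch t test from cell summaries (mean, se, n).
welch_from_cells <- function(m1, se1, n1, m2, se2, n2) {
  se <- sqrt(se1^2 + se2^2)
  if (se == 0) {
    return(list(statistic = 0, p_value = if (m1 == m2) 1 else 0))
  }
  t <- (m1 - m2) / se
  df <- se^4 / (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df))
}

#' Classify a vessel-by-ICP interaction pattern
#'
#' Operationalises the visual reading of an interaction plot. A main
#' effect at an ICP level is a significant Welch test of artery vs vein
#' cell means at that level ("sloped" connecting line). The interaction is
#' a Welch-type test of the difference-of-differences
#' `(vein - artery | normal) - (vein - artery | high)` with
#' Welch-Satterthwaite degrees of freedom; when significant it is
#' "disordinal" if the vein-minus-artery difference reverses sign between
#' the two ICP groups with both differences individually significant (the
#' connecting segments demonstrably cross between the two vessel
#' positions), otherwise "ordinal"; when not significant the pattern is
#' "none". Requiring both differences to be significant keeps a sign flip
#' that is indistinguishable from coincident segment endpoints from being
#' read as a crossing. Crossing is evaluated only between the two
#' categorical vessel positions, never by extrapolation.
#'
#' @param cells An [cell_means()] result (or a tibble with `vessel`,
#'   `icp_group`, `n`, `mean`, `se`).
#' @param alpha Significance level, default 0.05.
#' @return An `interaction_summary` object: list with
#'   `main_effect_normal`, `main_effect_high` (`"present"`/`"absent"`),
#'   `interaction` (`"none"`, `"ordinal"`, `"disordinal"`), and the
#'   supporting `p_values` (named: main_normal, main_high, interaction).
#' @export
classify_interaction <- function(cells, alpha = 0.05) {
  stopifnot(is.data.frame(cells),
            all(c("vessel", "icp_group", "n", "mean", "se") %in% names(cells)))
  cell <- function(v, g) cells[cells$vessel == v & cells$icp_group == g, ]
  an <- cell("artery", "normal"); ah <- cell("artery", "high")
  vn <- cell("vein", "normal"); vh <- cell("vein", "high")
  if (any(vapply(list(an, ah, vn, vh), nrow, integer(1)) != 1L)) {
    stop("all four (vessel, ICP group) cells are required", call. = FALSE)
  }

  main_n <- welch_from_cells(vn$mean, vn$se, vn$n, an$mean, an$se, an$n)
  main_h <- welch_from_cells(vh$mean, vh$se, vh$n, ah$mean, ah$se, ah$n)

  diff_n <- vn$mean - an$mean
  diff_h <- vh$mean - ah$mean
  D <- diff_n - diff_h
  seD <- sqrt(vn$se^2 + an$se^2 + vh$se^2 + ah$se^2)
  if (seD == 0) {
    p_int <- if (D == 0) 1 else 0
  } else {
    tD <- D / seD
    dfD <- seD^4 / (vn$se^4 / (vn$n - 1) + an$se^4 / (an$n - 1) +
                      vh$se^4 / (vh$n - 1) + ah$se^4 / (ah$n - 1))
    p_int <- 2 * stats::pt(-abs(tD), dfD)
  }

  crossing <- sign(diff_n) * sign(diff_h) < 0 &&
    main_n$p_value < alpha && main_h$p_value < alpha
  interaction <- if (p_int >= alpha) {
    "none"
  } else if (crossing) {
    "disordinal"
  } else {
    "ordinal"
  }
  structure(
    list(
      parameter = attr(cells, "parameter"),
      main_effect_normal = if (main_n$p_value < alpha) "present" else "absent",
      main_effect_high = if (main_h$p_value < alpha) "present" else "absent",
      interaction = interaction,
      p_values = c(main_normal = main_n$p_value,
                   main_high = main_h$p_value,
                   interaction = p_int)
    ),
    class = "interaction_summary"
  )
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat(sprintf("Interaction pattern%s:\n",
              if (!is.null(x$parameter)) paste0(" for ", x$parameter) else ""))
  cat(sprintf("  main effect (normal ICP): %s (p = %.3g)\n",
              x$main_effect_normal, x$p_values[["main_normal"]]))
  cat(sprintf("  main effect (high ICP)  : %s (p = %.3g)\n",
              x$main_effect_high, x$p_values[["main_high"]]))
  cat(sprintf("  interaction             : %s (p = %.3g)\n",
              x$interaction, x$p_values[["interaction"]]))
  invisible(x)
}

#' Classify the interaction pattern of every pulse parameter
#'
#' Runs [cell_means()] and [classify_interaction()] for each parameter
#' column and collects the classifications.
#'
#' @param table Cohort data frame.
#' @param parameters Columns to classify.
#' @param alpha Significance level.
#' @return Tibble: parameter, main_effect_normal, main_effect_high,
#'   interaction, p_main_normal, p_main_high, p_interaction.
#' @export
classify_cohort_interactions <- function(table,
                                         parameters = c("hrwa_yjt", "a_n1_yjt",
                                                        "b_n1_yjt", "a_n2_yjt",
                                                        "b_n2_yjt"),
                                         alpha = 0.05) {
  parameters <- intersect(parameters, names(table))
  purrr::map_dfr(parameters, function(p) {
    cls <- classify_interaction(cell_means(table, p), alpha = alpha)
    tibble::tibble(
      parameter = p,
      main_effect_normal = cls$main_effect_normal,
      main_effect_high = cls$main_effect_high,
      interaction = cls$interaction,
      p_main_normal = cls$p_values[["main_normal"]],
      p_main_high = cls$p_values[["main_high"]],
      p_interaction = cls$p_values[["interaction"]]
    )
  })
}
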