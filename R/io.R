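# Cohort CSV I/O, pipeline configuration and the end-to-end driver.

cohort_required_cols <- c(
  "subject_id", "eye", "hemiretina", "vessel", "pixel_id", "v_dist_mm",
  "odf_mu", "iop_b_mmHg", "iop_i_mmHg", "icp_cmH2O", "icp_group",
  "hrwa", "a_n1", "b_n1", "a_n2", "b_n2"
)

cohort_numeric_cols <- c("v_dist_mm", "odf_mu", "iop_b_mmHg", "iop_i_mmHg",
                         "icp_cmH2O", "hrwa", "a_n1", "b_n1", "a_n2", "b_n2")

#' Read a cohort analysis table from CSV
#'
#' Comma-separated, UTF-8, header row, `.` decimal, empty fields missing.
#' The schema is validated: required columns must be present, numeric
#' columns must parse, and the categorical columns must use the known
#' levels.
#'
#' @param path Path to the CSV file.
#' @return Tibble with one row per pixel.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  tb <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(tb) == 0 && ncol(tb) == 0) {
    stop("empty cohort file: ", path, call. = FALSE)
  }
  missing_cols <- setdiff(cohort_required_cols, names(tb))
  if (length(missing_cols) > 0) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in cohort_numeric_cols) {
    if (!is.numeric(tb[[col]])) {
      parsed <- suppressWarnings(as.numeric(tb[[col]]))
      bad <- which(!is.na(tb[[col]]) & is.na(parsed))
      if (length(bad) > 0) {
        stop("unparseable numeric value in column `", col, "`, row(s) ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
      tb[[col]] <- parsed
    }
  }
  check_levels <- function(col, levels) {
    bad <- setdiff(unique(stats::na.omit(tb[[col]])), levels)
    if (length(bad) > 0) {
      stop("invalid level(s) in `", col, "`: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  check_levels("vessel", c("artery", "vein"))
  check_levels("icp_group", c("normal", "high"))
  check_levels("eye", c("right", "left"))
  check_levels("hemiretina", c("superior", "inferior"))
  tb
}

#' Write a cohort analysis table to CSV
#'
#' @param table Cohort data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(cohort_required_cols, names(table))
  if (length(missing_cols) > 0) {
    stop("table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

pipeline_default_config <- function() {
  list(
    seed = 1L,
    design = list(),
    fit = list(enabled = FALSE, max_order = 4L, max_kept_order = 2L,
               n_pixels = 200L),
    transform = list(grid_min = -5, grid_max = 5, grid_step = 0.01),
    model = list(alpha = 0.05),
    output_dir = NULL,
    verbose = FALSE
  )
}

#' Read and validate a pipeline configuration
#'
#' YAML (or JSON) configuration with blocks `seed`, `design` (arguments to
#' [cohort_design()]), `fit` (`enabled`, `max_order`, `max_kept_order`,
#' `n_pixels`), `transform` (`grid_min`, `grid_max`, `grid_step`), `model`
#' (`alpha`), `output_dir` and `verbose`. Unknown keys are rejected.
#'
#' @param path Path to a YAML/JSON file, or `NULL` for the defaults.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- pipeline_default_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (!"seed" %in% names(user)) {
      stop("configuration must set an integer `seed`", call. = FALSE)
    }
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown configuration key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (k in names(user)) {
      if (is.list(cfg[[k]]) && k != "design") {
        sub_unknown <- setdiff(names(user[[k]]), names(cfg[[k]]))
        if (length(sub_unknown) > 0) {
          stop("unknown configuration key(s) in `", k, "`: ",
               paste(sub_unknown, collapse = ", "), call. = FALSE)
        }
        cfg[[k]][names(user[[k]])] <- user[[k]]
      } else {
        cfg[[k]] <- user[[k]]
      }
    }
  }
  if (is.null(cfg$seed) || !is.finite(cfg$seed)) {
    stop("configuration must set an integer `seed`", call. = FALSE)
  }
  design_unknown <- setdiff(names(cfg$design),
                            names(formals(cohort_design)))
  if (length(design_unknown) > 0) {
    stop("unknown design key(s): ",
         paste(design_unknown, collapse = ", "), call. = FALSE)
  }
  cfg
}

#' Run the full pulse-analysis pipeline
#'
#' Simulates a cohort from the configured design, optionally re-fits the
#' harmonic regression to a subset of simulated pixel series, estimates
#' Yeo-Johnson exponents and appends transformed columns, computes
#' descriptive statistics and rank-sum tests, fits the univariate and
#' interaction mixed models per vessel (with R-squared pair and
#' standardised betas), classifies the vessel-by-ICP interaction patterns,
#' and (when `output_dir` is set) writes the cohort table and all report
#' CSVs plus a plain-text run log.
#'
#' @param config Configuration list from [read_pipeline_config()], or a
#'   path to a YAML/JSON configuration file.
#' @return A list with `cohort` (table with `*_yjt` columns), `truth`,
#'   `pixel_fits` (NULL unless the fit stage is enabled), `lambda_report`,
#'   `summary`, `tests`, `models` (per vessel: fit, r2, betas, univariate
#'   slopes), `model_report` (Table-3-style tibble), `interactions`,
#'   `effect_grids`, and `config`.
#' @export
run_pipeline <- function(config = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config)) config <- read_pipeline_config(NULL)
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  t0 <- Sys.time()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  design <- stage("simulate", do.call(
    cohort_design, c(config$design, list(seed = as.integer(config$seed)))
  ))
  sim <- stage("simulate", simulate_cohort(design))
  cohort <- sim$table
  say("simulated ", nrow(cohort), " pixels")

  pixel_fits <- NULL
  if (isTRUE(config$fit$enabled)) {
    pixel_fits <- stage("fit", {
      set.seed(design$seed + 1L)
      pick <- cohort$pixel_id[sample.int(nrow(cohort),
                                         min(config$fit$n_pixels, nrow(cohort)))]
      series <- simulate_cohort_series(sim$truth, design, pixels = pick)
      fits <- fit_cohort_pixels(series, select_order = TRUE,
                                max_order = config$fit$max_order,
                                max_kept_order = config$fit$max_kept_order)
      # Replace the generator's pulse parameters with the re-fitted ones
      # for the pixels that were re-fitted.
      idx <- match(fits$pixel_id, cohort$pixel_id)
      for (col in c("a_n1", "b_n1", "a_n2", "b_n2", "hrwa")) {
        cohort[[col]][idx] <- fits[[col]]
      }
      fits
    })
    say("re-fitted ", nrow(pixel_fits), " pixel series")
  }

  grid <- seq(config$transform$grid_min, config$transform$grid_max,
              by = config$transform$grid_step)
  tr <- stage("transform", transform_cohort(cohort, grid = grid))
  cohort <- tr$table
  say("transformed; lambda range ",
      paste(round(range(tr$report$lambda), 3), collapse = " .. "))

  summ <- stage("summarize", summarize_cohort(cohort))

  models <- list()
  model_report <- list()
  effect_grids <- list()
  for (vt in c("vein", "artery")) {
    sub <- cohort[cohort$vessel == vt, , drop = FALSE]
    fit <- stage("model", fit_pulse_lmm(sub, response = "hrwa_yjt"))
    uni <- stage("model", univariate_effects(sub, response = "hrwa_yjt"))
    r2 <- r2_nakagawa(fit)
    betas <- standardized_betas(fit)
    models[[vt]] <- list(fit = fit, univariate = uni, r2 = r2, betas = betas)
    model_report[[vt]] <- dplyr::mutate(fit$coefficients, vessel = vt,
                                        response = "hrwa_yjt",
                                        .before = 1)
    effect_grids[[vt]] <- dplyr::mutate(effect_grid(fit), vessel = vt,
                                        .before = 1)
  }
  model_report <- dplyr::bind_rows(model_report)

  inter <- stage("interact", classify_cohort_interactions(
    cohort, alpha = config$model$alpha
  ))

  result <- list(
    cohort = cohort,
    truth = sim$truth,
    pixel_fits = pixel_fits,
    lambda_report = tr$report,
    summary = summ$summary,
    tests = summ$tests,
    models = models,
    model_report = model_report,
    interactions = inter,
    effect_grids = dplyr::bind_rows(effect_grids),
    config = config
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    outp <- function(f) file.path(config$output_dir, f)
    write_cohort_csv(cohort, outp("cohort.csv"))
    readr::write_csv(result$lambda_report, outp("lambda_report.csv"),
                     progress = FALSE)
    readr::write_csv(result$summary, outp("summary.csv"), progress = FALSE)
    readr::write_csv(result$tests, outp("tests.csv"), progress = FALSE)
    readr::write_csv(result$model_report, outp("model_report.csv"),
                     progress = FALSE)
    readr::write_csv(result$interactions, outp("interactions.csv"),
                     progress = FALSE)
    readr::write_csv(result$effect_grids, outp("effect_grids.csv"),
                     progress = FALSE)
    log_lines <- c(
      paste0("retinapulse ", as.character(utils::packageVersion("retinapulse"))),
      paste0("R ", R.version.string),
      paste0("seed: ", config$seed),
      paste0("pixels: ", nrow(cohort)),
      paste0("elapsed_s: ",
             round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    )
    writeLines(log_lines, outp("run_log.txt"))
  }
  result
}
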