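# End-to-end orchestration: simulate (or read) the study tables, run the
# model suites, and emit a consolidated results table plus per-model
# summaries, as CSV and JSON.

#' Build a pipeline configuration
#'
#' @param synthetic a [synthetic_config()] to simulate the study tables, or
#'   `NULL` when `paths` are given.
#' @param paths optional named list of input CSVs (`fish`, `transects`,
#'   `islands`, `length_weight`) read with the package readers.
#' @param models character vector of analysis suites to run, any of
#'   `"growth"`, `"growth_comparison"`, `"three_age"`, `"extremes"`,
#'   `"gsi"`, `"gsi_variants"`, `"correlation"`, `"population"`,
#'   `"drivers"`, `"rates"`, `"reproductive_potential"`.
#' @param mcmc an [mcmc_config()] used for every model.
#' @param allometry optional named list of [allometric_coefficients()]
#'   (required for the `"rates"` suite; the package ships no values).
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param seed integer seed for simulation and bootstrap steps.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), paths = NULL,
                            models = c("growth", "growth_comparison",
                                       "three_age", "extremes", "gsi",
                                       "correlation", "population",
                                       "drivers"),
                            mcmc = mcmc_config(), allometry = NULL,
                            out_dir = NULL, seed = 1) {
  if (is.null(synthetic) && is.null(paths)) {
    abort_config("pipeline_config needs either a synthetic config or input paths")
  }
  if (!is.null(paths)) {
    missing <- !vapply(paths, file.exists, logical(1))
    if (any(missing)) {
      abort_config(sprintf("input path(s) do not exist: %s",
                           paste(unlist(paths[missing]), collapse = ", ")))
    }
  }
  structure(
    list(synthetic = synthetic, paths = paths, models = models, mcmc = mcmc,
         allometry = allometry, out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

summary_rows <- function(tbl, model, quantity_col = "quantity") {
  dplyr::bind_cols(tibble::tibble(model = model), tbl)
}

#' Run the full analysis pipeline
#'
#' Executes the configured suites over simulated or read study tables:
#' the growth suite (offset VBGF, variant comparison, three-age
#' reparameterization, upper-quartile extremes), the GSI suite (length /
#' age / collection-day variants and the growth-GSI correlation), the
#' population suite (hurdle-gamma density and biomass, ex-Gaussian size
#' structure, size-frequency table), the drivers suite (seabird density,
#' tissue nitrogen, environmental covariates), and optional functional-rate
#' propagation. Any single model failure is recorded and the pipeline
#' continues.
#'
#' @param config a [pipeline_config()].
#' @return an `fd_report` list: `data` (the study tables), `fits`,
#'   `results` (one consolidated tibble of every derived quantity),
#'   `diagnostics`, `errors`, and `truth` (for synthetic runs). Written to
#'   `out_dir` as CSV/JSON when configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$paths)) {
    data <- list(
      fish = read_fish_table(config$paths$fish),
      transects = read_transect_table(config$paths$transects),
      islands = if (!is.null(config$paths$islands))
        read_island_table(config$paths$islands),
      length_weight = if (!is.null(config$paths$length_weight))
        read_length_weight(config$paths$length_weight)
    )
    truth <- NULL
  } else {
    data <- simulate_study(config$synthetic)
    truth <- data$truth
  }
  mcmc <- config$mcmc
  fits <- list()
  results <- list()
  errors <- list()
  run_step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      message(sprintf("pipeline step `%s` failed: %s", name,
                      conditionMessage(e)))
      NULL
    })
  }
  has <- function(m) m %in% config$models

  if (has("growth")) run_step("growth", {
    fits$growth <- fit_vbgf(data$fish, variant = "offset_k", mcmc = mcmc)
    d <- posterior_draws(fits$growth)
    results$growth <- dplyr::bind_rows(
      summary_rows(derived_summary(d$k, "k_rat_infested"), "growth"),
      summary_rows(derived_summary(d$k + d$k_b, "k_rat_free"), "growth"),
      summary_rows(derived_summary(d$k_b, "k_offset"), "growth"),
      summary_rows(percent_growth_difference(fits$growth), "growth"),
      summary_rows(
        dplyr::mutate(
          length_at_age_contrast(fits$growth, c(2, 4, 6)),
          quantity = sprintf("length_diff_age_%g", .data$age),
          age = NULL
        ),
        "growth_length_at_age"
      )
    )
  })
  if (has("growth_comparison")) run_step("growth_comparison", {
    fits$growth_no_offset <- fit_vbgf(data$fish, variant = "no_offset",
                                       mcmc = mcmc)
    fits$growth_offset_Linf <- fit_vbgf(data$fish,
                                         variant = "offset_k_and_Linf",
                                         mcmc = mcmc)
    cmp <- compare_models(
      offset_k = fits$growth, no_offset = fits$growth_no_offset,
      offset_k_and_Linf = fits$growth_offset_Linf
    )
    results$growth_comparison <- dplyr::bind_cols(
      tibble::tibble(model = "growth_comparison"),
      dplyr::rename(cmp, candidate = "model")
    )
  })
  if (has("three_age")) run_step("three_age", {
    fits$three_age <- fit_three_age_vbgf(data$fish, mcmc = mcmc)
    results$three_age <- summary_rows(
      dplyr::mutate(
        length_at_age_contrast(fits$three_age, c(2, 4, 6)),
        quantity = sprintf("length_diff_age_%g", .data$age),
        age = NULL
      ),
      "three_age_contrast"
    )
  })
  if (has("extremes")) run_step("extremes", {
    for (metric in c("age", "length")) {
      ex <- upper_quartile_extremes(data$fish, metric = metric, mcmc = mcmc)
      fits[[paste0("extremes_", metric)]] <- ex
      results[[paste0("extremes_", metric)]] <- summary_rows(
        ex$contrast, paste0("extremes_", metric)
      )
    }
  })
  if (has("gsi")) run_step("gsi", {
    fits$gsi <- fit_gsi_model(data$fish, covariate = "length", mcmc = mcmc)
    results$gsi <- summary_rows(fits$gsi$gsi, "gsi")
  })
  if (has("gsi_variants")) run_step("gsi_variants", {
    fits$gsi_age <- fit_gsi_model(data$fish, covariate = "age", mcmc = mcmc)
    fits$gsi_day <- fit_gsi_model(data$fish, covariate = "length",
                                   include_day = TRUE, mcmc = mcmc)
    results$gsi_variants <- dplyr::bind_rows(
      summary_rows(treatment_contrast(fits$gsi_age), "gsi_age"),
      summary_rows(treatment_contrast(fits$gsi_day), "gsi_day")
    )
  })
  if (has("correlation")) run_step("correlation", {
    if (is.null(fits$growth)) {
      fits$growth <- fit_vbgf(data$fish, variant = "offset_k", mcmc = mcmc)
    }
    if (is.null(fits$gsi)) {
      fits$gsi <- fit_gsi_model(data$fish, covariate = "length", mcmc = mcmc)
    }
    cor_tbl <- growth_gsi_correlation(data$fish, fits$growth, fits$gsi,
                                      seed = config$seed)
    results$correlation <- tibble::tibble(
      model = "correlation", quantity = "growth_gsi_correlation",
      median = cor_tbl$correlation,
      hpdi95_low = cor_tbl$conf_low, hpdi95_high = cor_tbl$conf_high
    )
  })
  if (has("population")) run_step("population", {
    ts <- transect_summaries(data$transects, data$length_weight)
    fits$density <- fit_treatment_effect(ts, "density_per_transect",
                                          family = "hurdle_gamma",
                                          mcmc = mcmc)
    fits$biomass <- fit_treatment_effect(ts, "biomass_g",
                                          family = "hurdle_gamma",
                                          mcmc = mcmc)
    fits$size <- fit_size_structure(data$transects, mcmc = mcmc)
    results$population <- dplyr::bind_rows(
      summary_rows(back_transform_ratio(fits$density), "density"),
      summary_rows(derived_summary(posterior_draws(fits$density)$p_zero,
                                   "zero_probability"), "density"),
      summary_rows(back_transform_ratio(fits$biomass), "biomass"),
      summary_rows(fits$size$size, "size_structure")
    )
  })
  if (has("drivers")) run_step("drivers", {
    fits$seabirds <- fit_treatment_effect(data$islands, "seabird_density",
                                           family = "lognormal", mcmc = mcmc)
    fits$percent_N <- fit_treatment_effect(data$fish, "percent_N",
                                            family = "gaussian", mcmc = mcmc)
    fits$d15N <- fit_treatment_effect(data$fish, "d15N",
                                       family = "gaussian", mcmc = mcmc)
    results$drivers <- dplyr::bind_rows(
      summary_rows(back_transform_ratio(fits$seabirds), "seabird_density"),
      summary_rows(treatment_contrast(fits$percent_N), "percent_N"),
      summary_rows(treatment_contrast(fits$d15N), "d15N")
    )
  })
  if (has("rates")) run_step("rates", {
    if (is.null(config$allometry)) {
      abort_config("the rates suite needs user-supplied allometric coefficients")
    }
    if (is.null(fits$growth)) {
      fits$growth <- fit_vbgf(data$fish, variant = "offset_k", mcmc = mcmc)
    }
    results$rates <- dplyr::bind_rows(lapply(
      names(config$allometry), function(nm) {
        summary_rows(
          propagate_function(fits$growth, age = 4, config$allometry[[nm]]),
          paste0("rate_", nm)
        )
      }
    ))
  })
  if (has("reproductive_potential")) run_step("reproductive_potential", {
    if (is.null(fits$gsi)) {
      fits$gsi <- fit_gsi_model(data$fish, covariate = "length", mcmc = mcmc)
    }
    results$reproductive_potential <- summary_rows(
      reproductive_potential(data$transects, fits$gsi, data$length_weight),
      "reproductive_potential"
    )
  })

  results_tbl <- if (length(results)) dplyr::bind_rows(results) else
    tibble::tibble(model = character(), quantity = character())
  diagnostics <- dplyr::bind_rows(lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (inherits(f, "fd_extremes")) f <- f$fit
    if (!inherits(f, "fd_fit")) return(NULL)
    dplyr::bind_cols(tibble::tibble(model = nm), f$diagnostics)
  }))
  report <- structure(
    list(data = data[c("fish", "transects", "islands", "length_weight")],
         fits = fits, results = results_tbl, diagnostics = diagnostics,
         errors = errors, truth = truth),
    class = "fd_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Emits `results.csv` (the consolidated quantity table), `results.json`,
#' `diagnostics.csv`, a markdown `report.md`, and — for synthetic runs —
#' `truth.json` with the generating parameters.
#'
#' @param report an `fd_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$results, file.path(out_dir, "results.csv"), na = "")
  jsonlite::write_json(report$results, file.path(out_dir, "results.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  readr::write_csv(report$diagnostics, file.path(out_dir, "diagnostics.csv"),
                   na = "")
  if (!is.null(report$truth)) {
    jsonlite::write_json(unclass(report$truth),
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  writeLines(report_markdown(report), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Render a report as markdown lines
#'
#' @param report an `fd_report`.
#' @return character vector of markdown lines.
#' @export
report_markdown <- function(report) {
  lines <- c("# Demographic analysis report", "")
  if (nrow(report$results) == 0) {
    lines <- c(lines, "No models were run.")
    return(lines)
  }
  for (m in unique(report$results$model)) {
    sub <- dplyr::filter(report$results, .data$model == m)
    lines <- c(lines, sprintf("## %s", m), "")
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      qty <- r$quantity %||% ""
      if (!is.null(r$median) && !is.na(r$median)) {
        ints <- ""
        if (!is.null(r$hpdi95_low) && !is.na(r$hpdi95_low)) {
          ints <- sprintf(" (95%% HPDI %.3f to %.3f)", r$hpdi95_low,
                          r$hpdi95_high)
        }
        lines <- c(lines, sprintf("- %s: %.4f%s", qty, r$median, ints))
      }
    }
    lines <- c(lines, "")
  }
  if (length(report$errors)) {
    lines <- c(lines, "## Failed steps", "",
               sprintf("- %s: %s", names(report$errors),
                       unlist(report$errors)), "")
  }
  lines
}

#' @export
print.fd_report <- function(x, ...) {
  cat(sprintf("<fd_report> %d fitted models, %d result rows, %d failed steps\n",
              length(x$fits), nrow(x$results), length(x$errors)))
  print(x$results, n = 30)
  invisible(x)
}
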