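#' Configuration for the full analysis pipeline
#'
#' Collects the settings for [run_icm_pipeline()]: an input measurement
#' CSV or a synthetic-generator configuration, which size metrics to
#' analyse, the grouping key and significance level for the pooling
#' decision, and the stochastic stage settings. One global seed
#' deterministically spawns a distinct seed per stage
#' (`stage_seed = seed + 1000 * stage_rank`), so any stage can be re-run
#' in isolation and reproduce its output.
#'
#' @param input Path to a measurement CSV (see
#'   [read_molar_measurements()]), or `NULL` to simulate.
#' @param generator A [generator_config()] used when `input` is `NULL`.
#' @param metrics Character vector of size metrics, subset of
#'   `c("length", "area")`; both by default, since the length (molar
#'   module component) and area (inhibitory cascade) phenotypes are
#'   analysed in parallel.
#' @param group Grouping column for the pooling decision
#'   (default `"locality"`).
#' @param alpha Significance level for the pooling decision.
#' @param n_draws,burn_in,thin Posterior sampler settings (see
#'   [fit_size_posterior()]).
#' @param reference_boot Bootstrap resamples for [reference_intervals()].
#' @param samplesize_reps Pseudoreplicates per N for
#'   [sample_size_simulation()].
#' @param samplesize_grid Grid of sub-sample sizes (`NULL` = `2:(n-1)`).
#' @param composite_grid Teeth-per-position grid for
#'   [composite_simulation()].
#' @param outer_reps,inner_reps Composite-simulation replicate counts.
#' @param run_sims Run the two resampling simulations (default `TRUE`).
#' @param seed Global integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, generator = generator_config(),
                            metrics = c("length", "area"),
                            group = "locality", alpha = 0.05,
                            n_draws = 1000, burn_in = 500000, thin = 1000,
                            reference_boot = 10000,
                            samplesize_reps = 10000, samplesize_grid = NULL,
                            composite_grid = 1:50,
                            outer_reps = 1000, inner_reps = 1000,
                            run_sims = TRUE, seed = 1) {
  metrics <- match.arg(metrics, c("length", "area"), several.ok = TRUE)
  structure(
    list(input = input, generator = generator, metrics = metrics,
         group = group, alpha = alpha, n_draws = n_draws,
         burn_in = burn_in, thin = thin, reference_boot = reference_boot,
         samplesize_reps = samplesize_reps,
         samplesize_grid = samplesize_grid,
         composite_grid = composite_grid, outer_reps = outer_reps,
         inner_reps = inner_reps, run_sims = run_sims,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

stage_seed <- function(config, rank) config$seed + 1000L * rank

#' Run the full molar-ratio analysis pipeline
#'
#' Executes the stages in order: data (read or simulate, average
#' replicates, repeatability), ratios, pooling decision, cascade test
#' (RMA regression, posterior fit, measurement-error adjustment, six
#' predictions), and the two resampling simulations. Each stage uses a
#' seed spawned deterministically from the global seed, so identical
#' configs produce identical bundles.
#'
#' When the sample is too small for the simulations (n < 10) that stage
#' is skipped with a recorded note and the earlier results are still
#' returned.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, ratio tables, CV
#'   report, prediction report, simulation tables and a JSON-free text
#'   summary are written there as CSVs/text.
#' @return A list of class `icm_pipeline_result` with elements
#'   `measurements, repeatability, rows, ratios, pooling, rma, posterior,
#'   predictions, reference, sample_size, composite, adequacy, notes`
#'   (per-metric where applicable), plus the `config`.
#' @export
run_icm_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  notes <- character()

  if (!is.null(config$input)) {
    measurements <- read_molar_measurements(config$input)
  } else {
    rows0 <- simulate_molar_rows(config$generator,
                                 seed = stage_seed(config, 1L))
    measurements <- add_replicate_noise(rows0,
                                        seed = stage_seed(config, 2L))
  }
  collapsed <- average_replicates(measurements)

  per_metric <- purrr::map(config$metrics, function(metric) {
    repeatability <- molar_repeatability(
      measurements, measure = if (metric == "area") "area" else "length")
    rows <- build_row_sizes(collapsed, metric = metric)
    ratios <- compute_ratios(rows)

    pooling <- tryCatch(
      pooling_decision(ratios, group = config$group, alpha = config$alpha),
      icmolar_error = function(e) {
        notes <<- c(notes, paste0("pooling skipped (", metric, "): ",
                                  conditionMessage(e)))
        NULL
      }
    )

    rma <- rma_regression(ratios$r21, ratios$r31,
                          seed = stage_seed(config, 3L))
    posterior <- tryCatch(
      {
        p <- fit_size_posterior(rows, n_draws = config$n_draws,
                                burn_in = config$burn_in,
                                thin = config$thin,
                                seed = stage_seed(config, 4L))
        adjust_measurement_error(p, repeatability)
      },
      icmolar_error = function(e) {
        notes <<- c(notes, paste0("posterior skipped (", metric, "): ",
                                  conditionMessage(e)))
        NULL
      }
    )
    predictions <- if (is.null(posterior)) NULL else
      evaluate_icm_predictions(posterior)

    sims <- list(reference = NULL, sample_size = NULL, composite = NULL,
                 adequacy = NULL)
    if (config$run_sims) {
      if (nrow(ratios) < 10) {
        notes <<- c(notes, sprintf(
          "simulations skipped (%s): n = %d is below the minimum of 10.",
          metric, nrow(ratios)))
      } else {
        reference <- reference_intervals(ratios,
                                         n_boot = config$reference_boot,
                                         seed = stage_seed(config, 5L))
        grid <- config$samplesize_grid %||% 2:(nrow(ratios) - 1)
        sample_size <- sample_size_simulation(
          ratios, reference, n_grid = grid, reps = config$samplesize_reps,
          seed = stage_seed(config, 6L))
        composite <- composite_simulation(
          rows, reference, n_grid = config$composite_grid,
          outer_reps = config$outer_reps, inner_reps = config$inner_reps,
          seed = stage_seed(config, 7L))
        adequacy <- dplyr::bind_rows(
          adequacy_threshold(sample_size, "mean"),
          adequacy_threshold(sample_size, "sd")
        )
        sims <- list(reference = reference, sample_size = sample_size,
                     composite = composite, adequacy = adequacy)
      }
    }
    c(list(metric = metric, repeatability = repeatability, rows = rows,
           ratios = ratios, pooling = pooling, rma = rma,
           posterior = posterior, predictions = predictions), sims)
  })
  names(per_metric) <- config$metrics

  result <- structure(
    list(measurements = measurements, metrics = per_metric,
         notes = notes, config = config),
    class = "icm_pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (metric in names(result$metrics)) {
    m <- result$metrics[[metric]]
    readr::write_csv(
      dplyr::select(m$ratios, "specimen_id", "locality", "sex", "metric",
                    "m1", "m2", "m3", "r21", "r31", "rel1", "rel2", "rel3"),
      file.path(out_dir, paste0("ratios_", metric, ".csv")))
    if (!is.null(m$predictions)) {
      readr::write_csv(tibble::as_tibble(m$predictions),
                       file.path(out_dir, paste0("predictions_", metric, ".csv")))
    }
    if (!is.null(m$pooling)) {
      readr::write_csv(m$pooling$cv,
                       file.path(out_dir, paste0("cv_", metric, ".csv")))
      readr::write_csv(m$pooling$tests,
                       file.path(out_dir, paste0("group_tests_", metric, ".csv")))
    }
    if (!is.null(m$sample_size)) {
      readr::write_csv(tibble::as_tibble(m$sample_size),
                       file.path(out_dir, paste0("sample_size_sim_", metric, ".csv")))
      readr::write_csv(tibble::as_tibble(m$composite),
                       file.path(out_dir, paste0("composite_sim_", metric, ".csv")))
      readr::write_csv(m$adequacy,
                       file.path(out_dir, paste0("adequacy_", metric, ".csv")))
    }
  }
  summary_lines <- utils::capture.output(print(result))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(result)
}

#' @export
print.icm_pipeline_result <- function(x, ...) {
  cat("Molar-ratio cascade analysis (seed ", x$config$seed, ")\n", sep = "")
  for (metric in names(x$metrics)) {
    m <- x$metrics[[metric]]
    cat("\n== metric:", metric, "==\n")
    cat(sprintf("  n = %d complete rows; repeatability = %.3f\n",
                nrow(m$rows), m$repeatability))
    if (!is.null(m$pooling)) {
      cat("  pooling decision:", m$pooling$decision, "\n")
    }
    cat(sprintf("  RMA slope %.3f [%.3f, %.3f], intercept %.3f [%.3f, %.3f]\n",
                m$rma$slope, m$rma$slope_ci[1], m$rma$slope_ci[2],
                m$rma$intercept, m$rma$intercept_ci[1], m$rma$intercept_ci[2]))
    if (!is.null(m$predictions)) {
      cons <- m$predictions$consistent
      cat(sprintf("  cascade predictions consistent: %d of 6%s\n",
                  sum(cons, na.rm = TRUE),
                  if (any(is.na(cons))) sprintf(" (%d unstable)",
                                                sum(is.na(cons))) else ""))
    }
    if (!is.null(m$adequacy)) {
      ad <- m$adequacy
      cat("  adequacy thresholds:",
          paste(sprintf("%s/%s: %s", ad$ratio, ad$statistic,
                        ifelse(is.na(ad$n_adequate), "none",
                               ad$n_adequate)), collapse = ", "), "\n")
    }
  }
  if (length(x$notes) > 0) {
    cat("\nNotes:\n")
    for (nt in x$notes) cat("  -", nt, "\n")
  }
  invisible(x)
}
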