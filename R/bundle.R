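# Report-bundle writers: the file-oriented surface of the pipeline. A thin
# Rscript front end over these functions lives in inst/cli/pulsetrace.R.

write_csv_units <- function(x, path, units) {
  # leading comment line carries column units; readr skips it on read
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", units), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset bundle
#'
#' Runs the tracer-fate simulator and writes the measurement records, the
#' pool table, the per-plot ground truth and the true node states as CSV
#' files (`measurements.csv`, `pools.csv`, `truth_tracer.csv`,
#' `truth_nodes.csv`). Outputs are deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param noise Add delta-scale measurement noise.
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulation_bundle <- function(config = sim_config(), out_dir,
                                    noise = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(config, noise = noise)
  meas <- sim$measurements |>
    dplyr::rename(delta15n_permil = "delta15n",
                  n_content_fraction = "n_content")
  paths <- c(
    measurements = file.path(out_dir, "measurements.csv"),
    pools = file.path(out_dir, "pools.csv"),
    truth_tracer = file.path(out_dir, "truth_tracer.csv"),
    truth_nodes = file.path(out_dir, "truth_nodes.csv"))
  write_csv_units(meas, paths["measurements"],
                  paste0("delta15n_permil [permil vs air N2], ",
                         "n_content_fraction [g N / g dry mass]; seed ",
                         config$seed))
  write_csv_units(config$pools, paths["pools"], "m_pool_gN_m2 [g N m^-2]")
  write_csv_units(sim$truth$tracer, paths["truth_tracer"],
                  paste0("frac_applied [fraction of dose], tracer_gN_m2 ",
                         "[g 15N m^-2]; seed ", config$seed))
  write_csv_units(sim$truth$nodes, paths["truth_nodes"],
                  paste0("frac_applied [fraction of dose]; seed ",
                         config$seed))
  invisible(paths)
}

#' Write the analysis report bundle
#'
#' Runs the full analysis on a set of measurement records and writes the
#' enrichment table, recovery table, annual totals, paired t-tests, the
#' flow ledger over the full observation interval (CSV + DOT), and, when
#' `fit_trend = TRUE`, the candidate-model AIC table and the coefficients
#' of the best trend model.
#'
#' @param measurements Measurement records (see [enrichment_table()]).
#' @param pools Pool table (`compartment, year, m_pool_gN_m2`).
#' @param out_dir Output directory (created if needed).
#' @param tracer A [tracer_application()].
#' @param mode Aggregation mode for the tables.
#' @param fit_trend Also fit and report the trend model (slower).
#' @param alpha Significance level for the paired tests.
#' @return Invisibly, the named vector of file paths.
#' @export
write_analysis_bundle <- function(measurements, pools, out_dir,
                                  tracer = tracer_application(),
                                  mode = "per_plot_mean",
                                  fit_trend = FALSE, alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- recovery_table(measurements, pools, tracer, mode = mode)
  tot <- annual_totals(rec)
  tests <- paired_delta_tests(measurements, alpha = alpha)
  yrs <- range(rec$year)
  ledger <- infer_flows(compartment_deltas(rec, yrs[1], yrs[2]))

  paths <- c(recovery = file.path(out_dir, "recovery_table.csv"),
             totals = file.path(out_dir, "annual_totals.csv"),
             tests = file.path(out_dir, "paired_tests.csv"),
             ledger = file.path(out_dir, "flow_ledger.csv"),
             dot = file.path(out_dir, "flow_ledger.dot"))
  write_csv_units(round_report(rec), paths["recovery"],
                  "enrichment [permil], recovery [% of applied tracer]")
  write_csv_units(round_report(tot), paths["totals"],
                  "total_recovery [% of applied tracer]")
  write_csv_units(round_report(tests), paths["tests"],
                  paste0("paired t-test, alpha = ", alpha))
  write_csv_units(
    round_report(tibble::as_tibble(ledger)), paths["ledger"],
    sprintf("flow [%% of applied tracer], interval %d-%d", yrs[1], yrs[2]))
  flows_to_dot(ledger, paths["dot"])

  if (fit_trend) {
    trend_data <- measurements |>
      enrichment_records() |>
      dplyr::mutate(compartment = main_compartment(.data$compartment)) |>
      dplyr::filter(!is.na(.data$compartment))
    sel <- select_model(trend_data)
    paths["model_selection"] <- file.path(out_dir, "model_selection.csv")
    paths["trend_coefficients"] <- file.path(out_dir,
                                             "trend_coefficients.csv")
    write_csv_units(round_report(sel$table, 3), paths["model_selection"],
                    "AIC by maximum likelihood; weight = Akaike weight")
    write_csv_units(round_report(tidy(sel$best), 3),
                    paths["trend_coefficients"],
                    "log-link scale; REML fit of the best candidate")
  }
  invisible(paths)
}

# report-time rounding (2 decimals by default); computation stays at full
# precision everywhere else
round_report <- function(x, digits = 2) {
  dplyr::mutate(x, dplyr::across(dplyr::where(is.numeric),
                                 ~ round(.x, digits)))
}

#' Per-plot enrichment records
#'
#' The per-plot analogue of [enrichment_table()]: one enrichment value per
#' labelled record (paired with its same-plot reference), the long-format
#' input of the trend model.
#'
#' @inheritParams enrichment_table
#' @return Tibble `plot, year, compartment, enrichment` (per mil).
#' @export
enrichment_records <- function(data, fallback = TRUE) {
  check_measurements(data)
  pair_measurements(data, fallback = fallback) |>
    dplyr::mutate(enrichment = enrichment(.data$delta15n,
                                          .data$delta15n_ref)) |>
    dplyr::select("plot", "year", "compartment", "enrichment")
}
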