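# Per-plot paired enrichment/recovery tables, annual totals and paired
# t-tests: the orchestration layer between raw measurement records and
# reportable results.

check_measurements <- function(data) {
  need <- c("plot", "role", "year", "compartment", "delta15n")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("measurement data lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(data$role), c("labelled", "reference"))
  if (length(bad_role)) {
    stop("`role` must be 'labelled' or 'reference', found: ",
         paste(bad_role, collapse = ", "), call. = FALSE)
  }
  check_compartments(data$compartment)
  dup <- dplyr::count(data, .data$plot, .data$role, .data$year,
                      .data$compartment) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate measurement cells: ",
         paste(dup$plot, dup$role, dup$year, dup$compartment,
               sep = "/", collapse = ", "),
         call. = FALSE)
  }
  if ("n_content" %in% names(data) &&
      any(stats::na.omit(data$n_content) < 0 |
          stats::na.omit(data$n_content) > 1)) {
    stop("`n_content` must be a mass fraction in [0, 1]", call. = FALSE)
  }
  invisible(data)
}

# Pair each labelled record with its same-plot reference; fall back to the
# compartment-year mean reference delta when the pair is missing.
pair_measurements <- function(data, fallback = TRUE) {
  lab <- dplyr::filter(data, .data$role == "labelled")
  ref <- dplyr::filter(data, .data$role == "reference") |>
    dplyr::select("plot", "year", "compartment", delta15n_ref = "delta15n")
  ref_mean <- ref |>
    dplyr::summarise(delta15n_ref_mean = mean(.data$delta15n_ref),
                     .by = c("year", "compartment"))
  paired <- lab |>
    dplyr::left_join(ref, by = c("plot", "year", "compartment")) |>
    dplyr::left_join(ref_mean, by = c("year", "compartment"))
  unmatched <- dplyr::filter(paired, is.na(.data$delta15n_ref))
  if (nrow(unmatched) && !fallback) {
    stop("labelled records without a same-plot reference: ",
         paste(unmatched$plot, unmatched$year, unmatched$compartment,
               sep = "/", collapse = ", "),
         call. = FALSE)
  }
  paired |>
    dplyr::mutate(
      ref_fallback = is.na(.data$delta15n_ref),
      delta15n_ref = dplyr::coalesce(.data$delta15n_ref,
                                     .data$delta15n_ref_mean)
    ) |>
    dplyr::select(-"delta15n_ref_mean") |>
    (\(d) {
      if (any(is.na(d$delta15n_ref))) {
        bad <- d[is.na(d$delta15n_ref), ]
        stop("no reference at all for: ",
             paste(bad$year, bad$compartment, sep = "/", collapse = ", "),
             call. = FALSE)
      }
      d
    })()
}

se_or_na <- function(x) {
  if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
}

#' Per-compartment, per-year 15N enrichment table
#'
#' Computes the per-mil enrichment of labelled over reference subplots for
#' every compartment and sampling year. Two aggregation modes are offered:
#' `per_plot_mean` (default) applies the enrichment formula to each plot pair
#' and then averages over plots (mean with standard error of the mean);
#' `mean_of_deltas` first averages the labelled and reference deltas over
#' plots and applies the formula to the two group means. The modes agree
#' exactly when all plots share one reference delta.
#'
#' @param data Measurement records: a data frame with columns `plot`, `role`
#'   (`"labelled"`/`"reference"`), `year`, `compartment`, `delta15n`
#'   (per mil) and optionally `n_content`.
#' @param mode Aggregation mode, see above.
#' @param fallback When a labelled record has no same-plot reference, use the
#'   compartment-year mean reference delta (default `TRUE`); with `FALSE`
#'   unmatched records are an error.
#' @return A tibble `compartment, year, n_plots, enrichment_mean,
#'   enrichment_se` (per mil; SE is `NA` for `mean_of_deltas` and when fewer
#'   than two plots contribute).
#' @export
enrichment_table <- function(data, mode = c("per_plot_mean", "mean_of_deltas"),
                             fallback = TRUE) {
  mode <- match.arg(mode)
  check_measurements(data)
  paired <- pair_measurements(data, fallback = fallback)
  if (mode == "per_plot_mean") {
    paired |>
      dplyr::mutate(en = enrichment(.data$delta15n, .data$delta15n_ref)) |>
      dplyr::summarise(
        n_plots = dplyr::n(),
        enrichment_mean = mean(.data$en),
        enrichment_se = se_or_na(.data$en),
        .by = c("compartment", "year")
      ) |>
      dplyr::arrange(.data$compartment, .data$year)
  } else {
    paired |>
      dplyr::summarise(
        n_plots = dplyr::n(),
        d_lab = mean(.data$delta15n),
        d_ref = mean(.data$delta15n_ref),
        .by = c("compartment", "year")
      ) |>
      dplyr::mutate(enrichment_mean = enrichment(.data$d_lab, .data$d_ref),
                    enrichment_se = NA_real_) |>
      dplyr::select("compartment", "year", "n_plots",
                    "enrichment_mean", "enrichment_se") |>
      dplyr::arrange(.data$compartment, .data$year)
  }
}

#' Per-compartment, per-year 15N tracer recovery table
#'
#' Converts paired delta measurements into recovered tracer mass and the
#' percentage of the applied tracer, per plot, then aggregates over plots
#' (mean and standard error). Labelled pools whose atom percent falls below
#' their reference produce negative per-plot recoveries; these are kept (they
#' signal measurement noise) and flagged with a warning.
#'
#' @inheritParams enrichment_table
#' @param pools Pool-mass series from [pool_series()] (columns `compartment`,
#'   `year`, `m_pool_gN_m2`); an entry must exist for every measured
#'   compartment-year.
#' @param tracer A [tracer_application()].
#' @param r_standard Standard ratio for delta conversions.
#' @return A tibble `compartment, year, n_plots, enrichment_mean,
#'   enrichment_se, recovery_mass_gN_m2, recovery_mean, recovery_se` with
#'   recovery columns in % of the applied tracer.
#' @export
recovery_table <- function(data, pools, tracer = tracer_application(),
                           mode = c("per_plot_mean", "mean_of_deltas"),
                           fallback = TRUE, r_standard = R15N_AIR) {
  mode <- match.arg(mode)
  check_measurements(data)
  stopifnot(inherits(tracer, "tracer_application"),
            all(c("compartment", "year", "m_pool_gN_m2") %in% names(pools)))
  paired <- pair_measurements(data, fallback = fallback)
  paired <- dplyr::left_join(paired, pools, by = c("compartment", "year"))
  gaps <- dplyr::distinct(
    dplyr::filter(paired, is.na(.data$m_pool_gN_m2)),
    .data$compartment, .data$year)
  if (nrow(gaps)) {
    stop("no pool mass for measured cell(s): ",
         paste(gaps$compartment, gaps$year, sep = ":", collapse = ", "),
         call. = FALSE)
  }
  per_plot <- paired |>
    dplyr::mutate(
      en = enrichment(.data$delta15n, .data$delta15n_ref),
      ap_pool = delta_to_atom_percent(.data$delta15n, r_standard),
      ap_ref = delta_to_atom_percent(.data$delta15n_ref, r_standard),
      rec_mass = recovery_mass(.data$m_pool_gN_m2, .data$ap_pool,
                               .data$ap_ref, tracer$label_atom_percent),
      rec_pct = relative_recovery(.data$rec_mass, tracer$applied_excess_g_m2)
    )
  n_below <- sum(per_plot$ap_pool < per_plot$ap_ref)
  if (n_below > 0) {
    warning(n_below, " labelled record(s) fall below the reference atom ",
            "percent; their negative recoveries are retained", call. = FALSE)
  }
  if (mode == "per_plot_mean") {
    out <- per_plot |>
      dplyr::summarise(
        n_plots = dplyr::n(),
        enrichment_mean = mean(.data$en),
        enrichment_se = se_or_na(.data$en),
        recovery_mass_gN_m2 = mean(.data$rec_mass),
        recovery_mean = mean(.data$rec_pct),
        recovery_se = se_or_na(.data$rec_pct),
        .by = c("compartment", "year")
      )
  } else {
    out <- per_plot |>
      dplyr::summarise(
        n_plots = dplyr::n(),
        d_lab = mean(.data$delta15n),
        d_ref = mean(.data$delta15n_ref),
        m_pool = mean(.data$m_pool_gN_m2),
        .by = c("compartment", "year")
      ) |>
      dplyr::mutate(
        enrichment_mean = enrichment(.data$d_lab, .data$d_ref),
        enrichment_se = NA_real_,
        recovery_mass_gN_m2 = recovery_mass(
          .data$m_pool,
          delta_to_atom_percent(.data$d_lab, r_standard),
          delta_to_atom_percent(.data$d_ref, r_standard),
          tracer$label_atom_percent),
        recovery_mean = relative_recovery(.data$recovery_mass_gN_m2,
                                          tracer$applied_excess_g_m2),
        recovery_se = NA_real_
      ) |>
      dplyr::select(-"d_lab", -"d_ref", -"m_pool")
  }
  dplyr::arrange(out, .data$compartment, .data$year)
}

#' Annual total tracer recovery
#'
#' Sums the compartment recovery means per year. Compartments that were not
#' sampled in every year (in the field design: older woody biomass and roots,
#' sampled twice) are excluded from the default totals and added in the years
#' they were sampled when `include_non_annual = TRUE`, mirroring how such
#' tables change composition across years.
#'
#' @param table A recovery table with columns `compartment`, `year`,
#'   `recovery_mean` (e.g. from [recovery_table()]).
#' @param include_non_annual Add non-annually-sampled compartments in the
#'   years they appear.
#' @return A tibble `year, n_compartments, total_recovery` (% of applied).
#' @export
annual_totals <- function(table, include_non_annual = FALSE) {
  stopifnot(all(c("compartment", "year", "recovery_mean") %in% names(table)))
  if (!nrow(table)) {
    warning("empty recovery table: no totals", call. = FALSE)
    return(tibble::tibble(year = integer(), n_compartments = integer(),
                          total_recovery = numeric()))
  }
  all_years <- sort(unique(table$year))
  coverage <- table |>
    dplyr::summarise(n_years = dplyr::n_distinct(.data$year),
                     .by = "compartment")
  annual_comps <- coverage$compartment[coverage$n_years == length(all_years)]
  keep <- if (include_non_annual) table else
    dplyr::filter(table, .data$compartment %in% annual_comps)
  dropped <- setdiff(unique(table$compartment), unique(keep$compartment))
  if (length(dropped)) {
    message("annual totals exclude non-annual compartment(s): ",
            paste(dropped, collapse = ", "))
  }
  keep |>
    dplyr::summarise(
      n_compartments = dplyr::n(),
      total_recovery = sum(.data$recovery_mean),
      .by = "year"
    ) |>
    dplyr::arrange(.data$year)
}

#' Paired t-tests of labelled versus reference delta-15N
#'
#' Two-sided paired Student's t-test per compartment and year, testing whether
#' labelled subplots deviate from the natural abundance measured in their
#' paired reference subplots. Cells with fewer than two complete pairs, or
#' with zero variance of the pair differences, are returned as not evaluable
#' (`NA` statistic, `evaluable = FALSE`) rather than dropped or made infinite.
#'
#' @inheritParams enrichment_table
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble `compartment, year, n_pairs, t_statistic, p_value,
#'   significant, evaluable`.
#' @export
paired_delta_tests <- function(data, alpha = 0.05) {
  check_measurements(data)
  stopifnot(alpha > 0, alpha < 1)
  wide <- data |>
    dplyr::select("plot", "role", "year", "compartment", "delta15n") |>
    tidyr::pivot_wider(names_from = "role", values_from = "delta15n") |>
    dplyr::filter(!is.na(.data$labelled) & !is.na(.data$reference))
  wide |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      .test = list({
        d <- .data$labelled - .data$reference
        if (length(d) < 2 || stats::sd(d) == 0) {
          tibble::tibble(t_statistic = NA_real_, p_value = NA_real_,
                         evaluable = FALSE)
        } else {
          tt <- stats::t.test(.data$labelled, .data$reference, paired = TRUE)
          tibble::tibble(t_statistic = unname(tt$statistic),
                         p_value = tt$p.value, evaluable = TRUE)
        }
      }),
      .by = c("compartment", "year")
    ) |>
    tidyr::unnest(".test") |>
    dplyr::mutate(significant = !is.na(.data$p_value) &
                    .data$p_value < alpha) |>
    dplyr::select("compartment", "year", "n_pairs", "t_statistic",
                  "p_value", "significant", "evaluable") |>
    dplyr::arrange(.data$compartment, .data$year)
}
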