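# Published group means shipped with the package, and small readers for the
# external CSV schemas.

heath_file <- function(name) {
  system.file("extdata", name, package = "pulsetrace", mustWork = TRUE)
}

#' Published decadal heathland pulse-labelling group means
#'
#' Group means (n = 7 plots, with standard errors) from a published
#' nine-year 15N pulse-labelling experiment in a NW-German *Calluna*
#' heathland: delta-15N of labelled and reference subplots per compartment
#' and year (`heathland_deltas()`), the derived per-mil enrichment means
#' (`heathland_enrichment()`), and tracer recovery as % of the applied dose
#' (`heathland_recovery()`). Only these printed aggregates are available;
#' the underlying per-plot records were not deposited, so analyses on these
#' tables operate on means (one pseudo-plot), not on the plot-level
#' replication.
#'
#' @return A tibble; see each CSV header under `inst/extdata/` for units.
#' @export
heathland_deltas <- function() {
  readr::read_csv(heath_file("heathland_delta15n_means.csv"),
                  show_col_types = FALSE)
}

#' @rdname heathland_deltas
#' @export
heathland_recovery <- function() {
  readr::read_csv(heath_file("heathland_recovery_means.csv"),
                  show_col_types = FALSE)
}

#' @rdname heathland_deltas
#' @export
heathland_enrichment <- function() {
  readr::read_csv(heath_file("heathland_enrichment_means.csv"),
                  show_col_types = FALSE)
}

#' Treat published group means as a single-pseudo-plot measurement set
#'
#' Reshapes a table of group-mean deltas (columns `year, compartment, role,
#' delta15n_mean`) into the measurement-record schema with one pseudo-plot,
#' so the enrichment pipeline can be applied to printed means (the
#' `mean_of_deltas` aggregation on such records is exactly the enrichment
#' of the means).
#'
#' @param means A tibble like [heathland_deltas()].
#' @return Measurement records (`plot, role, year, compartment, delta15n`).
#' @export
measurements_from_means <- function(means) {
  stopifnot(all(c("year", "compartment", "role", "delta15n_mean")
                %in% names(means)))
  tibble::tibble(plot = "group_mean", role = means$role,
                 year = means$year, compartment = means$compartment,
                 delta15n = means$delta15n_mean)
}

#' Read measurement records from CSV
#'
#' Expected columns: `plot, role, year, compartment, delta15n_permil,
#' n_content_fraction` (the last one optional). Schema violations raise an
#' error naming the missing columns.
#'
#' @param path CSV file path.
#' @return Measurement-record tibble as consumed by [enrichment_table()].
#' @export
read_measurements <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  need <- c("plot", "role", "year", "compartment", "delta15n_permil")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("measurement CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    plot = d$plot, role = d$role, year = as.integer(d$year),
    compartment = d$compartment, delta15n = d$delta15n_permil,
    n_content = if ("n_content_fraction" %in% names(d))
      d$n_content_fraction else NA_real_)
  check_measurements(out)
  out
}

#' Read a compartment pool-mass table from CSV
#'
#' Expected columns: `compartment, year, m_pool_gN_m2`.
#'
#' @param path CSV file path.
#' @return Pool tibble as consumed by [recovery_table()].
#' @export
read_pool_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  need <- c("compartment", "year", "m_pool_gN_m2")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("pool CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_compartments(d$compartment)
  tibble::as_tibble(d[need])
}
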