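# Compartment vocabulary, nitrogen-pool series and tracer-dose accounting.

#' Ecosystem compartment vocabulary
#'
#' The closed set of compartment names used throughout the package: the dwarf
#' shrub fractions (current-year shoots, 1-2 year shoots, older woody biomass,
#' roots, current-year litter), the moss layer, the O/A/B soil horizons of the
#' podzol profile, and leachate. Every measurement, pool entry and flow node
#' must use one of these names.
#'
#' @return Character vector of the ten compartment names.
#' @export
compartment_levels <- function() {
  c("current_year_shoots", "shoots_1_2yr", "calluna_old", "calluna_roots",
    "litter_current", "moss", "O_horizon", "A_horizon", "B_horizon",
    "leachate")
}

check_compartments <- function(x, what = "compartment") {
  bad <- setdiff(unique(as.character(x)), compartment_levels())
  if (length(bad)) {
    stop("unknown ", what, "(s): ", paste(bad, collapse = ", "),
         "; see compartment_levels()", call. = FALSE)
  }
  invisible(x)
}

#' Build the compartment nitrogen-pool series
#'
#' Expands starting pools into a complete (compartment x year) grid of
#' nitrogen pool masses (the `m_pool` of the recovery formula). Static
#' compartments (soil horizons, moss) carry their starting mass through all
#' years; plant compartments may instead follow an age-dependent growth model
#' (compound biomass increment times nitrogen content). A per-year override
#' table wins over both.
#'
#' @param start_pools Data frame with columns `compartment` and
#'   `m_pool_gN_m2`: the pool mass at the first year.
#' @param years Integer vector of years the series must cover.
#' @param growth Optional named list of growth rules, one per plant
#'   compartment, each a list with `base_biomass` (g dry mass m^-2 at the
#'   first year), `annual_increment` (fractional growth per year; a scalar or
#'   one value per subsequent year), and `n_content` (N mass fraction, scalar
#'   or per year). Compartments with a growth rule ignore `start_pools`.
#' @param overrides Optional data frame `compartment, year, m_pool_gN_m2`
#'   returned verbatim for the cells it covers.
#' @return A tibble `compartment, year, m_pool_gN_m2` covering every
#'   requested cell exactly once.
#' @examples
#' pool_series(
#'   data.frame(compartment = "O_horizon", m_pool_gN_m2 = 70),
#'   years = 2007:2015)
#' @export
pool_series <- function(start_pools, years, growth = NULL, overrides = NULL) {
  stopifnot(is.data.frame(start_pools),
            all(c("compartment", "m_pool_gN_m2") %in% names(start_pools)))
  years <- sort(unique(as.integer(years)))
  check_compartments(start_pools$compartment)
  if (any(start_pools$m_pool_gN_m2 < 0)) {
    stop("pool masses must be >= 0", call. = FALSE)
  }
  static <- tidyr::crossing(
    compartment = start_pools$compartment,
    year = years
  ) |>
    dplyr::left_join(
      dplyr::select(start_pools, "compartment", "m_pool_gN_m2"),
      by = "compartment"
    )

  grown <- NULL
  if (!is.null(growth)) {
    check_compartments(names(growth), "growth compartment")
    grown <- purrr::imap_dfr(growth, function(g, comp) {
      stopifnot(all(c("base_biomass", "annual_increment", "n_content")
                    %in% names(g)))
      inc <- rep_len(g$annual_increment, length(years) - 1)
      ncont <- rep_len(g$n_content, length(years))
      if (g$base_biomass < 0 || any(inc < 0) || any(ncont < 0)) {
        stop("growth model entries must be non-negative", call. = FALSE)
      }
      biomass <- g$base_biomass * cumprod(c(1, 1 + inc))
      tibble::tibble(compartment = comp, year = years,
                     m_pool_gN_m2 = biomass * ncont)
    })
    static <- dplyr::filter(static, !.data$compartment %in% names(growth))
  }

  out <- dplyr::bind_rows(static, grown)

  if (!is.null(overrides)) {
    stopifnot(all(c("compartment", "year", "m_pool_gN_m2")
                  %in% names(overrides)))
    check_compartments(overrides$compartment, "override compartment")
    out <- out |>
      dplyr::anti_join(overrides, by = c("compartment", "year")) |>
      dplyr::bind_rows(
        dplyr::select(overrides, "compartment", "year", "m_pool_gN_m2"))
  }

  out <- dplyr::arrange(out, .data$compartment, .data$year)
  gaps <- dplyr::filter(out, is.na(.data$m_pool_gN_m2))
  if (nrow(gaps)) {
    stop("no pool mass or growth rule for: ",
         paste(gaps$compartment, gaps$year, sep = ":", collapse = ", "),
         call. = FALSE)
  }
  dup <- dplyr::count(out, .data$compartment, .data$year) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate pool entries for: ",
         paste(dup$compartment, dup$year, sep = ":", collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(out)
}

# atomic masses (u): 15N, 14N, H, O
.mass_15n <- 15.0001089
.mass_14n <- 14.0030740
.mass_h <- 1.0079407
.mass_o <- 15.9994050

#' Applied excess 15N per square metre from a labelled ammonium-nitrate dose
#'
#' The pulse label is double-labelled ammonium nitrate (15NH4 15NO3) applied
#' at a known dose and label atom percent. The nitrogen mass in the dose is
#' computed from molar composition (2 N per formula unit, with the molar mass
#' built from the stated label atom percent), and the excess 15N above the
#' natural reference abundance is
#' `n_mass * (label - ref) / 100`. This excess is the denominator of relative
#' recovery; set `basis = "gross"` to use the gross 15N content of the dose
#' instead.
#'
#' @param dose_mg_m2 Salt dose in mg per square metre (>= 0).
#' @param label_atom_percent Atom-% 15N of the label (e.g. 98).
#' @param ref_atom_percent Natural-abundance atom-% 15N used as reference
#'   (default: air-N2 abundance from [R15N_AIR]).
#' @param basis `"excess"` (default) or `"gross"`.
#' @return Applied excess (or gross) 15N in g m^-2.
#' @examples
#' applied_excess_15n(100, 98)
#' @export
applied_excess_15n <- function(dose_mg_m2, label_atom_percent,
                               ref_atom_percent =
                                 ratio_to_atom_percent(R15N_AIR),
                               basis = c("excess", "gross")) {
  basis <- match.arg(basis)
  check_number(dose_mg_m2, nonneg = TRUE, what = "dose_mg_m2")
  check_number(label_atom_percent, positive = TRUE,
               what = "label_atom_percent")
  check_number(ref_atom_percent, positive = TRUE, what = "ref_atom_percent")
  if (label_atom_percent <= ref_atom_percent) {
    stop("`label_atom_percent` must exceed `ref_atom_percent`: ",
         "the dose carries no tracer excess", call. = FALSE)
  }
  p <- label_atom_percent / 100
  m_n <- p * .mass_15n + (1 - p) * .mass_14n
  molar_mass <- 2 * m_n + 4 * .mass_h + 3 * .mass_o
  n_mass_g <- dose_mg_m2 / 1000 * (2 * m_n) / molar_mass
  frac <- if (basis == "excess") {
    (label_atom_percent - ref_atom_percent) / 100
  } else {
    label_atom_percent / 100
  }
  n_mass_g * frac
}

#' Describe a tracer application
#'
#' Bundles the pulse-label parameters consumed by [recovery_table()] and the
#' simulator: salt dose, label atom percent, the reference abundance, and the
#' derived applied excess 15N per square metre.
#'
#' @inheritParams applied_excess_15n
#' @return A list of class `tracer_application` with elements
#'   `dose_mg_m2`, `label_atom_percent`, `ref_atom_percent`,
#'   `applied_excess_g_m2`.
#' @examples
#' tracer_application()    # the default 100 mg 98 at.% pulse
#' @export
tracer_application <- function(dose_mg_m2 = 100, label_atom_percent = 98,
                               ref_atom_percent =
                                 ratio_to_atom_percent(R15N_AIR),
                               basis = c("excess", "gross")) {
  basis <- match.arg(basis)
  structure(
    list(dose_mg_m2 = dose_mg_m2,
         label_atom_percent = label_atom_percent,
         ref_atom_percent = ref_atom_percent,
         applied_excess_g_m2 = applied_excess_15n(
           dose_mg_m2, label_atom_percent, ref_atom_percent, basis)),
    class = "tracer_application")
}

#' @export
print.tracer_application <- function(x, ...) {
  cat(sprintf(
    "<tracer_application> %g mg salt m^-2 at %g at.%% 15N (ref %.4f at.%%)\n",
    x$dose_mg_m2, x$label_atom_percent, x$ref_atom_percent))
  cat(sprintf("  applied excess 15N: %.6f g m^-2\n", x$applied_excess_g_m2))
  invisible(x)
}

#' Nitrogen flux leached below the rooting zone
#'
#' Leachate nitrogen export per collection interval is volume times total
#' nitrogen concentration (inorganic N plus dissolved organic N); the annual
#' total is the sum over intervals.
#'
#' @param records Data frame with columns `start_date`, `end_date`
#'   (ISO-8601 or Date), `volume_L_m2`, `n_inorg_mg_L`, `don_mg_L`, and
#'   optionally `delta15n_permil`.
#' @return A tibble with one row per interval and a `flux_gN_m2` column;
#'   the attribute `"annual_total"` carries the summed flux, also returned by
#'   `sum(out$flux_gN_m2)`.
#' @examples
#' leaching_n_flux(data.frame(
#'   start_date = "2014-06-01", end_date = "2014-06-08",
#'   volume_L_m2 = 10, n_inorg_mg_L = 0.6, don_mg_L = 0.4))
#' @export
leaching_n_flux <- function(records) {
  if (!nrow(records)) {
    out <- tibble::tibble(start_date = as.Date(character()),
                          end_date = as.Date(character()),
                          volume_L_m2 = numeric(), flux_gN_m2 = numeric())
    attr(out, "annual_total") <- 0
    return(out)
  }
  stopifnot(all(c("start_date", "end_date", "volume_L_m2",
                  "n_inorg_mg_L", "don_mg_L") %in% names(records)))
  if (any(records$volume_L_m2 < 0) || any(records$n_inorg_mg_L < 0) ||
      any(records$don_mg_L < 0)) {
    stop("leachate volumes and concentrations must be >= 0", call. = FALSE)
  }
  start <- as.Date(records$start_date)
  end <- as.Date(records$end_date)
  if (any(end < start)) stop("interval end before start", call. = FALSE)
  ord <- order(start)
  if (any(start[ord][-1] < end[ord][-length(ord)])) {
    stop("leachate collection intervals overlap", call. = FALSE)
  }
  out <- tibble::as_tibble(records) |>
    dplyr::mutate(
      start_date = as.Date(.data$start_date),
      end_date = as.Date(.data$end_date),
      # mg/L * L/m2 = mg/m2; /1000 -> g/m2
      flux_gN_m2 = .data$volume_L_m2 *
        (.data$n_inorg_mg_L + .data$don_mg_L) / 1000
    ) |>
    dplyr::arrange(.data$start_date)
  attr(out, "annual_total") <- sum(out$flux_gN_m2)
  out
}
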