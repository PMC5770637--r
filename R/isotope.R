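# Exact isotope arithmetic for the 15N/14N system. All functions are
# vectorised, pure, and carried at full double precision; rounding happens
# only in report writers.

#' Conventional 15N/14N ratio of atmospheric N2
#'
#' The international delta scale for nitrogen is anchored to atmospheric N2.
#' This constant is the conventional absolute ratio used to move between the
#' delta scale and atom fractions; every conversion function accepts an
#' `r_standard` argument so a different calibration can be supplied.
#'
#' @format A length-one numeric (dimensionless isotope-amount ratio).
#' @export
R15N_AIR <- 0.0036765

#' Convert delta-15N to an isotope ratio
#'
#' The delta notation expresses a sample's 15N/14N ratio as the per-mil
#' deviation from the air-N2 standard:
#' \deqn{\delta^{15}N = (R_{sample}/R_{standard} - 1) \times 1000.}
#' `delta_to_ratio()` inverts the notation to the absolute ratio;
#' `ratio_to_delta()` is its exact inverse.
#'
#' @param delta Numeric vector of delta-15N values in per mil. Values must
#'   exceed -1000 (the zero-15N limit, where the ratio would be non-positive).
#' @param ratio Numeric vector of 15N/14N isotope-amount ratios (> 0).
#' @param r_standard The 15N/14N ratio of the standard (default [R15N_AIR]).
#' @return Numeric vector: the isotope ratio (dimensionless) or the delta
#'   value (per mil).
#' @examples
#' delta_to_ratio(0)              # the standard itself
#' ratio_to_delta(delta_to_ratio(12.5))
#' @export
delta_to_ratio <- function(delta, r_standard = R15N_AIR) {
  check_number(r_standard, positive = TRUE, what = "r_standard")
  if (any(!is.finite(delta)) || any(delta <= -1000)) {
    stop("`delta` must be finite and > -1000 per mil (non-physical otherwise)",
         call. = FALSE)
  }
  r_standard * (delta / 1000 + 1)
}

#' @rdname delta_to_ratio
#' @export
ratio_to_delta <- function(ratio, r_standard = R15N_AIR) {
  check_number(r_standard, positive = TRUE, what = "r_standard")
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("`ratio` must be finite and > 0", call. = FALSE)
  }
  (ratio / r_standard - 1) * 1000
}

#' Convert between isotope ratio and atom percent 15N
#'
#' Atom percent is the share of nitrogen atoms that are 15N,
#' `100 * r / (1 + r)` for ratio `r`; strictly increasing in `r`, so the
#' two functions round-trip exactly (to floating precision).
#'
#' @param ratio Numeric vector of 15N/14N ratios (> 0).
#' @param atom_percent Numeric vector of atom-% 15N values in (0, 100).
#' @return Numeric vector of atom-% 15N, or of isotope ratios.
#' @examples
#' ratio_to_atom_percent(1)      # equal abundance: 50 %
#' atom_percent_to_ratio(ratio_to_atom_percent(R15N_AIR))
#' @export
ratio_to_atom_percent <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("`ratio` must be finite and > 0", call. = FALSE)
  }
  100 * ratio / (1 + ratio)
}

#' @rdname ratio_to_atom_percent
#' @export
atom_percent_to_ratio <- function(atom_percent) {
  if (any(!is.finite(atom_percent)) ||
      any(atom_percent <= 0) || any(atom_percent >= 100)) {
    stop("`atom_percent` must be in the open interval (0, 100)", call. = FALSE)
  }
  atom_percent / (100 - atom_percent)
}

#' @rdname delta_to_ratio
#' @export
delta_to_atom_percent <- function(delta, r_standard = R15N_AIR) {
  ratio_to_atom_percent(delta_to_ratio(delta, r_standard))
}

#' @rdname ratio_to_atom_percent
#' @param r_standard The 15N/14N ratio of the standard (default [R15N_AIR]).
#' @export
atom_percent_to_delta <- function(atom_percent, r_standard = R15N_AIR) {
  ratio_to_delta(atom_percent_to_ratio(atom_percent), r_standard)
}

#' Per-mil 15N enrichment of a labelled sample over its reference
#'
#' Enrichment expresses how much a sample from a labelled subplot deviates,
#' in per mil, from the paired sample in the non-labelled subplot:
#' \deqn{EN = 1000 (\delta_{sample} - \delta_{ref}) / (\delta_{ref} + 1000).}
#' This equals the relative ratio change `(R_sample/R_ref - 1) * 1000` and is
#' therefore independent of the standard; it is zero iff the two deltas agree
#' and carries the sign of their difference.
#'
#' @param delta_sample,delta_ref Delta-15N values (per mil) of the labelled
#'   sample and its unlabelled reference. `delta_ref` must exceed -1000.
#' @return Per-mil enrichment, same length as the inputs.
#' @examples
#' enrichment(8.16, 5.33)
#' enrichment(-6.2, -6.2)   # identical pair: 0
#' @export
enrichment <- function(delta_sample, delta_ref) {
  if (any(!is.finite(delta_ref)) || any(delta_ref <= -1000)) {
    stop("`delta_ref` must be finite and > -1000 per mil", call. = FALSE)
  }
  if (any(!is.finite(delta_sample)) || any(delta_sample <= -1000)) {
    stop("`delta_sample` must be finite and > -1000 per mil", call. = FALSE)
  }
  1000 * (delta_sample - delta_ref) / (delta_ref + 1000)
}

#' Mass of tracer 15N recovered in a compartment
#'
#' Tracer recovery converts an atom-percent excess into the mass of labelled
#' nitrogen held by a compartment pool:
#' \deqn{recovery = m_{pool} \frac{at.\%_{pool} - at.\%_{ref}}
#'   {at.\%_{tracer} - at.\%_{ref}},}
#' where `m_pool` is the nitrogen pool mass (g N m^-2) of the compartment,
#' `at.%_pool` and `at.%_ref` the atom-% 15N in the labelled and unlabelled
#' subplots, and `at.%_tracer` the atom-% of the applied label. The result is
#' in g m^-2 of tracer-equivalent nitrogen, linear in `m_pool`, and zero when
#' the pool shows no excess over its reference.
#'
#' @param m_pool Nitrogen pool mass, g N m^-2 (>= 0).
#' @param ap_pool,ap_ref,ap_tracer Atom-% 15N of the labelled pool, the
#'   reference pool, and the applied tracer. `ap_tracer` must exceed `ap_ref`.
#' @return Recovered tracer mass, g 15N m^-2 (negative if the labelled pool
#'   sits below its reference, which flags measurement noise).
#' @examples
#' recovery_mass(100, 0.3700, 0.3663, 98)
#' @export
recovery_mass <- function(m_pool, ap_pool, ap_ref, ap_tracer) {
  if (any(!is.finite(m_pool)) || any(m_pool < 0)) {
    stop("`m_pool` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(ap_pool)) || any(!is.finite(ap_ref)) ||
      any(!is.finite(ap_tracer))) {
    stop("atom-percent inputs must be finite", call. = FALSE)
  }
  if (any(ap_tracer <= ap_ref)) {
    stop("`ap_tracer` must exceed `ap_ref` (denominator of the recovery ",
         "formula would be <= 0)", call. = FALSE)
  }
  m_pool * (ap_pool - ap_ref) / (ap_tracer - ap_ref)
}

#' Recovery as a percentage of the tracer applied
#'
#' @param recovered Recovered tracer mass, g 15N m^-2.
#' @param applied Applied excess 15N, g m^-2 (> 0); see [applied_excess_15n()].
#' @return Percentage of the applied tracer (additive over compartments).
#' @examples
#' relative_recovery(0.01, 0.04)
#' @export
relative_recovery <- function(recovered, applied) {
  check_number(applied, positive = TRUE, what = "applied")
  if (any(!is.finite(recovered))) {
    stop("`recovered` must be finite", call. = FALSE)
  }
  100 * recovered / applied
}

# internal: scalar argument checks shared across modules
check_number <- function(x, positive = FALSE, nonneg = FALSE, what = "value") {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop("`", what, "` must be a single finite number", call. = FALSE)
  }
  if (positive && x <= 0) stop("`", what, "` must be > 0", call. = FALSE)
  if (nonneg && x < 0) stop("`", what, "` must be >= 0", call. = FALSE)
  invisible(x)
}
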