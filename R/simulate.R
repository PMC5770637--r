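# Tracer-fate simulator: a seeded, mass-conserving annual compartment model
# of the pulse-labelling experiment, plus the back-conversion of true tracer
# masses into paired-subplot delta-15N measurement records, and a generator
# for gamma GAMM enrichment datasets.

#' Simulation configuration for the tracer-fate model
#'
#' Describes the simulated experiment: a paired-subplot design (`n_plots`
#' plots, one labelled and one reference subplot each), annual sampling over
#' `n_years` occasions, first-order annual transfer fractions along the
#' default flow topology, per-plot lognormal jitter of the transfer rates,
#' and delta-scale measurement noise. The default rates are chosen so the
#' moss layer captures the pulse, releases about a third of its stock per
#' year (roughly half of that reaching the organic horizon and the rest
#' leaving as unattributed loss), and the O-horizon accumulates towards
#' ~40 % of the dose within eight years — the qualitative trajectory of a
#' decadal heathland pulse-labelling study.
#'
#' @param n_plots Number of plots (paired subplots), default 7.
#' @param n_years Number of annual sampling occasions, default 9.
#' @param start_year Calendar year of the pulse and first sampling.
#' @param rates Named numeric vector of annual first-order transfer
#'   fractions: `moss_to_o`, `moss_to_loss`, `o_to_a`, `o_to_plant`,
#'   `a_to_b`, `plant_to_litter`, `litter_to_o`, `b_to_leachate`; all in
#'   `[0, 1]` with per-node outgoing sums <= 1.
#' @param natural_delta Named vector of natural-abundance delta-15N (per
#'   mil) per measured compartment.
#' @param pools Pool-mass table (`compartment, year, m_pool_gN_m2`), default
#'   [synthetic_pool_table()].
#' @param tracer A [tracer_application()].
#' @param sd_rate_plot Lognormal SD of the per-plot rate jitter (log scale).
#' @param sd_delta_noise Gaussian measurement noise SD on the delta scale
#'   (per mil).
#' @param seed Integer seed; the same seed gives bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_plots = 7, n_years = 9, start_year = 2007,
                       rates = c(moss_to_o = 0.15, moss_to_loss = 0.17,
                                 o_to_a = 0.02, o_to_plant = 0.03,
                                 a_to_b = 0.05, plant_to_litter = 0.40,
                                 litter_to_o = 0.70, b_to_leachate = 0.002),
                       natural_delta = c(current_year_shoots = -6.2,
                                         shoots_1_2yr = -7.2,
                                         litter_current = -6.8,
                                         moss = -6.3, O_horizon = -4.2,
                                         A_horizon = 4.5, B_horizon = 7.0),
                       pools = synthetic_pool_table(start_year, n_years),
                       tracer = tracer_application(),
                       sd_rate_plot = 0.15, sd_delta_noise = 0.5,
                       seed = 1L) {
  need <- c("moss_to_o", "moss_to_loss", "o_to_a", "o_to_plant", "a_to_b",
            "plant_to_litter", "litter_to_o", "b_to_leachate")
  miss <- setdiff(need, names(rates))
  if (length(miss)) stop("missing rate(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(rates < 0 | rates > 1)) {
    stop("all transfer rates must lie in [0, 1]", call. = FALSE)
  }
  out_sums <- c(moss = rates[["moss_to_o"]] + rates[["moss_to_loss"]],
                O = rates[["o_to_a"]] + rates[["o_to_plant"]],
                A = rates[["a_to_b"]], plant = rates[["plant_to_litter"]],
                litter = rates[["litter_to_o"]],
                B = rates[["b_to_leachate"]])
  if (any(out_sums > 1)) {
    stop("outgoing rate fractions exceed 1 for node(s): ",
         paste(names(out_sums)[out_sums > 1], collapse = ", "),
         call. = FALSE)
  }
  stopifnot(n_plots >= 1, n_years >= 1, sd_rate_plot >= 0,
            sd_delta_noise >= 0)
  structure(list(n_plots = as.integer(n_plots),
                 n_years = as.integer(n_years),
                 start_year = as.integer(start_year),
                 rates = rates, natural_delta = natural_delta,
                 pools = pools, tracer = tracer,
                 sd_rate_plot = sd_rate_plot,
                 sd_delta_noise = sd_delta_noise,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Synthetic compartment pool-mass table
#'
#' A plausible nitrogen pool-mass table (g N m^-2) for the simulated
#' heathland: moss layer ~8.5, O-horizon ~70, mineral horizons >150, small
#' plant fractions. These are synthetic fixture values in the range reported
#' for sandy podzol heathlands, not measurements from any specific site.
#'
#' @param start_year,n_years Years the table must cover.
#' @return Tibble `compartment, year, m_pool_gN_m2`.
#' @export
synthetic_pool_table <- function(start_year = 2007, n_years = 9) {
  base <- tibble::tibble(
    compartment = c("current_year_shoots", "shoots_1_2yr", "litter_current",
                    "moss", "O_horizon", "A_horizon", "B_horizon"),
    m_pool_gN_m2 = c(1.2, 0.75, 0.3, 8.5, 70, 170, 160))
  pool_series(base, years = start_year + seq_len(n_years) - 1L)
}

# internal node order of the simulator state vector
.sim_nodes <- c("moss", "O_horizon", "A_horizon", "B_horizon", "plant",
                "litter_current", "leachate", "loss")

# one annual step of the first-order transfer dynamics for one plot;
# state and return value are fractions of the applied tracer per node
sim_step <- function(state, r) {
  out <- state
  moss_out <- state[["moss"]] * (r[["moss_to_o"]] + r[["moss_to_loss"]])
  o_out <- state[["O_horizon"]] * (r[["o_to_a"]] + r[["o_to_plant"]])
  a_out <- state[["A_horizon"]] * r[["a_to_b"]]
  b_out <- state[["B_horizon"]] * r[["b_to_leachate"]]
  p_out <- state[["plant"]] * r[["plant_to_litter"]]
  l_out <- state[["litter_current"]] * r[["litter_to_o"]]
  out[["moss"]] <- state[["moss"]] - moss_out
  out[["O_horizon"]] <- state[["O_horizon"]] - o_out +
    state[["moss"]] * r[["moss_to_o"]] + l_out
  out[["A_horizon"]] <- state[["A_horizon"]] - a_out +
    state[["O_horizon"]] * r[["o_to_a"]]
  out[["B_horizon"]] <- state[["B_horizon"]] - b_out + a_out
  out[["plant"]] <- state[["plant"]] - p_out +
    state[["O_horizon"]] * r[["o_to_plant"]]
  out[["litter_current"]] <- state[["litter_current"]] - l_out + p_out
  out[["leachate"]] <- state[["leachate"]] + b_out
  out[["loss"]] <- state[["loss"]] + state[["moss"]] * r[["moss_to_loss"]]
  out
}

#' Simulate the fate of the 15N pulse through the compartment cascade
#'
#' The pulse enters the moss layer at time zero; each year every compartment
#' exports its first-order rate fractions along the topology
#' (moss -> O -> A -> B -> leachate, O -> plants -> litter -> O, and
#' moss -> loss as the unattributed pathway). Per-plot heterogeneity enters
#' as a lognormal jitter of the transfer rates. The first sampling occasion
#' observes the state after one annual step. All states are fractions of the
#' applied tracer; mass is conserved exactly at every step.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_truth`: `tracer` (tibble `plot, year,
#'   compartment, frac_applied, tracer_gN_m2` for the measured
#'   compartments, where the simulator's aggregate plant pool is split
#'   between current-year and 1-2 year shoots), `nodes` (tibble of all node
#'   states incl. loss/leachate per plot-year), `rates` (the per-plot
#'   jittered rates) and the `config`.
#' @export
simulate_tracer_fate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  years <- config$start_year + seq_len(config$n_years) - 1L
  applied <- config$tracer$applied_excess_g_m2

  res <- purrr::map_dfr(seq_len(config$n_plots), function(p) {
    jitter <- exp(stats::rnorm(length(config$rates), 0,
                               config$sd_rate_plot))
    r <- config$rates * jitter
    # renormalise any node whose outgoing fractions now exceed 1
    cap <- function(keys) {
      s <- sum(r[keys])
      if (s > 1) r[keys] <<- r[keys] / s
    }
    cap(c("moss_to_o", "moss_to_loss"))
    cap(c("o_to_a", "o_to_plant"))
    state <- stats::setNames(numeric(length(.sim_nodes)), .sim_nodes)
    state[["moss"]] <- 1
    purrr::map_dfr(seq_along(years), function(k) {
      state <<- sim_step(state, r)
      tibble::tibble(plot = p, year = years[k],
                     node = names(state), frac_applied = unname(state),
                     rates = list(r))
    })
  })

  nodes <- dplyr::select(res, "plot", "year", "node", "frac_applied")
  rates <- res |>
    dplyr::distinct(.data$plot, .keep_all = TRUE) |>
    dplyr::select("plot", "rates")

  # split the aggregate plant pool into the two measured shoot fractions
  # (fixed 65/35 allocation of above-ground tracer)
  plant_split <- c(current_year_shoots = 0.65, shoots_1_2yr = 0.35)
  tracer <- nodes |>
    dplyr::filter(!.data$node %in% c("loss", "leachate", "plant")) |>
    dplyr::rename(compartment = "node") |>
    dplyr::bind_rows(
      nodes |>
        dplyr::filter(.data$node == "plant") |>
        tidyr::crossing(part = names(plant_split)) |>
        dplyr::mutate(frac_applied = .data$frac_applied *
                        plant_split[.data$part]) |>
        dplyr::select("plot", "year", compartment = "part",
                      "frac_applied")
    ) |>
    dplyr::mutate(tracer_gN_m2 = .data$frac_applied * applied) |>
    dplyr::arrange(.data$plot, .data$year, .data$compartment)

  structure(list(tracer = tracer, nodes = nodes, rates = rates,
                 config = config),
            class = "sim_truth")
}

#' Convert true tracer masses into paired-subplot measurement records
#'
#' Inverts the recovery formula: the labelled-subplot atom percent of a
#' compartment is its natural abundance plus
#' `tracer_mass / m_pool * (at.%_tracer - at.%_ref)`, converted back to the
#' delta scale; reference subplots carry the natural abundance. Gaussian
#' measurement noise is applied on the delta scale (the scale on which
#' isotope-ratio mass spectrometry errors live). With `noise = FALSE` the
#' records round-trip through [recovery_table()] to the simulated truth
#' exactly.
#'
#' @param truth A [simulate_tracer_fate()] result.
#' @param noise Add delta-scale measurement noise (default `TRUE`)?
#' @return A tibble of measurement records (`plot, role, year, compartment,
#'   delta15n, n_content`).
#' @export
tracer_to_measurements <- function(truth, noise = TRUE) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  set.seed(config$seed + 1L)
  ap_ref <- delta_to_atom_percent(
    config$natural_delta[names(config$natural_delta)])
  nat <- tibble::tibble(compartment = names(config$natural_delta),
                        delta_nat = unname(config$natural_delta),
                        ap_ref = unname(ap_ref))
  d <- truth$tracer |>
    dplyr::inner_join(nat, by = "compartment") |>
    dplyr::inner_join(config$pools, by = c("compartment", "year"))
  if (any(d$tracer_gN_m2 > d$m_pool_gN_m2)) {
    stop("simulated tracer mass exceeds the compartment nitrogen pool; ",
         "non-physical configuration", call. = FALSE)
  }
  ap_tracer <- config$tracer$label_atom_percent
  d <- d |>
    dplyr::mutate(
      ap_lab = .data$ap_ref + .data$tracer_gN_m2 / .data$m_pool_gN_m2 *
        (ap_tracer - .data$ap_ref),
      delta_lab = atom_percent_to_delta(.data$ap_lab))
  sd_n <- if (noise) config$sd_delta_noise else 0
  lab <- d |>
    dplyr::transmute(.data$plot, role = "labelled", .data$year,
                     .data$compartment,
                     delta15n = .data$delta_lab +
                       stats::rnorm(dplyr::n(), 0, sd_n),
                     n_content = 0.01)
  ref <- d |>
    dplyr::transmute(.data$plot, role = "reference", .data$year,
                     .data$compartment,
                     delta15n = .data$delta_nat +
                       stats::rnorm(dplyr::n(), 0, sd_n),
                     n_content = 0.01)
  dplyr::bind_rows(lab, ref) |>
    dplyr::arrange(.data$plot, .data$role, .data$year, .data$compartment)
}

#' Simulate the full experiment in one call
#'
#' Runs [simulate_tracer_fate()] and [tracer_to_measurements()] and returns
#' both the ground truth and the measurement records.
#'
#' @inheritParams tracer_to_measurements
#' @param config A [sim_config()].
#' @return List with `truth`, `measurements`, and the `config`.
#' @export
simulate_experiment <- function(config = sim_config(), noise = TRUE) {
  truth <- simulate_tracer_fate(config)
  list(truth = truth,
       measurements = tracer_to_measurements(truth, noise = noise),
       config = config)
}

#' True flow ledger of a simulated interval
#'
#' Aggregates the simulator's plot-mean node states into the same
#' per-interval gains/losses and flows that [infer_flows()] reconstructs
#' from measurements, for use as ground truth in round-trip checks.
#'
#' @param truth A [simulate_tracer_fate()] result.
#' @param year_from,year_to Interval endpoints (sampling years).
#' @return Tibble `node, delta` (percentage points of applied tracer) plus
#'   attributes `loss_gain` and `leachate_gain` over the interval.
#' @export
true_node_deltas <- function(truth, year_from, year_to) {
  stopifnot(inherits(truth, "sim_truth"))
  st <- truth$nodes |>
    dplyr::filter(.data$year %in% c(year_from, year_to)) |>
    dplyr::summarise(frac = mean(.data$frac_applied),
                     .by = c("node", "year")) |>
    tidyr::pivot_wider(names_from = "year", values_from = "frac",
                       names_prefix = "y") |>
    dplyr::mutate(delta = 100 * (.data[[paste0("y", year_to)]] -
                                   .data[[paste0("y", year_from)]]))
  out <- dplyr::select(st, "node", "delta")
  attr(out, "loss_gain") <- out$delta[out$node == "loss"]
  attr(out, "leachate_gain") <- out$delta[out$node == "leachate"]
  out
}

#' Simulate enrichment data from the gamma trend model
#'
#' Draws a dataset from the gamma log-link mixed model: linear predictor
#' `alpha + f_c(time) + beta_c + b_i + eps_{ics}` with a normal plot random
#' intercept `b_i`, an AR-1 latent chain `eps` per plot-by-compartment
#' series (marginal SD `sd_resid`, correlation `rho`), and a gamma response
#' with mean `exp(eta)` and the given shape. Per-compartment time effects
#' are centered over the design years so the intercept keeps its meaning.
#'
#' @param n_plots Number of plots.
#' @param years Vector of sampling years.
#' @param intercept Log-scale intercept.
#' @param comp_effects Named log-scale contrasts for `moss`, `O_horizon`,
#'   `A_horizon`, `B_horizon` against the above-ground baseline.
#' @param time_effect Common time effect: a function of scaled time
#'   `u in [0, 1]`, or `NULL` for none. Ignored for compartments listed in
#'   `compartment_time_effects`.
#' @param compartment_time_effects Optional named list of per-compartment
#'   time-effect functions (scaled time), e.g.
#'   [field_like_time_effects()], producing compartment-specific trends.
#' @param sd_plot,sd_resid,rho,shape Variance components: plot random
#'   intercept SD, AR-1 chain marginal SD and correlation (log scale), and
#'   the gamma shape (`Inf` makes the response equal its mean `exp(eta)`
#'   exactly).
#' @param seed Integer seed.
#' @return Tibble `plot, year, compartment, enrichment, eta_true`.
#' @export
simulate_enrichment_glmm <- function(n_plots = 7, years = 2007:2015,
                                     intercept = 3.941,
                                     comp_effects = c(moss = 1.358,
                                                      O_horizon = -0.349,
                                                      A_horizon = -2.321,
                                                      B_horizon = -3.364),
                                     time_effect = function(u)
                                       -1.5 * u + 0.5 * u^2,
                                     compartment_time_effects = NULL,
                                     sd_plot = 0.226, sd_resid = 0.439,
                                     rho = 0.197, shape = 50,
                                     seed = 1L) {
  stopifnot(abs(rho) < 1, sd_plot >= 0, sd_resid >= 0, shape > 0)
  set.seed(as.integer(seed))
  comps <- c("aboveground", names(comp_effects))
  beta <- c(0, unname(comp_effects))
  names(beta) <- comps
  u <- if (length(years) > 1) {
    (years - min(years)) / (max(years) - min(years))
  } else rep(0, length(years))

  f_of <- function(cmp) {
    f <- NULL
    if (!is.null(compartment_time_effects) &&
        cmp %in% names(compartment_time_effects)) {
      f <- compartment_time_effects[[cmp]]
    } else if (!is.null(time_effect)) {
      f <- time_effect
    }
    if (is.null(f)) return(rep(0, length(u)))
    v <- f(u)
    v - mean(v)   # centered over the design years
  }
  fmat <- vapply(comps, f_of, numeric(length(years)))

  b <- stats::rnorm(n_plots, 0, sd_plot)
  d <- tidyr::crossing(plot = seq_len(n_plots),
                       compartment = factor(comps, levels = comps)) |>
    dplyr::mutate(.series = dplyr::row_number()) |>
    tidyr::crossing(year_index = seq_along(years)) |>
    dplyr::arrange(.data$.series, .data$year_index)
  eps <- as.vector(vapply(seq_len(n_plots * length(comps)), function(s) {
    e <- numeric(length(years))
    e[1] <- stats::rnorm(1, 0, sd_resid)
    if (length(years) > 1) {
      for (k in 2:length(years)) {
        e[k] <- rho * e[k - 1] +
          stats::rnorm(1, 0, sd_resid * sqrt(1 - rho^2))
      }
    }
    e
  }, numeric(length(years))))
  d <- d |>
    dplyr::mutate(
      year = years[.data$year_index],
      eta_true = intercept + beta[as.character(.data$compartment)] +
        fmat[cbind(.data$year_index,
                   match(as.character(.data$compartment), comps))] +
        b[.data$plot] + eps,
      enrichment = if (is.infinite(shape)) exp(.data$eta_true) else
        stats::rgamma(dplyr::n(), shape = shape,
                      rate = shape / exp(.data$eta_true)))
  dplyr::select(d, "plot", "year", "compartment", "enrichment", "eta_true")
}

#' Field-like compartment-specific time effects
#'
#' Log-scale time-effect functions (of scaled time `u in [0, 1]`) whose
#' shapes and magnitudes echo the decadal field pattern: steep moss decline,
#' moderate above-ground decline, rising O- and B-horizon enrichment, and a
#' rise-then-fall in the A-horizon. Used to generate data with strongly
#' compartment-specific trends.
#'
#' @return Named list of functions, one per main compartment.
#' @export
field_like_time_effects <- function() {
  list(
    aboveground = function(u) -1.2 * u + 0.3 * u^2,
    moss = function(u) -2.8 * u + 0.4 * u * (1 - u),
    O_horizon = function(u) 0.95 * u,
    A_horizon = function(u) 1.6 * u - 1.2 * u^2,
    B_horizon = function(u) 2.0 * u)
}
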