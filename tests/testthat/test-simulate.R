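test_that("simulator conserves the dose exactly at every step", {
  sim <- simulate_tracer_fate(sim_config(seed = 3))
  totals <- sim$nodes |>
    dplyr::summarise(s = sum(.data$frac_applied),
                     .by = c("plot", "year"))
  expect_true(all(abs(totals$s - 1) <= 1e-9))
})

test_that("same seed gives bit-identical output, different seed differs", {
  a <- simulate_experiment(sim_config(seed = 10))
  b <- simulate_experiment(sim_config(seed = 10))
  c <- simulate_experiment(sim_config(seed = 11))
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$truth$tracer, b$truth$tracer)
  expect_false(identical(a$measurements$delta15n,
                         c$measurements$delta15n))
})

test_that("absorbing edge cases: zero rates trap the dose in moss,
           moss_to_loss = 1 empties it in one year", {
  r0 <- c(moss_to_o = 0, moss_to_loss = 0, o_to_a = 0, o_to_plant = 0,
          a_to_b = 0, plant_to_litter = 0, litter_to_o = 0,
          b_to_leachate = 0)
  sim <- simulate_tracer_fate(sim_config(rates = r0, seed = 1,
                                         sd_rate_plot = 0))
  moss <- dplyr::filter(sim$nodes, .data$node == "moss")
  expect_true(all(moss$frac_applied == 1))

  r1 <- r0; r1[["moss_to_loss"]] <- 1
  sim1 <- simulate_tracer_fate(sim_config(rates = r1, seed = 1,
                                          sd_rate_plot = 0))
  first <- dplyr::filter(sim1$nodes, .data$year == 2007)
  expect_equal(first$frac_applied[first$node == "loss"][1], 1)
  expect_equal(first$frac_applied[first$node == "moss"][1], 0)
})

test_that("default trajectory echoes the decadal field pattern", {
  cfg <- sim_config(sd_rate_plot = 0, seed = 1)
  sim <- simulate_tracer_fate(cfg)
  st <- sim$nodes |>
    dplyr::filter(.data$plot == 1) |>
    tidyr::pivot_wider(names_from = "node",
                       values_from = "frac_applied")
  moss <- 100 * st$moss
  o <- 100 * st$O_horizon
  # moss: ~2/3 of the dose at first sampling, falling to ~1/7 in 4 steps
  expect_gt(moss[1], 55); expect_lt(moss[1], 75)
  expect_gt(moss[5], 9); expect_lt(moss[5], 20)
  # O-horizon approaches ~40 % by the eighth year
  expect_gt(o[8], 30); expect_lt(o[8], 47)
  # loss exceeds 30 points within the first five years
  expect_gt(100 * st$loss[5], 30)
})

test_that("invalid rate configurations are rejected at load", {
  bad <- c(moss_to_o = 0.7, moss_to_loss = 0.5, o_to_a = 0, o_to_plant = 0,
           a_to_b = 0, plant_to_litter = 0, litter_to_o = 0,
           b_to_leachate = 0)
  expect_error(sim_config(rates = bad), "exceed 1")
  bad2 <- bad; bad2[["moss_to_o"]] <- -0.1
  expect_error(sim_config(rates = bad2), "\\[0, 1\\]")
  expect_error(sim_config(rates = bad[-1]), "missing rate")
})

test_that("measurement inversion: zero tracer gives natural delta, and
           doubling the pool halves the atom-percent excess", {
  cfg <- sim_config(sd_rate_plot = 0, seed = 4)
  r0 <- cfg$rates * 0
  cfg0 <- sim_config(rates = r0, sd_rate_plot = 0, seed = 4)
  m <- tracer_to_measurements(simulate_tracer_fate(cfg0), noise = FALSE)
  o_lab <- dplyr::filter(m, .data$compartment == "O_horizon",
                         .data$role == "labelled")
  expect_equal(unique(o_lab$delta15n),
               unname(cfg0$natural_delta[["O_horizon"]]))

  truth <- simulate_tracer_fate(cfg)
  m1 <- tracer_to_measurements(truth, noise = FALSE)
  cfg2 <- cfg
  cfg2$pools$m_pool_gN_m2 <- 2 * cfg2$pools$m_pool_gN_m2
  truth2 <- truth; truth2$config <- cfg2
  m2 <- tracer_to_measurements(truth2, noise = FALSE)
  ex1 <- delta_to_atom_percent(m1$delta15n[m1$role == "labelled"]) -
    delta_to_atom_percent(m1$delta15n[m1$role == "reference"])
  ex2 <- delta_to_atom_percent(m2$delta15n[m2$role == "labelled"]) -
    delta_to_atom_percent(m2$delta15n[m2$role == "reference"])
  expect_equal(ex2, ex1 / 2, tolerance = 1e-9)
})

test_that("noise-free pipeline inversion returns the simulated truth", {
  cfg <- sim_config(seed = 8)
  sim <- simulate_experiment(cfg, noise = FALSE)
  rec <- recovery_table(sim$measurements, cfg$pools, cfg$tracer)
  truth <- sim$truth$tracer |>
    dplyr::summarise(truth = 100 * mean(.data$frac_applied),
                     .by = c("compartment", "year"))
  j <- dplyr::inner_join(rec, truth, by = c("compartment", "year"))
  expect_equal(j$recovery_mean, j$truth, tolerance = 1e-9)
})

test_that("delta-scale noise widens the downstream standard errors", {
  mean_se <- function(noise_sd, seed) {
    cfg <- sim_config(sd_delta_noise = noise_sd, seed = seed)
    sim <- simulate_experiment(cfg)
    # high delta noise legitimately pushes some labelled pools below their
    # reference; the flagged negatives are part of what widens the SEs
    rec <- suppressWarnings(
      recovery_table(sim$measurements, cfg$pools, cfg$tracer))
    mean(rec$recovery_se)
  }
  seeds <- 1:10
  lo <- vapply(seeds, function(s) mean_se(0.05, s), numeric(1))
  hi <- vapply(seeds, function(s) mean_se(5, s), numeric(1))
  expect_gt(mean(hi), mean(lo))
  expect_gt(mean(hi > lo), 0.8)
})

test_that("gamma trend generator honours its variance switches", {
  # zero variances and infinite shape: response equals exp(alpha + beta)
  d <- simulate_enrichment_glmm(n_plots = 2, years = 2007:2009,
                                time_effect = NULL, sd_plot = 0,
                                sd_resid = 0, rho = 0, shape = Inf,
                                seed = 1)
  moss <- dplyr::filter(d, .data$compartment == "moss")
  expect_equal(unique(moss$enrichment), exp(3.941 + 1.358))

  # AR-1 chain: empirical lag-1 autocorrelation tracks rho at large n
  d2 <- simulate_enrichment_glmm(n_plots = 2, years = 1:400,
                                 time_effect = NULL, sd_plot = 0,
                                 rho = 0.9, shape = Inf, seed = 2)
  eps <- log(d2$enrichment) - 3.941 -
    c(aboveground = 0, moss = 1.358, O_horizon = -0.349,
      A_horizon = -2.321, B_horizon = -3.364)[as.character(d2$compartment)]
  ac <- d2 |>
    dplyr::mutate(eps = eps) |>
    dplyr::arrange(.data$plot, .data$compartment, .data$year) |>
    dplyr::summarise(ac = stats::cor(.data$eps[-1],
                                     .data$eps[-length(.data$eps)]),
                     .by = c("plot", "compartment"))
  expect_equal(mean(ac$ac), 0.9, tolerance = 0.05)
  expect_error(simulate_enrichment_glmm(rho = 1.2), "rho")
})
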