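test_that("hand mass balance: moss loses 10, O gains 4, chain quiet", {
  d <- tibble::tibble(compartment = c("moss", "O_horizon"),
                      delta = c(-10, 4))
  led <- infer_flows(d)
  expect_equal(led$flow[led$from == "moss" & led$to == "O"], 4)
  expect_equal(attr(led, "residual"), 6)
  expect_equal(led$flow[led$from == "O" & led$to == "A"], 0)
})

test_that("all-zero deltas give an all-zero ledger", {
  d <- tibble::tibble(compartment = compartment_levels()[1:9], delta = 0)
  led <- infer_flows(d)
  expect_true(all(led$flow == 0))
  expect_equal(attr(led, "residual"), 0)
})

test_that("ledger closes at every node and conserves tracer globally", {
  set.seed(5)
  for (i in 1:20) {
    d <- tibble::tibble(compartment = compartment_levels()[1:9],
                        delta = rnorm(9, 0, 5))
    leach <- abs(rnorm(1, 0, 0.1))
    litter <- abs(rnorm(1, 0, 0.5))
    led <- suppressWarnings(infer_flows(d, litter_flux = litter,
                                        leachate_flux = leach))
    # closure is validated internally; check global conservation here:
    # sum of measured-node deltas + residual + leachate export = 0
    meas <- sum(d$delta[d$compartment != "leachate"])
    expect_equal(meas + attr(led, "residual") + leach, 0,
                 tolerance = 1e-9)
  }
})

test_that("flow inference is linear in the deltas (superposition)", {
  set.seed(6)
  d1 <- tibble::tibble(compartment = compartment_levels()[1:9],
                       delta = rnorm(9))
  d2 <- dplyr::mutate(d1, delta = rnorm(9))
  dsum <- dplyr::mutate(d1, delta = d1$delta + d2$delta)
  f <- function(d) suppressWarnings(infer_flows(d))$flow
  expect_equal(f(dsum), f(d1) + f(d2), tolerance = 1e-9)
})

test_that("flows recovered from a noise-free simulation match the
           simulated transfers", {
  cfg <- sim_config(sd_rate_plot = 0, sd_delta_noise = 0, seed = 2)
  sim <- simulate_experiment(cfg, noise = FALSE)
  rec <- recovery_table(sim$measurements, cfg$pools, cfg$tracer)
  r <- cfg$rates

  # one-year interval: inferred flows equal the first-order transfers
  y0 <- 2008; y1 <- 2009
  state <- sim$truth$nodes |>
    dplyr::filter(.data$plot == 1, .data$year == y0)
  frac <- stats::setNames(state$frac_applied, state$node)
  litter_flux <- 100 * frac[["litter_current"]] * r[["litter_to_o"]]
  leach_flux <- 100 * frac[["B_horizon"]] * r[["b_to_leachate"]]
  led <- infer_flows(compartment_deltas(rec, y0, y1),
                     litter_flux = litter_flux,
                     leachate_flux = leach_flux)
  expect_equal(led$flow[led$from == "moss" & led$to == "O"],
               100 * frac[["moss"]] * r[["moss_to_o"]], tolerance = 1e-6)
  expect_equal(attr(led, "residual"),
               100 * frac[["moss"]] * r[["moss_to_loss"]],
               tolerance = 1e-6)
  expect_equal(led$flow[led$from == "O" & led$to == "A"],
               100 * frac[["O_horizon"]] * r[["o_to_a"]], tolerance = 1e-6)
  expect_equal(led$flow[led$from == "O" & led$to == "plants"],
               100 * frac[["O_horizon"]] * r[["o_to_plant"]],
               tolerance = 1e-6)
})

test_that("deltas from the printed recovery table match their differences", {
  rec <- heathland_recovery()
  d <- compartment_deltas(rec, 2007, 2011)
  expect_equal(d$delta[d$compartment == "O_horizon"], 24.27 - 17.80,
               tolerance = 1e-9)
  expect_equal(d$delta[d$compartment == "moss"], 14.42 - 66.38,
               tolerance = 1e-9)
  # compartments missing an endpoint year are excluded with a message
  expect_message(compartment_deltas(rec, 2007, 2014), "calluna")
  # identical years: all deltas zero
  expect_true(all(compartment_deltas(rec, 2009, 2009)$delta == 0))
})

test_that("negative residuals warn and unsolvable topologies error", {
  d <- tibble::tibble(compartment = c("moss", "O_horizon"),
                      delta = c(2, 4))   # net creation of tracer
  expect_warning(infer_flows(d), "negative residual")

  topo <- flow_topology()
  topo$edges$type[topo$edges$from == "plants"] <- "unknown"
  topo$edges$flow <- NULL
  d2 <- tibble::tibble(compartment = "moss", delta = -1)
  expect_error(infer_flows(d2, topology = topo), "not solvable")
})

test_that("DOT export carries every edge", {
  led <- infer_flows(tibble::tibble(compartment = "moss", delta = -5))
  dot <- flows_to_dot(led)
  expect_match(dot, "digraph")
  expect_equal(length(gregexpr("->", dot)[[1]]), nrow(led))
  tf <- withr::local_tempfile(fileext = ".dot")
  flows_to_dot(led, tf)
  expect_true(file.exists(tf))
})
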