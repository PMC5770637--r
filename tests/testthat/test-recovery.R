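test_that("enrichment table is zero when labelled equals reference", {
  d <- tidyr::crossing(plot = 1:4, year = 2007:2008,
                       compartment = c("moss", "O_horizon")) |>
    tidyr::crossing(role = c("labelled", "reference")) |>
    dplyr::mutate(delta15n = -6.2)
  en <- enrichment_table(d)
  expect_true(all(en$enrichment_mean == 0))
  expect_true(all(en$n_plots == 4))
})

test_that("the two aggregation modes agree under a shared reference delta", {
  set.seed(9)
  labs <- tidyr::crossing(plot = 1:5, year = 2007,
                          compartment = "moss") |>
    dplyr::mutate(role = "labelled", delta15n = runif(5, 100, 700))
  refs <- dplyr::mutate(labs, role = "reference", delta15n = -6.0)
  d <- dplyr::bind_rows(labs, refs)
  a <- enrichment_table(d, mode = "per_plot_mean")
  b <- enrichment_table(d, mode = "mean_of_deltas")
  # enrichment is linear in delta_sample at fixed reference
  expect_equal(a$enrichment_mean, b$enrichment_mean, tolerance = 1e-12)
})

test_that("unmatched labelled records error without fallback, pair via cell
           mean with it", {
  d <- tibble::tibble(
    plot = c(1, 1, 2), role = c("labelled", "reference", "labelled"),
    year = 2007, compartment = "moss", delta15n = c(100, -6, 90))
  expect_error(enrichment_table(d, fallback = FALSE), "without a same-plot")
  en <- enrichment_table(d, fallback = TRUE)
  expect_equal(en$n_plots, 2)
})

test_that("recovery table inverts a constructed tracer allocation exactly", {
  pools <- simple_pools()
  fracs <- c(moss = 0.66, O_horizon = 0.18, A_horizon = 0.05,
             B_horizon = 0.004)
  d <- make_known_measurements(fracs, pools)
  rec <- recovery_table(d, pools)
  expect_equal(stats::setNames(rec$recovery_mean, rec$compartment),
               100 * fracs[rec$compartment], tolerance = 1e-9)
  expect_true(all(rec$recovery_se < 1e-9))  # identical plots

  # closure: a single compartment holding the whole dose recovers 100 %
  d1 <- make_known_measurements(c(O_horizon = 1), pools)
  rec1 <- recovery_table(d1, pools)
  expect_equal(rec1$recovery_mean, 100, tolerance = 1e-9)

  # additivity: total over compartments equals recovery of the pooled mass
  expect_equal(sum(rec$recovery_mean), 100 * sum(fracs), tolerance = 1e-9)
})

test_that("recovery table flags missing pools and sub-reference pools", {
  pools <- simple_pools()
  d <- make_known_measurements(c(moss = 0.5), pools)
  expect_error(recovery_table(d, dplyr::filter(pools, year != 2007)),
               "no pool mass")
  d_low <- d
  d_low$delta15n[d_low$role == "labelled"] <- -20  # below reference
  expect_warning(recovery_table(d_low, pools), "below the reference")
})

test_that("annual totals change composition exactly as sampled", {
  rec <- heathland_recovery()
  suppressMessages({
    tot <- annual_totals(rec)
    tot_all <- annual_totals(rec, include_non_annual = TRUE)
  })
  # the two non-annual compartments only widen the 2014/2015 totals
  expect_equal(tot$total_recovery[tot$year == 2009], 64.15,
               tolerance = 1e-9)
  expect_equal(tot_all$total_recovery[tot_all$year == 2015] -
                 tot$total_recovery[tot$year == 2015],
               2.59 + 4.86, tolerance = 1e-9)
  expect_warning(annual_totals(rec[0, ]), "empty")
})

test_that("paired t-tests: power under a large shift, zero-variance cells
           flagged", {
  # planted shift of 10 within-pair SDs, n = 7: essentially always detected
  set.seed(101)
  n_rep <- 200
  detected <- vapply(seq_len(n_rep), function(i) {
    ref <- rnorm(7, -6, 1)
    lab <- ref + 10 + rnorm(7, 0, 1)
    d <- tibble::tibble(
      plot = rep(1:7, 2),
      role = rep(c("labelled", "reference"), each = 7),
      year = 2007, compartment = "moss", delta15n = c(lab, ref))
    paired_delta_tests(d)$significant
  }, logical(1))
  expect_gt(mean(detected), 0.99)

  # identical pairs: not evaluable, not significant, no infinities
  d0 <- tibble::tibble(plot = rep(1:3, 2),
                       role = rep(c("labelled", "reference"), each = 3),
                       year = 2007, compartment = "moss", delta15n = 5)
  r0 <- paired_delta_tests(d0)
  expect_false(r0$evaluable)
  expect_false(r0$significant)
  expect_true(is.na(r0$t_statistic))

  # a single pair is flagged rather than tested
  d1 <- dplyr::filter(d0, plot == 1)
  expect_false(paired_delta_tests(d1)$evaluable)
})

test_that("duplicate measurement cells and bad roles are rejected", {
  d <- tibble::tibble(plot = c(1, 1), role = "labelled", year = 2007,
                      compartment = "moss", delta15n = c(1, 2))
  expect_error(enrichment_table(d), "duplicate")
  d2 <- tibble::tibble(plot = 1, role = "treated", year = 2007,
                       compartment = "moss", delta15n = 1)
  expect_error(enrichment_table(d2), "role")
})
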