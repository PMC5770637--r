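test_that("response offset is applied and guarded", {
  expect_equal(prepare_response(0), 0.001)
  expect_equal(prepare_response(746.60), 746.601)
  expect_error(prepare_response(-0.002), "index: 1")
  expect_error(prepare_response(c(1, NA)), "finite")
})

test_that("outlier screening removes the planted extreme and caps removal", {
  set.seed(30)
  d <- tibble::tibble(compartment = "moss",
                      enrichment = rnorm(500, 100, 5))
  d$enrichment[137] <- 100 + 20 * stats::IQR(d$enrichment[-137])
  out <- remove_outliers(d)
  rep <- attr(out, "outlier_report")
  expect_equal(nrow(rep), 1)
  expect_equal(nrow(out), 499)
  expect_equal(rep$enrichment, d$enrichment[137])

  # 10 % planted extremes, 2 % cap: only the worst 2 % go, with a warning
  d2 <- tibble::tibble(compartment = "moss",
                       enrichment = c(rnorm(450, 100, 5),
                                      1000 + seq_len(50) * 100))
  expect_warning(out2 <- remove_outliers(d2), "cap")
  expect_equal(nrow(out2), 500 - floor(0.02 * 500))
  # the removals are the most extreme points
  expect_true(all(attr(out2, "outlier_report")$enrichment >=
                    1000 + 41 * 100))

  # clean data pass through untouched
  out3 <- remove_outliers(d[-137, ])
  expect_equal(nrow(attr(out3, "outlier_report")), 0)
  expect_error(remove_outliers(d, max_fraction = 0.2), "0.05")
})

test_that("cubic regression spline basis has df centered columns and spans
           natural cubic splines", {
  x <- rep(2007:2015, 5)
  B <- time_basis(x, df = 4)
  expect_equal(ncol(B), 4)
  expect_equal(colMeans(B), rep(0, 4), tolerance = 1e-10,
               ignore_attr = TRUE)

  # independent textbook construction: natural cubic splines on the same
  # knots lie in span{1, B}
  knots <- attr(B, "smooth")$xp
  N <- splines::ns(x, knots = knots[-c(1, length(knots))],
                   Boundary.knots = range(knots))
  for (j in seq_len(ncol(N))) {
    res <- stats::residuals(stats::lm(N[, j] ~ B))
    expect_lt(max(abs(res)), 1e-10)
  }
  # prediction reproduces the basis at the original points
  expect_equal(eval_time_basis(B, x), unclass(B)[, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(time_basis(rep(1:3, 5), df = 4), "distinct time")
})

test_that("reduced trend model matches an independent gamma GLM", {
  d <- simulate_enrichment_glmm(n_plots = 4, time_effect = NULL,
                                sd_plot = 0, sd_resid = 0, rho = 0,
                                shape = 20, seed = 21)
  fit <- fit_gamma_gamm(d, fixed = "compartment", random = "none")
  glm_fit <- stats::glm(
    prepare_response(enrichment) ~ compartment, data = d,
    family = stats::Gamma(link = "log"))
  expect_equal(unname(glmmTMB::fixef(fit$model)$cond),
               unname(stats::coef(glm_fit)), tolerance = 1e-5)
})

test_that("full trend fit recovers the generating parameters on one draw", {
  d <- simulate_enrichment_glmm(seed = 77)
  fit <- fit_gamma_gamm(d, fixed = "additive", method = "REML")
  co <- tidy(fit)
  expect_equal(unname(co$estimate[co$term == "(Intercept)"]), 3.941,
               tolerance = 3 * co$std_error[co$term == "(Intercept)"] /
                 3.941, ignore_attr = TRUE)
  vc <- variance_components(fit)
  expect_gt(vc$sd_resid, 0.2); expect_lt(vc$sd_resid, 0.7)
  expect_true(abs(vc$rho) < 1)
  g <- glance(fit)
  expect_true(is.finite(g$AIC))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("a flat single-compartment series yields a near-null smooth", {
  d <- simulate_enrichment_glmm(n_plots = 7, time_effect = NULL,
                                sd_plot = 0.1, sd_resid = 0.2, rho = 0,
                                shape = 100, seed = 5) |>
    dplyr::filter(.data$compartment == "moss")
  fit <- fit_gamma_gamm(d, fixed = "time")
  sm <- predict_smooth(fit)
  # smooth variation small relative to its own confidence band
  expect_lt(diff(range(sm$eta)), 4 * max(sm$se))
})

test_that("Akaike weights: normalisation, invariance, ties", {
  aic <- c(100, 103, 110)
  w <- akaike_weights(aic)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(akaike_weights(aic + 57), w, tolerance = 1e-12)
  expect_equal(akaike_weights(c(5, 5)), c(0.5, 0.5))
  expect_error(akaike_weights(c(1, NA)), "finite")
})

test_that("model selection prefers the generating structure", {
  # strongly compartment-specific trends: interaction must win decisively
  d <- simulate_enrichment_glmm(
    compartment_time_effects = field_like_time_effects(), seed = 13)
  sel <- select_model(d)
  expect_equal(sel$table$model[1], "interaction")
  expect_gt(sel$table$weight[1], 0.99)
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-12)
  expect_equal(sel$best$spec$method, "REML")
  expect_s3_class(tidy(sel), "tbl_df")

  # no time effect at all: compartment-only beats the time-only model
  d0 <- simulate_enrichment_glmm(time_effect = NULL, seed = 14)
  sel0 <- select_model(d0, candidates = c("time", "compartment"))
  expect_equal(sel0$table$model[1], "compartment")
})
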