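# Gamma log-link additive mixed model for 15N enrichment trends:
# response preparation, outlier screening, fixed-df cubic regression spline
# basis, model fitting (plot random intercept + AR-1 within-series
# correlation) and AIC-based candidate-model selection.

#' Map sampled compartments to the five main trend-model strata
#'
#' The trend analysis stratifies the sampled compartments into five main
#' groups: above-ground dwarf-shrub biomass (current-year shoots, 1-2 year
#' shoots and current-year litter), the moss layer, and the O/A/B soil
#' horizons. Roots, older woody biomass and leachate are not part of the
#' annual trend design and map to `NA`.
#'
#' @param compartment Character vector of [compartment_levels()] names.
#' @return Factor with levels `aboveground, moss, O_horizon, A_horizon,
#'   B_horizon` (baseline: `aboveground`).
#' @export
main_compartment <- function(compartment) {
  map <- c(current_year_shoots = "aboveground", shoots_1_2yr = "aboveground",
           litter_current = "aboveground", moss = "moss",
           O_horizon = "O_horizon", A_horizon = "A_horizon",
           B_horizon = "B_horizon")
  factor(unname(map[as.character(compartment)]),
         levels = c("aboveground", "moss", "O_horizon", "A_horizon",
                    "B_horizon"))
}

#' Offset an enrichment response for the gamma likelihood
#'
#' The gamma log-link model requires a strictly positive response; measured
#' enrichments include exact zeros (and small negative values from
#' measurement noise), so a small constant is added before fitting.
#'
#' @param x Numeric enrichment values (per mil).
#' @param offset Positive constant added to every value (default 0.001).
#' @return `x + offset`; an error names the offending indices if any result
#'   is not strictly positive.
#' @export
prepare_response <- function(x, offset = 0.001) {
  check_number(offset, positive = TRUE, what = "offset")
  if (any(!is.finite(x))) stop("enrichment values must be finite",
                               call. = FALSE)
  out <- x + offset
  if (any(out <= 0)) {
    stop("response not positive after offset at index: ",
         paste(which(out <= 0), collapse = ", "),
         "; increase `offset` or screen these records", call. = FALSE)
  }
  out
}

#' Screen extreme enrichment values
#'
#' Flags, within each compartment, points beyond `Q3 + 3 IQR` (or below
#' `Q1 - 3 IQR`) and removes at most `max_fraction` of all points, most
#' extreme first. This operationalises dotplot-based visual screening as a
#' reproducible rule.
#'
#' @param data Data frame with an enrichment column and a `compartment`
#'   column used as the screening stratum.
#' @param value Name of the enrichment column (default `"enrichment"`).
#' @param max_fraction Cap on the removed share of all points (default 0.02,
#'   must be in `[0, 0.05]`).
#' @return `data` without the removed rows; the attribute `"outlier_report"`
#'   is a tibble of the removed rows with their fence distances. A warning is
#'   raised when the cap truncates the flagged set.
#' @export
remove_outliers <- function(data, value = "enrichment", max_fraction = 0.02) {
  stopifnot(is.data.frame(data), value %in% names(data),
            "compartment" %in% names(data))
  if (max_fraction < 0 || max_fraction > 0.05) {
    stop("`max_fraction` must be in [0, 0.05]", call. = FALSE)
  }
  x <- data[[value]]
  scores <- rep(0, nrow(data))
  for (cmp in unique(data$compartment)) {
    i <- which(data$compartment == cmp)
    q <- stats::quantile(x[i], c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    if (iqr == 0) next
    hi <- q[2] + 3 * iqr
    lo <- q[1] - 3 * iqr
    # positive score = distance beyond the fence, in IQR units
    scores[i] <- pmax(x[i] - hi, lo - x[i], 0) / iqr
  }
  flagged <- which(scores > 0)
  cap <- floor(max_fraction * nrow(data))
  if (length(flagged) > cap) {
    warning(length(flagged), " points beyond the outlier fence; removing ",
            "only the ", cap, " most extreme (cap ", max_fraction * 100,
            " % of the data)", call. = FALSE)
    flagged <- flagged[order(scores[flagged], decreasing = TRUE)][seq_len(cap)]
  }
  report <- tibble::as_tibble(data[flagged, , drop = FALSE])
  report$fence_distance_iqr <- scores[flagged]
  out <- if (length(flagged)) data[-flagged, , drop = FALSE] else data
  out <- tibble::as_tibble(out)
  attr(out, "outlier_report") <- report
  out
}

#' Fixed-df cubic regression spline basis for the time effect
#'
#' Builds an unpenalised cubic regression spline basis (knots at quantiles of
#' the observed times, identifiability absorbed by column centering) with a
#' fixed number of degrees of freedom, so the smooth enters the mixed model
#' as `df` parametric columns.
#'
#' @param times Numeric vector of observation times; at least `df + 1`
#'   distinct values are required.
#' @param df Degrees of freedom of the smooth (>= 2, default 4).
#' @return A numeric matrix with `df` columns (`s1..s<df>`), carrying the
#'   smooth construction as attribute `"smooth"` for later evaluation via
#'   [eval_time_basis()].
#' @export
time_basis <- function(times, df = 4) {
  check_number(df, positive = TRUE, what = "df")
  if (df < 2) stop("`df` must be >= 2", call. = FALSE)
  if (length(unique(times)) < df + 1) {
    stop("need at least df + 1 = ", df + 1, " distinct time points, have ",
         length(unique(times)), call. = FALSE)
  }
  sm <- mgcv::smoothCon(mgcv::s(time, bs = "cr", k = df + 1, fx = TRUE),
                        data = data.frame(time = times),
                        absorb.cons = TRUE)[[1]]
  X <- sm$X
  colnames(X) <- paste0("s", seq_len(ncol(X)))
  attr(X, "smooth") <- sm
  X
}

#' @rdname time_basis
#' @param basis A matrix returned by [time_basis()].
#' @param new_times Times at which to evaluate the same basis.
#' @export
eval_time_basis <- function(basis, new_times) {
  sm <- attr(basis, "smooth")
  stopifnot(!is.null(sm))
  X <- mgcv::PredictMat(sm, data.frame(time = new_times))
  colnames(X) <- colnames(basis)
  X
}

trend_candidates <- function() c("time", "compartment", "additive",
                                 "interaction")

trend_formula <- function(fixed, s_cols, random = "plot_ar1") {
  s_sum <- paste(s_cols, collapse = " + ")
  rhs <- switch(fixed,
    time = s_sum,
    compartment = "compartment",
    additive = paste(s_sum, "+ compartment"),
    interaction = paste0("(", s_sum, ") * compartment"))
  if (random == "plot_ar1") {
    rhs <- paste(rhs, "+ (1 | plot) + ar1(0 + yearf | series)")
  }
  stats::as.formula(paste("response ~", rhs))
}

#' Fit the gamma log-link enrichment trend model
#'
#' Fits `EN ~ Gamma(log link)` with a fixed-df cubic regression spline for
#' time, a compartment effect according to `fixed`, a normally distributed
#' plot random intercept, and an AR-1 correlated latent chain per
#' plot-by-compartment series (the residual autocorrelation structure,
#' ordered by year). Estimation is by Laplace-approximated maximum
#' likelihood via `glmmTMB`; `method = "REML"` (default) restricts the
#' likelihood for variance-component reporting, `"ML"` is used for model
#' comparison.
#'
#' @param data Data frame with columns `plot`, `year`, `compartment` (the
#'   five main strata, see [main_compartment()]) and `enrichment` (per mil).
#' @param fixed Fixed-effects structure: `"time"`, `"compartment"`,
#'   `"additive"` (time + compartment) or `"interaction"`
#'   (time x compartment).
#' @param df Spline degrees of freedom (default 4).
#' @param method `"REML"` or `"ML"`.
#' @param offset Response offset, see [prepare_response()].
#' @param random `"plot_ar1"` (the full random structure, default) or
#'   `"none"` (fixed effects only, i.e. an ordinary gamma GLM; useful for
#'   reduced-model comparisons).
#' @return An object of class `trend_fit`: list with the fitted `model`, the
#'   model `spec`, the spline `basis`, and the prepared `data`. Supports
#'   [generics::tidy()], [generics::glance()], `predict_smooth()` and
#'   [ggplot2::autoplot()].
#' @export
fit_gamma_gamm <- function(data, fixed = c("additive", "time", "compartment",
                                           "interaction"),
                           df = 4, method = c("REML", "ML"), offset = 0.001,
                           random = c("plot_ar1", "none")) {
  fixed <- match.arg(fixed)
  method <- match.arg(method)
  random <- match.arg(random)
  stopifnot(all(c("plot", "year", "compartment", "enrichment")
                %in% names(data)))
  d <- tibble::as_tibble(data)
  d$response <- prepare_response(d$enrichment, offset)
  d$plot <- factor(d$plot)
  d$compartment <- if (is.factor(d$compartment)) droplevels(d$compartment)
    else factor(d$compartment)
  d$yearf <- factor(d$year)
  d$series <- interaction(d$plot, d$compartment, drop = TRUE)
  B <- time_basis(d$year, df = df)
  for (j in seq_len(ncol(B))) d[[colnames(B)[j]]] <- B[, j]

  quiet_fit <- function(...) {
    withCallingHandlers(
      glmmTMB::glmmTMB(
        trend_formula(fixed, colnames(B), random),
        family = stats::Gamma(link = "log"),
        data = d, REML = (method == "REML"), ...),
      warning = function(w) {
        # boundary fits (AR-1 SD -> 0) emit convergence warnings but carry
        # usable estimates; demote and keep the fit
        if (grepl("convergence|NA/NaN|Hessian", conditionMessage(w),
                  ignore.case = TRUE)) {
          invokeRestart("muffleWarning")
        }
      })
  }
  model <- tryCatch(quiet_fit(), error = function(e) e)
  if (inherits(model, "error")) {
    # nlminb occasionally aborts on a NaN gradient step; retry with BFGS
    model <- quiet_fit(control = glmmTMB::glmmTMBControl(
      optimizer = stats::optim, optArgs = list(method = "BFGS")))
  }
  beta_hat <- glmmTMB::fixef(model)$cond
  if (any(!is.finite(beta_hat))) {
    stop("trend model did not converge: non-finite coefficient estimates ",
         "(optimizer message: ", model$fit$message, ")", call. = FALSE)
  }
  conv <- list(code = model$fit$convergence, message = model$fit$message,
               pd_hessian = isTRUE(model$sdr$pdHess))
  structure(
    list(model = model, basis = B,
         spec = list(fixed = fixed, df = df, method = method,
                     offset = offset, random = random),
         convergence = conv, data = d),
    class = "trend_fit")
}

# log-likelihood / AIC robust to a non-PD REML/ML Hessian: fall back to the
# optimized objective (negative log-likelihood) when logLik() is NA.
trend_loglik <- function(fit) {
  m <- fit$model
  ll <- as.numeric(stats::logLik(m))
  if (is.finite(ll)) ll else -m$fit$objective
}

trend_npar <- function(fit) {
  df <- attr(stats::logLik(fit$model), "df")
  if (is.numeric(df) && is.finite(df)) return(as.integer(df))
  # REML profiles the fixed effects out of fit$par; add them back
  n_beta <- if (fit$spec$method == "REML")
    length(glmmTMB::fixef(fit$model)$cond) else 0L
  length(fit$model$fit$par) + n_beta
}

trend_aic <- function(fit) -2 * trend_loglik(fit) + 2 * trend_npar(fit)

#' Variance components of a trend fit
#'
#' @param fit A [fit_gamma_gamm()] object.
#' @return Tibble with the plot random-intercept SD, the AR-1 chain marginal
#'   SD and correlation (log-link scale), and the gamma shape parameter.
#' @export
variance_components <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  vc <- glmmTMB::VarCorr(fit$model)$cond
  sd_plot <- attr(vc$plot, "stddev")[1]
  sd_resid <- attr(vc$series, "stddev")[1]
  corr <- attr(vc$series, "correlation")
  tibble::tibble(
    sd_plot = if (is.null(sd_plot)) NA_real_ else unname(sd_plot),
    sd_resid = if (is.null(sd_resid)) NA_real_ else unname(sd_resid),
    rho = if (is.null(corr)) NA_real_ else unname(corr[2, 1]),
    gamma_shape = 1 / stats::sigma(fit$model)^2)
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> gamma log-link GAMM, fixed = %s, spline df = %d, %s\n",
    x$spec$fixed, x$spec$df, x$spec$method))
  cat(sprintf("  n = %d, AIC = %.2f\n", nrow(x$data), trend_aic(x)))
  vc <- variance_components(x)
  cat(sprintf("  SD(plot) = %.3f, SD(resid) = %.3f, rho = %.3f\n",
              vc$sd_plot, vc$sd_resid, vc$rho))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.trend_fit <- function(x, ...) {
  co <- summary(x$model)$coefficients$cond
  tibble::tibble(term = rownames(co), estimate = co[, 1],
                 std_error = co[, 2], statistic = co[, 3],
                 p_value = co[, 4])
}

#' @export
glance.trend_fit <- function(x, ...) {
  vc <- variance_components(x)
  tibble::tibble(
    fixed = x$spec$fixed, df_spline = x$spec$df, method = x$spec$method,
    n = nrow(x$data), npar = trend_npar(x),
    log_lik = trend_loglik(x), AIC = trend_aic(x),
    sd_plot = vc$sd_plot, sd_resid = vc$sd_resid, rho = vc$rho,
    r_squared_adj = trend_r2_adj(x))
}

# approximate adjusted R^2 on the link scale against the intercept-only
# predictor (the fit's own account of explained variation; not the
# likelihood-ratio R^2 of any other software)
trend_r2_adj <- function(fit) {
  eta <- stats::predict(fit$model, type = "link")
  z <- log(fit$data$response)
  r2 <- 1 - sum((z - eta)^2) / sum((z - mean(z))^2)
  n <- length(z)
  p <- length(glmmTMB::fixef(fit$model)$cond) - 1
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Evaluate the fitted time smooth per compartment
#'
#' Evaluates the fixed-effects linear predictor over a fine time grid for
#' each compartment (random effects set to zero), with pointwise standard
#' errors, for plotting the estimated enrichment trends.
#'
#' @param fit A [fit_gamma_gamm()] object.
#' @param n_grid Number of grid points over the observed time range.
#' @return Tibble `compartment, year, eta, se, mu` (`mu = exp(eta)`, per-mil
#'   enrichment scale).
#' @export
predict_smooth <- function(fit, n_grid = 50) {
  stopifnot(inherits(fit, "trend_fit"))
  yrs <- seq(min(fit$data$year), max(fit$data$year), length.out = n_grid)
  comps <- levels(fit$data$compartment)
  nd <- tidyr::crossing(year = yrs, compartment = factor(comps,
                                                         levels = comps))
  Xs <- eval_time_basis(fit$basis, nd$year)
  for (j in seq_len(ncol(Xs))) nd[[colnames(Xs)[j]]] <- Xs[, j]
  nd$plot <- NA
  nd$yearf <- NA
  nd$series <- NA
  pr <- stats::predict(fit$model, newdata = nd, type = "link",
                       se.fit = TRUE, re.form = NA,
                       allow.new.levels = TRUE)
  nd |>
    dplyr::mutate(eta = pr$fit, se = pr$se.fit, mu = exp(pr$fit)) |>
    dplyr::select("compartment", "year", "eta", "se", "mu")
}

#' @export
autoplot.trend_fit <- function(object, ...) {
  sm <- predict_smooth(object)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$year, y = .data$mu)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = exp(.data$eta - 2 * .data$se),
                                      ymax = exp(.data$eta + 2 * .data$se)),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~compartment, scales = "free_y") +
    ggplot2::labs(x = "year",
                  y = "fitted 15N enrichment [‰]",
                  title = "Estimated enrichment trends") +
    ggplot2::theme_minimal()
}

#' Akaike weights from AIC values
#'
#' `w_i = exp(-0.5 * delta_i) / sum_j exp(-0.5 * delta_j)` with
#' `delta_i = AIC_i - min(AIC)`; invariant to adding a constant to every
#' log-likelihood and summing to one.
#'
#' @param aic Numeric vector of AIC values.
#' @return Numeric vector of weights.
#' @export
akaike_weights <- function(aic) {
  if (any(!is.finite(aic))) stop("AIC values must be finite", call. = FALSE)
  w <- exp(-0.5 * (aic - min(aic)))
  w / sum(w)
}

#' AIC-based selection among trend-model candidates
#'
#' Fits each candidate fixed-effects structure by maximum likelihood,
#' ranks them by AIC with Akaike weights, and refits the best candidate by
#' REML for parameter reporting. Candidates that fail to converge are
#' excluded with a warning and the weights renormalised.
#'
#' @inheritParams fit_gamma_gamm
#' @param candidates Character vector of fixed-effects structures to
#'   compare (default: all four).
#' @return An object of class `trend_selection`: list with `table` (tibble
#'   `model, npar, AIC, delta_aic, weight`, ranked), `fits` (the ML fits),
#'   and `best` (the REML refit of the winner). `tidy()` returns the table.
#' @export
select_model <- function(data, candidates = trend_candidates(), df = 4,
                         offset = 0.001) {
  candidates <- match.arg(candidates, trend_candidates(),
                          several.ok = TRUE)
  if (length(candidates) < 2) stop("need >= 2 candidates", call. = FALSE)
  fits <- purrr::map(candidates, function(cand) {
    tryCatch(
      fit_gamma_gamm(data, fixed = cand, df = df, method = "ML",
                     offset = offset),
      error = function(e) {
        warning("candidate '", cand, "' failed to converge and is ",
                "excluded: ", conditionMessage(e), call. = FALSE)
        NULL
      })
  })
  names(fits) <- candidates
  fits <- purrr::compact(fits)
  if (!length(fits)) stop("no candidate converged", call. = FALSE)
  tab <- tibble::tibble(
    model = names(fits),
    npar = purrr::map_int(fits, trend_npar),
    AIC = purrr::map_dbl(fits, trend_aic)) |>
    dplyr::mutate(delta_aic = .data$AIC - min(.data$AIC),
                  weight = akaike_weights(.data$AIC)) |>
    dplyr::arrange(.data$delta_aic)
  best <- tryCatch(
    fit_gamma_gamm(data, fixed = tab$model[1], df = df,
                   method = "REML", offset = offset),
    error = function(e) {
      warning("REML refit of the best model failed (",
              conditionMessage(e), "); reporting the ML fit", call. = FALSE)
      fits[[tab$model[1]]]
    })
  structure(list(table = tab, fits = fits, best = best),
            class = "trend_selection")
}

#' @export
print.trend_selection <- function(x, ...) {
  cat("<trend_selection> candidate gamma GAMMs, ML fits ranked by AIC\n")
  print(x$table)
  cat("best model refit by REML:\n")
  print(x$best)
  invisible(x)
}

#' @export
tidy.trend_selection <- function(x, ...) x$table
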