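#' Parametric "true" exposure-response curve
#'
#' A U-shaped log-relative-risk curve used as ground truth by the mortality
#' generator. The default `"spline"` form is a natural cubic spline — the
#' same function class the fitting stage estimates — whose coefficients are
#' solved from three conditions: a stationary minimum at the MMT and
#' anchored relative risks on the cold and heat sides. Two parametric
#' alternatives are kept for oracle tests: `"cubic_heat"` (quadratic cold
#' arm plus cubic heat hinge, twice continuously differentiable) and
#' `"quadratic"` (separate quadratic arms, curvature kink at the MMT).
#' Defaults: MMT 24.0 degC, RR 1.7 at a 35 degC day, RR 1.4 at 0 degC —
#' calibrated so a 5-day heatwave in the mid-30s attributes roughly 40 %
#' of deaths to heat, the magnitude city-level heat-health studies report.
#'
#' @param mmt Minimum-mortality temperature in degC.
#' @param rr_hot Relative risk at `t_hot` (defines the heat arm).
#' @param t_hot Reference hot temperature for `rr_hot`.
#' @param rr_cold Relative risk at `t_cold` (defines the cold curvature).
#' @param t_cold Reference cold temperature for `rr_cold`.
#' @param form `"spline"` (default), `"cubic_heat"` or `"quadratic"`.
#' @param knots,boundary Knot temperatures of the `"spline"` form.
#' @return An object of class `true_erf`.
#' @export
true_erf <- function(mmt = 24.0, rr_hot = 1.7, t_hot = 35,
                     rr_cold = 1.4, t_cold = 0,
                     form = c("spline", "cubic_heat", "quadratic"),
                     knots = c(13, mmt), boundary = c(-8, 38)) {
  form <- match.arg(form)
  stopifnot(t_hot > mmt, t_cold < mmt, rr_hot >= 1, rr_cold >= 1)
  a_cold <- log(rr_cold) / (mmt - t_cold)^2
  dh <- t_hot - mmt
  obj <- list(mmt = mmt, form = form, a_cold = a_cold)
  if (form == "spline") {
    # solve the spline coefficients from three conditions: the anchored
    # cold and heat relative risks, and a stationary point at the MMT
    B <- function(x) build_spline_basis(x, knots, boundary)
    h <- 1e-4
    A <- rbind(B(t_cold) - B(mmt), B(t_hot) - B(mmt),
               (B(mmt + h) - B(mmt - h)) / (2 * h))
    obj$spline_coef <- solve(A, c(log(rr_cold), log(rr_hot), 0))
    obj$spline_knots <- knots
    obj$spline_boundary <- boundary
    grid <- seq(boundary[1], boundary[2], by = 0.1)
    lrr <- drop(B(grid) %*% obj$spline_coef)
    if (abs(grid[which.min(lrr)] - mmt) > 0.11)
      stop("spline truth minimum is not at the requested MMT; ",
           "adjust knots or anchors")
  } else if (form == "cubic_heat") {
    obj$b_heat <- (log(rr_hot) - a_cold * dh^2) / dh^3
    if (obj$b_heat < 0)
      stop("heat arm weaker than the cold arm at t_hot; increase rr_hot")
  } else {
    obj$a_heat <- log(rr_hot) / dh^2
  }
  structure(obj, class = "true_erf")
}

#' Relative risk of the true curve
#'
#' @param erf A `true_erf`.
#' @param temp Temperatures in degC (vectorised).
#' @return Relative risk, 1 at the MMT.
#' @export
rr_true <- function(erf, temp) {
  stopifnot(inherits(erf, "true_erf"))
  d <- temp - erf$mmt
  lrr <- switch(erf$form,
    spline = {
      b <- build_spline_basis(c(temp, erf$mmt), erf$spline_knots,
                              erf$spline_boundary)
      v <- drop(b %*% erf$spline_coef)
      v[seq_along(temp)] - v[length(temp) + 1L]
    },
    cubic_heat = erf$a_cold * d^2 + erf$b_heat * pmax(d, 0)^3,
    quadratic = ifelse(d > 0, erf$a_heat * d^2, erf$a_cold * d^2))
  exp(lrr)
}

#' Default city daily-maximum temperature climate
#'
#' Sinusoidal annual cycle for the city-aggregate daily maximum plus
#' Gaussian day-to-day weather noise: annual mean 13 degC, amplitude
#' 10 degC (summer peak around day 200), noise sd 4.5 degC, so the series
#' spans roughly 0-38 degC over a decade with regular excursions above the
#' default MMT of 24 degC.
#'
#' @return A config list for [gen_city_tmax()].
#' @export
default_climate_config <- function() {
  list(mean = 13, amplitude = 10, peak_doy = 200, noise_sd = 4.5)
}

#' Generate a city-aggregate daily maximum temperature series
#'
#' @param n_days Series length in days.
#' @param config See [default_climate_config()].
#' @param seed Integer seed.
#' @param start_date First date of the series.
#' @return A data.frame with `date` and `tmax`.
#' @export
gen_city_tmax <- function(n_days, config = default_climate_config(),
                          seed = 1L, start_date = as.Date("2010-01-01")) {
  if (n_days < 1) stop("need at least 1 day")
  set.seed(seed)
  dates <- start_date + seq_len(n_days) - 1L
  doy <- as.integer(format(dates, "%j"))
  mu <- config$mean +
    config$amplitude * cos(2 * pi * (doy - config$peak_doy) / 365.25)
  tmax <- mu + stats::rnorm(n_days, 0, config$noise_sd)
  data.frame(date = dates, tmax = tmax)
}

#' Default baseline mortality-rate configuration
#'
#' Expected daily deaths absent any temperature effect: a base rate of 30
#' deaths/day with a 12 % winter-peaking seasonal modulation and no secular
#' trend, the standard structure that the exposure-response regression
#' controls for with harmonics and a trend term.
#'
#' @return A config list for [gen_mortality()].
#' @export
default_rate_config <- function() {
  list(base_rate = 30, season_amp = 0.12, season_peak_doy = 15,
       trend_per_year = 0, overdispersion = 1)
}

#' Generate a synthetic daily mortality series
#'
#' Daily all-cause death counts with mean
#' `mu_t = base_t * RR_true(T_t)`, where `base_t` carries annual
#' seasonality and a linear log-trend, and `RR_true` is the configured true
#' exposure-response curve. Counts are Poisson, or negative-binomial when
#' `overdispersion > 1` (variance = overdispersion * mean).
#'
#' @param tmax_series Data.frame with `date` and `tmax` (e.g. from
#'   [gen_city_tmax()]).
#' @param erf_true A `true_erf`.
#' @param rate_config See [default_rate_config()].
#' @param seed Integer seed.
#' @return A data.frame of class `mortality_series` with `date`, `deaths`,
#'   `tmax` and, as attributes, the per-day true expectation (`mu_true`)
#'   and baseline rate (`base_rate_t`) for oracle checks.
#' @export
gen_mortality <- function(tmax_series, erf_true,
                          rate_config = default_rate_config(), seed = 1L) {
  stopifnot(inherits(erf_true, "true_erf"),
            all(c("date", "tmax") %in% names(tmax_series)))
  if (rate_config$base_rate <= 0) stop("base rate must be positive")
  n <- nrow(tmax_series)
  doy <- as.integer(format(tmax_series$date, "%j"))
  yrs <- as.numeric(tmax_series$date - tmax_series$date[1]) / 365.25
  base_t <- rate_config$base_rate *
    exp(rate_config$season_amp *
          cos(2 * pi * (doy - rate_config$season_peak_doy) / 365.25) +
        rate_config$trend_per_year * yrs)
  mu <- base_t * rr_true(erf_true, tmax_series$tmax)
  set.seed(seed)
  phi <- rate_config$overdispersion %||% 1
  deaths <- if (phi > 1) {
    stats::rnbinom(n, size = mu / (phi - 1), mu = mu)
  } else {
    stats::rpois(n, mu)
  }
  out <- data.frame(date = tmax_series$date, deaths = deaths,
                    tmax = tmax_series$tmax)
  attr(out, "mu_true") <- mu
  attr(out, "base_rate_t") <- base_t
  class(out) <- c("mortality_series", "data.frame")
  out
}
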