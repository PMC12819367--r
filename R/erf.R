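#' Natural cubic spline basis for temperature
#'
#' Wraps the natural-spline construction: cubic between the boundary knots
#' and linear beyond them, no intercept column, so the column count equals
#' the number of internal knots plus one.
#'
#' @param temps Numeric vector of temperatures.
#' @param knots Internal knot temperatures, strictly increasing and
#'   strictly inside the boundary.
#' @param boundary Length-2 boundary knots.
#' @return A basis matrix with `length(knots) + 1` columns.
#' @export
build_spline_basis <- function(temps, knots, boundary = range(temps)) {
  if (length(knots) < 1L) stop("need at least one internal knot")
  if (is.unsorted(knots, strictly = TRUE)) stop("knots must be strictly increasing")
  if (min(knots) <= boundary[1] || max(knots) >= boundary[2])
    stop("internal knots must lie strictly inside the boundary knots")
  unclass(splines::ns(temps, knots = knots, Boundary.knots = boundary))
}

#' Fit a temperature-mortality exposure-response function
#'
#' Quasi-Poisson regression of daily death counts on a natural cubic spline
#' of daily maximum temperature, controlling for seasonality (annual
#' sine/cosine harmonics) and a linear secular trend:
#' `log E[deaths_t] = a + spline(Tmax_t) + harmonics_t + trend_t`.
#' The dispersion (Pearson chi-square over residual df) scales the
#' coefficient covariance. The minimum-mortality temperature (MMT) is the
#' grid argmin of the fitted curve between the 1st and 99th percentile of
#' the fitting temperatures, and the relative-risk curve is recentred there
#' so that RR(MMT) = 1.
#'
#' @param series A `mortality_series` (columns `date`, `deaths`, `tmax`).
#' @param knot_spec Quantiles of `tmax` used as internal knots (default
#'   quartiles plus the 90th percentile, which resolves the curvature
#'   around the risk minimum) or, if `knot_temps` is given, explicit knot
#'   temperatures.
#' @param knot_temps Optional explicit internal knots in degC.
#' @param n_harmonics Number of annual harmonic pairs (default 2).
#' @param mmt_step Grid resolution for the MMT search in degC.
#' @return An object of class `erf` with fields `knots`, `boundary`,
#'   `coef` (spline block), `vcov` (dispersion-scaled spline block),
#'   `mmt`, `dispersion`, `data_range`, `fit` (the glm).
#' @export
fit_erf <- function(series, knot_spec = c(0.25, 0.5, 0.75, 0.9),
                    knot_temps = NULL,
                    n_harmonics = 2L, mmt_step = 0.1) {
  stopifnot(all(c("date", "deaths", "tmax") %in% names(series)))
  if (any(series$deaths < 0)) stop("negative death counts")
  if (all(series$deaths == 0)) stop("all-zero death series cannot be fitted")
  tmax <- series$tmax
  boundary <- range(tmax)
  knots <- if (is.null(knot_temps))
    unname(stats::quantile(tmax, knot_spec)) else knot_temps
  basis <- build_spline_basis(tmax, knots, boundary)
  colnames(basis) <- paste0("tspl", seq_len(ncol(basis)))
  doy <- as.integer(format(series$date, "%j"))
  yrs <- as.numeric(series$date - series$date[1]) / 365.25
  X <- data.frame(deaths = series$deaths, basis, trend = yrs)
  for (h in seq_len(n_harmonics)) {
    X[[paste0("sin", h)]] <- sin(2 * pi * h * doy / 365.25)
    X[[paste0("cos", h)]] <- cos(2 * pi * h * doy / 365.25)
  }
  fit <- stats::glm(deaths ~ ., data = X, family = stats::quasipoisson())
  if (!fit$converged) stop("quasi-Poisson fit did not converge")
  sel <- grep("^tspl", names(stats::coef(fit)))
  erf <- structure(
    list(knots = knots, boundary = boundary,
         coef = unname(stats::coef(fit)[sel]),
         vcov = unname(stats::vcov(fit)[sel, sel, drop = FALSE]),
         dispersion = summary(fit)$dispersion,
         data_range = boundary, mmt = NA_real_, fit = fit),
    class = "erf")
  search <- unname(stats::quantile(tmax, c(0.01, 0.99)))
  erf$mmt <- find_mmt(erf, search[1], search[2], mmt_step)
  erf
}

#' @export
print.erf <- function(x, ...) {
  cat("<erf> natural spline,", length(x$coef), "df; MMT",
      round(x$mmt, 1), "degC; dispersion", round(x$dispersion, 2), "\n")
  invisible(x)
}

# basis %*% coef via rowSums so the floating-point accumulation is
# independent of how many temperatures are evaluated at once
basis_dot <- function(b, cf) {
  rowSums(b * matrix(cf, nrow(b), length(cf), byrow = TRUE))
}

erf_logrr_raw <- function(erf, temp) {
  basis_dot(build_spline_basis(temp, erf$knots, erf$boundary), erf$coef)
}

#' Locate the minimum-mortality temperature
#'
#' Grid search of the fitted log-relative-risk curve at resolution `step`;
#' ties break to the lowest temperature. The returned value is a grid
#' point, so it is quantised at `step`.
#'
#' @param erf An `erf`.
#' @param search_lo,search_hi Search bounds in degC (inside data support).
#' @param step Grid step in degC (default 0.1).
#' @return The MMT in degC.
#' @export
find_mmt <- function(erf, search_lo, search_hi, step = 0.1) {
  if (step <= 0) stop("step must be positive")
  if (search_hi < search_lo) stop("empty search range")
  grid <- seq(search_lo, search_hi, by = step)
  lrr <- erf_logrr_raw(erf, grid)
  grid[which.min(lrr)]
}

#' Relative risk at a temperature
#'
#' `RR(T) = exp(logrr(T) - logrr(MMT))`, so RR(MMT) = 1 exactly.
#'
#' @param erf An `erf`.
#' @param temp Temperatures in degC (vectorised).
#' @param coefs Optional replacement coefficient vector (used by the
#'   Monte-Carlo machinery); MMT stays fixed at the fitted point estimate.
#' @return Relative risks.
#' @export
rr_at <- function(erf, temp, coefs = NULL) {
  cf <- if (is.null(coefs)) erf$coef else coefs
  b <- build_spline_basis(c(temp, erf$mmt), erf$knots, erf$boundary)
  lrr <- basis_dot(b, cf)
  n <- length(temp)
  exp(lrr[seq_len(n)] - lrr[n + 1L])
}

#' Heat-attributable number of deaths
#'
#' `AN = sum over days with T_t > MMT of D_t * (RR(T_t) - 1) / RR(T_t)`;
#' days at or below the MMT contribute zero. The attributable fraction
#' `(RR - 1)/RR` lies in [0, 1) whenever RR >= 1.
#'
#' @param erf An `erf`.
#' @param window A `mortality_series` (observed `deaths` and `tmax`).
#' @param coefs Optional replacement coefficients (Monte-Carlo draws).
#' @return The attributable number (deaths).
#' @export
attributable_number <- function(erf, window, coefs = NULL) {
  if (any(window$deaths < 0)) stop("negative death counts")
  hot <- window$tmax > erf$mmt
  if (!any(hot)) return(0)
  rr <- rr_at(erf, window$tmax[hot], coefs)
  sum(window$deaths[hot] * (rr - 1) / rr)
}

#' Monte-Carlo confidence interval for the attributable number
#'
#' Draws coefficient vectors from a multivariate normal centred at the
#' fitted spline coefficients with the dispersion-scaled covariance,
#' recomputes the AN per draw with the MMT held fixed at its point
#' estimate, and returns percentile bounds. Zero covariance collapses the
#' interval onto the point estimate.
#'
#' @param erf An `erf`.
#' @param window A `mortality_series`.
#' @param n_sim Number of draws (>= 100).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return An object of class `an_estimate`: list with `an` (point),
#'   `ci` (length 2), `draws` (per-draw ANs), `n_sim`, `level`.
#' @export
mc_ci <- function(erf, window, n_sim = 1000L, seed = 1L, level = 0.95) {
  if (n_sim < 100L) stop("n_sim must be at least 100")
  ev <- eigen(erf$vcov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("coefficient covariance is not positive semi-definite; ",
         "add a small diagonal jitter")
  set.seed(seed)
  draws_cf <- MASS::mvrnorm(n_sim, mu = erf$coef, Sigma = erf$vcov)
  an_draws <- apply(draws_cf, 1L, function(cf)
    attributable_number(erf, window, coefs = cf))
  a <- (1 - level) / 2
  an_estimate(
    an = attributable_number(erf, window),
    ci = unname(stats::quantile(an_draws, c(a, 1 - a))),
    draws = an_draws, level = level)
}

#' Attributable-number estimate container
#'
#' @param an Point estimate (deaths).
#' @param ci Length-2 confidence bounds.
#' @param draws Optional per-draw ANs (required for paired comparison).
#' @param level Confidence level.
#' @return An `an_estimate`.
#' @export
an_estimate <- function(an, ci = c(an, an), draws = NULL, level = 0.95) {
  structure(list(an = an, ci = ci, draws = draws, n_sim = length(draws),
                 level = level),
            class = "an_estimate")
}

#' Compare a scenario's attributable deaths against the baseline
#'
#' Avoided deaths = AN(baseline) - AN(scenario), as a point estimate and,
#' when both estimates carry Monte-Carlo draws from the same coefficient
#' samples (paired), per-draw differences give the avoided-deaths CI. The
#' percent reduction is 100 * avoided / AN(baseline); when the baseline AN
#' is zero it is undefined and reported as NA.
#'
#' @param an_base,an_scen `an_estimate` objects for baseline and scenario.
#' @param scenario Scenario label for the output row.
#' @param paired Use paired per-draw differences for the avoided-deaths CI
#'   (requires draws of equal length in both estimates).
#' @return A one-row data.frame of class `attribution_result`: `scenario`,
#'   `an`, `ci_low`, `ci_high`, `avoided`, `avoided_ci_low`,
#'   `avoided_ci_high`, `pct_reduction` (unrounded; reports round to one
#'   decimal).
#' @export
compare_scenarios <- function(an_base, an_scen, scenario = "scenario",
                              paired = TRUE) {
  stopifnot(inherits(an_base, "an_estimate"), inherits(an_scen, "an_estimate"))
  avoided <- an_base$an - an_scen$an
  if (paired && !is.null(an_base$draws) && !is.null(an_scen$draws)) {
    if (length(an_base$draws) != length(an_scen$draws))
      stop("paired comparison needs draws of equal length")
    dd <- an_base$draws - an_scen$draws
    a <- (1 - an_base$level) / 2
    av_ci <- unname(stats::quantile(dd, c(a, 1 - a)))
  } else {
    av_ci <- c(NA_real_, NA_real_)
  }
  pct <- if (an_base$an == 0) NA_real_ else 100 * avoided / an_base$an
  structure(
    data.frame(scenario = scenario,
               an = an_scen$an, ci_low = an_scen$ci[1],
               ci_high = an_scen$ci[2],
               avoided = avoided,
               avoided_ci_low = av_ci[1], avoided_ci_high = av_ci[2],
               pct_reduction = pct),
    class = c("attribution_result", "data.frame"))
}

#' Reporting percentage convention
#'
#' `100 * part / total`, rounded to one decimal — the convention used for
#' percent reductions and attributable shares in reports.
#'
#' @param part,total Numerator and denominator.
#' @param digits Decimal places (default 1).
#' @return Rounded percentage (NA when `total` is 0).
#' @export
percent_of <- function(part, total, digits = 1) {
  if (total == 0) return(NA_real_)
  round(100 * part / total, digits)
}
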