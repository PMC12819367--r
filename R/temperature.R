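#' Temperature field container
#'
#' Daily maximum and minimum 2 m air temperature grids for one scenario.
#' `tmax` and `tmin` are 3-D arrays with dimensions (day, row, col).
#'
#' @param scenario_name Scenario label.
#' @param dates Vector of class Date, one per day.
#' @param tmax,tmin Arrays (day, row, col) in degrees Celsius.
#' @param tmin_corrected Logical flag recording whether the minimum
#'   temperature has been bias corrected (it never is; kept as metadata).
#' @return An object of class `temperature_field`.
#' @export
temperature_field <- function(scenario_name, dates, tmax, tmin,
                              tmin_corrected = FALSE) {
  stopifnot(length(dim(tmax)) == 3L, identical(dim(tmax), dim(tmin)))
  if (dim(tmax)[1] != length(dates))
    stop("first array dimension must match the number of dates")
  if (any(tmax < tmin))
    stop("tmax < tmin at some pixel-day")
  structure(
    list(scenario_name = scenario_name, dates = as.Date(dates),
         tmax = tmax, tmin = tmin, tmin_corrected = tmin_corrected),
    class = "temperature_field"
  )
}

#' @export
print.temperature_field <- function(x, ...) {
  d <- dim(x$tmax)
  cat("<temperature_field>", x$scenario_name, ":", d[1], "days,",
      d[2], "x", d[3], "pixels\n")
  cat("  tmax range:", paste(round(range(x$tmax), 2), collapse = " .. "),
      "degC\n")
  invisible(x)
}

field_dim <- function(field) dim(field$tmax)[2:3]

#' Default baseline-temperature configuration
#'
#' Five heatwave days with a rural background calibrated so that, combined
#' with the per-LCZ urban heat island (UHI) offsets, urban means fall near
#' the mid-30s degC for daily maxima and around 20 degC for daily minima.
#' The UHI offsets encode two structural facts about the synthetic city:
#' urban pixels are warmer than rural, and the compact-vs-open gap is larger
#' for minimum than for maximum temperature (nocturnal heat storage).
#'
#' @return A list understood by [gen_baseline_temperature()].
#' @export
default_baseline_config <- function() {
  list(
    n_days = 5L,
    start_date = as.Date("2019-07-22"),
    # rural background daily series (degC)
    background_tmax = c(31.9, 32.6, 33.3, 34.6, 33.7),
    background_tmin = c(17.5, 17.9, 18.4, 18.8, 18.1),
    # per-LCZ UHI offsets added on top of the background
    uhi_tmax = c(`2` = 3.30, `3` = 3.25, `6` = 2.97, `9` = 2.75),
    uhi_tmin = c(`2` = 4.85, `3` = 4.75, `6` = 3.62, `9` = 3.40),
    noise_sd = 0.15
  )
}

#' Generate a baseline scenario temperature field
#'
#' Daily maxima and minima are the configured regional background series
#' plus a per-LCZ urban heat island offset plus Gaussian spatial noise
#' (independent per pixel-day). With zero offsets and zero noise the field
#' is spatially uniform and equals the background.
#'
#' @param lcz An `lcz_grid`.
#' @param morph A `pixel_morphology` (reserved for morphology-dependent
#'   refinements; the default offsets are class-based).
#' @param config See [default_baseline_config()].
#' @param seed Integer seed.
#' @return A `temperature_field` named `"baseline"`.
#' @export
gen_baseline_temperature <- function(lcz, morph,
                                     config = default_baseline_config(),
                                     seed = 1L) {
  stopifnot(inherits(lcz, "lcz_grid"))
  n_days <- as.integer(config$n_days)
  if (n_days < 1L) stop("need at least 1 day")
  if (length(config$background_tmax) != n_days ||
      length(config$background_tmin) != n_days)
    stop("background series must have n_days entries")
  nr <- lcz$nrows; nc <- lcz$ncols
  off_max <- matrix(0, nr, nc)
  off_min <- matrix(0, nr, nc)
  for (code in names(config$uhi_tmax)) {
    sel <- lcz$codes == as.integer(code)
    off_max[sel] <- config$uhi_tmax[[code]]
    off_min[sel] <- config$uhi_tmin[[code]]
  }
  set.seed(seed)
  tmax <- array(0, c(n_days, nr, nc))
  tmin <- array(0, c(n_days, nr, nc))
  for (t in seq_len(n_days)) {
    nz_max <- if (config$noise_sd > 0)
      matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
    else matrix(0, nr, nc)
    nz_min <- if (config$noise_sd > 0)
      matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
    else matrix(0, nr, nc)
    tmax[t, , ] <- config$background_tmax[t] + off_max + nz_max
    tmin[t, , ] <- config$background_tmin[t] + off_min + nz_min
  }
  # enforce the physical ordering pixel-wise (noise is small relative to
  # the diurnal range, so this never triggers with default settings)
  tmin <- pmin(tmin, tmax - 0.1)
  dates <- config$start_date + seq_len(n_days) - 1L
  temperature_field("baseline", dates, tmax, tmin)
}

#' Default scenario-response configuration
#'
#' Linear cooling emulator coefficients: degrees of cooling per unit
#' plan-area-weighted roof-albedo increase (`k_alb_*`) and per unit increase
#' in the unpaved fraction (`k_green_*`), separately for daily maxima and
#' minima. Defaults place the albedo response at about 0.9 degC (maximum)
#' and 0.4 degC (minimum) per 0.1 neighbourhood albedo increase — the upper
#' end of the range reported by modelling reviews — and the greening
#' response so that a 20 % relative increase in urban vegetation cools
#' minima more than maxima.
#'
#' @return A list understood by [gen_scenario_temperature()].
#' @export
default_response_config <- function() {
  list(k_alb_max = 9.0, k_alb_min = 4.1,
       k_green_max = 6.3, k_green_min = 9.6,
       noise_sd = 0.05)
}

#' Generate a scenario temperature field from the baseline
#'
#' Emulates the atmospheric response to a morphology change as a local
#' linear function of the parameter deltas:
#' `dT = -k_alb * d(roof_albedo) * plan_area_fraction
#'       - k_green * d(1 - ISA) + noise`,
#' applied separately to tmax and tmin with their own coefficients. Pixels
#' whose morphology is unchanged are untouched (up to noise, which is only
#' added where a deterministic delta exists). The rural scenario instead
#' removes the configured per-LCZ UHI offsets entirely.
#'
#' @param baseline Baseline `temperature_field`.
#' @param spec A `scenario_spec`.
#' @param morph_base,morph_scen `pixel_morphology` before/after the scenario
#'   transform.
#' @param response_config See [default_response_config()]. For the rural
#'   scenario, must also carry `uhi_tmax`/`uhi_tmin` (the offsets to remove)
#'   and the `lcz` grid.
#' @param seed Integer seed for the response noise.
#' @return A `temperature_field` named after the scenario.
#' @export
gen_scenario_temperature <- function(baseline, spec, morph_base, morph_scen,
                                     response_config = default_response_config(),
                                     seed = 1L) {
  stopifnot(inherits(baseline, "temperature_field"),
            inherits(spec, "scenario_spec"))
  gd <- field_dim(baseline)
  if (!identical(gd, morph_dim(morph_base)) ||
      !identical(gd, morph_dim(morph_scen)))
    stop("grid shapes of baseline field and morphology do not match")
  nr <- gd[1]; nc <- gd[2]
  if (isTRUE(spec$rural_flag)) {
    if (is.null(response_config$lcz))
      stop("rural scenario needs the lcz grid in response_config")
    lcz <- response_config$lcz
    d_max <- matrix(0, nr, nc); d_min <- matrix(0, nr, nc)
    for (code in names(response_config$uhi_tmax)) {
      sel <- lcz$codes == as.integer(code)
      d_max[sel] <- -response_config$uhi_tmax[[code]]
      d_min[sel] <- -response_config$uhi_tmin[[code]]
    }
  } else {
    d_alb <- morph_scen$roof_albedo - morph_base$roof_albedo
    d_unpaved <- (1 - morph_scen$isa) - (1 - morph_base$isa)
    d_max <- -response_config$k_alb_max * d_alb * morph_base$plan_area_fraction -
      response_config$k_green_max * d_unpaved
    d_min <- -response_config$k_alb_min * d_alb * morph_base$plan_area_fraction -
      response_config$k_green_min * d_unpaved
  }
  changed <- d_max != 0 | d_min != 0
  n_days <- dim(baseline$tmax)[1]
  set.seed(seed)
  tmax <- baseline$tmax
  tmin <- baseline$tmin
  for (t in seq_len(n_days)) {
    nz_max <- matrix(0, nr, nc); nz_min <- matrix(0, nr, nc)
    if (response_config$noise_sd > 0) {
      nz_max[changed] <- stats::rnorm(sum(changed), 0, response_config$noise_sd)
      nz_min[changed] <- stats::rnorm(sum(changed), 0, response_config$noise_sd)
    }
    tmax[t, , ] <- tmax[t, , ] + d_max + nz_max
    tmin[t, , ] <- tmin[t, , ] + d_min + nz_min
  }
  tmin <- pmin(tmin, tmax - 0.1)
  temperature_field(spec$name, baseline$dates, tmax, tmin)
}
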