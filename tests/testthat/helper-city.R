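# Small synthetic-city fixtures shared across tests; everything is built in
# code so sizes stay small and seeds explicit.

small_city_config <- function() {
  list(nrows = 30L, ncols = 30L, cell_size_km = 1,
       radii = c(lcz2 = 2, lcz3 = 4, lcz6 = 8, lcz9 = 11))
}

small_city <- function(seed = 1L, jitter_sd = 0.05) {
  lcz <- gen_lcz_grid(small_city_config())
  morph <- gen_pixel_morphology(lcz, jitter_sd = jitter_sd, seed = seed)
  list(lcz = lcz, morph = morph)
}

# zero-noise baseline config over 3 days for exact arithmetic checks
quiet_baseline_config <- function(uhi = TRUE) {
  cfg <- default_baseline_config()
  cfg$n_days <- 3L
  cfg$background_tmax <- c(32, 33, 34)
  cfg$background_tmin <- c(18, 19, 20)
  cfg$noise_sd <- 0
  if (!uhi) {
    cfg$uhi_tmax[] <- 0
    cfg$uhi_tmin[] <- 0
  }
  cfg
}

quiet_response_config <- function() {
  cfg <- default_response_config()
  cfg$noise_sd <- 0
  cfg
}

# uniform morphology on a tiny grid, handy for exact pixel arithmetic
uniform_morph <- function(nr = 4, nc = 4, isa = 0.4, roof_albedo = 0.3,
                          plan_area_fraction = 0.5) {
  m <- list()
  for (f in heatadapt:::MORPH_FIELDS) m[[f]] <- matrix(0.3, nr, nc)
  m$isa <- matrix(isa, nr, nc)
  m$roof_albedo <- matrix(roof_albedo, nr, nc)
  m$plan_area_fraction <- matrix(plan_area_fraction, nr, nc)
  m$ground_albedo <- matrix(0.2, nr, nc)
  structure(m, class = "pixel_morphology", dim_grid = dim(m$isa))
}

make_field <- function(tmax, tmin = tmax - 12, scenario = "baseline",
                       dates = NULL) {
  force(tmin)
  if (length(dim(tmax)) == 2L) {
    tmax <- array(tmax, c(1, dim(tmax)))
    tmin <- array(tmin, c(1, dim(tmin)))
  }
  if (is.null(dates))
    dates <- as.Date("2019-07-22") + seq_len(dim(tmax)[1]) - 1L
  temperature_field(scenario, dates, tmax, tmin)
}

# an erf object that mirrors a spline-form true_erf exactly
erf_from_truth <- function(truth) {
  stopifnot(truth$form == "spline")
  structure(
    list(knots = truth$spline_knots, boundary = truth$spline_boundary,
         coef = truth$spline_coef,
         vcov = matrix(0, length(truth$spline_coef),
                       length(truth$spline_coef)),
         dispersion = 1, data_range = truth$spline_boundary,
         mmt = truth$mmt),
    class = "erf")
}

heatwave_window <- function(deaths = c(25, 28, 31, 34, 30),
                            tmax = c(32.5, 33.4, 34.8, 35.6, 33.9)) {
  out <- data.frame(date = as.Date("2019-07-22") + 0:4,
                    deaths = deaths, tmax = tmax)
  class(out) <- c("mortality_series", "data.frame")
  out
}
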