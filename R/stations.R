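#' Construct the "true" field implied by a model bias
#'
#' The synthetic model field overestimates urban daily maxima; the truth is
#' the model minus a bias that is a linear function of the six morphological
#' predictors: `bias = intercept + sum_j coef_j * x_j`. With the default a
#' constant +1.35 degC (the typical crowdsourced-network mean bias), truth =
#' model - 1.35 at urban pixels. Rural pixels are unbiased.
#'
#' @param model_field A `temperature_field` (the raw model).
#' @param morph A `pixel_morphology`.
#' @param intercept Constant bias component in degC.
#' @param coefs Named numeric vector over (a subset of) the six predictors;
#'   missing names contribute 0.
#' @return A `temperature_field` holding the truth.
#' @export
apply_true_bias <- function(model_field, morph, intercept = 1.35,
                            coefs = NULL) {
  bias <- bias_surface(morph, intercept, coefs)
  urban <- morph$isa > 0
  bias[!urban] <- 0
  tmax <- model_field$tmax
  for (t in seq_len(dim(tmax)[1])) tmax[t, , ] <- tmax[t, , ] - bias
  tf <- model_field
  tf$tmax <- tmax
  tf$tmin <- pmin(model_field$tmin, tmax - 0.1)
  tf$scenario_name <- paste0(model_field$scenario_name, "_truth")
  tf
}

bias_surface <- function(morph, intercept, coefs) {
  d <- morph_dim(morph)
  bias <- matrix(intercept, d[1], d[2])
  for (nm in names(coefs)) {
    if (!nm %in% BIAS_PREDICTORS)
      stop("unknown bias predictor: ", nm)
    bias <- bias + coefs[[nm]] * morph[[nm]]
  }
  bias
}

#' Generate crowdsourced-style station observations
#'
#' Places `n_stations` stations on distinct urban pixels (uniformly at
#' random) and records, for every day, the truth field's daily maximum at
#' the station pixel plus Gaussian measurement noise. The paired model
#' field value is included so that bias fitting needs no re-lookup.
#'
#' @param model_field Raw model `temperature_field`.
#' @param truth_field The matching truth (e.g. from [apply_true_bias()]).
#' @param morph A `pixel_morphology` (defines the urban placement set,
#'   ISA > 0).
#' @param n_stations Number of stations; must not exceed the number of
#'   urban pixels.
#' @param noise_sd Measurement noise sd in degC.
#' @param seed Integer seed.
#' @return A data.frame of class `station_set` with columns `station_id`,
#'   `row`, `col`, `date`, `tmax_obs`, `tmax_model`.
#' @export
gen_stations <- function(model_field, truth_field, morph, n_stations = 100L,
                         noise_sd = 0.5, seed = 1L) {
  stopifnot(identical(dim(model_field$tmax), dim(truth_field$tmax)))
  urban <- which(morph$isa > 0, arr.ind = TRUE)
  if (n_stations > nrow(urban))
    stop("n_stations (", n_stations, ") exceeds urban pixel count (",
         nrow(urban), ")")
  set.seed(seed)
  pick <- urban[sample.int(nrow(urban), n_stations), , drop = FALSE]
  n_days <- dim(model_field$tmax)[1]
  out <- expand.grid(station_id = seq_len(n_stations),
                     day = seq_len(n_days))
  out$row <- pick[out$station_id, 1]
  out$col <- pick[out$station_id, 2]
  out$date <- model_field$dates[out$day]
  idx <- cbind(out$day, out$row, out$col)
  noise <- if (noise_sd > 0) stats::rnorm(nrow(out), 0, noise_sd) else 0
  out$tmax_obs <- truth_field$tmax[idx] + noise
  out$tmax_model <- model_field$tmax[idx]
  out$day <- NULL
  class(out) <- c("station_set", "data.frame")
  out
}
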