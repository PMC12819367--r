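#' Evaluation metrics for paired prediction/observation series
#'
#' @param pred,obs Equal-length numeric vectors.
#' @return A list with `rmse`, `mae`, `r2` (squared Pearson correlation;
#'   NA when either series has zero variance), `mean_bias`
#'   (mean of pred - obs).
#' @export
eval_metrics <- function(pred, obs) {
  if (length(pred) != length(obs) || length(pred) == 0L)
    stop("pred and obs must have equal nonzero length")
  e <- pred - obs
  r2 <- if (stats::sd(pred) == 0 || stats::sd(obs) == 0) NA_real_
        else stats::cor(pred, obs)^2
  list(rmse = sqrt(mean(e^2)), mae = mean(abs(e)), r2 = r2,
       mean_bias = mean(e))
}

station_design <- function(stations, morph) {
  idx <- cbind(stations$row, stations$col)
  X <- sapply(BIAS_PREDICTORS, function(f) morph[[f]][idx])
  colnames(X) <- BIAS_PREDICTORS
  as.data.frame(X)
}

#' Fit a spatially explicit bias model
#'
#' Regresses the per-station-day model bias (model tmax minus observed
#' tmax) on the six morphological predictors of the station pixel — urban
#' fraction, building-surface-to-plan ratio, plan area fraction, frontal
#' area fraction, surface height, mean building height. The predictors are
#' per-pixel constants, so the learned correction is one static spatial
#' surface applied to every day.
#'
#' @param stations A `station_set` (carries `tmax_obs` and `tmax_model`).
#' @param morph A `pixel_morphology`.
#' @param kind One of `"mean_only"`, `"linear"`, `"ridge"`, `"lasso"`,
#'   `"random_forest"`.
#' @param hyper Hyperparameters: `lambda` grid for the penalised kinds
#'   (internal CV picks one), `ntree`/`mtry` for the forest, `seed` for the
#'   forest's bootstrap.
#' @return An object of class `bias_model` with the fitted regressor and
#'   in-sample training metrics.
#' @export
fit_bias_model <- function(stations, morph, kind = "linear",
                           hyper = list(lambda = 10^seq(-3, 1, length.out = 20),
                                        ntree = 200, seed = 1L)) {
  kind <- match.arg(kind, BIAS_KINDS)
  if (length(unique(stations$station_id)) < 2L) stop("need at least 2 stations")
  y <- stations$tmax_model - stations$tmax_obs
  X <- station_design(stations, morph)
  fitted <- switch(kind,
    mean_only = list(mu = mean(y)),
    linear = {
      fit <- stats::lm(y ~ ., data = cbind(y = y, X))
      if (anyNA(stats::coef(fit))) {
        bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
        stop("singular design: collinear predictor(s) ",
             paste(bad, collapse = ", "))
      }
      fit
    },
    ridge = ,
    lasso = {
      set.seed(hyper$seed %||% 1L)
      glmnet::cv.glmnet(as.matrix(X), y,
                        alpha = if (kind == "lasso") 1 else 0,
                        lambda = hyper$lambda, nfolds = 5)
    },
    random_forest = {
      set.seed(hyper$seed %||% 1L)
      randomForest::randomForest(X, y, ntree = hyper$ntree %||% 200,
                                 mtry = hyper$mtry %||% 2)
    })
  model <- structure(
    list(kind = kind, fitted = fitted, predictors = BIAS_PREDICTORS),
    class = "bias_model")
  model$train_metrics <- eval_metrics(predict_bias_points(model, X), y)
  model
}

BIAS_KINDS <- c("mean_only", "linear", "ridge", "lasso", "random_forest")

predict_bias_points <- function(model, X) {
  switch(model$kind,
    mean_only = rep(model$fitted$mu, nrow(X)),
    linear = unname(stats::predict(model$fitted, newdata = X)),
    ridge = ,
    lasso = drop(stats::predict(model$fitted, newx = as.matrix(X),
                                s = "lambda.min")),
    random_forest = unname(stats::predict(model$fitted, newdata = X)))
}

#' Predict the bias surface on the full grid
#'
#' @param model A `bias_model`.
#' @param morph A `pixel_morphology`.
#' @return A matrix of predicted bias (degC), one value per pixel.
#' @export
predict_bias <- function(model, morph) {
  if (!all(model$predictors %in% names(morph))) stop("missing predictors")
  d <- morph_dim(morph)
  X <- as.data.frame(lapply(morph[BIAS_PREDICTORS], as.vector))
  matrix(predict_bias_points(model, X), d[1], d[2])
}

#' Select a bias-model kind by station-level bootstrap
#'
#' For each candidate kind, repeatedly splits the *stations* (not
#' station-days, to avoid leakage across days of one station) into a
#' training and a held-out fraction, fits on the training stations and
#' scores RMSE on the held-out station-days. The kind with the lowest mean
#' held-out RMSE wins; ties break to the simpler kind in the fixed order
#' mean_only < linear < ridge < lasso < random_forest. The winner is
#' refitted on all stations.
#'
#' @param stations A `station_set`.
#' @param morph A `pixel_morphology`.
#' @param kinds Candidate kinds (subset of the five).
#' @param n_boot Number of bootstrap resamples (>= 1).
#' @param train_fraction Fraction of stations used for training, in (0, 1).
#' @param seed Integer seed for the resampling.
#' @param hyper Passed to [fit_bias_model()].
#' @return The selected, refitted `bias_model`, with `selection` attached:
#'   a data.frame of per-kind mean held-out RMSE.
#' @export
select_model <- function(stations, morph, kinds = BIAS_KINDS, n_boot = 20L,
                         train_fraction = 0.8, seed = 1L,
                         hyper = list(lambda = 10^seq(-3, 1, length.out = 20),
                                      ntree = 200, seed = 1L)) {
  kinds <- match.arg(kinds, BIAS_KINDS, several.ok = TRUE)
  if (n_boot < 1L) stop("n_boot must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  ids <- sort(unique(stations$station_id))
  n_train <- floor(train_fraction * length(ids))
  if (n_train < 2L || n_train >= length(ids))
    stop("too few stations for a nonempty train/test split")
  set.seed(seed)
  splits <- lapply(seq_len(n_boot), function(b)
    sample(ids, n_train))
  scores <- sapply(kinds, function(k) {
    mean(vapply(splits, function(tr) {
      train <- stations[stations$station_id %in% tr, ]
      test <- stations[!stations$station_id %in% tr, ]
      m <- fit_bias_model(train, morph, k, hyper)
      pred <- predict_bias_points(m, station_design(test, morph))
      sqrt(mean((pred - (test$tmax_model - test$tmax_obs))^2))
    }, numeric(1)))
  })
  # stable order: candidates scored in complexity order, ties -> first
  ord <- match(kinds, BIAS_KINDS)
  kinds <- kinds[order(ord)]; scores <- scores[order(ord)]
  best <- kinds[which.min(scores)]
  model <- fit_bias_model(stations, morph, best, hyper)
  model$selection <- data.frame(kind = kinds, mean_rmse = unname(scores))
  model
}

#' Bias-correct the baseline daily maximum temperature
#'
#' Subtracts the predicted static bias surface from the raw daily maximum
#' at urban pixels (ISA > 0); daily minima and rural pixels pass through
#' unchanged.
#'
#' @param baseline Raw baseline `temperature_field`.
#' @param bias_model A `bias_model`.
#' @param morph A `pixel_morphology`.
#' @return The corrected `temperature_field`.
#' @export
correct_baseline <- function(baseline, bias_model, morph) {
  bias <- predict_bias(bias_model, morph)
  bias[morph$isa <= 0] <- 0
  tmax <- baseline$tmax
  for (t in seq_len(dim(tmax)[1])) tmax[t, , ] <- tmax[t, , ] - bias
  out <- baseline
  out$tmax <- tmax
  out
}

#' Propagate the raw scenario delta onto the corrected baseline
#'
#' Assumes the modelled scenario-minus-baseline difference is unaffected by
#' the bias: `corrected_scen = corrected_base + (raw_scen - raw_base)`,
#' element-wise per pixel and day, for tmax and (flagged as uncorrected)
#' tmin.
#'
#' @param corrected_base Bias-corrected baseline `temperature_field`.
#' @param raw_base,raw_scen Raw baseline and scenario fields.
#' @return The corrected scenario `temperature_field`.
#' @export
propagate_delta <- function(corrected_base, raw_base, raw_scen) {
  if (!identical(dim(corrected_base$tmax), dim(raw_base$tmax)) ||
      !identical(dim(raw_base$tmax), dim(raw_scen$tmax)))
    stop("field shapes do not match")
  if (!identical(raw_base$dates, raw_scen$dates))
    stop("field dates do not match")
  out <- corrected_base
  out$scenario_name <- raw_scen$scenario_name
  out$tmax <- corrected_base$tmax + (raw_scen$tmax - raw_base$tmax)
  out$tmin <- corrected_base$tmin + (raw_scen$tmin - raw_base$tmin)
  out$tmin_corrected <- FALSE
  out
}
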