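#' Default end-to-end run configuration
#'
#' One document controlling every stage: the synthetic city, the scenario
#' list, the bias-correction candidates and bootstrap, the exposure binning
#' and the mortality model. Each stochastic stage derives its own seed from
#' the global seed (global seed plus a fixed per-stage offset), so stages
#' can be rerun independently yet reproducibly.
#'
#' @param seed Global integer seed.
#' @return A nested config list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    city = default_city_config(),
    morphology = list(jitter_sd = 0.05),
    baseline = default_baseline_config(),
    response = default_response_config(),
    population = default_population_config(),
    scenarios = c("cool_roofs", "green20", "green20_cool_roofs", "rural"),
    stations = list(n_stations = 120L, noise_sd = 0.4,
                    bias_intercept = 1.35,
                    bias_coefs = list(urban_fraction = 0.8)),
    bias_correction = list(kinds = c("mean_only", "linear", "random_forest"),
                           n_boot = 10L, train_fraction = 0.8),
    exposure = list(bin_width = 0.25, fractions = c(0.5, 0.99),
                    green_threshold = 0.2),
    mortality = list(n_years_fit = 5L, erf = list(mmt = 24.0, rr_hot = 1.7),
                     rate = default_rate_config(),
                     window_base_rate = 22,
                     knot_spec = c(0.25, 0.5, 0.75, 0.9),
                     n_sim = 1000L, level = 0.95)
  )
}

# fixed per-stage seed offsets (kept small so derived seeds stay < 2^31)
STAGE_SEED_OFFSET <- c(city = 11L, morphology = 23L, population = 37L,
                       baseline = 41L, scenario = 53L, stations = 67L,
                       climate = 71L, mortality = 83L, window = 89L,
                       bias = 97L, mc = 101L)

stage_seed <- function(config, stage) {
  (config$seed * 1009L + STAGE_SEED_OFFSET[[stage]]) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' Generate the synthetic city and its inputs, apply the adaptation
#' scenarios, bias-correct the baseline daily maxima and propagate scenario
#' deltas, compute population-weighted exposure statistics per scenario,
#' and estimate heat-attributable deaths with scenario comparisons. Rerun
#' with an identical config is bit-identical.
#'
#' @param config A config list from [default_run_config()] or
#'   [read_run_config()].
#' @return A list of stage artifacts: `lcz`, `morph`, `pop`, `mask`,
#'   `fields` (corrected, per scenario), `scenario_summaries`, `exposure`,
#'   `erf`, `attribution`, `manifest`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  # --- generate -----------------------------------------------------------
  lcz <- gen_lcz_grid(config$city)
  morph <- gen_pixel_morphology(lcz, jitter_sd = config$morphology$jitter_sd,
                                seed = stage_seed(config, "morphology"))
  pop <- gen_population(lcz, config$population,
                        seed = stage_seed(config, "population"))
  raw_base <- gen_baseline_temperature(lcz, morph, config$baseline,
                                       seed = stage_seed(config, "baseline"))
  mask <- urban_mask(morph, config$exposure$green_threshold)

  # --- scenarios ----------------------------------------------------------
  scen_names <- setdiff(config$scenarios, "baseline")
  response <- config$response
  response$lcz <- lcz
  response$uhi_tmax <- config$baseline$uhi_tmax
  response$uhi_tmin <- config$baseline$uhi_tmin
  raw_fields <- list(baseline = raw_base)
  morphs <- list(baseline = morph)
  for (i in seq_along(scen_names)) {
    sp <- scenario_spec(scen_names[i])
    m2 <- apply_scenario(morph, sp, lcz, config$exposure$green_threshold)
    morphs[[sp$name]] <- m2
    raw_fields[[sp$name]] <- gen_scenario_temperature(
      raw_base, sp, morph, m2, response,
      seed = stage_seed(config, "scenario") + i)
  }
  scenario_summaries <- do.call(rbind, lapply(names(morphs), function(nm)
    cbind(scenario = nm, summarize_scenario(morphs[[nm]], mask))))

  # --- bias correction ----------------------------------------------------
  truth <- apply_true_bias(raw_base, morph,
                           intercept = config$stations$bias_intercept,
                           coefs = config$stations$bias_coefs)
  stations <- gen_stations(raw_base, truth, morph,
                           n_stations = config$stations$n_stations,
                           noise_sd = config$stations$noise_sd,
                           seed = stage_seed(config, "stations"))
  bias_model <- select_model(stations, morph,
                             kinds = config$bias_correction$kinds,
                             n_boot = config$bias_correction$n_boot,
                             train_fraction = config$bias_correction$train_fraction,
                             seed = stage_seed(config, "bias"))
  corr_base <- correct_baseline(raw_base, bias_model, morph)
  fields <- list(baseline = corr_base)
  for (nm in scen_names)
    fields[[nm]] <- propagate_delta(corr_base, raw_base, raw_fields[[nm]])

  # --- exposure -----------------------------------------------------------
  stat_base <- list(max = period_statistic(corr_base, "max"),
                    min = period_statistic(corr_base, "min"))
  exposure <- list(
    bins = lapply(stat_base, function(s)
      pop_weighted_distribution(s, pop, mask, config$exposure$bin_width)),
    thresholds = lapply(stat_base, function(s)
      stats::setNames(
        vapply(config$exposure$fractions, function(f)
          pop_weighted_threshold(s, pop, mask, f), numeric(1)),
        paste0("p", 100 * config$exposure$fractions))),
    cooling = lapply(stats::setNames(scen_names, scen_names), function(nm)
      list(max = lcz_cooling_curves(stat_base$max,
                                    period_statistic(fields[[nm]], "max"),
                                    pop, mask, lcz),
           min = lcz_cooling_curves(stat_base$min,
                                    period_statistic(fields[[nm]], "min"),
                                    pop, mask, lcz))))

  # --- mortality ----------------------------------------------------------
  mcfg <- config$mortality
  erf0 <- do.call(true_erf, mcfg$erf)
  clim <- gen_city_tmax(ceiling(365.25 * mcfg$n_years_fit),
                        seed = stage_seed(config, "climate"))
  fit_series <- gen_mortality(clim, erf0, mcfg$rate,
                              seed = stage_seed(config, "mortality"))
  erf <- fit_erf(fit_series, knot_spec = mcfg$knot_spec)

  city_tmax <- lapply(fields, function(f) city_series(f, pop, mask))
  wrate <- mcfg$rate
  wrate$base_rate <- mcfg$window_base_rate
  window <- gen_mortality(city_tmax$baseline, erf0, wrate,
                          seed = stage_seed(config, "window"))
  mc_seed <- stage_seed(config, "mc")
  an <- lapply(city_tmax, function(ct) {
    w <- window
    w$tmax <- ct$tmax  # same observed deaths, scenario temperatures
    mc_ci(erf, w, n_sim = mcfg$n_sim, seed = mc_seed, level = mcfg$level)
  })
  attribution <- do.call(rbind, lapply(scen_names, function(nm)
    compare_scenarios(an$baseline, an[[nm]], scenario = nm)))
  attribution <- rbind(
    compare_scenarios(an$baseline, an$baseline, scenario = "baseline"),
    attribution)

  manifest <- list(seed = config$seed,
                   stage_seeds = lapply(
                     stats::setNames(names(STAGE_SEED_OFFSET),
                                     names(STAGE_SEED_OFFSET)),
                     function(s) stage_seed(config, s)),
                   scenarios = c("baseline", scen_names),
                   n_days = config$baseline$n_days,
                   grid = c(lcz$nrows, lcz$ncols),
                   bias_kind = bias_model$kind,
                   mmt = erf$mmt,
                   window_deaths = sum(window$deaths))
  list(lcz = lcz, morph = morph, morphs = morphs, pop = pop, mask = mask,
       raw_fields = raw_fields, fields = fields, stations = stations,
       bias_model = bias_model, scenario_summaries = scenario_summaries,
       exposure = exposure, erf = erf, window = window,
       an = an, attribution = attribution, manifest = manifest)
}

#' Population-weighted city-aggregate daily series
#'
#' Daily maximum temperature for the city as a whole: the
#' population-weighted mean of the urban pixels' daily maxima.
#'
#' @param field A `temperature_field`.
#' @param pop Population grid.
#' @param mask Urban mask.
#' @return A data.frame with `date` and `tmax`.
#' @export
city_series <- function(field, pop, mask) {
  p <- as.vector(unclass(pop))[as.vector(mask)]
  w <- p / sum(p)
  n_days <- dim(field$tmax)[1]
  tm <- vapply(seq_len(n_days), function(t) {
    sum(field$tmax[t, , ][mask] * w)
  }, numeric(1))
  data.frame(date = field$dates, tmax = tm)
}

#' Report tables from pipeline artifacts
#'
#' Assembles the scenario-summary table (mean urban albedo, paved fraction,
#' urban-mean daily max/min temperatures with deltas to baseline), the
#' exposure thresholds and per-LCZ median cooling, and the attribution
#' table, all with one-decimal rounding for temperatures, deaths and
#' percentages. Optionally writes them as CSV/JSON under `out_dir`.
#'
#' @param artifacts Result of [run_pipeline()].
#' @param out_dir Optional output directory.
#' @return A list of data.frames: `scenario_table`, `exposure_table`,
#'   `cooling_medians`, `attribution_table`.
#' @export
report_tables <- function(artifacts, out_dir = NULL) {
  if (is.null(artifacts$fields)) stop("missing pipeline artifacts")
  mask <- artifacts$mask; pop <- artifacts$pop
  scen <- names(artifacts$fields)
  urban_mean <- function(field, which) {
    s <- period_statistic(field, which)
    mean(s[mask])
  }
  tmax <- vapply(artifacts$fields, urban_mean, numeric(1), which = "max")
  tmin <- vapply(artifacts$fields, urban_mean, numeric(1), which = "min")
  st <- artifacts$scenario_summaries
  st <- st[match(scen, st$scenario), ]
  scenario_table <- data.frame(
    scenario = scen,
    mean_urban_albedo = round(st$mean_urban_albedo, 2),
    mean_urban_paved_fraction = round(st$mean_urban_paved_fraction, 2),
    mean_tmax = round(tmax, 1),
    delta_tmax = round(tmax - tmax[["baseline"]], 1),
    mean_tmin = round(tmin, 1),
    delta_tmin = round(tmin - tmin[["baseline"]], 1),
    row.names = NULL)

  thr <- artifacts$exposure$thresholds
  exposure_table <- data.frame(
    statistic = rep(names(thr), each = length(thr[[1]])),
    fraction = rep(names(thr[[1]]), length(thr)),
    temperature = round(unlist(thr, use.names = FALSE), 1))

  cooling_medians <- do.call(rbind, lapply(names(artifacts$exposure$cooling),
    function(nm) {
      cl <- artifacts$exposure$cooling[[nm]]
      do.call(rbind, lapply(names(cl), function(w)
        cbind(scenario = nm, statistic = w,
              transform(cl[[w]]$medians,
                        median_cooling = round(median_cooling, 1)))))
    }))

  at <- artifacts$attribution
  attribution_table <- data.frame(
    scenario = at$scenario,
    an = round(at$an, 1), ci_low = round(at$ci_low, 1),
    ci_high = round(at$ci_high, 1),
    avoided = round(at$avoided, 1),
    pct_reduction = round(at$pct_reduction, 1))

  out <- list(scenario_table = scenario_table,
              exposure_table = exposure_table,
              cooling_medians = cooling_medians,
              attribution_table = attribution_table)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(artifacts$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
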