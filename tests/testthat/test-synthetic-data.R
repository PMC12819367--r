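test_that("concentric LCZ grid has an urban core and rural corners", {
  lcz <- gen_lcz_grid(default_city_config())
  ctr <- c(ceiling(lcz$nrows / 2), ceiling(lcz$ncols / 2))
  expect_equal(lcz$codes[ctr[1], ctr[2]], 2L)
  expect_equal(lcz$codes[1, 1], 101L)
  expect_equal(lcz$codes[lcz$nrows, lcz$ncols], 101L)
  expect_setequal(unique(as.vector(lcz$codes)), c(2L, 3L, 6L, 9L, 101L))

  cfg <- default_city_config()
  cfg$radii[] <- 0
  expect_true(all(gen_lcz_grid(cfg)$codes == 101L))

  cfg <- small_city_config()
  cfg$radii["lcz9"] <- 40
  expect_error(gen_lcz_grid(cfg), "too small")
  cfg$radii <- c(lcz2 = 5, lcz3 = 3, lcz6 = 8, lcz9 = 11)
  expect_error(gen_lcz_grid(cfg), "non-decreasing")
})

test_that("generators are deterministic under a fixed seed", {
  city <- small_city(seed = 4L)
  expect_identical(small_city(seed = 4L)$morph, city$morph)
  expect_identical(gen_population(city$lcz, seed = 9L),
                   gen_population(city$lcz, seed = 9L))
  f1 <- gen_baseline_temperature(city$lcz, city$morph, seed = 2L)
  expect_identical(f1, gen_baseline_temperature(city$lcz, city$morph,
                                                seed = 2L))
  truth <- apply_true_bias(f1, city$morph)
  expect_identical(
    gen_stations(f1, truth, city$morph, 20L, seed = 3L),
    gen_stations(f1, truth, city$morph, 20L, seed = 3L))
  clim <- gen_city_tmax(400, seed = 5L)
  expect_identical(clim, gen_city_tmax(400, seed = 5L))
  expect_identical(gen_mortality(clim, true_erf(), seed = 6L),
                   gen_mortality(clim, true_erf(), seed = 6L))
})

test_that("population densities follow the configured per-LCZ means", {
  city <- small_city()
  cfg <- default_population_config()
  totals <- sapply(1:20, function(s) {
    pop <- gen_population(city$lcz, cfg, seed = s)
    c(lcz6 = sum(pop[city$lcz$codes == 6L]),
      rural = sum(pop[city$lcz$codes == 101L]))
  })
  expect_gt(mean(totals["lcz6", ]), mean(totals["rural", ]))
  # lognormal factor is mean-one, so per-pixel expectation is the density
  n6 <- sum(city$lcz$codes == 6L)
  expect_equal(mean(totals["lcz6", ]) / n6, cfg$density[["6"]],
               tolerance = 0.1)

  cfg0 <- cfg
  cfg0$density[] <- 0
  expect_true(all(gen_population(city$lcz, cfg0, seed = 1) == 0))
  cfg$density[["6"]] <- -5
  expect_error(gen_population(city$lcz, cfg), "non-negative")
})

test_that("baseline field equals background when offsets and noise are zero", {
  city <- small_city(jitter_sd = 0)
  cfg <- quiet_baseline_config(uhi = FALSE)
  f <- gen_baseline_temperature(city$lcz, city$morph, cfg, seed = 1L)
  for (t in 1:3) {
    expect_true(all(f$tmax[t, , ] == cfg$background_tmax[t]))
    expect_true(all(f$tmin[t, , ] == cfg$background_tmin[t]))
  }
  cfg$n_days <- 0L
  expect_error(gen_baseline_temperature(city$lcz, city$morph, cfg), "1 day")
})

test_that("baseline urban heat island matches the configured offsets", {
  city <- small_city(jitter_sd = 0)
  cfg <- quiet_baseline_config()
  f <- gen_baseline_temperature(city$lcz, city$morph, cfg, seed = 1L)
  stat_max <- period_statistic(f, "max")
  stat_min <- period_statistic(f, "min")
  rural <- city$lcz$codes == 101L
  # zero noise: per-class offsets are exact
  for (code in c("2", "3", "6", "9")) {
    sel <- city$lcz$codes == as.integer(code)
    expect_equal(mean(stat_max[sel]) - mean(stat_max[rural]),
                 cfg$uhi_tmax[[code]], tolerance = 1e-12)
  }
  # compact-vs-open gap is wider at night than by day
  compact <- city$lcz$codes %in% c(2L, 3L)
  open <- city$lcz$codes %in% c(6L, 9L)
  gap_min <- mean(stat_min[compact]) - mean(stat_min[open])
  gap_max <- mean(stat_max[compact]) - mean(stat_max[open])
  expect_gt(gap_min, gap_max)
  # physical ordering with noise on
  cfg$noise_sd <- 0.3
  fn <- gen_baseline_temperature(city$lcz, city$morph, cfg, seed = 2L)
  expect_true(all(fn$tmax >= fn$tmin))
})

test_that("scenario emulator reproduces its stated arithmetic", {
  morph <- uniform_morph(isa = 0.4, roof_albedo = 0.30,
                         plan_area_fraction = 0.5)
  f <- make_field(matrix(34, 4, 4))
  rc <- quiet_response_config()
  rc$k_alb_max <- 4

  # identity when nothing changes
  same <- gen_scenario_temperature(f, scenario_spec("cool_roofs"), morph,
                                   morph, rc, seed = 1L)
  expect_equal(same$tmax, f$tmax)

  # cool roof: dTmax = -k_alb * 0.55 * 0.5 = -1.1 degC
  m2 <- apply_cool_roofs(morph, 0.85)
  cooled <- gen_scenario_temperature(f, scenario_spec("cool_roofs"), morph,
                                     m2, rc, seed = 1L)
  expect_equal(unique(as.vector(f$tmax - cooled$tmax)), 1.1)

  bad <- uniform_morph(nr = 3, nc = 3)
  expect_error(
    gen_scenario_temperature(f, scenario_spec("cool_roofs"), morph, bad, rc),
    "shape")
})

test_that("cool-roof cooling is stronger in compact than open zones", {
  city <- small_city(jitter_sd = 0)
  f <- gen_baseline_temperature(city$lcz, city$morph,
                                quiet_baseline_config(), seed = 1L)
  m2 <- apply_cool_roofs(city$morph, 0.85)
  scen <- gen_scenario_temperature(f, scenario_spec("cool_roofs"),
                                   city$morph, m2,
                                   quiet_response_config(), seed = 1L)
  dt <- period_statistic(f, "max") - period_statistic(scen, "max")
  compact <- city$lcz$codes %in% c(2L, 3L)
  open <- city$lcz$codes %in% c(6L, 9L)
  expect_gt(mean(dt[compact]), mean(dt[open]))
  rural <- city$lcz$codes == 101L
  expect_true(all(dt[rural] == 0))
})

test_that("station observations recover the configured model bias", {
  city <- small_city(jitter_sd = 0.05)
  f <- gen_baseline_temperature(city$lcz, city$morph,
                                quiet_baseline_config(), seed = 1L)

  # zero bias, zero noise: observations equal the model
  truth0 <- apply_true_bias(f, city$morph, intercept = 0)
  st0 <- gen_stations(f, truth0, city$morph, 30L, noise_sd = 0, seed = 2L)
  expect_equal(st0$tmax_obs, st0$tmax_model)

  # constant bias: mean(model - obs) = 1.35 exactly with zero noise
  truth <- apply_true_bias(f, city$morph, intercept = 1.35)
  st <- gen_stations(f, truth, city$morph, 30L, noise_sd = 0, seed = 2L)
  expect_equal(mean(st$tmax_model - st$tmax_obs), 1.35, tolerance = 1e-12)

  # bias linear in urban fraction: least squares recovers the slope
  truth2 <- apply_true_bias(f, city$morph, intercept = 0.5,
                            coefs = list(urban_fraction = 2))
  st2 <- gen_stations(f, truth2, city$morph, 60L, noise_sd = 0, seed = 3L)
  uf <- city$morph$urban_fraction[cbind(st2$row, st2$col)]
  fit <- lm((st2$tmax_model - st2$tmax_obs) ~ uf)
  expect_equal(unname(coef(fit)["uf"]), 2, tolerance = 1e-8)

  expect_error(gen_stations(f, truth, city$morph, 10000L), "exceeds")
})

test_that("mortality counts follow the configured risk structure", {
  # flat risk: sample mean matches the base rate
  flat <- true_erf(rr_hot = 1, rr_cold = 1, form = "quadratic")
  clim <- gen_city_tmax(2000, seed = 1L)
  cfg <- default_rate_config()
  cfg$season_amp <- 0
  mort <- gen_mortality(clim, flat, cfg, seed = 2L)
  expect_equal(mean(mort$deaths), 30, tolerance = 0.05)

  # expected count scales with RR: hottest day's mean doubles when its
  # risk doubles (checked through the stored true means)
  erf0 <- true_erf()
  m1 <- gen_mortality(clim, erf0, cfg, seed = 3L)
  hot <- which.max(clim$tmax)
  mu <- attr(m1, "mu_true")
  base <- attr(m1, "base_rate_t")
  expect_equal(mu[hot] / base[hot], rr_true(erf0, clim$tmax[hot]),
               tolerance = 1e-12)

  # long series: binned empirical death rate is U-shaped with its minimum
  # near the configured MMT
  clim10 <- gen_city_tmax(3653, seed = 4L)
  m10 <- gen_mortality(clim10, erf0, cfg, seed = 5L)
  bins <- cut(m10$tmax, breaks = seq(-10, 40, 2))
  rate <- tapply(m10$deaths, bins, mean)
  ctrs <- seq(-9, 39, 2)[!is.na(rate)]
  rate <- rate[!is.na(rate)]
  min_bin <- ctrs[which.min(rate)]
  expect_lt(abs(min_bin - 24), 4)
  expect_gt(rate[length(rate)], min(rate))  # heat arm rises
  expect_gt(rate[1], min(rate))             # cold arm rises

  cfg$base_rate <- 0
  expect_error(gen_mortality(clim, erf0, cfg), "positive")
})

test_that("generated attributable excess matches the analytic expectation", {
  # over replicates, sum(D_t - base_t) on hot days estimates
  # sum(base_t * (RR_t - 1)); agreement within 3 standard errors
  erf0 <- true_erf()
  w <- heatwave_window()
  doy <- as.integer(format(w$date, "%j"))
  base_t <- 25 * exp(0.12 * cos(2 * pi * (doy - 15) / 365.25))
  mu <- base_t * rr_true(erf0, w$tmax)
  analytic <- sum(base_t * (rr_true(erf0, w$tmax) - 1))
  set.seed(42)
  excess <- replicate(300, sum(rpois(5, mu) - base_t))
  se <- sd(excess) / sqrt(length(excess))
  expect_lt(abs(mean(excess) - analytic), 3 * se)
})
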