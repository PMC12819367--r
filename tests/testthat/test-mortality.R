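test_that("spline basis is natural and spans the natural-spline space", {
  x <- seq(-5, 35, by = 0.25)
  B <- build_spline_basis(x, knots = c(10, 20), boundary = c(-5, 35))
  expect_equal(ncol(B), 3L)  # internal knots + 1, no intercept column

  # linear beyond the boundary knots: numeric second differences vanish
  xl <- seq(-15, -6, by = 0.5)
  xr <- seq(36, 45, by = 0.5)
  for (xx in list(xl, xr)) {
    Bb <- build_spline_basis(xx, knots = c(10, 20), boundary = c(-5, 35))
    expect_lt(max(abs(diff(Bb, differences = 2))), 1e-9)
  }

  # independent oracle: a natural interpolating cubic spline (stats::
  # splinefun, method "natural") lies in the span of the basis
  f <- stats::splinefun(x = c(-5, 10, 20, 35), y = c(2.0, 0.3, 0.8, 3.1),
                        method = "natural")
  y <- f(x)
  fit <- stats::lm(y ~ B)
  expect_lt(max(abs(residuals(fit))), 1e-8)

  expect_error(build_spline_basis(x, knots = c(20, 10)), "increasing")
  expect_error(build_spline_basis(x, knots = c(-10, 20),
                                  boundary = c(-5, 35)), "inside")
  expect_error(build_spline_basis(x, knots = numeric(0)), "at least one")
})

test_that("fitted curve is flat under the null and recovers a known truth", {
  flat <- true_erf(rr_hot = 1, rr_cold = 1, form = "quadratic")
  ok_flat <- sapply(1:20, function(s) {
    clim <- gen_city_tmax(3653, seed = 100 + s)
    mort <- gen_mortality(clim, flat, seed = 200 + s)
    e <- fit_erf(mort)
    grid <- quantile(clim$tmax, c(0.05, 0.25, 0.5, 0.75, 0.95))
    all(rr_at(e, grid) > 0.95 & rr_at(e, grid) < 1.05)
  })
  expect_gte(sum(ok_flat), 18)

  # quadratic-form truth: fitted RR at the 99th percentile within 10 %
  quad <- true_erf(rr_hot = 1.7, t_hot = 35, rr_cold = 1.4,
                   form = "quadratic")
  ratio <- sapply(1:10, function(s) {
    clim <- gen_city_tmax(1827, seed = 300 + s)
    mort <- gen_mortality(clim, quad, seed = 400 + s)
    e <- fit_erf(mort)
    t99 <- quantile(clim$tmax, 0.99)
    rr_at(e, t99) / (rr_true(quad, t99) / rr_true(quad, e$mmt))
  })
  expect_lt(abs(mean(ratio) - 1), 0.1)

  zero <- heatwave_window(deaths = rep(0L, 5))
  expect_error(fit_erf(zero), "all-zero")
})

test_that("minimum-mortality temperature search is an exact grid argmin", {
  # erf whose curve is a natural-spline approximation of a vertex-24
  # quadratic: analytic vertex and grid argmin agree
  x <- seq(0, 38, by = 0.05)
  y <- 0.003 * (x - 24)^2
  B <- build_spline_basis(x, knots = c(10, 18, 24, 30), boundary = c(0, 38))
  cf <- coef(stats::lm(y ~ B))[-1]  # intercept only shifts the level
  e <- structure(list(knots = c(10, 18, 24, 30), boundary = c(0, 38),
                      coef = unname(cf), vcov = diag(0, 5),
                      dispersion = 1, mmt = NA_real_), class = "erf")
  expect_equal(find_mmt(e, 10, 35, 0.1), 24, tolerance = 0.5)

  # monotone curve: argmin is the lower search bound
  ymono <- 0.02 * x
  cf2 <- coef(stats::lm(ymono ~ B - 1))
  e2 <- e; e2$coef <- unname(cf2)
  expect_equal(find_mmt(e2, 5, 35, 0.1), 5)

  # result is a grid point at the requested resolution
  expect_equal(find_mmt(e, 10.05, 35, 0.5) %% 0.5, 10.05 %% 0.5,
               tolerance = 1e-9)
  expect_error(find_mmt(e, 30, 10, 0.1), "empty")
  expect_error(find_mmt(e, 10, 30, -1), "positive")
})

test_that("relative risk is anchored at the MMT and round-trips the truth", {
  truth <- true_erf()
  e <- erf_from_truth(truth)
  expect_equal(rr_at(e, e$mmt), 1)
  # zero coefficients: RR identically 1
  e0 <- e; e0$coef <- rep(0, length(e$coef))
  expect_equal(rr_at(e0, c(0, 15, 30, 38)), rep(1, 4))
  # same basis, same coefficients: exact round trip at any temperature
  temps <- c(-5, 0, 13, 24, 30, 35, 38)
  expect_equal(rr_at(e, temps), rr_true(truth, temps), tolerance = 1e-12)
})

test_that("attributable number matches its closed form and day-loop oracle", {
  # rescale the default truth so RR(35) = 2 exactly: multiplying the
  # log-RR coefficients preserves the stationary minimum at the MMT
  truth <- true_erf(rr_hot = 1.7, t_hot = 35)
  e <- erf_from_truth(truth)
  e$coef <- e$coef * log(2) / log(1.7)

  # all days at or below the MMT contribute nothing
  cold <- heatwave_window(deaths = c(10, 10, 10, 10, 10),
                          tmax = c(20, 22, 23, 24, 18))
  expect_equal(attributable_number(e, cold), 0)

  # one day, D = 10, RR = 2 (anchored exactly at 35): AN = 5
  one <- heatwave_window(deaths = c(10, 0, 0, 0, 0),
                         tmax = c(35, 10, 10, 10, 10))
  expect_equal(attributable_number(e, one), 5, tolerance = 1e-12)

  # vectorized AN equals a literal day-by-day loop on random windows
  an_loop <- function(erf, w) {
    contrib <- numeric(nrow(w))
    for (i in seq_len(nrow(w))) {
      if (w$tmax[i] > erf$mmt) {
        rr <- rr_at(erf, w$tmax[i])
        contrib[i] <- w$deaths[i] * (rr - 1) / rr
      }
    }
    sum(contrib)
  }
  set.seed(21)
  for (r in 1:200) {
    w <- heatwave_window(deaths = rpois(5, 30),
                         tmax = runif(5, 15, 38))
    expect_identical(attributable_number(e, w), an_loop(e, w))
  }

  # monotone under uniform warming; attributable fraction in [0, 1)
  w <- heatwave_window()
  ans <- vapply(seq(0, 3, 0.5), function(d) {
    ww <- w; ww$tmax <- ww$tmax + d
    attributable_number(e, ww)
  }, numeric(1))
  expect_true(all(diff(ans) >= 0))
  rr <- rr_at(e, seq(24.1, 38, 0.1))
  af <- (rr - 1) / rr
  expect_true(all(af >= 0 & af < 1))

  bad <- heatwave_window(deaths = c(-1, 2, 3, 4, 5))
  expect_error(attributable_number(e, bad), "negative")
})

test_that("Monte-Carlo intervals degenerate, scale, and stay paired", {
  clim <- gen_city_tmax(1096, seed = 31L)
  mort <- gen_mortality(clim, true_erf(), seed = 32L)
  e <- fit_erf(mort)
  w <- heatwave_window()

  # zero covariance collapses the CI onto the point estimate
  e0 <- e; e0$vcov <- 0 * e0$vcov
  est0 <- mc_ci(e0, w, n_sim = 200, seed = 1L)
  expect_equal(est0$ci[1], est0$an)
  expect_equal(est0$ci[2], est0$an)

  # scaling the covariance by 4 at least doubles the mean half-width
  hw <- function(erf, seeds) mean(sapply(seeds, function(s) {
    ci <- mc_ci(erf, w, n_sim = 400, seed = s)$ci
    (ci[2] - ci[1]) / 2
  }))
  e4 <- e; e4$vcov <- 4 * e4$vcov
  expect_gte(hw(e4, 1:5), 2 * hw(e, 1:5) * 0.95)

  # non-positive-semi-definite covariance is rejected with advice
  ebad <- e
  ebad$vcov <- matrix(c(1, 2, 0, 0, 0,
                        2, 1, 0, 0, 0,
                        0, 0, 1, 0, 0,
                        0, 0, 0, 1, 0,
                        0, 0, 0, 0, 1), 5, 5)
  expect_error(mc_ci(ebad, w, n_sim = 200, seed = 1L), "jitter")
  expect_error(mc_ci(e, w, n_sim = 10, seed = 1L), "at least 100")

  # paired comparison: same draws, and the avoided-deaths CI is narrower
  # than the sum of the individual half-widths
  w2 <- w; w2$tmax <- w2$tmax - 1.5
  base <- mc_ci(e, w, n_sim = 500, seed = 9L)
  scen <- mc_ci(e, w2, n_sim = 500, seed = 9L)
  cmp <- compare_scenarios(base, scen, scenario = "cooler")
  expect_equal(cmp$avoided, base$an - scen$an)
  hw_av <- (cmp$avoided_ci_high - cmp$avoided_ci_low) / 2
  hw_sum <- (base$ci[2] - base$ci[1]) / 2 + (scen$ci[2] - scen$ci[1]) / 2
  expect_lte(hw_av, hw_sum)
})

test_that("scenario comparison reproduces reporting arithmetic", {
  base <- an_estimate(46.7)
  expect_equal(percent_of(compare_scenarios(base, an_estimate(46.7 - 11.9),
                                            "cool")$avoided, 46.7), 25.5)
  # identical scenario: zero avoided, zero percent
  cmp0 <- compare_scenarios(base, base, "same")
  expect_equal(cmp0$avoided, 0)
  expect_equal(cmp0$pct_reduction, 0)
  # zero baseline: percent reduction undefined
  cmpna <- compare_scenarios(an_estimate(0), an_estimate(0), "x")
  expect_true(is.na(cmpna$pct_reduction))
})
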