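#' Period-mean daily statistic per pixel
#'
#' Arithmetic mean over days of the daily maximum (or minimum) at each
#' pixel — the per-pixel "average daily maximum temperature" of the study
#' period.
#'
#' @param field A `temperature_field`.
#' @param which `"max"` or `"min"`.
#' @return A matrix, one value per pixel.
#' @export
period_statistic <- function(field, which = c("max", "min")) {
  which <- match.arg(which)
  arr <- if (which == "max") field$tmax else field$tmin
  if (dim(arr)[1] < 1L) stop("field has no days")
  apply(arr, c(2, 3), mean)
}

#' Population-weighted temperature distribution
#'
#' Assigns each masked pixel's whole population to the half-open bin
#' `[edge, edge + width)` containing its temperature, with edges aligned to
#' multiples of `bin_width` (default 0.25 degC). Bin populations sum to the
#' masked population exactly.
#'
#' @param stat Per-pixel temperature statistic (matrix).
#' @param pop A `population_grid` (or plain matrix).
#' @param mask Logical urban mask (baseline-scenario mask by convention).
#' @param bin_width Bin width in degC.
#' @return A data.frame with `bin_lower`, `bin_upper`, `population`.
#' @export
pop_weighted_distribution <- function(stat, pop, mask, bin_width = 0.25) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (!any(mask)) stop("empty mask")
  if (any(pop < 0)) stop("negative population")
  temps <- stat[mask]; p <- as.vector(unclass(pop))[as.vector(mask)]
  lower <- floor(temps / bin_width) * bin_width
  agg <- tapply(p, lower, sum)
  data.frame(bin_lower = as.numeric(names(agg)),
             bin_upper = as.numeric(names(agg)) + bin_width,
             population = as.numeric(agg), row.names = NULL)
}

#' Population-weighted exposure threshold
#'
#' The highest temperature such that at least `fraction` of the masked
#' population lives at pixels with that temperature or higher: sort pixel
#' temperatures descending, accumulate population, and return the
#' temperature at which the accumulated share first reaches `fraction`
#' (pixels sharing a value enter together). `fraction = 1` returns the
#' minimum masked temperature.
#'
#' @param stat Per-pixel temperature statistic (matrix).
#' @param pop Population grid.
#' @param mask Logical mask.
#' @param fraction Population fraction in (0, 1].
#' @return A temperature in degC.
#' @export
pop_weighted_threshold <- function(stat, pop, mask, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  temps <- stat[mask]; p <- as.vector(unclass(pop))[as.vector(mask)]
  total <- sum(p)
  if (total <= 0) stop("zero total population under mask")
  # collapse ties so pixels sharing a value enter together
  agg <- tapply(p, temps, sum)
  vals <- as.numeric(names(agg))
  ord <- order(vals, decreasing = TRUE)
  cum <- cumsum(as.numeric(agg)[ord]) / total
  vals[ord][which(cum >= fraction - 1e-12)[1]]
}

#' Population-weighted median of a pixel statistic
#'
#' The largest value experienced by at least half of the masked population
#' (the "at least 50 %" reading of the median), via
#' [pop_weighted_threshold()] on the statistic itself.
#'
#' @inheritParams pop_weighted_threshold
#' @return The weighted median.
#' @export
pop_weighted_median <- function(stat, pop, mask) {
  pop_weighted_threshold(stat, pop, mask, 0.5)
}

#' LCZ-stratified cumulative cooling curves
#'
#' For each LCZ present under the mask (and for all urban pixels pooled),
#' computes the cumulative population fraction experiencing a temperature
#' reduction of at least x, for x on a fixed grid, plus the population-
#' weighted median cooling (the reduction experienced by at least 50 % of
#' that LCZ's population). Cooling is `baseline - scenario` (positive =
#' cooler scenario).
#'
#' @param stat_base,stat_scen Per-pixel period statistics (matrices).
#' @param pop Population grid.
#' @param mask Baseline urban mask.
#' @param lcz The `lcz_grid`.
#' @param delta_grid Cooling grid (degC) for the cumulative curves.
#' @return A list with `curves` (data.frame `lcz`, `delta_t`,
#'   `cum_pop_fraction`), `medians` (data.frame `lcz`, `median_cooling`,
#'   `population`), and `omitted` (LCZ codes absent from the mask).
#' @export
lcz_cooling_curves <- function(stat_base, stat_scen, pop, mask, lcz,
                               delta_grid = seq(-1, 6, by = 0.1)) {
  if (!identical(dim(stat_base), dim(stat_scen)))
    stop("grids are not aligned")
  dt <- stat_base - stat_scen
  strata <- c(list(all = mask),
              stats::setNames(
                lapply(LCZ_URBAN_CODES, function(k) mask & lcz$codes == k),
                as.character(LCZ_URBAN_CODES)))
  present <- vapply(strata, any, logical(1))
  omitted <- names(strata)[!present]
  if (length(omitted))
    message("LCZ absent from mask, omitted: ",
            paste(omitted, collapse = ", "))
  strata <- strata[present]
  curves <- do.call(rbind, lapply(names(strata), function(nm) {
    m <- strata[[nm]]
    p <- as.vector(unclass(pop))[as.vector(m)]; d <- dt[m]
    frac <- vapply(delta_grid, function(x) sum(p[d >= x]) / sum(p),
                   numeric(1))
    data.frame(lcz = nm, delta_t = delta_grid, cum_pop_fraction = frac)
  }))
  medians <- do.call(rbind, lapply(names(strata), function(nm) {
    m <- strata[[nm]]
    data.frame(lcz = nm,
               median_cooling = pop_weighted_threshold(dt, pop, m, 0.5),
               population = sum(as.vector(unclass(pop))[as.vector(m)]))
  }))
  list(curves = curves, medians = medians, omitted = omitted)
}
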