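#' Adaptation scenario specification
#'
#' Names one of the study scenarios and carries its parameters: cool roofs
#' set every urban roof albedo to a fixed value (default 0.85); green20
#' increases the unpaved fraction of sufficiently paved urban pixels by a
#' relative fraction (default 20 %); the combined scenario applies both; the
#' rural scenario replaces urban land use with the surrounding natural class.
#'
#' @param name One of `"baseline"`, `"cool_roofs"`, `"green20"`,
#'   `"green20_cool_roofs"`, `"rural"`.
#' @param roof_albedo_override Roof albedo in [0, 1] for cool-roof
#'   scenarios.
#' @param green_relative_increase Relative increase of the unpaved fraction
#'   for greening scenarios.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(name = c("baseline", "cool_roofs", "green20",
                                   "green20_cool_roofs", "rural"),
                          roof_albedo_override = NULL,
                          green_relative_increase = NULL) {
  name <- match.arg(name)
  if (name %in% c("cool_roofs", "green20_cool_roofs") &&
      is.null(roof_albedo_override))
    roof_albedo_override <- 0.85
  if (name %in% c("green20", "green20_cool_roofs") &&
      is.null(green_relative_increase))
    green_relative_increase <- 0.2
  if (name == "baseline" &&
      (!is.null(roof_albedo_override) || !is.null(green_relative_increase)))
    stop("baseline scenario takes no parameter overrides")
  structure(
    list(name = name,
         roof_albedo_override = roof_albedo_override,
         green_relative_increase = green_relative_increase,
         rural_flag = identical(name, "rural")),
    class = "scenario_spec"
  )
}

#' Cool-roof transform
#'
#' Sets the roof albedo of every urban pixel (any pixel with positive plan
#' area fraction belonging to an urban LCZ carries roofs; here "urban" is
#' ISA > 0, i.e. any built pixel) to `albedo`. All other morphology fields
#' and all rural pixels are unchanged. Idempotent.
#'
#' @param morph A `pixel_morphology`.
#' @param albedo New roof albedo in [0, 1].
#' @return The transformed `pixel_morphology`.
#' @export
apply_cool_roofs <- function(morph, albedo = 0.85) {
  if (!is.numeric(albedo) || albedo < 0 || albedo > 1)
    stop("albedo must lie in [0, 1]")
  urban <- morph$isa > 0
  morph$roof_albedo[urban] <- albedo
  morph
}

#' Relative-greening transform
#'
#' For every pixel whose impermeable surface fraction (ISA) strictly
#' exceeds `threshold`, multiplies the unpaved fraction by
#' `1 + relative_increase`:
#' `isa_new = 1 - (1 + relative_increase) * (1 - isa)`.
#' Pixels at or below the threshold are unchanged. A combination of
#' threshold and increase that would drive ISA negative is an error rather
#' than a silent clip (with the defaults 0.20 / 0.2 the minimum attainable
#' value is 0.04, so this cannot occur).
#'
#' @param morph A `pixel_morphology`.
#' @param relative_increase Relative increase of the unpaved fraction
#'   (default 0.2 = 20 %).
#' @param threshold Strict ISA eligibility threshold (default 0.20).
#' @return The transformed `pixel_morphology`.
#' @export
apply_green20 <- function(morph, relative_increase = 0.2, threshold = 0.20) {
  if (relative_increase < 0) stop("relative_increase must be >= 0")
  if (threshold < 0 || threshold >= 1) stop("threshold must lie in [0, 1)")
  eligible <- morph$isa > threshold
  isa_new <- 1 - (1 + relative_increase) * (1 - morph$isa[eligible])
  if (any(isa_new < 0))
    stop("greening would drive ISA below 0 at ", sum(isa_new < 0),
         " pixels; choose a compatible threshold/increase")
  morph$isa[eligible] <- isa_new
  morph
}

#' Scalar form of the greening transform
#'
#' The same affine map as [apply_green20()] on a bare ISA value, applied
#' unconditionally: `1 - (1 + relative_increase) * (1 - isa)`. Because the
#' map is affine, it commutes with averaging — the transformed mean paved
#' fraction equals the transform of the mean.
#'
#' @param isa Paved fraction in [0, 1].
#' @param relative_increase Relative increase of the unpaved fraction.
#' @return Transformed paved fraction.
#' @export
green_isa <- function(isa, relative_increase = 0.2) {
  1 - (1 + relative_increase) * (1 - isa)
}

#' Rural-replacement transform
#'
#' Replaces every urban pixel's LCZ code by the modal natural class among
#' non-urban pixels within `neighborhood_radius` (Euclidean, in pixels);
#' ties break to the lowest code, and a pixel with no natural neighbour in
#' radius takes the global modal natural class. The pixel's morphology
#' becomes that class's table values with ISA = 0.
#'
#' @param lcz An `lcz_grid`.
#' @param morph The matching `pixel_morphology`.
#' @param neighborhood_radius Search radius in pixels.
#' @param table Per-LCZ morphology table for the replacement values.
#' @return A list with elements `lcz` and `morph`.
#' @export
apply_rural <- function(lcz, morph, neighborhood_radius = 5,
                        table = default_morphology_table()) {
  codes <- lcz$codes
  urban <- is_urban_code(codes)
  if (!any(urban)) return(list(lcz = lcz, morph = morph))
  natural <- !urban
  if (!any(natural)) stop("no natural pixels to replace urban land use with")
  nat_codes <- codes[natural]
  global_mode <- modal_lowest(nat_codes)
  ui <- which(urban, arr.ind = TRUE)
  ni <- which(natural, arr.ind = TRUE)
  new_codes <- codes
  for (k in seq_len(nrow(ui))) {
    d2 <- (ni[, 1] - ui[k, 1])^2 + (ni[, 2] - ui[k, 2])^2
    close <- d2 <= neighborhood_radius^2
    new_codes[ui[k, 1], ui[k, 2]] <-
      if (any(close)) modal_lowest(codes[natural][close]) else global_mode
  }
  new_lcz <- lcz_grid(new_codes, lcz$cell_size_km)
  # replacement morphology: table values of the (single) rural row; natural
  # classes not in the table fall back to the rural row as in generation
  idx <- match(new_codes, table$lcz)
  idx[is.na(idx) & new_codes >= LCZ_NATURAL_MIN] <- match(101L, table$lcz)
  new_morph <- morph
  for (f in MORPH_FIELDS) {
    vals <- matrix(table[[f]][idx], nrow(new_codes), ncol(new_codes))
    new_morph[[f]][urban] <- vals[urban]
  }
  new_morph$isa[urban] <- 0
  list(lcz = new_lcz, morph = new_morph)
}

modal_lowest <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which(tab == max(tab))][1])  # names sorted ascending
}

#' Urban mask from the paved fraction
#'
#' A pixel is urban when its impermeable surface fraction strictly exceeds
#' the threshold (default 0.2). The baseline-scenario mask should be reused
#' across all scenario analyses so that the compared population is fixed.
#'
#' @param morph A `pixel_morphology`.
#' @param threshold Strict ISA threshold in [0, 1).
#' @return A logical matrix.
#' @export
urban_mask <- function(morph, threshold = 0.2) {
  if (threshold < 0 || threshold >= 1) stop("threshold must lie in [0, 1)")
  morph$isa > threshold
}

#' Apply a scenario spec to morphology
#'
#' Dispatches to the individual transforms; the combined scenario applies
#' greening and cool roofs (the two commute since they touch disjoint
#' fields).
#'
#' @param morph A `pixel_morphology`.
#' @param spec A `scenario_spec`.
#' @param lcz The `lcz_grid` (needed for the rural scenario).
#' @param green_threshold ISA eligibility threshold for greening.
#' @return For rural, a list `(lcz, morph)`; otherwise the transformed
#'   `pixel_morphology`.
#' @export
apply_scenario <- function(morph, spec, lcz = NULL, green_threshold = 0.2) {
  stopifnot(inherits(spec, "scenario_spec"))
  switch(spec$name,
    baseline = morph,
    cool_roofs = apply_cool_roofs(morph, spec$roof_albedo_override),
    green20 = apply_green20(morph, spec$green_relative_increase,
                            green_threshold),
    green20_cool_roofs = apply_cool_roofs(
      apply_green20(morph, spec$green_relative_increase, green_threshold),
      spec$roof_albedo_override),
    rural = {
      if (is.null(lcz)) stop("rural scenario needs the lcz grid")
      apply_rural(lcz, morph)$morph
    }
  )
}

#' Scenario summary table row
#'
#' Mean urban albedo and mean urban paved fraction over the masked pixels.
#' Per-pixel albedo combines roof and ground surfaces with the plan area
#' fraction as roof weight:
#' `albedo = plan_area_fraction * roof_albedo +
#'           (1 - plan_area_fraction) * ground_albedo`.
#'
#' @param morph A `pixel_morphology`.
#' @param mask Logical urban mask (from the baseline scenario).
#' @return A one-row data.frame with `mean_urban_albedo` and
#'   `mean_urban_paved_fraction`.
#' @export
summarize_scenario <- function(morph, mask) {
  if (!any(mask)) stop("empty urban mask")
  alb <- morph$plan_area_fraction * morph$roof_albedo +
    (1 - morph$plan_area_fraction) * morph$ground_albedo
  data.frame(mean_urban_albedo = mean(alb[mask]),
             mean_urban_paved_fraction = mean(morph$isa[mask]))
}

#' Cooling per 0.1 neighbourhood albedo increase
#'
#' Normalises a scenario's mean urban temperature reduction by the mean
#' urban albedo change, expressed per 0.1 albedo: e.g. a 2.08 degC cooling
#' for an albedo change from 0.24 to 0.47 is 0.9 degC per 0.1 albedo.
#'
#' @param delta_t Mean cooling in degC (positive = cooling).
#' @param albedo_base,albedo_scen Mean urban albedo before/after.
#' @param digits Rounding for the reported value (default 1, reporting
#'   convention).
#' @return Cooling in degC per 0.1 albedo increase.
#' @export
albedo_normalized_cooling <- function(delta_t, albedo_base, albedo_scen,
                                      digits = 1) {
  d_alb <- albedo_scen - albedo_base
  if (d_alb == 0) stop("albedo change is zero")
  round(delta_t / (d_alb / 0.1), digits)
}
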