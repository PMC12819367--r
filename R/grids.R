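# LCZ codes used throughout: urban classes 2 (compact mid-rise),
# 3 (compact low-rise), 6 (open low-rise), 8 (large low-rise),
# 9 (sparsely built); natural classes are coded >= 101.
LCZ_URBAN_CODES <- c(2L, 3L, 6L, 8L, 9L)
LCZ_NATURAL_MIN <- 101L

#' Local Climate Zone grid
#'
#' A regular raster of LCZ category codes for a synthetic city. Urban codes
#' are 2, 3, 6, 8, 9; natural (rural) classes are coded 101 and above.
#'
#' @param codes Integer matrix of LCZ codes.
#' @param cell_size_km Grid resolution in kilometres.
#' @return An object of class `lcz_grid` with elements `codes`, `nrows`,
#'   `ncols`, `cell_size_km`.
#' @export
lcz_grid <- function(codes, cell_size_km = 1) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (nrow(codes) < 1L || ncol(codes) < 1L)
    stop("LCZ grid dimensions must be positive")
  ok <- codes %in% LCZ_URBAN_CODES | codes >= LCZ_NATURAL_MIN
  if (!all(ok))
    stop("invalid LCZ codes: ", paste(unique(codes[!ok]), collapse = ", "))
  structure(
    list(codes = codes, nrows = nrow(codes), ncols = ncol(codes),
         cell_size_km = cell_size_km),
    class = "lcz_grid"
  )
}

#' @export
print.lcz_grid <- function(x, ...) {
  cat("<lcz_grid>", x$nrows, "x", x$ncols, "pixels @",
      x$cell_size_km, "km\n")
  print(table(x$codes))
  invisible(x)
}

is_urban_code <- function(codes) {
  out <- codes %in% LCZ_URBAN_CODES
  if (!is.null(dim(codes))) dim(out) <- dim(codes)
  out
}

#' Generate a concentric synthetic LCZ map
#'
#' Builds a city as concentric rings around the grid centre: a compact
#' mid-rise core (LCZ2), then compact low-rise (LCZ3), open low-rise (LCZ6),
#' sparsely built (LCZ9), and rural (code 101) beyond the outermost ring.
#' Ring membership is by Euclidean distance from the centre pixel, so the
#' layout is deterministic; `seed` is accepted for interface uniformity with
#' the other generators but unused.
#'
#' @param config List with `nrows`, `ncols`, `cell_size_km` and `radii`, a
#'   named numeric vector of ring outer radii (in pixels) for
#'   `lcz2`, `lcz3`, `lcz6`, `lcz9` (non-decreasing).
#' @param seed Unused; present so every generator shares a signature.
#' @return An `lcz_grid`.
#' @export
gen_lcz_grid <- function(config = default_city_config(), seed = NULL) {
  nr <- config$nrows; nc <- config$ncols
  r <- config$radii
  need <- c("lcz2", "lcz3", "lcz6", "lcz9")
  if (!all(need %in% names(r))) stop("radii must name lcz2, lcz3, lcz6, lcz9")
  r <- r[need]
  if (any(diff(r) < 0)) stop("ring radii must be non-decreasing")
  if (nr < 1L || nc < 1L) stop("grid dimensions must be positive")
  # all rings must fit strictly inside the grid so rural pixels exist
  if (max(r) >= min(nr, nc) / 2 && max(r) > 0)
    stop("grid too small to contain all rings plus a rural margin")
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  d <- sqrt(outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, `+`))
  codes <- matrix(101L, nr, nc)
  codes[d <= r["lcz9"]] <- 9L
  codes[d <= r["lcz6"]] <- 6L
  codes[d <= r["lcz3"]] <- 3L
  codes[d <= r["lcz2"]] <- 2L
  lcz_grid(codes, config$cell_size_km %||% 1)
}

#' Default synthetic-city configuration
#'
#' A 50 x 50 grid at 1 km resolution with ring radii chosen so that the open
#' low-rise class (LCZ6) dominates the urban area, mirroring the typical
#' Belgian situation where most urban dwellers live in open low-rise
#' neighbourhoods.
#'
#' @return A list understood by [gen_lcz_grid()].
#' @export
default_city_config <- function() {
  list(nrows = 50L, ncols = 50L, cell_size_km = 1,
       radii = c(lcz2 = 3, lcz3 = 6, lcz6 = 14, lcz9 = 18))
}

MORPH_FIELDS <- c("roof_albedo", "ground_albedo", "isa", "urban_fraction",
                  "building_surface_to_plan_ratio", "plan_area_fraction",
                  "frontal_area_fraction", "surface_height",
                  "mean_building_height")

# The six predictors used by the spatially explicit bias model.
BIAS_PREDICTORS <- c("urban_fraction", "building_surface_to_plan_ratio",
                     "plan_area_fraction", "frontal_area_fraction",
                     "surface_height", "mean_building_height")

#' Default per-LCZ morphology table
#'
#' Per-class surface parameters: roof and ground albedo, impermeable surface
#' fraction (ISA), urban fraction, building-surface-to-plan-area ratio, plan
#' area fraction, frontal area fraction, surface height and mean building
#' height. Values follow published LCZ parameter ranges (compact classes are
#' denser, taller and more paved than open classes); they are configuration,
#' not ground truth. The rural row has ISA exactly 0 so the paved-fraction
#' urban mask is exact by construction.
#'
#' @return A data.frame, one row per LCZ code (2, 3, 6, 9, 101).
#' @export
default_morphology_table <- function() {
  data.frame(
    lcz = c(2L, 3L, 6L, 9L, 101L),
    roof_albedo   = c(0.30, 0.30, 0.30, 0.30, 0.00),
    ground_albedo = c(0.20, 0.20, 0.21, 0.21, 0.20),
    isa           = c(0.90, 0.80, 0.45, 0.25, 0.00),
    urban_fraction = c(0.95, 0.90, 0.60, 0.30, 0.00),
    building_surface_to_plan_ratio = c(2.0, 1.3, 0.8, 0.4, 0.0),
    plan_area_fraction  = c(0.55, 0.50, 0.30, 0.10, 0.00),
    frontal_area_fraction = c(0.30, 0.25, 0.15, 0.05, 0.00),
    surface_height      = c(25, 12, 8, 6, 0.5),
    mean_building_height = c(17.5, 6.5, 5.5, 5.0, 0.0)
  )
}

#' Per-pixel morphology from an LCZ map
#'
#' Expands the per-class morphology table to one value per pixel, with
#' optional multiplicative jitter on urban pixels to create intra-class
#' spatial variability (fractions are clipped to [0, 1] after jitter; ISA on
#' rural pixels stays exactly 0).
#'
#' @param lcz An `lcz_grid`.
#' @param table Per-LCZ morphology table (see [default_morphology_table()]).
#' @param jitter_sd Relative (lognormal) jitter standard deviation; 0
#'   disables jitter.
#' @param seed Integer seed for the jitter.
#' @return An object of class `pixel_morphology`: a list of matrices, one per
#'   morphology field, same shape as the LCZ grid.
#' @export
gen_pixel_morphology <- function(lcz, table = default_morphology_table(),
                                 jitter_sd = 0.05, seed = 1L) {
  stopifnot(inherits(lcz, "lcz_grid"))
  codes <- lcz$codes
  # natural classes not in the table fall back to the rural row
  idx <- match(codes, table$lcz)
  idx[is.na(idx) & codes >= LCZ_NATURAL_MIN] <- match(101L, table$lcz)
  if (anyNA(idx)) stop("LCZ code missing from morphology table")
  set.seed(seed)
  urban <- is_urban_code(codes)
  out <- list()
  for (f in MORPH_FIELDS) {
    m <- matrix(table[[f]][idx], nrow(codes), ncol(codes))
    if (jitter_sd > 0) {
      jit <- matrix(exp(stats::rnorm(length(m), 0, jitter_sd)),
                    nrow(codes), ncol(codes))
      m[urban] <- m[urban] * jit[urban]
      if (f %in% c("roof_albedo", "ground_albedo", "isa", "urban_fraction",
                   "plan_area_fraction", "frontal_area_fraction"))
        m <- pmin(pmax(m, 0), 1)
    }
    out[[f]] <- m
  }
  out$isa[!urban] <- 0
  structure(out, class = "pixel_morphology",
            dim_grid = dim(codes))
}

#' @export
print.pixel_morphology <- function(x, ...) {
  d <- attr(x, "dim_grid")
  cat("<pixel_morphology>", d[1], "x", d[2], "pixels;",
      length(MORPH_FIELDS), "fields\n")
  cat("  mean ISA:", round(mean(x$isa), 3),
      " mean roof albedo:", round(mean(x$roof_albedo), 3), "\n")
  invisible(x)
}

morph_dim <- function(morph) attr(morph, "dim_grid")

`%||%` <- function(a, b) if (is.null(a)) b else a
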