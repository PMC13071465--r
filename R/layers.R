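# Criterion-layer derivation: spectral indices, terrain, and point
# interpolation surfaces feeding the suitability overlay.

#' Normalized difference vegetation index
#'
#' Per-cell `(NIR - Red) / (NIR + Red)` on reflectance grids. Cells where
#' the sum is zero (no signal) become nodata; output is bounded in
#' \[-1, 1\].
#'
#' @param nir,red Aligned reflectance `Grid`s scaled to \[0, 1\].
#' @return A `Grid` of NDVI values.
#' @export
ndvi <- function(nir, red) {
  stop_if_misaligned(nir, red, "NDVI input bands")
  s <- nir$values + red$values
  out <- nir
  out$values <- (nir$values - red$values) / s
  out$values[!is.na(s) & s == 0] <- NA_real_
  out$band_name <- "ndvi"
  out
}

#' Tasseled-cap wetness coefficients for Landsat OLI
#'
#' Published wetness coefficients for surface-reflectance OLI bands
#' (blue, green, red, NIR, SWIR1, SWIR2). The wetness transform is the
#' only standard index whose natural breakpoints (positive = wet,
#' below -0.2 = dry) match the suitability rank thresholds used here.
#'
#' @return Named numeric vector of six coefficients.
#' @export
tc_wetness_oli <- function() {
  c(blue = 0.1511, green = 0.1973, red = 0.3283,
    nir = 0.3407, swir1 = -0.7117, swir2 = -0.4559)
}

#' Tasseled-cap wetness index
#'
#' Per-cell linear combination of six reflectance bands with a wetness
#' coefficient vector (default: published OLI coefficients,
#' [tc_wetness_oli()]). Nodata in any band propagates.
#'
#' @param bands List of exactly six aligned reflectance `Grid`s in the
#'   order blue, green, red, NIR, SWIR1, SWIR2.
#' @param coefficients Numeric vector of six weights.
#' @return A `Grid` of wetness values.
#' @export
wetness <- function(bands, coefficients = tc_wetness_oli()) {
  if (length(bands) != 6) stop("wetness requires exactly six bands", call. = FALSE)
  if (length(coefficients) != 6) stop("coefficient vector must have length 6", call. = FALSE)
  for (b in bands[-1]) stop_if_misaligned(bands[[1]], b, "wetness input bands")
  out <- bands[[1]]
  acc <- matrix(0, nrow(out$values), ncol(out$values))
  for (k in seq_len(6)) acc <- acc + coefficients[k] * bands[[k]]$values
  out$values <- acc
  out$band_name <- "wetness"
  out
}

#' Slope in degrees from a DEM (Horn's method)
#'
#' 8-neighbour finite differences on a 3x3 window (the standard GIS slope
#' operator), with edge rows/columns handled by edge replication. Output
#' is the slope angle in degrees, in \[0, 90).
#'
#' @param dem A `Grid` of elevations in metres on a metric grid.
#' @return A `Grid` of slope angles (degrees).
#' @export
slope_degrees <- function(dem) {
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  if (nr < 2 || nc < 2) stop("DEM must have at least 2 rows and 2 columns", call. = FALSE)
  # pad by edge replication so the 3x3 window is defined everywhere
  z <- dem$values[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  # Horn kernel: weights 1,2,1 along each edge of the window
  dzdx <- ((z[i - 1, j + 1] + 2 * z[i, j + 1] + z[i + 1, j + 1]) -
           (z[i - 1, j - 1] + 2 * z[i, j - 1] + z[i + 1, j - 1])) /
          (8 * dem$cell_size)
  dzdy <- ((z[i + 1, j - 1] + 2 * z[i + 1, j] + z[i + 1, j + 1]) -
           (z[i - 1, j - 1] + 2 * z[i - 1, j] + z[i - 1, j + 1])) /
          (8 * dem$cell_size)
  out <- dem
  out$values <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  out$values[is.na(dem$values)] <- NA_real_
  out$band_name <- "slope_deg"
  out
}

#' Inverse-distance-weighted interpolation of point samples
#'
#' For each cell centre, the weighted mean of the `max_neighbors` nearest
#' samples with weights `d^(-power)`. A cell whose centre coincides with a
#' sample (distance below `eps`) takes that sample's value exactly. The
#' output is a convex combination of sample values, so it is bounded by
#' their range.
#'
#' @param samples Data frame with columns `x`, `y`, `value` (map metres).
#' @param template A `Grid` defining the output geometry.
#' @param power IDW exponent, > 0 (default 2).
#' @param max_neighbors Number of nearest samples used per cell (default 12).
#' @param eps Snap distance in metres for exact hits (default 1e-6).
#' @return A `Grid` aligned with `template`.
#' @export
idw_interpolate <- function(samples, template, power = 2, max_neighbors = 12,
                            eps = 1e-6) {
  if (is.null(samples) || nrow(samples) == 0) {
    stop("at least one point sample is required", call. = FALSE)
  }
  if (power <= 0) stop("`power` must be positive", call. = FALSE)
  cc <- cell_centers(template)
  px <- as.vector(cc$x); py <- as.vector(cc$y)
  sx <- samples$x; sy <- samples$y; sv <- samples$value
  k <- min(max_neighbors, length(sx))
  n_cells <- length(px)
  out_v <- numeric(n_cells)
  # distance from every cell to every sample; scenes are small enough that
  # the dense n_cells x n_samples matrix is fine
  d2 <- outer(px, sx, function(a, b) (a - b)^2) +
        outer(py, sy, function(a, b) (a - b)^2)
  d <- sqrt(d2)
  for (i in seq_len(n_cells)) {
    di <- d[i, ]
    if (min(di) < eps) {
      out_v[i] <- sv[which.min(di)]
      next
    }
    idx <- order(di)[seq_len(k)]
    w <- di[idx]^(-power)
    w <- w / sum(w)
    out_v[i] <- sum(w * sv[idx])
  }
  out <- template
  out$values <- matrix(out_v, nrow(template$values), ncol(template$values))
  out$legend <- NULL
  class(out) <- "Grid"
  out
}

#' Precipitation surface from station records
#'
#' Mean-annual-precipitation surface (mm/yr) interpolated from climate
#' stations by IDW; a thin wrapper over [idw_interpolate()] so the station
#' step carries its own units and defaults.
#'
#' @param stations Data frame with columns `x`, `y`, `value` (mm/yr).
#' @param template A `Grid` defining the output geometry.
#' @param power,max_neighbors IDW parameters (see [idw_interpolate()]).
#' @return A `Grid` of precipitation in mm/yr.
#' @export
precipitation_surface <- function(stations, template, power = 2,
                                  max_neighbors = 12) {
  g <- idw_interpolate(stations, template, power = power,
                       max_neighbors = max_neighbors)
  g$band_name <- "precip_mm"
  g
}
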