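# Seeded generator of a miniature study area: a valley-to-hill DEM with a
# highway along the valley floor, six-class LULC evolving 1990-2021 by
# road-proximal urbanization and road-distal forest reversion coupled to
# ward population trajectories, class-dependent spectral bands, spatially
# autocorrelated soil fields sampled at points, three precipitation
# stations, and validation points concentrated on suitable farmland.

#' Default LULC legend of the synthetic scenes
#'
#' Six classes: 1 forest, 2 agriculture, 3 urban, 4 barren/river,
#' 5 water, 6 swamp.
#'
#' @return Named character vector (code -> label).
#' @export
lulc_legend <- function() {
  c("1" = "forest", "2" = "agriculture", "3" = "urban",
    "4" = "barren", "5" = "water", "6" = "swamp")
}

#' Configuration for the synthetic scene generator
#'
#' The defaults define the study conditions every scene emulates: a
#' 120 x 120 grid of 30 m cells (~13 km2), 20 wards, an elevation range
#' placing the valley floor below the 800 m suitability threshold,
#' monsoon-scale precipitation (~4000 mm/yr), soil fields spanning the
#' nutrient breakpoints, and per-decade conversion rates that shrink
#' agriculture toward urban near the road and forest far from it.
#'
#' @param seed Integer seed; every stochastic layer derives a sub-seed
#'   from it, so scenes are bit-reproducible.
#' @param n_rows,n_cols Grid shape (>= 8 each).
#' @param cell_size Cell edge (m).
#' @param n_wards Number of ward zones (Voronoi partition).
#' @param elev_range Valley-floor to ridge-top elevation (m).
#' @param urbanization_rate Per-decade max probability that an
#'   agricultural cell adjacent to the road urbanizes.
#' @param reversion_rate Per-decade max probability that a remote
#'   agricultural cell reverts to forest.
#' @param road_scale Gradient length scale (m) of the road effect.
#' @param coupling Population-urbanization coupling coefficient in
#'   \[0, 1\]: 0 decouples ward growth from conversion.
#' @param band_noise_sd Reflectance noise sd around class means.
#' @param n_soil_samples Number of soil sample points.
#' @param soil_correlation_m Correlation length (m) of soil fields.
#' @param station_values Mean annual precipitation (mm) at the three
#'   stations.
#' @param n_validation Number of validation points.
#' @return A `scene_config` list.
#' @export
scene_config <- function(seed = 1, n_rows = 120, n_cols = 120,
                         cell_size = 30, n_wards = 20,
                         elev_range = c(450, 1200),
                         urbanization_rate = 0.35,
                         reversion_rate = 0.30,
                         road_scale = 800,
                         coupling = 0.6,
                         band_noise_sd = 0.02,
                         n_soil_samples = 50,
                         soil_correlation_m = 600,
                         station_values = c(3900, 4200, 4050),
                         n_validation = 46) {
  if (n_rows < 8 || n_cols < 8) stop("scene must be at least 8x8 cells", call. = FALSE)
  stopifnot(urbanization_rate >= 0, urbanization_rate <= 1,
            reversion_rate >= 0, reversion_rate <= 1,
            coupling >= 0, coupling <= 1, band_noise_sd >= 0)
  structure(as.list(environment()), class = "scene_config")
}

# reflectance means per class (rows) and band (cols): chosen so NDVI and
# tasseled-cap wetness separate the classes the way the rank tables expect
class_spectra <- function() {
  m <- rbind(
    forest      = c(0.03, 0.06, 0.04, 0.40, 0.08, 0.04),
    # post-monsoon cropland: high NIR (green canopy) but drier SWIR than
    # forest, so wetness sits in the moderate band the way autumn
    # farmland imagery does
    agriculture = c(0.05, 0.08, 0.07, 0.45, 0.28, 0.12),
    urban       = c(0.12, 0.14, 0.16, 0.20, 0.22, 0.20),
    barren      = c(0.10, 0.13, 0.15, 0.22, 0.30, 0.25),
    water       = c(0.06, 0.05, 0.03, 0.02, 0.01, 0.01),
    swamp       = c(0.05, 0.07, 0.06, 0.30, 0.12, 0.08))
  colnames(m) <- c("blue", "green", "red", "nir", "swir1", "swir2")
  m
}

# run fn under a derived sub-seed without disturbing the caller's RNG
with_subseed <- function(seed, offset, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed * 131L + offset) %% .Machine$integer.max)
  fn()
}

# smoothed standard-normal random field with ~sigma_cells correlation
gaussian_field <- function(nr, nc, sigma_cells) {
  pad <- max(1L, ceiling(3 * sigma_cells))
  z <- matrix(stats::rnorm((nr + 2 * pad) * (nc + 2 * pad)),
              nr + 2 * pad, nc + 2 * pad)
  k <- stats::dnorm(seq(-pad, pad), sd = sigma_cells)
  k <- k / sum(k)
  z <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
  z <- t(apply(z, 1, function(row) stats::filter(row, k, sides = 2)))
  z <- z[(pad + 1):(pad + nr), (pad + 1):(pad + nc)]
  (z - mean(z)) / stats::sd(z)
}

#' Generate a complete synthetic study area
#'
#' Deterministic for a fixed seed. See [scene_config()] for what the
#' scene emulates. The returned bundle carries every input the pipeline
#' consumes plus the generating truth (ward growth multipliers,
#' conversion parameters) for recovery tests.
#'
#' @param cfg A [scene_config()].
#' @return A `scene_bundle` list: `dem`, `bands` (per date, six grids),
#'   `lulc` (per date), `wards`, `road` (vertex matrix), `soil_samples`,
#'   `stations`, `population`, `validation_points`, `truth`, `cfg`.
#' @export
generate_scene <- function(cfg = scene_config()) {
  nr <- cfg$n_rows; nc <- cfg$n_cols; cs <- cfg$cell_size
  template <- new_grid(matrix(0, nr, nc), cell_size = cs)
  cc <- cell_centers(template)

  # --- terrain: valley floor along mid-row, ridges to north and south ---
  dem_vals <- with_subseed(cfg$seed, 1L, function() {
    vfrac <- abs((row(matrix(0, nr, nc)) - 0.5) / nr - 0.5) * 2  # 0 at valley
    z <- cfg$elev_range[1] +
      (cfg$elev_range[2] - cfg$elev_range[1]) * vfrac^1.4
    z + 25 * gaussian_field(nr, nc, 4)
  })
  dem <- new_grid(dem_vals, cell_size = cs, band_name = "dem_m")

  # --- highway along the valley floor with gentle bends ---
  ext <- grid_extent(template)
  road_x <- seq(ext["xmin"], ext["xmax"], length.out = 9)
  mid_y <- (ext["ymin"] + ext["ymax"]) / 2
  road_y <- with_subseed(cfg$seed, 2L, function() {
    mid_y + cumsum(stats::rnorm(9, 0, cs * 2))
  })
  road <- cbind(x = road_x, y = road_y)
  d_road <- road_distance(road, template)

  # --- wards: Voronoi partition of random centres ---
  ward_vals <- with_subseed(cfg$seed, 3L, function() {
    wx <- stats::runif(cfg$n_wards, ext["xmin"], ext["xmax"])
    wy <- stats::runif(cfg$n_wards, ext["ymin"], ext["ymax"])
    px <- as.vector(cc$x); py <- as.vector(cc$y)
    d2 <- outer(px, wx, function(a, b) (a - b)^2) +
          outer(py, wy, function(a, b) (a - b)^2)
    matrix(max.col(-d2), nr, nc)
  })
  ward_legend <- stats::setNames(paste0("ward_", seq_len(cfg$n_wards)),
                                 as.character(seq_len(cfg$n_wards)))
  wards <- new_categorical_grid(ward_vals, ward_legend, cell_size = cs,
                                band_name = "ward")

  # --- initial LULC (1990): valley agriculture, hill forest, urban seed
  #     near the road, a lake with a swamp fringe, river barren strip ---
  lulc0 <- with_subseed(cfg$seed, 4L, function() {
    v <- matrix(1, nr, nc)                       # forest default
    # terraced farmland fills the valley and climbs well past the 800 m
    # suitability breakpoint (as mid-hill farmland does), leaving forest
    # on the upper slopes; elevation and slope ranks therefore mix on
    # agricultural land, and remote wards hold farmland that can revert
    v[dem_vals < cfg$elev_range[1] + 0.75 *
        (cfg$elev_range[2] - cfg$elev_range[1])] <- 2   # agriculture
    v[d_road$values < 2.5 * cs & v == 2 &
        matrix(stats::runif(nr * nc), nr, nc) < 0.5] <- 3  # urban seed
    # lake in the valley, offset from the road
    lake_r <- round(nr / 2 + nr / 8); lake_c <- round(nc / 5)
    rr <- row(v); ccx <- col(v)
    lake <- (rr - lake_r)^2 + (ccx - lake_c)^2 < (nr / 14)^2
    v[lake] <- 5
    fringe <- (rr - lake_r)^2 + (ccx - lake_c)^2 < (nr / 11)^2 & !lake
    v[fringe & v == 2] <- 6                      # swamp fringe
    # braided river strip: barren along a column band near the road
    riv <- abs(ccx - round(3 * nc / 4)) <= 1 & abs(rr - nr / 2) < nr / 4
    v[riv & v %in% c(2, 3)] <- 4
    v
  })

  # --- ward population trajectories coupled to road proximity ---
  ward_prox <- vapply(seq_len(cfg$n_wards), function(w) {
    mean(exp(-d_road$values[ward_vals == w] / cfg$road_scale))
  }, numeric(1))
  # per-decade growth multipliers: road-proximal wards draw in-migration,
  # remote hill wards lose population to out-migration (the abandonment
  # driver behind road-distal forest reversion)
  growth <- with_subseed(cfg$seed, 5L, function() {
    1 + 0.05 + cfg$coupling * 0.30 * (ward_prox - mean(ward_prox)) /
      max(stats::sd(ward_prox), 1e-9) +
      stats::rnorm(cfg$n_wards, 0, 0.03)
  })
  growth <- pmax(growth, 0.70)
  pop0 <- with_subseed(cfg$seed, 6L, function() {
    cells <- tabulate(ward_vals, nbins = cfg$n_wards)
    round(cells * stats::runif(cfg$n_wards, 9, 11))
  })
  census_years <- c(1991, 2001, 2011, 2021)
  pop_tab <- do.call(rbind, lapply(seq_along(census_years), function(k) {
    data.frame(ward = seq_len(cfg$n_wards), year = census_years[k],
               population = round(pop0 * growth^(k - 1)),
               households = round(pop0 * growth^(k - 1) / 4.5))
  }))

  # --- LULC evolution: ag -> urban near road in growing wards,
  #     ag -> forest far from road in declining wards ---
  pf <- (growth - min(growth)) / max(max(growth) - min(growth), 1e-9)
  dates <- c(1990, 2000, 2010, 2021)
  lulc_list <- list(`1990` = lulc0)
  cur <- lulc0
  near <- exp(-d_road$values / cfg$road_scale)
  for (k in 2:4) {
    cur <- with_subseed(cfg$seed, 10L + k, function() {
      v <- cur
      ag <- which(v == 2)
      pfa <- pf[ward_vals[ag]]
      p_urb <- cfg$urbanization_rate * near[ag] * (0.25 + 0.75 * pfa)
      p_for <- cfg$reversion_rate * (1 - near[ag]) * (0.25 + 0.75 * (1 - pfa))
      u <- stats::runif(length(ag))
      v[ag[u < p_urb]] <- 3
      v[ag[u >= p_urb & u < p_urb + p_for]] <- 1
      v
    })
    lulc_list[[as.character(dates[k])]] <- cur
  }
  legend <- lulc_legend()
  lulc <- lapply(lulc_list, function(v) {
    new_categorical_grid(v, legend, cell_size = cs, band_name = "lulc")
  })

  # --- spectral bands per date from class means plus noise ---
  spectra <- class_spectra()
  band_names <- colnames(spectra)
  bands <- list()
  for (k in seq_along(dates)) {
    v <- lulc_list[[as.character(dates[k])]]
    bands[[as.character(dates[k])]] <- with_subseed(cfg$seed, 20L + k, function() {
      out <- list()
      for (b in seq_len(6)) {
        refl <- matrix(spectra[v, b], nr, nc) +
          matrix(stats::rnorm(nr * nc, 0, cfg$band_noise_sd), nr, nc)
        out[[band_names[b]]] <- new_grid(pmax(refl, 0), cell_size = cs,
                                         band_name = band_names[b])
      }
      out
    })
  }

  # --- spatially autocorrelated soil fields, sampled at points ---
  sigma_cells <- cfg$soil_correlation_m / cs
  soil_ranges <- list(ph = c(5.2, 7.8), oc_pct = c(0.3, 1.6),
                      n_kg_ha = c(200, 800), p_kg_ha = c(8, 40),
                      k_kg_ha = c(80, 420))
  soil_fields <- list()
  for (i in seq_along(soil_ranges)) {
    soil_fields[[names(soil_ranges)[i]]] <- with_subseed(cfg$seed, 30L + i, function() {
      f <- gaussian_field(nr, nc, sigma_cells)
      r <- soil_ranges[[i]]
      r[1] + (r[2] - r[1]) * stats::pnorm(f)
    })
  }
  soil_samples <- with_subseed(cfg$seed, 40L, function() {
    idx <- sample(which(lulc0 == 2), min(cfg$n_soil_samples, sum(lulc0 == 2)))
    rr <- (idx - 1) %% nr + 1; ccx <- (idx - 1) %/% nr + 1
    df <- data.frame(
      x = template$origin_x + (ccx - 0.5) * cs,
      y = template$origin_y - (rr - 0.5) * cs)
    for (nm in names(soil_fields)) df[[nm]] <- soil_fields[[nm]][cbind(rr, ccx)]
    df
  })

  # --- three precipitation stations spread across the scene ---
  stations <- data.frame(
    name = c("west", "airport", "east"),
    x = ext["xmin"] + c(0.15, 0.5, 0.85) * (ext["xmax"] - ext["xmin"]),
    y = mid_y + c(0.2, -0.1, 0.15) * (ext["ymax"] - ext["ymin"]) / 2,
    value = cfg$station_values)

  # --- validation points: agricultural cells of the final date, sampled
  #     with probability increasing in the generated suitability score ---
  suit_truth <- scene_suitability(dem, bands[["2021"]], soil_samples,
                                  stations, lulc[["2021"]])
  validation_points <- with_subseed(cfg$seed, 50L, function() {
    sc <- suit_truth$score$values
    cand <- which(!is.na(sc))
    wts <- (sc[cand] - 1) + 0.1
    idx <- sample(cand, min(cfg$n_validation, length(cand)), prob = wts)
    rr <- (idx - 1) %% nr + 1; ccx <- (idx - 1) %/% nr + 1
    data.frame(
      x = template$origin_x + (ccx - 0.5 + stats::runif(length(idx), -0.4, 0.4)) * cs,
      y = template$origin_y - (rr - 0.5 + stats::runif(length(idx), -0.4, 0.4)) * cs,
      label = "agroforestry_practice")
  })

  structure(list(
    dem = dem, bands = bands, lulc = lulc, wards = wards, road = road,
    soil_samples = soil_samples, stations = stations, population = pop_tab,
    validation_points = validation_points,
    truth = list(growth = growth, ward_prox = ward_prox, pf = pf,
                 spectra = spectra,
                 urbanization_rate = cfg$urbanization_rate,
                 reversion_rate = cfg$reversion_rate,
                 suitability = suit_truth$classes),
    cfg = cfg), class = "scene_bundle")
}

# the full criterion -> rank -> overlay chain on one scene's layers;
# shared by the generator (truth) and the pipeline driver
scene_suitability <- function(dem, bands6, soil_samples, stations, lulc_grid,
                              scheme = default_scheme(),
                              ag_code = 2, exclusion_codes = c(4, 5)) {
  template <- new_grid(matrix(0, nrow(dem$values), ncol(dem$values)),
                       origin_x = dem$origin_x, origin_y = dem$origin_y,
                       cell_size = dem$cell_size)
  ndvi_g <- ndvi(bands6$nir, bands6$red)
  wet_g <- wetness(bands6)
  slope_g <- slope_degrees(dem)
  soil <- function(col) {
    idw_interpolate(data.frame(x = soil_samples$x, y = soil_samples$y,
                               value = soil_samples[[col]]), template)
  }
  nut <- nutrient_criteria()
  n_rank <- rank_layer(soil("n_kg_ha"), nut$nitrogen)
  p_rank <- rank_layer(soil("p_kg_ha"), nut$phosphorus)
  k_rank <- rank_layer(soil("k_kg_ha"), nut$potassium)
  precip <- precipitation_surface(
    data.frame(x = stations$x, y = stations$y, value = stations$value),
    template)
  ranks <- list(
    elevation = rank_layer(dem, scheme$criteria$elevation),
    precipitation = rank_layer(precip, scheme$criteria$precipitation),
    wetness = rank_layer(wet_g, scheme$criteria$wetness),
    nutrient = rank_layer(nutrient_composite(n_rank, p_rank, k_rank),
                          scheme$criteria$nutrient),
    organic_carbon = rank_layer(soil("oc_pct"), scheme$criteria$organic_carbon),
    ph = rank_layer(soil("ph"), scheme$criteria$ph),
    ndvi = rank_layer(ndvi_g, scheme$criteria$ndvi),
    slope = rank_layer(slope_g, scheme$criteria$slope))
  score <- weighted_score(ranks, scheme)
  classes <- classify_suitability(score, scheme)
  classes <- apply_exclusions(classes, lulc_grid, ag_code, exclusion_codes)
  score_masked <- apply_mask(score, lulc_grid, ag_code)
  list(score = score_masked, score_full = score, classes = classes,
       ranks = ranks)
}

#' Write a scene bundle to pipeline input files
#'
#' Emits every raster as an ESRI ASCII grid, the point and population
#' tables as CSV, and the road as a GeoJSON LineString — exactly the
#' formats the pipeline drivers read. A manifest CSV with MD5 checksums
#' is written last.
#'
#' @param bundle A [generate_scene()] result.
#' @param directory Output directory (created if absent).
#' @return Data frame manifest (`path`, `md5`), invisibly.
#' @export
scene_to_files <- function(bundle, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(directory, paste0(...))
  written <- character(0)
  w <- function(path) written <<- c(written, path)

  write_raster(bundle$dem, p("dem.asc")); w(p("dem.asc"))
  write_raster(bundle$wards, p("wards.asc")); w(p("wards.asc"))
  for (yr in names(bundle$lulc)) {
    write_raster(bundle$lulc[[yr]], p("lulc_", yr, ".asc"))
    w(p("lulc_", yr, ".asc"))
  }
  for (yr in names(bundle$bands)) {
    for (b in names(bundle$bands[[yr]])) {
      write_raster(bundle$bands[[yr]][[b]], p("band_", b, "_", yr, ".asc"))
      w(p("band_", b, "_", yr, ".asc"))
    }
  }
  utils::write.csv(bundle$soil_samples, p("soil_samples.csv"), row.names = FALSE)
  w(p("soil_samples.csv"))
  utils::write.csv(bundle$stations, p("stations.csv"), row.names = FALSE)
  w(p("stations.csv"))
  utils::write.csv(bundle$population, p("population.csv"), row.names = FALSE)
  w(p("population.csv"))
  utils::write.csv(bundle$validation_points, p("validation_points.csv"),
                   row.names = FALSE)
  w(p("validation_points.csv"))
  write_road_geojson(bundle$road, p("road.geojson")); w(p("road.geojson"))

  manifest <- data.frame(path = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Validate a scene directory against its manifest
#'
#' @param directory A directory written by [scene_to_files()].
#' @return Data frame `path`, `status` (`"ok"`, `"missing"`,
#'   `"checksum_mismatch"`).
#' @export
validate_manifest <- function(directory) {
  mf <- utils::read.csv(file.path(directory, "manifest.csv"),
                        stringsAsFactors = FALSE)
  status <- vapply(seq_len(nrow(mf)), function(i) {
    f <- file.path(directory, mf$path[i])
    if (!file.exists(f)) return("missing")
    if (unname(tools::md5sum(f)) != mf$md5[i]) return("checksum_mismatch")
    "ok"
  }, character(1))
  data.frame(path = mf$path, status = status, stringsAsFactors = FALSE)
}

#' Write a polyline as a GeoJSON LineString
#'
#' @param road Two-column vertex matrix `(x, y)`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_road_geojson <- function(road, path) {
  road <- as.matrix(road)
  gj <- list(type = "Feature",
             geometry = list(type = "LineString",
                             coordinates = lapply(seq_len(nrow(road)),
                                                  function(i) unname(road[i, ]))),
             properties = list(name = "highway"))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON LineString as a vertex matrix
#'
#' @param path GeoJSON file holding a LineString feature (or bare
#'   geometry).
#' @return Two-column matrix `(x, y)`.
#' @export
read_road_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  geom <- if (!is.null(gj$geometry)) gj$geometry else gj
  if (is.null(geom$coordinates) || !identical(geom$type, "LineString")) {
    stop("expected a GeoJSON LineString in ", path, call. = FALSE)
  }
  coords <- do.call(rbind, lapply(geom$coordinates, function(v) {
    as.numeric(unlist(v))
  }))
  colnames(coords) <- c("x", "y")
  if (nrow(coords) < 2) stop("road polyline needs at least two vertices", call. = FALSE)
  coords
}
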