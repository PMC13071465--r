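# End-to-end drivers: orchestrate layer derivation -> rank -> weighted
# overlay -> classification -> zonal summary (suitability), transition /
# zonal / gradient / association accounting (change), and the
# validation-point overlay. Each driver reads the file layout written by
# scene_to_files() and writes CSV/raster reports plus a provenance
# record.

read_scene_inputs <- function(input_dir) {
  p <- function(...) file.path(input_dir, paste0(...))
  need <- function(f) {
    if (!file.exists(f)) stop("missing input file: ", f, call. = FALSE)
    f
  }
  lulc_files <- list.files(input_dir, "^lulc_\\d+\\.asc$")
  years <- sub("^lulc_(\\d+)\\.asc$", "\\1", lulc_files)
  legend <- lulc_legend()
  lulc <- lapply(lulc_files, function(f) {
    g <- read_raster(file.path(input_dir, f), band_name = "lulc")
    new_categorical_grid(g$values, legend, g$origin_x, g$origin_y,
                         g$cell_size, g$nodata, "lulc")
  })
  names(lulc) <- years
  band_names <- c("blue", "green", "red", "nir", "swir1", "swir2")
  bands <- lapply(years, function(yr) {
    out <- lapply(band_names, function(b) {
      read_raster(need(p("band_", b, "_", yr, ".asc")), band_name = b)
    })
    names(out) <- band_names
    out
  })
  names(bands) <- years
  wards_g <- read_raster(need(p("wards.asc")))
  ward_codes <- sort(unique(stats::na.omit(as.vector(wards_g$values))))
  wards <- new_categorical_grid(
    wards_g$values,
    stats::setNames(paste0("ward_", ward_codes), as.character(ward_codes)),
    wards_g$origin_x, wards_g$origin_y, wards_g$cell_size, wards_g$nodata,
    "ward")
  list(
    dem = read_raster(need(p("dem.asc")), band_name = "dem_m"),
    lulc = lulc, bands = bands, wards = wards,
    road = read_road_geojson(need(p("road.geojson"))),
    soil_samples = utils::read.csv(need(p("soil_samples.csv"))),
    stations = utils::read.csv(need(p("stations.csv"))),
    population = if (file.exists(p("population.csv")))
      utils::read.csv(p("population.csv")) else NULL,
    validation_points = if (file.exists(p("validation_points.csv")))
      utils::read.csv(p("validation_points.csv")) else NULL)
}

write_provenance <- function(out_dir, stage, params) {
  rec <- list(stage = stage, package_version = "0.1.0",
              timestamp_utc = format(Sys.time(), tz = "UTC"),
              params = params)
  jsonlite::write_json(rec, file.path(out_dir, paste0(stage, "_run.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full suitability analysis on a scene directory
#'
#' Derives NDVI, wetness, slope, IDW soil surfaces and the precipitation
#' surface from the inputs, ranks each against the scheme, builds the
#' nutrient composite, combines by weighted sum, classifies S1/S2/S3,
#' restricts to agricultural land with exclusions, and summarizes by
#' ward. Writes `suitability_score.asc`, `suitability_classes.asc`,
#' `zone_summary.csv` and a provenance record.
#'
#' @param input_dir Directory in the layout written by
#'   [scene_to_files()].
#' @param out_dir Output directory (created if absent).
#' @param scheme A `suitability_scheme` (default [default_scheme()]).
#' @param lulc_year LULC date used as the agricultural mask (default:
#'   latest available).
#' @param ag_code Agricultural LULC code (default 2).
#' @param exclusion_codes LULC codes mapped to "not suitable" (default
#'   barren/river 4 and water 5).
#' @return List with `score`, `classes`, `summary` (invisibly also
#'   written to `out_dir`).
#' @export
run_suitability <- function(input_dir, out_dir,
                            scheme = default_scheme(),
                            lulc_year = NULL, ag_code = 2,
                            exclusion_codes = c(4, 5)) {
  inp <- read_scene_inputs(input_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(lulc_year)) lulc_year <- max(as.integer(names(inp$lulc)))
  yr <- as.character(lulc_year)
  if (!yr %in% names(inp$lulc)) stop("no LULC map for year ", yr, call. = FALSE)
  res <- scene_suitability(inp$dem, inp$bands[[yr]], inp$soil_samples,
                           inp$stations, inp$lulc[[yr]],
                           scheme = scheme, ag_code = ag_code,
                           exclusion_codes = exclusion_codes)
  summary_tab <- summarize_suitability(res$classes, inp$wards)
  write_raster(res$score, file.path(out_dir, "suitability_score.asc"))
  write_raster(res$classes, file.path(out_dir, "suitability_classes.asc"))
  utils::write.csv(summary_tab, file.path(out_dir, "zone_summary.csv"),
                   row.names = FALSE)
  write_provenance(out_dir, "suitability",
                   list(input_dir = input_dir, lulc_year = lulc_year,
                        ag_code = ag_code,
                        exclusion_codes = exclusion_codes,
                        weights = vapply(scheme$criteria, `[[`,
                                         numeric(1), "weight"),
                        composite_breaks = scheme$composite_breaks,
                        extensions = scheme$extensions))
  invisible(list(score = res$score, classes = res$classes,
                 summary = summary_tab))
}

#' Run the land-use transition analysis on a scene directory
#'
#' Cross-tabulates the earliest and latest LULC dates, accounts
#' per-ward agricultural conversion to urban and to forest, labels the
#' road-distance gradient, builds the urban trend series, and (when a
#' population table is present) tests the Kendall association between
#' ward population change and conversion areas. Writes
#' `transition_matrix.csv`, `ward_conversion.csv`, `band_conversion.csv`,
#' `trend_urban.csv`, `tau_report.csv` and a provenance record.
#'
#' @param input_dir Directory in the layout written by
#'   [scene_to_files()].
#' @param out_dir Output directory.
#' @param band_width_m,n_bands Road-distance banding (defaults 500 m,
#'   10 bands).
#' @param ag_code,urban_code,forest_code LULC codes (defaults 2, 3, 1).
#' @return List with `transition`, `ward_conversion` (urban and forest),
#'   `band_conversion`, `trend`, `tau` (or `NULL` without population).
#' @export
run_change <- function(input_dir, out_dir, band_width_m = 500, n_bands = 10,
                       ag_code = 2, urban_code = 3, forest_code = 1) {
  inp <- read_scene_inputs(input_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  years <- sort(as.integer(names(inp$lulc)))
  if (length(years) < 2) stop("need LULC maps for at least two dates", call. = FALSE)
  t1 <- inp$lulc[[as.character(years[1])]]
  t2 <- inp$lulc[[as.character(years[length(years)])]]
  tm <- cross_tabulate(t1, t2)

  ward_urb <- zonal_conversion(t1, t2, inp$wards, ag_code, urban_code)
  ward_for <- zonal_conversion(t1, t2, inp$wards, ag_code, forest_code)

  bands_g <- distance_bands(inp$road, t1, band_width_m, n_bands)
  band_urb <- zonal_conversion(t1, t2, bands_g, ag_code, urban_code)
  band_for <- zonal_conversion(t1, t2, bands_g, ag_code, forest_code)
  band_tab <- data.frame(band = band_urb$zone,
                         ag_1990_ha = band_urb$from_area_ha,
                         ag_to_urban_ha = band_urb$converted_ha,
                         urban_fraction = band_urb$fraction,
                         ag_to_forest_ha = band_for$converted_ha,
                         forest_fraction = band_for$fraction)

  trend <- trend_series(inp$lulc, urban_code)

  tau <- NULL
  if (!is.null(inp$population)) {
    pop <- inp$population
    y0 <- min(pop$year); y1 <- max(pop$year)
    dpop <- merge(pop[pop$year == y0, c("ward", "population")],
                  pop[pop$year == y1, c("ward", "population")],
                  by = "ward", suffixes = c("_0", "_1"))
    dpop$change <- dpop$population_1 - dpop$population_0
    m <- merge(merge(dpop, ward_urb, by.x = "ward", by.y = "zone"),
               ward_for, by.x = "ward", by.y = "zone",
               suffixes = c("_urban", "_forest"))
    t_urb <- kendall_tau_b(m$change, m$converted_ha_urban)
    t_for <- kendall_tau_b(m$change, m$converted_ha_forest)
    tau <- data.frame(
      conversion = c("ag_to_urban", "ag_to_forest"),
      tau = c(t_urb$tau, t_for$tau),
      p_value = c(t_urb$p_value, t_for$p_value),
      n = c(t_urb$n, t_for$n),
      variant = c(t_urb$method, t_for$method))
    utils::write.csv(tau, file.path(out_dir, "tau_report.csv"),
                     row.names = FALSE)
  } else {
    warning("no population table found; Kendall association skipped")
  }

  utils::write.csv(tm$counts, file.path(out_dir, "transition_matrix.csv"))
  utils::write.csv(ward_urb, file.path(out_dir, "ward_conversion_urban.csv"),
                   row.names = FALSE)
  utils::write.csv(ward_for, file.path(out_dir, "ward_conversion_forest.csv"),
                   row.names = FALSE)
  utils::write.csv(band_tab, file.path(out_dir, "band_conversion.csv"),
                   row.names = FALSE)
  utils::write.csv(trend, file.path(out_dir, "trend_urban.csv"),
                   row.names = FALSE)
  write_provenance(out_dir, "change",
                   list(input_dir = input_dir, years = years,
                        band_width_m = band_width_m, n_bands = n_bands))
  invisible(list(transition = tm, ward_conversion_urban = ward_urb,
                 ward_conversion_forest = ward_for,
                 band_conversion = band_tab, trend = trend, tau = tau))
}

#' Overlay validation points on a computed suitability map
#'
#' @param classes_path Path to a suitability classes raster written by
#'   [run_suitability()].
#' @param points_path CSV of validation points with `x`, `y` columns.
#' @param out_dir Output directory for `validation_report.csv`.
#' @return The [overlay_points()] report (invisibly written to disk).
#' @export
run_validate <- function(classes_path, points_path, out_dir) {
  g <- read_raster(classes_path)
  classes <- new_categorical_grid(g$values, suitability_legend(),
                                  g$origin_x, g$origin_y, g$cell_size,
                                  g$nodata, "suitability_class")
  points <- utils::read.csv(points_path)
  if (nrow(points) == 0) stop("empty validation point file", call. = FALSE)
  rep <- overlay_points(points, classes)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- data.frame(category = c(names(rep$counts), "agreement"),
                    count = c(unname(rep$counts), sum(rep$counts[1:3])),
                    percent = c(unname(rep$percent), rep$agreement_pct))
  utils::write.csv(out, file.path(out_dir, "validation_report.csv"),
                   row.names = FALSE)
  write_provenance(out_dir, "validate",
                   list(classes_path = classes_path,
                        points_path = points_path, n = rep$n))
  invisible(rep)
}

#' Regenerate the synthetic test fixtures
#'
#' @param directory Target directory.
#' @param seed Scene seed.
#' @param ... Further arguments to [scene_config()].
#' @return The scene manifest, invisibly.
#' @export
make_fixtures <- function(directory, seed = 1, ...) {
  bundle <- generate_scene(scene_config(seed = seed, ...))
  scene_to_files(bundle, directory)
}
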