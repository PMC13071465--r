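# LULC transition accounting between map dates, per-ward conversion,
# road-distance bands and trend series.

#' Cross-tabulate two LULC maps into a transition matrix
#'
#' Counts, for every ordered class pair (i, j), the cells classified i at
#' the earlier date and j at the later date. Cells nodata at either date
#' are excluded, so the matrix total equals the number of cells valid at
#' both dates; the diagonal holds unchanged cells.
#'
#' @param t1,t2 Aligned `CategoricalGrid`s sharing a legend.
#' @return A `transition_matrix`: list with `counts` (class x class
#'   integer matrix, rows = earlier date), `legend`, `cell_size`.
#' @export
cross_tabulate <- function(t1, t2) {
  stop_if_misaligned(t1, t2, "LULC maps")
  if (!identical(sort(names(t1$legend)), sort(names(t2$legend)))) {
    stop("LULC maps do not share a legend", call. = FALSE)
  }
  codes <- sort(as.integer(names(t1$legend)))
  v1 <- as.vector(t1$values); v2 <- as.vector(t2$values)
  ok <- !is.na(v1) & !is.na(v2)
  counts <- table(factor(v1[ok], levels = codes),
                  factor(v2[ok], levels = codes))
  counts <- matrix(as.integer(counts), length(codes), length(codes),
                   dimnames = list(from = as.character(codes),
                                   to = as.character(codes)))
  structure(list(counts = counts, legend = t1$legend[as.character(codes)],
                 cell_size = t1$cell_size),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> rows = earlier date, cols = later date\n")
  m <- x$counts
  dimnames(m) <- list(from = unname(x$legend), to = unname(x$legend))
  print(m)
  invisible(x)
}

#' Converted area between two classes, in hectares
#'
#' @param tm A [cross_tabulate()] result.
#' @param from_class,to_class Integer class codes.
#' @return Hectares of cells moving `from_class` to `to_class`.
#' @export
conversion_area <- function(tm, from_class, to_class) {
  f <- as.character(from_class); t <- as.character(to_class)
  if (!f %in% rownames(tm$counts) || !t %in% colnames(tm$counts)) {
    stop("unknown class code in conversion query", call. = FALSE)
  }
  tm$counts[f, t] * tm$cell_size^2 / 1e4
}

#' Per-zone conversion between two classes
#'
#' For each zone: the earlier-date area of `from_class`, the area
#' converted to `to_class`, and the converted fraction. Zones with no
#' `from_class` at the earlier date report the fraction as `NA`.
#'
#' @param t1,t2 Aligned dated `CategoricalGrid`s.
#' @param zones Aligned `CategoricalGrid` of zone labels.
#' @param from_class,to_class Integer class codes.
#' @return Data frame with columns `zone`, `from_area_ha`,
#'   `converted_ha`, `fraction`.
#' @export
zonal_conversion <- function(t1, t2, zones, from_class, to_class) {
  stop_if_misaligned(t1, t2, "LULC maps")
  stop_if_misaligned(t1, zones, "LULC and zone grids")
  v1 <- as.vector(t1$values); v2 <- as.vector(t2$values)
  zv <- as.vector(zones$values)
  ok <- !is.na(v1) & !is.na(v2) & !is.na(zv)
  cell_ha <- t1$cell_size^2 / 1e4
  zs <- sort(unique(zv[ok]))
  res <- lapply(zs, function(z) {
    sel <- ok & zv == z
    from_n <- sum(v1[sel] == from_class)
    conv_n <- sum(v1[sel] == from_class & v2[sel] == to_class)
    data.frame(zone = z,
               from_area_ha = from_n * cell_ha,
               converted_ha = conv_n * cell_ha,
               fraction = if (from_n > 0) conv_n / from_n else NA_real_)
  })
  do.call(rbind, res)
}

# shortest distance from points (px, py) to the segment (x1,y1)-(x2,y2)
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Distance from each cell to a road polyline
#'
#' Euclidean distance from every cell centre to the nearest segment of
#' the polyline, in metres.
#'
#' @param road Two-column matrix (or data frame) of polyline vertices
#'   `(x, y)` in map coordinates; at least two vertices.
#' @param template A `Grid` defining the cell geometry.
#' @return A `Grid` of distances (m).
#' @export
road_distance <- function(road, template) {
  road <- as.matrix(road)
  if (nrow(road) < 2) stop("road polyline needs at least two vertices", call. = FALSE)
  cc <- cell_centers(template)
  px <- as.vector(cc$x); py <- as.vector(cc$y)
  d <- rep(Inf, length(px))
  for (s in seq_len(nrow(road) - 1)) {
    d <- pmin(d, point_segment_distance(px, py,
                                        road[s, 1], road[s, 2],
                                        road[s + 1, 1], road[s + 1, 2]))
  }
  out <- template
  out$values <- matrix(d, nrow(template$values), ncol(template$values))
  out$legend <- NULL
  class(out) <- "Grid"
  out$band_name <- "road_distance_m"
  out
}

#' Label cells by distance band from a road
#'
#' Each cell is labelled `floor(distance / band_width)`, capped at
#' `n_bands - 1`, so band 0 hugs the road. Used both for the
#' urbanization-gradient analysis and, with `n_bands = 2`, for the
#' urban/rural split drawn around the highway.
#'
#' @param road Polyline vertex matrix as in [road_distance()].
#' @param template A `Grid`.
#' @param band_width_m Band width in metres (default 500).
#' @param n_bands Number of bands; the outermost absorbs all farther
#'   cells (default 10).
#' @return A `CategoricalGrid` of band indices `0 .. n_bands - 1`.
#' @export
distance_bands <- function(road, template, band_width_m = 500, n_bands = 10) {
  if (band_width_m <= 0) stop("`band_width_m` must be positive", call. = FALSE)
  d <- road_distance(road, template)
  band <- pmin(floor(d$values / band_width_m), n_bands - 1)
  legend <- stats::setNames(
    paste0("band_", seq_len(n_bands) - 1), as.character(seq_len(n_bands) - 1))
  new_categorical_grid(band, legend,
                       origin_x = template$origin_x,
                       origin_y = template$origin_y,
                       cell_size = template$cell_size,
                       nodata = template$nodata,
                       band_name = "road_band")
}

#' Class-area trend over dated maps
#'
#' @param maps Named list of aligned `CategoricalGrid`s; names are years.
#' @param code Class code to track.
#' @return Data frame `year`, `area_ha`, sorted chronologically.
#' @export
trend_series <- function(maps, code) {
  if (length(maps) < 2) stop("need at least two dated maps", call. = FALSE)
  years <- as.integer(names(maps))
  if (anyNA(years)) stop("map list names must be years", call. = FALSE)
  if (anyDuplicated(years)) stop("duplicate year in map list", call. = FALSE)
  for (m in maps[-1]) stop_if_misaligned(maps[[1]], m, "dated maps")
  ord <- order(years)
  data.frame(year = years[ord],
             area_ha = vapply(maps[ord], class_area, numeric(1), code = code))
}

#' Percent change between two totals
#'
#' `100 * (to - from) / from`; e.g. a population rise from 413,934 to
#' 513,504 is a 24.1% increase.
#'
#' @param from,to Numeric scalars, `from` non-zero.
#' @return Percent change.
#' @export
percent_change <- function(from, to) {
  if (from == 0) stop("`from` must be non-zero", call. = FALSE)
  100 * (to - from) / from
}
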