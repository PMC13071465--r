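# FAO-style rank-and-weight suitability overlay. Each criterion layer is
# ranked 3/2/1 (high/moderate/marginal) against breakpoint tables, the
# ranks are combined by weighted sum, and the continuous score is
# classified into S1/S2/S3 on agricultural land.

# Suitability class codes used throughout: 3 = S1 (highly suitable),
# 2 = S2 (moderately suitable), 1 = S3 (marginally suitable),
# 0 = not suitable (excluded surfaces).
SUIT_LEGEND <- c("3" = "S1", "2" = "S2", "1" = "S3", "0" = "Not suitable")

#' Suitability class legend
#'
#' @return Named character vector mapping class code to FAO class label.
#' @export
suitability_legend <- function() SUIT_LEGEND

#' Define one suitability criterion
#'
#' A criterion maps raw layer values to ranks 1 (marginal, S3), 2
#' (moderate, S2) or 3 (high, S1) through explicit intervals, and carries
#' its weight in the overlay. Interval boundaries follow the convention
#' that a shared boundary value belongs to the lower-suitability side
#' (e.g. nitrogen "> 560" is strict, so 560 kg/ha ranks 2).
#'
#' @param name Criterion label.
#' @param weight Weight as a fraction of 1.
#' @param breaks Data frame with columns `lower`, `upper` (interval ends,
#'   `-Inf`/`Inf` allowed), `lower_open`, `upper_open` (logicals) and
#'   `rank` (1, 2 or 3). Several rows may share a rank (disjoint pieces).
#' @param units Free-text unit label.
#' @return A `criterion_spec` object.
#' @export
criterion_spec <- function(name, weight, breaks, units = "") {
  stopifnot(is.data.frame(breaks),
            all(c("lower", "upper", "lower_open", "upper_open", "rank")
                %in% names(breaks)),
            all(breaks$rank %in% 1:3),
            is.numeric(weight), length(weight) == 1, weight >= 0)
  structure(list(name = name, weight = weight, breaks = breaks,
                 units = units),
            class = "criterion_spec")
}

brk <- function(lower, upper, lower_open, upper_open, rank) {
  data.frame(lower = lower, upper = upper, lower_open = lower_open,
             upper_open = upper_open, rank = rank)
}

#' Default nutrient ranking criteria (N, P, K)
#'
#' Breakpoints for total nitrogen, available phosphorus and available
#' potassium in kg/ha: N > 560 / 560-280 / < 280; P > 25 / 25-10 / < 10;
#' K > 280 / 280-108 / < 108, ranked 3/2/1. The three nutrients carry
#' equal weight in the nutrient-status composite.
#'
#' @return Named list of three `criterion_spec`s with weights 1/3 each.
#' @export
nutrient_criteria <- function() {
  three <- function(name, hi, lo) {
    criterion_spec(name, 1 / 3, rbind(
      brk(hi, Inf, TRUE, FALSE, 3),
      brk(lo, hi, FALSE, FALSE, 2),
      brk(-Inf, lo, TRUE, TRUE, 1)), units = "kg/ha")
  }
  list(nitrogen = three("nitrogen", 560, 280),
       phosphorus = three("phosphorus", 25, 10),
       potassium = three("potassium", 280, 108))
}

#' Default suitability scheme (eight criteria)
#'
#' Encodes the standard agroforestry land-requirement table: elevation
#' (weight 25%; < 800 m high), precipitation (12.5%; > 1075 mm high),
#' tasseled-cap wetness (12.5%; > 0 high), nutrient status (8.33%),
#' organic carbon (8.33%; > 0.75% high), soil pH (8.33%; 6.6-7.3 high),
#' NDVI (12.5%; > 0.3 high) and slope (12.5%; < 15 degrees high). The
#' printed weights total 99.99% and are renormalized to sum exactly 1.
#'
#' Two pH gaps left open by the printed table are closed by
#' nearest-interval continuity: 5.5 < pH < 5.6 ranks 2, pH > 8.4 ranks 1
#' (flagged in the returned object's `extensions` field).
#'
#' @param composite_breaks Score thresholds `c(s2, s1)`: scores at or
#'   above the second element classify S1, at or above the first S2,
#'   below it S3. Default: equal thirds of \[1, 3\].
#' @param exclusion_codes LULC codes mapped to "not suitable"
#'   (rock/river/water/ice surfaces); interpreted by [apply_exclusions()].
#' @return A `suitability_scheme` object.
#' @export
default_scheme <- function(composite_breaks = c(5 / 3, 7 / 3),
                           exclusion_codes = integer(0)) {
  crits <- list(
    elevation = criterion_spec("elevation", 0.25, rbind(
      brk(-Inf, 800, TRUE, TRUE, 3),
      brk(800, 1500, FALSE, FALSE, 2),
      brk(1500, Inf, TRUE, FALSE, 1)), units = "m"),
    precipitation = criterion_spec("precipitation", 0.125, rbind(
      brk(1075, Inf, TRUE, FALSE, 3),
      brk(1050, 1075, FALSE, FALSE, 2),
      brk(-Inf, 1050, TRUE, TRUE, 1)), units = "mm/yr"),
    wetness = criterion_spec("wetness", 0.125, rbind(
      brk(0, Inf, TRUE, FALSE, 3),
      brk(-0.2, 0, FALSE, FALSE, 2),
      brk(-Inf, -0.2, TRUE, TRUE, 1)), units = "index"),
    nutrient = criterion_spec("nutrient", 0.0833, rbind(
      brk(2.5, Inf, TRUE, FALSE, 3),
      brk(1.5, 2.5, FALSE, FALSE, 2),
      brk(-Inf, 1.5, TRUE, TRUE, 1)), units = "status rank"),
    organic_carbon = criterion_spec("organic_carbon", 0.0833, rbind(
      brk(0.75, Inf, TRUE, FALSE, 3),
      brk(0.5, 0.75, FALSE, FALSE, 2),
      brk(-Inf, 0.5, TRUE, TRUE, 1)), units = "%"),
    ph = criterion_spec("ph", 0.0833, rbind(
      brk(6.6, 7.3, FALSE, FALSE, 3),
      brk(5.5, 6.6, TRUE, TRUE, 2),      # includes printed 5.6-6.5 plus gap fill
      brk(7.3, 8.4, TRUE, FALSE, 2),     # printed 7.4-8.4 plus gap fill
      brk(-Inf, 5.5, TRUE, FALSE, 1),
      brk(8.4, Inf, TRUE, FALSE, 1)), units = "pH"),
    ndvi = criterion_spec("ndvi", 0.125, rbind(
      brk(0.3, Inf, TRUE, FALSE, 3),
      brk(0.2, 0.3, FALSE, FALSE, 2),
      brk(-Inf, 0.2, TRUE, TRUE, 1)), units = "index"),
    slope = criterion_spec("slope", 0.125, rbind(
      brk(-Inf, 15, TRUE, TRUE, 3),
      brk(15, 35, FALSE, FALSE, 2),
      brk(35, Inf, TRUE, FALSE, 1)), units = "degrees")
  )
  w <- vapply(crits, `[[`, numeric(1), "weight")
  for (k in seq_along(crits)) crits[[k]]$weight <- unname(w[k] / sum(w))
  structure(list(criteria = crits, composite_breaks = composite_breaks,
                 exclusion_codes = as.integer(exclusion_codes),
                 extensions = c("pH gap 5.5-5.6 -> rank 2",
                                "pH > 8.4 -> rank 1")),
            class = "suitability_scheme")
}

#' @export
print.suitability_scheme <- function(x, ...) {
  cat("<suitability_scheme>", length(x$criteria), "criteria\n")
  for (cr in x$criteria) {
    cat(sprintf("  %-15s w=%.4f (%s)\n", cr$name, cr$weight, cr$units))
  }
  cat("  composite breaks:", paste(signif(x$composite_breaks, 4), collapse = ", "), "\n")
  invisible(x)
}

rank_values <- function(v, breaks) {
  out <- rep(NA_real_, length(v))
  hits <- integer(length(v))
  for (r in seq_len(nrow(breaks))) {
    lo <- breaks$lower[r]; up <- breaks$upper[r]
    inside <- (if (breaks$lower_open[r]) v > lo else v >= lo) &
              (if (breaks$upper_open[r]) v < up else v <= up)
    inside[is.na(inside)] <- FALSE
    hits <- hits + inside
    out[inside] <- breaks$rank[r]
  }
  ok <- !is.na(v)
  if (any(hits[ok] == 0)) {
    stop("values fall outside every rank interval (first offender: ",
         v[ok & hits == 0][1], ")", call. = FALSE)
  }
  if (any(hits[ok] > 1)) {
    stop("rank intervals overlap at value ", v[ok & hits > 1][1], call. = FALSE)
  }
  out
}

#' Rank a criterion layer
#'
#' Maps each non-nodata cell of `layer` to rank 1, 2 or 3 through the
#' criterion's breakpoint intervals; nodata propagates. A value covered
#' by no interval is an error — break tables must cover the support
#' explicitly.
#'
#' @param layer A `Grid` in the criterion's units.
#' @param spec A [criterion_spec()].
#' @return A `Grid` of ranks in \{1, 2, 3\}.
#' @examples
#' sch <- default_scheme()
#' g <- new_grid(matrix(c(10, 20, 40, 5), 2, 2))
#' rank_layer(g, sch$criteria$slope)$values  # 3, 2, 1, 3
#' @export
rank_layer <- function(layer, spec) {
  out <- layer
  out$values <- matrix(rank_values(as.vector(layer$values), spec$breaks),
                       nrow(layer$values), ncol(layer$values))
  out$band_name <- paste0("rank_", spec$name)
  out
}

classify_thirds <- function(x, breaks = c(5 / 3, 7 / 3)) {
  ifelse(x >= breaks[2], 3, ifelse(x >= breaks[1], 2, 1))
}

#' Nutrient-status composite from N, P, K rank layers
#'
#' The three nutrient ranks are averaged with equal weights and the mean
#' re-classified to a status rank by equal thirds of \[1, 3\]: mean >= 7/3
#' is high (3), >= 5/3 medium (2), below marginal (1).
#'
#' @param n_rank,p_rank,k_rank Aligned rank `Grid`s from [rank_layer()].
#' @return A `Grid` of nutrient status ranks in \{1, 2, 3\}.
#' @export
nutrient_composite <- function(n_rank, p_rank, k_rank) {
  stop_if_misaligned(n_rank, p_rank, "nutrient rank grids")
  stop_if_misaligned(n_rank, k_rank, "nutrient rank grids")
  out <- n_rank
  m <- (n_rank$values + p_rank$values + k_rank$values) / 3
  out$values <- classify_thirds(m)
  out$band_name <- "nutrient_status"
  out
}

#' Weighted suitability score
#'
#' Per-cell weighted sum of the criterion ranks; with weights summing to
#' 1 the score lies in \[1, 3\] and equals the rank wherever all criteria
#' agree. A cell missing in any input layer is nodata in the output.
#'
#' @param rank_layers Named list of rank `Grid`s, one per scheme
#'   criterion (names must match).
#' @param scheme A [default_scheme()]-style `suitability_scheme`.
#' @return A `Grid` of continuous scores.
#' @export
weighted_score <- function(rank_layers, scheme) {
  missing_crit <- setdiff(names(scheme$criteria), names(rank_layers))
  if (length(missing_crit)) {
    stop("missing rank layer(s) for criterion: ",
         paste(missing_crit, collapse = ", "), call. = FALSE)
  }
  ref <- rank_layers[[names(scheme$criteria)[1]]]
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (nm in names(scheme$criteria)) {
    g <- rank_layers[[nm]]
    stop_if_misaligned(ref, g, "rank layers")
    acc <- acc + scheme$criteria[[nm]]$weight * g$values
  }
  out <- ref
  # scrub accumulation dust so unanimous ranks score exactly their rank
  # and class-boundary comparisons are deterministic
  out$values <- round(acc, 12)
  out$legend <- NULL
  class(out) <- "Grid"
  out$band_name <- "suitability_score"
  out
}

#' Classify a continuous suitability score into S1/S2/S3
#'
#' Default equal-interval rule on \[1, 3\]: score >= 7/3 is S1, >= 5/3 S2,
#' below S3. The thresholds come from the scheme so other mappings can be
#' tested.
#'
#' @param score A score `Grid` from [weighted_score()].
#' @param scheme A `suitability_scheme` supplying `composite_breaks`.
#' @return A `CategoricalGrid` with codes 3 = S1, 2 = S2, 1 = S3.
#' @export
classify_suitability <- function(score, scheme = default_scheme()) {
  out_vals <- classify_thirds(score$values, scheme$composite_breaks)
  new_categorical_grid(out_vals, SUIT_LEGEND,
                       origin_x = score$origin_x, origin_y = score$origin_y,
                       cell_size = score$cell_size, nodata = score$nodata,
                       band_name = "suitability_class")
}

#' Restrict suitability classes to agricultural land and apply exclusions
#'
#' Cells whose LULC is an exclusion code (rock, river water, dams, ice)
#' become "not suitable" (code 0); all other cells outside the
#' agricultural class become nodata; agricultural cells keep their class.
#'
#' @param classes A suitability `CategoricalGrid`.
#' @param lulc An aligned LULC `CategoricalGrid`.
#' @param ag_code LULC code of the agricultural class.
#' @param exclusion_codes Integer LULC codes mapped to "not suitable".
#' @return A `CategoricalGrid` over \{S1, S2, S3, not suitable\}.
#' @export
apply_exclusions <- function(classes, lulc, ag_code,
                             exclusion_codes = integer(0)) {
  stop_if_misaligned(classes, lulc, "suitability and LULC grids")
  if (!as.character(ag_code) %in% names(lulc$legend)) {
    stop("agricultural code ", ag_code, " not in LULC legend", call. = FALSE)
  }
  v <- classes$values
  excl <- !is.na(lulc$values) & lulc$values %in% exclusion_codes
  outside <- is.na(lulc$values) | (lulc$values != ag_code & !excl)
  v[excl] <- 0
  v[outside] <- NA_real_
  new_categorical_grid(v, SUIT_LEGEND,
                       origin_x = classes$origin_x, origin_y = classes$origin_y,
                       cell_size = classes$cell_size, nodata = classes$nodata,
                       band_name = "suitability_class")
}

#' Summarize suitability classes by zone
#'
#' Per-zone (ward) and municipality-wide TOTAL rows for each suitability
#' class: area in hectares, percent of the zone's suitable area, and the
#' zone's percent of the municipality-wide class total. "Suitable" means
#' classes S1, S2, S3 (code > 0); not-suitable cells contribute area rows
#' but are excluded from suitable-percent denominators.
#'
#' @param classes A suitability `CategoricalGrid` (after exclusions).
#' @param zones An aligned `CategoricalGrid` of zone labels, or `NULL`
#'   for a single-zone summary.
#' @return Data frame with columns `zone`, `class`, `area_ha`,
#'   `pct_of_zone_suitable`, `pct_of_class_total` (full precision;
#'   round for presentation).
#' @export
summarize_suitability <- function(classes, zones = NULL) {
  if (!is.null(zones)) stop_if_misaligned(classes, zones, "class and zone grids")
  cl <- as.vector(classes$values)
  zn <- if (is.null(zones)) rep("ALL", length(cl)) else as.vector(zones$values)
  keep <- !is.na(cl) & !is.na(zn)
  cl <- cl[keep]; zn <- as.character(zn[keep])
  cell_ha <- classes$cell_size^2 / 1e4
  zone_levels <- c(sort(unique(zn)), "TOTAL")
  class_codes <- c(3, 2, 1, 0)
  rows <- list()
  # municipality-wide class totals (ha) for the share-of-class column
  tot_by_class <- vapply(class_codes,
                         function(k) sum(cl == k) * cell_ha, numeric(1))
  names(tot_by_class) <- as.character(class_codes)
  for (z in zone_levels) {
    sel <- if (z == "TOTAL") rep(TRUE, length(cl)) else zn == z
    areas <- vapply(class_codes,
                    function(k) sum(cl[sel] == k) * cell_ha, numeric(1))
    suitable <- sum(areas[1:3])  # codes 3,2,1
    for (i in seq_along(class_codes)) {
      k <- class_codes[i]
      rows[[length(rows) + 1]] <- data.frame(
        zone = z,
        class = unname(SUIT_LEGEND[as.character(k)]),
        area_ha = areas[i],
        pct_of_zone_suitable =
          if (k > 0 && suitable > 0) 100 * areas[i] / suitable else NA_real_,
        pct_of_class_total =
          if (tot_by_class[as.character(k)] > 0)
            100 * areas[i] / tot_by_class[as.character(k)] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
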