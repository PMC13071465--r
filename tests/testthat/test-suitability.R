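sch <- default_scheme()

test_that("criterion weights are normalized and the printed ratios kept", {
  w <- vapply(sch$criteria, `[[`, numeric(1), "weight")
  expect_equal(sum(w), 1)
  expect_equal(unname(w["elevation"] / w["precipitation"]), 2, tolerance = 1e-3)
  expect_equal(unname(w["precipitation"] / w["ph"]), 12.5 / 8.33, tolerance = 1e-3)
})

test_that("rank tables reproduce the printed breakpoints", {
  rk <- function(crit, vals) {
    as.vector(rank_layer(toy_grid(matrix(vals, 1)), sch$criteria[[crit]])$values)
  }
  expect_equal(rk("slope", c(10, 20, 40)), c(3, 2, 1))
  expect_equal(rk("ph", c(7.0, 8.0, 5.0)), c(3, 2, 1))
  expect_equal(rk("elevation", c(500, 1000, 2000)), c(3, 2, 1))
  expect_equal(rk("precipitation", c(4000, 1060, 900)), c(3, 2, 1))
  expect_equal(rk("wetness", c(0.1, -0.1, -0.3)), c(3, 2, 1))
  expect_equal(rk("organic_carbon", c(1.0, 0.6, 0.2)), c(3, 2, 1))
  expect_equal(rk("ndvi", c(0.5, 0.25, 0.1)), c(3, 2, 1))
  nut <- nutrient_criteria()
  nrk <- function(spec, vals) {
    as.vector(rank_layer(toy_grid(matrix(vals, 1)), spec)$values)
  }
  expect_equal(nrk(nut$nitrogen, c(600, 400, 100)), c(3, 2, 1))
  expect_equal(nrk(nut$phosphorus, c(30, 15, 5)), c(3, 2, 1))
  expect_equal(nrk(nut$potassium, c(300, 200, 50)), c(3, 2, 1))
})

test_that("boundary values fall on the lower-suitability side", {
  rk <- function(crit, vals) {
    as.vector(rank_layer(toy_grid(matrix(vals, 1)), sch$criteria[[crit]])$values)
  }
  expect_equal(rk("slope", c(15, 35)), c(2, 2))
  expect_equal(rk("elevation", c(800, 1500)), c(2, 2))
  expect_equal(rk("precipitation", c(1075, 1050)), c(2, 2))
  nut <- nutrient_criteria()
  expect_equal(as.vector(rank_layer(toy_grid(matrix(c(560, 280), 1)),
                                    nut$nitrogen)$values), c(2, 2))
  # pH gaps closed by nearest-interval continuity
  expect_equal(rk("ph", c(5.55, 8.5, 5.5, 8.4)), c(2, 1, 1, 2))
})

test_that("rank_layer demands explicit break coverage and propagates nodata", {
  partial <- criterion_spec("partial", 0.5, data.frame(
    lower = 0, upper = 10, lower_open = FALSE, upper_open = FALSE, rank = 3))
  expect_error(rank_layer(toy_grid(matrix(c(5, 11), 1)), partial), "outside every")
  g <- toy_grid(matrix(c(10, NA), 1))
  out <- rank_layer(g, sch$criteria$slope)
  expect_equal(as.vector(out$values), c(3, NA))
})

test_that("nutrient composite applies the thirds rule to the mean rank", {
  mk <- function(v) toy_grid(matrix(v, 1, 1))
  comp <- function(a, b, c) {
    nutrient_composite(mk(a), mk(b), mk(c))$values[1, 1]
  }
  expect_equal(comp(3, 3, 3), 3)
  expect_equal(comp(1, 1, 1), 1)
  expect_equal(comp(3, 2, 1), 2)   # mean 2 -> medium
  expect_equal(comp(3, 3, 1), 3)   # mean 7/3 sits on the high boundary
  expect_equal(comp(2, 1, 1), 1)   # mean 4/3 below 5/3 -> marginal
})

test_that("weighted score interpolates ranks and flags missing criteria", {
  uniform <- function(r) {
    ranks <- lapply(sch$criteria, function(cr) toy_grid(matrix(r, 2, 2)))
    weighted_score(ranks, sch)
  }
  expect_true(all(uniform(3)$values == 3))
  expect_true(all(uniform(1)$values == 1))
  ranks <- lapply(sch$criteria, function(cr) toy_grid(matrix(3, 1, 1)))
  ranks$elevation <- toy_grid(matrix(2, 1, 1))
  expect_equal(weighted_score(ranks, sch)$values[1, 1],
               3 - sch$criteria$elevation$weight)
  expect_error(weighted_score(ranks[-1], sch), "elevation")
})

test_that("score classification uses the equal-thirds default breaks", {
  cls <- function(s) {
    classify_suitability(toy_grid(matrix(s, 1)), sch)$values[1, ]
  }
  expect_equal(unname(cls(c(3.0, 1.0, 2.75, 2.0))), c(3, 1, 3, 2))
  expect_equal(unname(cls(7 / 3)), 3)          # boundary is S1
  expect_equal(unname(cls(7 / 3 - 1e-9)), 2)
})

test_that("exclusions restrict classes to farmland and flag excluded surfaces", {
  classes <- toy_cat(matrix(3, 4, 4), legend = suitability_legend())
  all_ag <- toy_cat(matrix(2, 4, 4))
  expect_identical(apply_exclusions(classes, all_ag, 2, c(4, 5))$values,
                   classes$values)
  all_water <- toy_cat(matrix(5, 4, 4))
  out <- apply_exclusions(classes, all_water, 2, c(4, 5))
  expect_true(all(out$values == 0))
  # mixed toy: enumerate expectations cell by cell
  lulc <- toy_cat(matrix(c(2, 1, 5, 2,
                           4, 2, 2, 3,
                           2, 2, 1, 5,
                           6, 2, 2, 2), 4, 4, byrow = TRUE))
  cls <- toy_cat(matrix(rep(c(3, 2, 1, 2), 4), 4, 4, byrow = TRUE),
                 legend = suitability_legend())
  out <- apply_exclusions(cls, lulc, 2, c(4, 5))
  for (i in 1:4) for (j in 1:4) {
    l <- lulc$values[i, j]
    if (l %in% c(4, 5)) expect_equal(out$values[i, j], 0)
    else if (l != 2) expect_true(is.na(out$values[i, j]))
    else expect_equal(out$values[i, j], cls$values[i, j])
  }
  expect_error(apply_exclusions(cls, lulc, 99, c(4)), "not in LULC legend")
})

test_that("zone summaries conserve areas and percentages", {
  # two equal zones of uniform S1: each holds half the class total
  cls <- toy_cat(matrix(3, 4, 4), legend = suitability_legend())
  zones <- toy_cat(cbind(matrix(1, 4, 2), matrix(2, 4, 2)),
                   legend = c("1" = "west", "2" = "east"))
  s <- summarize_suitability(cls, zones)
  s1w <- s[s$zone == "1" & s$class == "S1", ]
  expect_equal(s1w$pct_of_class_total, 50)
  expect_equal(s1w$pct_of_zone_suitable, 100)
  # a zone with no suitable cells reports zero-area rows
  cls2 <- toy_cat(cbind(matrix(3, 4, 2), matrix(NA_real_, 4, 2)),
                  legend = suitability_legend())
  s2 <- summarize_suitability(cls2, zones)
  expect_equal(sum(s2[s2$zone == "2", "area_ha"]), 0)
  # suitable percentages within each populated zone sum to 100
  set.seed(9)
  cls3 <- toy_cat(matrix(sample(1:3, 144, replace = TRUE), 12, 12),
                  legend = suitability_legend())
  zones3 <- toy_cat(matrix(rep(1:3, each = 48), 12, 12),
                    legend = setNames(letters[1:3], 1:3))
  s3 <- summarize_suitability(cls3, zones3)
  for (z in unique(s3$zone)) {
    expect_equal(sum(s3[s3$zone == z & s3$class %in% c("S1", "S2", "S3"),
                        "pct_of_zone_suitable"]), 100, tolerance = 0.1)
  }
  # areas conserve: zone totals add up to the TOTAL row per class
  for (k in c("S1", "S2", "S3")) {
    expect_equal(sum(s3[s3$zone != "TOTAL" & s3$class == k, "area_ha"]),
                 s3[s3$zone == "TOTAL" & s3$class == k, "area_ha"])
  }
})

test_that("raising a single cell's rank never lowers the weighted score", {
  set.seed(31)
  for (rep in 1:5) {
    ranks <- lapply(sch$criteria, function(cr) {
      toy_grid(matrix(sample(1:3, 9, replace = TRUE), 3, 3))
    })
    base <- weighted_score(ranks, sch)
    crit <- sample(names(ranks), 1)
    cell <- sample(9, 1)
    v <- ranks[[crit]]$values
    if (v[cell] == 3) next
    v[cell] <- v[cell] + 1
    ranks[[crit]]$values <- v
    bumped <- weighted_score(ranks, sch)
    expect_true(all(bumped$values >= base$values))
    expect_gt(bumped$values[cell], base$values[cell])
  }
})

test_that("unanimous ranks map to their own class through the whole chain", {
  for (r in 1:3) {
    ranks <- lapply(sch$criteria, function(cr) toy_grid(matrix(r, 2, 2)))
    score <- weighted_score(ranks, sch)
    expect_true(all(score$values == r))
    expect_true(all(classify_suitability(score, sch)$values == r))
  }
})

test_that("the engine matches a literal per-cell oracle on a tiny scene", {
  set.seed(41)
  n <- 8
  raw <- list(
    elevation = runif(n * n, 300, 2000),
    precipitation = runif(n * n, 900, 4500),
    wetness = runif(n * n, -0.5, 0.3),
    organic_carbon = runif(n * n, 0.1, 1.5),
    ph = runif(n * n, 4.5, 9.0),
    ndvi = runif(n * n, -0.2, 0.9),
    slope = runif(n * n, 0, 60),
    n = runif(n * n, 100, 800),
    p = runif(n * n, 2, 40),
    k = runif(n * n, 50, 400))
  grids <- lapply(raw, function(v) toy_grid(matrix(v, n, n)))
  nut <- nutrient_criteria()
  ranks <- list(
    elevation = rank_layer(grids$elevation, sch$criteria$elevation),
    precipitation = rank_layer(grids$precipitation, sch$criteria$precipitation),
    wetness = rank_layer(grids$wetness, sch$criteria$wetness),
    nutrient = rank_layer(nutrient_composite(
      rank_layer(grids$n, nut$nitrogen),
      rank_layer(grids$p, nut$phosphorus),
      rank_layer(grids$k, nut$potassium)), sch$criteria$nutrient),
    organic_carbon = rank_layer(grids$organic_carbon, sch$criteria$organic_carbon),
    ph = rank_layer(grids$ph, sch$criteria$ph),
    ndvi = rank_layer(grids$ndvi, sch$criteria$ndvi),
    slope = rank_layer(grids$slope, sch$criteria$slope))
  score <- weighted_score(ranks, sch)
  classes <- classify_suitability(score, sch)
  for (cell in seq_len(n * n)) {
    oracle <- engine_oracle_cell(lapply(raw, `[[`, cell), sch)
    expect_equal(score$values[cell], oracle$score)
    expect_equal(classes$values[cell], oracle$class)
  }
})
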