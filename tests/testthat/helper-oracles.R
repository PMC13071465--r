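# Independent brute-force oracles used across test files. These are
# deliberately literal (per-cell loops, pair enumeration) so they stay
# independent of the vectorized implementation paths they check.

# per-cell Horn slope: explicit 3x3 window loop with edge replication
horn_slope_oracle <- function(z, cell) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  at <- function(i, j) z[min(max(i, 1), nr), min(max(j, 1), nc)]
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    dzdx <- ((at(i - 1, j + 1) + 2 * at(i, j + 1) + at(i + 1, j + 1)) -
             (at(i - 1, j - 1) + 2 * at(i, j - 1) + at(i + 1, j - 1))) / (8 * cell)
    dzdy <- ((at(i + 1, j - 1) + 2 * at(i + 1, j) + at(i + 1, j + 1)) -
             (at(i - 1, j - 1) + 2 * at(i - 1, j) + at(i - 1, j + 1))) / (8 * cell)
    out[i, j] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  }
  out
}

# Kendall tau-b by literal pair enumeration
tau_b_oracle <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# literal per-cell reimplementation of the whole suitability engine for
# tiny scenes: rank each value by linear scan of the break rows, average
# nutrients, weighted sum, thirds classification
engine_oracle_cell <- function(values, scheme) {
  rank1 <- function(v, breaks) {
    for (r in seq_len(nrow(breaks))) {
      lo_ok <- if (breaks$lower_open[r]) v > breaks$lower[r] else v >= breaks$lower[r]
      up_ok <- if (breaks$upper_open[r]) v < breaks$upper[r] else v <= breaks$upper[r]
      if (lo_ok && up_ok) return(breaks$rank[r])
    }
    stop("oracle: uncovered value ", v)
  }
  nut <- nutrient_criteria()
  nr <- rank1(values$n, nut$nitrogen$breaks)
  pr <- rank1(values$p, nut$phosphorus$breaks)
  kr <- rank1(values$k, nut$potassium$breaks)
  m <- (nr + pr + kr) / 3
  nstat <- if (m >= 7 / 3) 3 else if (m >= 5 / 3) 2 else 1
  layer_vals <- c(elevation = values$elevation,
                  precipitation = values$precipitation,
                  wetness = values$wetness, nutrient = nstat,
                  organic_carbon = values$organic_carbon, ph = values$ph,
                  ndvi = values$ndvi, slope = values$slope)
  score <- 0
  for (nm in names(scheme$criteria)) {
    score <- score + scheme$criteria[[nm]]$weight *
      rank1(layer_vals[[nm]], scheme$criteria[[nm]]$breaks)
  }
  cls <- if (score >= scheme$composite_breaks[2]) 3 else
    if (score >= scheme$composite_breaks[1]) 2 else 1
  list(score = score, class = cls)
}

# small aligned grid builders
toy_grid <- function(values, cell = 30) new_grid(as.matrix(values), cell_size = cell)
toy_cat <- function(values, legend = lulc_legend(), cell = 30) {
  new_categorical_grid(as.matrix(values), legend, cell_size = cell)
}
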