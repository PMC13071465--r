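test_that("confusion matrices are built by per-point cell lookup", {
  leg <- c("1" = "forest", "2" = "agriculture", "3" = "urban")
  pred <- toy_cat(matrix(c(1, 1, 2, 2, 3, 3, 1, 2, 3), 3, 3), legend = leg)
  cc <- cell_centers(pred)
  # all points on correctly classified cells -> diagonal
  pts <- data.frame(x = as.vector(cc$x), y = as.vector(cc$y),
                    label = as.vector(pred$values))
  cm <- build_confusion(pts, pred)
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0L)
  expect_equal(sum(cm$counts), 9L)
  # single mismatching point -> one off-diagonal count
  one <- data.frame(x = cc$x[1, 1], y = cc$y[1, 1], label = 3)
  cm1 <- build_confusion(one, pred)
  expect_equal(cm1$counts["3", "1"], 1L)
  expect_equal(sum(cm1$counts), 1L)
  # scattered points: enumerate expected counts by direct lookup
  set.seed(23)
  idx <- sample(9, 10, replace = TRUE)
  pts10 <- data.frame(x = as.vector(cc$x)[idx], y = as.vector(cc$y)[idx],
                      label = sample(1:3, 10, replace = TRUE))
  cm10 <- build_confusion(pts10, pred)
  for (r in 1:3) for (p in 1:3) {
    expected <- sum(pts10$label == r & as.vector(pred$values)[idx] == p)
    expect_equal(cm10$counts[as.character(r), as.character(p)], expected)
  }
  outside <- data.frame(x = -100, y = -100, label = 1)
  expect_error(build_confusion(outside, pred), "outside grid extent")
})

test_that("points on nodata cells are reported, not silently dropped", {
  leg <- c("1" = "a", "2" = "b")
  pred <- toy_cat(matrix(c(1, NA, 2, 2), 2, 2), legend = leg)
  cc <- cell_centers(pred)
  pts <- data.frame(x = as.vector(cc$x), y = as.vector(cc$y),
                    label = c(1, 1, 2, 2))
  cm <- build_confusion(pts, pred)
  expect_equal(cm$n_nodata, 1L)
  expect_equal(sum(cm$counts), 3L)
})

test_that("overall accuracy and kappa follow the marginal formulas", {
  perfect <- as_confusion(matrix(c(2, 0, 0, 2), 2, 2))
  expect_equal(overall_accuracy(perfect), 100)
  expect_equal(kappa_coefficient(perfect), 1)
  chance <- as_confusion(matrix(1, 2, 2))
  expect_equal(overall_accuracy(chance), 50)
  expect_equal(kappa_coefficient(chance), 0)
  cm <- as_confusion(matrix(c(35, 6, 4, 40), 2, 2))  # rows = reference
  p_o <- (35 + 40) / 85
  p_e <- (39 * 41 + 46 * 44) / 85^2
  expect_equal(overall_accuracy(cm), 100 * p_o)
  expect_equal(kappa_coefficient(cm), (p_o - p_e) / (1 - p_e))
  expect_error(overall_accuracy(as_confusion(matrix(0, 2, 2))), "empty")
})

test_that("kappa is 1 exactly for diagonal matrices with positive trace", {
  set.seed(29)
  for (rep in 1:10) {
    m <- matrix(sample(0:20, 9, replace = TRUE), 3, 3)
    if (sum(m) == 0) next
    cm <- as_confusion(m)
    is_diag <- sum(m) == sum(diag(m)) && sum(diag(m)) > 0
    k <- kappa_coefficient(cm)
    if (is_diag) expect_equal(k, 1) else expect_true(is.na(k) || k < 1)
  }
  diag3 <- as_confusion(diag(c(5, 7, 9)))
  expect_equal(kappa_coefficient(diag3), 1)
})

test_that("producer and user accuracies are bounded and consistent with OA", {
  set.seed(37)
  m <- matrix(sample(1:30, 16, replace = TRUE), 4, 4)
  cm <- as_confusion(m)
  acc <- class_accuracies(cm)
  expect_true(all(acc$producer_pct >= 0 & acc$producer_pct <= 100))
  expect_true(all(acc$user_pct >= 0 & acc$user_pct <= 100))
  expect_equal(sum(acc$producer_pct * rowSums(m)) / sum(m),
               overall_accuracy(cm))
})

test_that("Landis-Koch labels use the standard bins", {
  expect_equal(landis_koch(0.745), "substantial")
  expect_equal(landis_koch(1.0), "almost perfect")
  expect_equal(landis_koch(0.1), "slight")
  expect_equal(landis_koch(-0.2), "poor")
  expect_equal(landis_koch(0.5), "moderate")
  expect_equal(landis_koch(0.3), "fair")
  expect_error(landis_koch(1.5), "\\[-1, 1\\]")
})

test_that("tau-b handles perfect order, reversal and the 3-point example", {
  expect_equal(kendall_tau_b(1:5, 1:5)$tau, 1)
  expect_equal(kendall_tau_b(1:5, 5:1)$tau, -1)
  expect_equal(kendall_tau_b(c(1, 2, 3), c(1, 3, 2))$tau, 1 / 3)
})

test_that("tau-b equals exhaustive pair enumeration for n <= 8", {
  set.seed(43)
  for (n in c(4, 5, 6, 8)) {
    for (rep in 1:5) {
      x <- sample(1:4, n, replace = TRUE)  # ties likely
      y <- sample(1:4, n, replace = TRUE)
      if (length(unique(x)) == 1 || length(unique(y)) == 1) next
      expect_equal(kendall_tau_b(x, y)$tau, tau_b_oracle(x, y))
    }
  }
})

test_that("tau-b agrees with the reference implementation", {
  set.seed(47)
  x <- rnorm(20); y <- x + rnorm(20)   # tie-free, normal-approximation path
  ours <- kendall_tau_b(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                          exact = FALSE, continuity = FALSE))
  expect_equal(ours$tau, unname(ref$estimate))
  expect_equal(ours$p_value, ref$p.value)
  # tied data: estimates still agree (cor.test reports tau-b under ties)
  xt <- sample(1:5, 30, replace = TRUE); yt <- sample(1:5, 30, replace = TRUE)
  ours_t <- kendall_tau_b(xt, yt)
  ref_t <- suppressWarnings(stats::cor.test(xt, yt, method = "kendall",
                                            exact = FALSE, continuity = FALSE))
  expect_equal(ours_t$tau, unname(ref_t$estimate))
  expect_equal(ours_t$p_value, ref_t$p.value)
})

test_that("degenerate tau inputs flag undefined instead of failing", {
  out <- kendall_tau_b(c(2, 2, 2, 2), c(1, 3, 2, 4))
  expect_true(out$undefined)
  expect_true(is.na(out$tau))
  expect_error(kendall_tau_b(1:2, 1:2), "at least 3")
})

test_that("exact permutation p-values are valid probabilities under the null", {
  out <- kendall_tau_b(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_true(out$p_value > 0 && out$p_value <= 1)
  expect_match(out$method, "exact")
  # perfectly concordant small sample: p = 2/n! * (orderings at |S|max)
  perf <- kendall_tau_b(1:4, 1:4)
  expect_equal(perf$p_value, 2 / factorial(4))
})

test_that("validation overlay counts classes with half-up percentages", {
  leg <- suitability_legend()
  cls <- toy_cat(matrix(3, 2, 2), legend = leg)
  cc <- cell_centers(cls)
  pts <- data.frame(x = as.vector(cc$x), y = as.vector(cc$y))
  rep4 <- overlay_points(pts, cls)
  expect_equal(rep4$agreement_pct, 100)
  expect_equal(unname(rep4$percent["S1"]), 100)
  expect_equal(sum(rep4$percent), 100, tolerance = 0.1)
  expect_error(overlay_points(pts[0, ], cls), "no validation points")
  far <- data.frame(x = 1e6, y = 1e6)
  expect_error(overlay_points(far, cls), "outside grid extent")
})
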