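# Accuracy assessment (confusion matrix, overall accuracy, Cohen's
# kappa, Landis-Koch labels), tie-corrected Kendall rank correlation,
# and validation-point overlay.

#' Round half-up
#'
#' Report tables use conventional half-up rounding (95.65 -> 95.7), not
#' R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build a confusion matrix from reference points
#'
#' Each labelled reference point contributes one count at (reference
#' label, predicted class of its containing cell). Points on nodata
#' cells are tallied separately, not silently dropped; points outside
#' the grid extent are an error listing the offenders.
#'
#' @param points Data frame with columns `x`, `y`, `label` (integer
#'   class codes matching the map legend).
#' @param predicted A `CategoricalGrid`.
#' @return A `confusion_matrix`: list with `counts` (reference rows x
#'   predicted cols), `legend`, `n_nodata`.
#' @export
build_confusion <- function(points, predicted) {
  loc <- locate_cells(predicted, points$x, points$y)
  if (anyNA(loc$row)) {
    bad <- which(is.na(loc$row))
    stop("reference point(s) outside grid extent at rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  pred <- predicted$values[cbind(loc$row, loc$col)]
  on_nodata <- is.na(pred)
  codes <- sort(as.integer(names(predicted$legend)))
  counts <- table(factor(points$label[!on_nodata], levels = codes),
                  factor(pred[!on_nodata], levels = codes))
  counts <- matrix(as.integer(counts), length(codes), length(codes),
                   dimnames = list(reference = as.character(codes),
                                   predicted = as.character(codes)))
  structure(list(counts = counts,
                 legend = predicted$legend[as.character(codes)],
                 n_nodata = sum(on_nodata)),
            class = "confusion_matrix")
}

#' Confusion matrix from a plain count matrix
#'
#' @param counts Square matrix of reference (rows) x predicted (cols)
#'   counts.
#' @param legend Optional class labels.
#' @return A `confusion_matrix`.
#' @export
as_confusion <- function(counts, legend = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("confusion matrix must be square", call. = FALSE)
  if (any(counts < 0)) stop("confusion counts must be non-negative", call. = FALSE)
  if (is.null(legend)) {
    legend <- stats::setNames(paste0("class_", seq_len(nrow(counts))),
                              as.character(seq_len(nrow(counts))))
  }
  structure(list(counts = counts, legend = legend, n_nodata = 0L),
            class = "confusion_matrix")
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm A `confusion_matrix`.
#' @return Percent of reference points on the diagonal (0-100).
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm$counts)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(cm$counts)) / total
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the row/column marginals. When expected agreement is
#' exactly 1 the statistic is 1 for a perfect matrix and `NA`
#' (undefined) otherwise.
#'
#' @param cm A `confusion_matrix`.
#' @return Kappa coefficient in \[-1, 1\] (or `NA` when undefined).
#' @export
kappa_coefficient <- function(cm) {
  total <- sum(cm$counts)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  p_o <- sum(diag(cm$counts)) / total
  p_e <- sum(rowSums(cm$counts) * colSums(cm$counts)) / total^2
  if (p_e >= 1) return(if (p_o == 1) 1 else NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Producer's and user's accuracy per class
#'
#' Producer's accuracy is per-class recall (diagonal over reference row
#' total), user's accuracy per-class precision (diagonal over predicted
#' column total), both in percent.
#'
#' @param cm A `confusion_matrix`.
#' @return Data frame `class`, `producer_pct`, `user_pct`.
#' @export
class_accuracies <- function(cm) {
  d <- diag(cm$counts)
  rs <- rowSums(cm$counts); cs <- colSums(cm$counts)
  data.frame(class = unname(cm$legend),
             producer_pct = ifelse(rs > 0, 100 * d / rs, NA_real_),
             user_pct = ifelse(cs > 0, 100 * d / cs, NA_real_))
}

#' Landis-Koch agreement label for a kappa value
#'
#' Standard verbal bins: below 0 poor, to 0.20 slight, to 0.40 fair, to
#' 0.60 moderate, to 0.80 substantial, to 1.00 almost perfect.
#'
#' @param kappa Kappa coefficient in \[-1, 1\].
#' @return Character label.
#' @examples
#' landis_koch(0.745)  # "substantial"
#' @export
landis_koch <- function(kappa) {
  if (is.na(kappa) || kappa < -1 || kappa > 1) {
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  }
  if (kappa < 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

# signed concordance statistic S = C - D and tie counts
kendall_S <- function(x, y) {
  n <- length(x)
  sx <- sign(outer(x, x, "-")); sy <- sign(outer(y, y, "-"))
  S <- sum(sx[lower.tri(sx)] * sy[lower.tri(sy)])
  list(S = S, n = n)
}

#' Kendall's tau-b rank correlation with significance
#'
#' Tie-corrected Kendall correlation: `tau_b = (C - D) /
#' sqrt((n0 - n1)(n0 - n2))` where `n0 = n(n-1)/2` and `n1`, `n2` are
#' the tied-pair counts of each vector. The two-sided p-value uses the
#' tie-adjusted normal approximation; for `n <= exact_max` it is the
#' exact permutation probability `P(|S| >= |S_obs|)` over all `n!`
#' orderings. A fully tied vector leaves tau undefined (`NA` with an
#' `undefined` flag), never an error.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @param exact_max Largest n for which the exact permutation null is
#'   enumerated (default 8; factorial cost beyond that).
#' @return List with `tau`, `p_value`, `S`, `n`, `method`, `undefined`.
#' @examples
#' kendall_tau_b(c(1, 2, 3), c(1, 3, 2))$tau  # 1/3
#' @export
kendall_tau_b <- function(x, y, exact_max = 8) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  ks <- kendall_S(x, y)
  S <- ks$S
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) {
    return(list(tau = NA_real_, p_value = NA_real_, S = S, n = n,
                method = "tau-b", undefined = TRUE))
  }
  tau <- S / denom
  if (n <= exact_max) {
    perms <- permutations_of(n)
    s_obs <- abs(S)
    count <- 0L
    for (r in seq_len(nrow(perms))) {
      if (abs(kendall_S(x, y[perms[r, ]])$S) >= s_obs) count <- count + 1L
    }
    p <- count / nrow(perms)
    method <- "tau-b, exact permutation p"
  } else {
    # tie-adjusted variance of S (normal approximation)
    t_ <- as.numeric(tx); u_ <- as.numeric(ty)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(t_ * (t_ - 1) * (2 * t_ + 5))
    vu <- sum(u_ * (u_ - 1) * (2 * u_ + 5))
    v1 <- sum(t_ * (t_ - 1)) * sum(u_ * (u_ - 1)) / (2 * n * (n - 1))
    v2 <- sum(t_ * (t_ - 1) * (t_ - 2)) * sum(u_ * (u_ - 1) * (u_ - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(var_s)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "tau-b, normal approximation"
  }
  list(tau = tau, p_value = p, S = S, n = n, method = method,
       undefined = FALSE)
}

# all permutations of 1..n as a matrix (n! rows); recursion, small n only
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

#' Overlay validation points on a suitability map
#'
#' Counts the validation points falling in each suitability class and
#' outside agricultural land, with half-up percentages to one decimal.
#' The agreement rate is the share of points on suitable agricultural
#' land (classes S1, S2, S3).
#'
#' @param points Data frame with columns `x`, `y` (map coordinates).
#' @param suitability A suitability `CategoricalGrid` (nodata outside
#'   agricultural land, code 0 for excluded surfaces).
#' @return List with `n`, `counts` (named S1/S2/S3/outside),
#'   `percent` (half-up, 1 decimal), `agreement_pct`.
#' @export
overlay_points <- function(points, suitability) {
  if (is.null(points) || nrow(points) == 0) {
    stop("no validation points supplied", call. = FALSE)
  }
  loc <- locate_cells(suitability, points$x, points$y)
  if (anyNA(loc$row)) {
    bad <- which(is.na(loc$row))
    stop("validation point(s) outside grid extent at rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  cls <- suitability$values[cbind(loc$row, loc$col)]
  n <- nrow(points)
  counts <- c(S1 = sum(cls == 3, na.rm = TRUE),
              S2 = sum(cls == 2, na.rm = TRUE),
              S3 = sum(cls == 1, na.rm = TRUE),
              outside = sum(is.na(cls) | cls == 0))
  percent <- round_half_up(100 * counts / n, 1)
  agreement <- round_half_up(100 * sum(counts[c("S1", "S2", "S3")]) / n, 1)
  list(n = n, counts = counts, percent = percent,
       agreement_pct = agreement)
}
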