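#' Combine the 60 low-level maps into the six high-level feature maps
#'
#' Equal-weight (mean) combination within feature type: luminance,
#' red-green, blue-yellow, orientation (8 maps), flicker, and opponent
#' motion (48 maps).
#'
#' @param stack a [feature_stack()].
#' @return array `n` x `n` x 6 with the high-level feature names.
#' @export
combine_high_level <- function(stack) {
  g <- feature_groups(stack)
  n <- stack$n
  out <- array(0, c(n, n, nlevels(g)), dimnames = list(NULL, NULL, levels(g)))
  for (lv in levels(g)) {
    idx <- which(g == lv)
    m <- matrix(0, n, n)
    for (i in idx) m <- m + stack$low[, , i]
    out[, , lv] <- m / length(idx)
  }
  out
}

#' Feature-agnostic saliency map from high-level feature maps
#'
#' The square root of each high-level map is taken and the six are
#' combined with equal weight.
#'
#' @param high array `n` x `n` x 6 of non-negative high-level maps.
#' @return `n` x `n` saliency map.
#' @export
saliency_map <- function(high) {
  stopifnot(all(high >= 0))
  n <- dim(high)[1]
  m <- matrix(0, n, n)
  for (i in seq_len(dim(high)[3])) m <- m + sqrt(high[, , i])
  m / dim(high)[3]
}

#' Leave-one-out normalization of feature time series
#'
#' For each held-out test clip, every feature is divided by its maximum
#' over all *other* clips (training set), so the normalizer never depends
#' on the test clip's own values.  Training-set values then lie in
#' \[0, 1\]; test values may exceed 1 and are retained (clipping is a
#' rendering concern only).  Features whose training maximum is zero are
#' dropped for that fold (set to `NA`) and reported.
#'
#' @param series list of clips, each a numeric matrix (time x features)
#'   with matching columns.
#' @param test_clip index of the held-out clip.
#' @return the normalized test matrix, with attributes `normalizer` and
#'   `dropped` (names/indices of zero-max features).
#' @export
loo_normalize <- function(series, test_clip) {
  stopifnot(length(series) >= 2, test_clip >= 1, test_clip <= length(series))
  train <- series[-test_clip]
  mx <- apply(do.call(rbind, train), 2, max)
  out <- series[[test_clip]]
  dropped <- which(mx == 0)
  for (j in seq_along(mx))
    out[, j] <- if (mx[j] > 0) out[, j] / mx[j] else NA_real_
  attr(out, "normalizer") <- mx
  attr(out, "dropped") <- dropped
  out
}

## equal-occupancy discretization into at most `bins` levels
.eq_bins <- function(x, bins) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 8))
  if (length(qs) < 3) return(NULL)                # effectively constant
  findInterval(x, qs[-c(1, length(qs))]) + 1L
}

mutual_information <- function(xb, yb) {
  tab <- table(xb, yb)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / (px[row(p)][nz] * py[col(p)][nz])))
}

#' Optimal feature-to-response delay by mutual information
#'
#' Estimates the mutual information between a feature series and a spike
#' density series at candidate delays (0 to `max_delay` ms in steps of the
#' common sampling interval) and returns the delay maximizing it.  MI is
#' estimated from the joint histogram with equal-occupancy marginal bins;
#' estimator bias is immaterial because only the argmax over delay is
#' used.  Ties break toward the smaller delay.
#'
#' @param feature_series,rate_series numeric vectors on a common clock.
#' @param max_delay largest candidate delay, ms.
#' @param dt sample interval, ms.
#' @param bins number of equal-occupancy bins per marginal.
#' @return list of class `delay_profile`: `delay` (ms), `delays`, `mi`
#'   (the MI curve), and `flagged` (TRUE when either series is constant,
#'   in which case delay 0 is returned).
#' @export
mi_delay <- function(feature_series, rate_series, max_delay = 150, dt = 5,
                     bins = 16) {
  n <- length(feature_series)
  stopifnot(length(rate_series) == n)
  delays <- seq(0, max_delay, by = dt)
  ks <- delays / dt
  mi <- numeric(length(delays))
  fb_all <- .eq_bins(feature_series, bins)
  rb_all <- .eq_bins(rate_series, bins)
  if (is.null(fb_all) || is.null(rb_all))
    return(structure(list(delay = 0, delays = delays,
                          mi = rep(0, length(delays)), flagged = TRUE),
                     class = "delay_profile"))
  for (i in seq_along(ks)) {
    k <- ks[i]
    f <- feature_series[seq_len(n - k)]
    r <- rate_series[seq_len(n - k) + k]
    mi[i] <- mutual_information(.eq_bins(f, bins), .eq_bins(r, bins))
  }
  structure(list(delay = delays[which.max(mi)], delays = delays, mi = mi,
                 flagged = FALSE),
            class = "delay_profile")
}

#' Saliency response from delay-aligned high-level feature series
#'
#' Square root of each (non-negative) feature, combined with equal weight.
#'
#' @param features time x 6 matrix of aligned, normalized high-level
#'   feature values.
#' @return numeric saliency response series.
#' @export
saliency_response <- function(features) {
  features <- as.matrix(features)
  stopifnot(all(features >= 0, na.rm = TRUE))
  rowMeans(sqrt(features), na.rm = TRUE)
}

#' Saliency within an RF region
#'
#' Normalized sum (mean over covered grid units) of a map within the
#' region bounded by an RF polygon.
#'
#' @param map map on the model grid.
#' @param grid the grid.
#' @param rf_poly polygon from [rf_boundary()], or a precomputed logical
#'   mask from [units_in_polygon()].
#' @return scalar mean saliency in the RF.
#' @export
rf_saliency <- function(map, grid, rf_poly) {
  mask <- if (is.logical(rf_poly)) rf_poly else units_in_polygon(grid, rf_poly)
  if (!any(mask))
    stop("RF region covers no grid units (RF too small for the grid resolution)")
  mean(map[mask])
}
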