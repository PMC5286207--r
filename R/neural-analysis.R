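#' Spike density function
#'
#' Convolves spike times with a unit-mass kernel.  The default kernel
#' resembles an excitatory post-synaptic potential,
#' \eqn{(1 - e^{-t/5})\,e^{-t/20}} for `t >= 0` (rise 5 ms, decay 20 ms),
#' causal, used for event-aligned rates.  The `"gaussian"` variant bins
#' spikes at 5 ms and convolves with a 50 ms Gaussian, used for the model
#' fitting path.
#'
#' @param spikes spike times, ms.
#' @param t_range `c(start, end)` of the density support, ms.
#' @param kernel `"epsp"` or `"gaussian"`.
#' @param rise,decay EPSP kernel time constants, ms.
#' @param gauss_sd Gaussian kernel standard deviation, ms.
#' @return list of class `spike_density` with `t` (bin centres, ms),
#'   `rate` (spikes/s), `dt` and `kernel`.
#' @export
spike_density <- function(spikes, t_range, kernel = c("epsp", "gaussian"),
                          rise = 5, decay = 20, gauss_sd = 50) {
  kernel <- match.arg(kernel)
  dt <- if (kernel == "epsp") 1 else 5
  breaks <- seq(t_range[1], t_range[2], by = dt)
  counts <- graphics::hist(spikes[spikes >= t_range[1] & spikes < t_range[2]],
                           breaks = c(breaks, t_range[2] + dt), plot = FALSE,
                           right = FALSE)$counts
  if (kernel == "epsp") {
    u <- seq(0, 8 * decay, by = dt)
    k <- (1 - exp(-u / rise)) * exp(-u / decay)
  } else {
    u <- seq(-4 * gauss_sd, 4 * gauss_sd, by = dt)
    k <- exp(-u^2 / (2 * gauss_sd^2))
  }
  k <- k / (sum(k) * dt)                      # unit mass in spikes/ms
  n <- length(counts)
  if (kernel == "epsp") {
    pad <- length(k) - 1
    y <- stats::filter(c(rep(0, pad), counts), k, sides = 1)
    rate <- as.numeric(y[pad + seq_len(n)]) * 1000          # spikes/s
  } else {
    h <- (length(k) - 1) / 2
    y <- stats::filter(c(rep(0, h), counts, rep(0, h)), k, sides = 2)
    rate <- as.numeric(y[h + seq_len(n)]) * 1000
  }
  structure(list(t = breaks + dt / 2, rate = pmax(rate, 0), dt = dt,
                 kernel = kernel),
            class = "spike_density")
}

window_rate <- function(spikes, onset, window) {
  vapply(onset, function(o)
    sum(spikes >= o + window[1] & spikes < o + window[2]) /
      diff(window) * 1000, numeric(1))
}

#' Classify a neuron as visual (SCs) or visuomotor (SCi)
#'
#' Visual flag: mean activity 40-120 ms after stimulus onset significantly
#' greater than the pre-stimulus baseline (-80 to 0 ms), one-sided paired
#' comparison across trials.  Motor flag: peri-saccadic activity (-25 to
#' +25 ms around saccade onset) significantly greater than the
#' pre-saccadic baseline (-150 to -50 ms).  Visual neurons without a motor
#' component are SCs; with one, SCi; neurons without a visual response are
#' excluded.  For free viewing the saccade-aligned trials can be the
#' subset of saccades directed into the RF.
#'
#' @param stim_trials list of per-trial spike-time vectors, ms relative to
#'   stimulus onset.
#' @param sacc_trials list of per-trial spike-time vectors, ms relative to
#'   saccade onset.
#' @param alpha test level.
#' @param min_trials fewer aligned trials than this leaves the neuron
#'   unclassified.
#' @return list with `visual`, `motor` (logical), `layer_class` (`"SCs"`,
#'   `"SCi"` or `NA`), `excluded`, and the two p values.
#' @export
classify_neuron <- function(stim_trials, sacc_trials, alpha = 0.05,
                            min_trials = 10) {
  paired_p <- function(trials, win_test, win_base) {
    a <- vapply(trials, function(s)
      sum(s >= win_test[1] & s < win_test[2]) / diff(win_test), numeric(1))
    b <- vapply(trials, function(s)
      sum(s >= win_base[1] & s < win_base[2]) / diff(win_base), numeric(1))
    if (all(a == b)) return(1)
    stats::wilcox.test(a, b, paired = TRUE, alternative = "greater",
                       exact = FALSE)$p.value
  }
  if (length(stim_trials) < min_trials || length(sacc_trials) < min_trials)
    return(list(visual = NA, motor = NA, layer_class = NA_character_,
                excluded = TRUE, p_visual = NA_real_, p_motor = NA_real_))
  p_v <- paired_p(stim_trials, c(40, 120), c(-80, 0))
  p_m <- paired_p(sacc_trials, c(-25, 25), c(-150, -50))
  visual <- p_v < alpha
  motor <- p_m < alpha
  list(visual = visual, motor = motor,
       layer_class = if (!visual) NA_character_ else if (motor) "SCi" else "SCs",
       excluded = !visual, p_visual = p_v, p_motor = p_m)
}

#' 0-1 rescaling of a spike density curve
#'
#' Rescales by the minimum and maximum within the post-event window
#' (default 0-500 ms).  A flat curve maps to all zeros with attribute
#' `flat = TRUE`.  The rescaling is invariant to multiplying the input by
#' a constant.
#'
#' @param rate numeric rate curve.
#' @param t time stamps of `rate`, ms relative to the event.
#' @param window window within which min and max are taken, ms.
#' @return normalized curve (same length as `rate`).
#' @export
normalize_rate <- function(rate, t, window = c(0, 500)) {
  sel <- t >= window[1] & t <= window[2]
  if (!any(sel)) {
    sel <- rep(TRUE, length(t))
    warning("window not covered; normalizing over available data")
  }
  lo <- min(rate[sel]); hi <- max(rate[sel])
  if (hi <= lo) {
    out <- rep(0, length(rate))
    attr(out, "flat") <- TRUE
    return(out)
  }
  out <- (rate - lo) / (hi - lo)
  attr(out, "flat") <- FALSE
  out
}

#' Spearman correlation between RF saliency and firing rate
#'
#' @param saliency,rate per-fixation values for one neuron.
#' @param min_n minimum number of fixations (the analysis requires a
#'   substantial sample per neuron).
#' @return list with `rho`, `p` (two-sided) and `n`; `rho = NA` with
#'   attribute `flagged` when either variable has zero variance.
#' @export
per_neuron_correlation <- function(saliency, rate, min_n = 65) {
  ok <- is.finite(saliency) & is.finite(rate)
  saliency <- saliency[ok]; rate <- rate[ok]
  if (length(saliency) < min_n)
    stop(sprintf("only %d fixations; at least %d required", length(saliency), min_n))
  if (stats::sd(saliency) == 0 || stats::sd(rate) == 0) {
    out <- list(rho = NA_real_, p = NA_real_, n = length(saliency))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  ct <- suppressWarnings(stats::cor.test(saliency, rate, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(saliency))
}

#' Balanced tertile assignment
#'
#' Splits values into low/medium/high thirds by stable rank order; group
#' sizes differ by at most one and ties are resolved by original order.
#'
#' @param x numeric vector.
#' @return factor with levels `low`, `medium`, `high`.
#' @export
assign_tertiles <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "first")
  cuts <- c(floor(n / 3), floor(2 * n / 3))
  f <- ifelse(r <= cuts[1], "low", ifelse(r <= cuts[2], "medium", "high"))
  factor(f, levels = c("low", "medium", "high"))
}

## event-aligned rate curves: slice a full-session density at event onsets
## (uniform density grid, so slicing is pure index arithmetic)
aligned_curves <- function(density, onsets, window = c(-100, 500), bin = 5) {
  dt <- density$dt
  t0 <- density$t[1]
  per <- round(bin / dt)
  nb <- floor(diff(window) / bin)
  len <- nb * per
  nt <- length(density$rate)
  edges <- window[1] + bin * (seq_len(nb) - 1)
  out <- matrix(NA_real_, length(onsets), nb)
  if (length(onsets)) {
    i0 <- round((onsets + window[1] - t0) / dt) + 1
    idx <- outer(i0, seq_len(len) - 1L, `+`)
    bad <- idx < 1 | idx > nt
    idx[bad] <- 1L
    v <- matrix(density$rate[idx], nrow(idx), ncol(idx))
    v[bad] <- NA_real_
    ## average every `per` consecutive samples into one bin
    for (j in seq_len(nb))
      out[, j] <- rowMeans(v[, (j - 1) * per + seq_len(per), drop = FALSE],
                           na.rm = FALSE)
  }
  attr(out, "t") <- edges + bin / 2
  out
}

.epoch_for <- function(alignment) {
  if (alignment == "fixation") c(0, 200) else c(-150, -50)
}

#' Saliency tertile curves and epoch means
#'
#' For each neuron, included fixations are split into saliency tertiles;
#' the fixation-aligned (or saccade-aligned) firing-rate curves are
#' averaged per tertile, and epoch means are taken over the saccade-free
#' window (0-200 ms post fixation, or -150 to -50 ms pre saccade).  For
#' the saccade alignment, fixations shorter than 150 ms are excluded so
#' the epoch stays saccade-free.
#'
#' @param neurons list; each element needs `samples` (data frame with
#'   `saliency`, `t_on`, `sacc_on`, `duration`, `included`) and `density`
#'   (full-session [spike_density()]).
#' @param alignment `"fixation"` or `"saccade"`.
#' @param window aligned window, ms.
#' @return list with `epoch` (neuron x tertile matrix), `curves` (neuron x
#'   tertile x bin array with time attribute), `population` (mean and sem
#'   per tertile per bin), `table` (long condition table for
#'   repeated-measures testing) and `anova` (the fitted `aov`).
#' @export
tertile_curves <- function(neurons, alignment = c("fixation", "saccade"),
                           window = NULL) {
  alignment <- match.arg(alignment)
  if (is.null(window))
    window <- if (alignment == "fixation") c(-100, 500) else c(-300, 200)
  epoch <- .epoch_for(alignment)
  terts <- c("low", "medium", "high")
  nn <- length(neurons)
  ep <- matrix(NA_real_, nn, 3, dimnames = list(NULL, terts))
  curves <- NULL
  for (i in seq_len(nn)) {
    s <- neurons[[i]]$samples
    s <- s[s$included, , drop = FALSE]
    if (alignment == "saccade") {
      s <- s[!is.na(s$sacc_on) & s$duration >= 150, , drop = FALSE]
      onsets <- s$sacc_on
    } else onsets <- s$t_on
    tert <- assign_tertiles(s$saliency)
    ac <- aligned_curves(neurons[[i]]$density, onsets, window)
    tv <- attr(ac, "t")
    if (is.null(curves)) curves <- array(NA_real_, c(nn, 3, ncol(ac)),
                                         dimnames = list(NULL, terts, NULL))
    for (k in seq_along(terts)) {
      rows <- which(tert == terts[k])
      if (!length(rows)) next
      curves[i, k, ] <- colMeans(ac[rows, , drop = FALSE], na.rm = TRUE)
      ep[i, k] <- mean(colMeans(ac[rows, tv >= epoch[1] & tv <= epoch[2],
                                   drop = FALSE], na.rm = TRUE))
    }
  }
  pop_mean <- apply(curves, c(2, 3), mean, na.rm = TRUE)
  pop_sem <- apply(curves, c(2, 3), function(v)
    stats::sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v))))
  tab <- data.frame(neuron = factor(rep(seq_len(nn), 3)),
                    tertile = factor(rep(terts, each = nn), levels = terts),
                    epoch_mean = as.vector(ep))
  fit <- if (nn >= 2)
    stats::aov(epoch_mean ~ tertile + Error(neuron / tertile),
               data = tab[is.finite(tab$epoch_mean), ])
  else NULL
  structure(list(epoch = ep, curves = curves, t = attr(aligned_curves(
    neurons[[1]]$density, numeric(0), window), "t"),
    population = list(mean = pop_mean, sem = pop_sem),
    table = tab, anova = fit, alignment = alignment),
    class = "tertile_curves")
}

#' Saccade-goal split of the saliency effect
#'
#' Crosses saliency (upper versus lower tertile) with saccade goal (next
#' saccade in versus opposite the RF).  Per neuron the four condition
#' curves are 0-1 normalized (by default jointly across conditions, so
#' between-condition amplitude differences survive), averaged over the
#' saccade-free epoch, and tested: a one-sided paired comparison of high
#' versus low saliency within each goal condition, a repeated-measures
#' saliency x goal ANOVA, and per-bin paired Wilcoxon tests with
#' Bonferroni-Holm correction marking where the curves diverge.
#'
#' @inheritParams tertile_curves
#' @param normalize_mode `"across"` (default) normalizes each neuron by
#'   the min/max over all four condition curves; `"per"` normalizes each
#'   condition separately.
#' @param alpha level for the divergence marks.
#' @return list with `epoch` (neuron x 4 matrix: high_in, low_in,
#'   high_opp, low_opp), `curves`, `tests` (per-goal paired p values),
#'   `anova`, `divergence` (logical per bin per goal), `dropped`
#'   (neurons with an empty cell).
#' @export
goal_split_analysis <- function(neurons, alignment = c("fixation", "saccade"),
                                window = NULL, normalize_mode = c("across", "per"),
                                alpha = 0.05) {
  alignment <- match.arg(alignment)
  normalize_mode <- match.arg(normalize_mode)
  if (is.null(window))
    window <- if (alignment == "fixation") c(-100, 500) else c(-300, 200)
  epoch <- .epoch_for(alignment)
  conds <- c("high_in", "low_in", "high_opp", "low_opp")
  nn <- length(neurons)
  ep <- matrix(NA_real_, nn, 4, dimnames = list(NULL, conds))
  curves <- NULL
  dropped <- logical(nn)
  norm_win <- if (alignment == "fixation") c(0, 500) else c(-300, 200)
  for (i in seq_len(nn)) {
    s <- neurons[[i]]$samples
    s <- s[s$included & !is.na(s$goal) & s$goal %in% c("in", "opposite"), ,
           drop = FALSE]
    if (alignment == "saccade") {
      s <- s[!is.na(s$sacc_on) & s$duration >= 150, , drop = FALSE]
      onsets <- s$sacc_on
    } else onsets <- s$t_on
    tert <- assign_tertiles(s$saliency)
    cell <- list(high_in = tert == "high" & s$goal == "in",
                 low_in = tert == "low" & s$goal == "in",
                 high_opp = tert == "high" & s$goal == "opposite",
                 low_opp = tert == "low" & s$goal == "opposite")
    if (any(vapply(cell, sum, 0L) == 0)) { dropped[i] <- TRUE; next }
    ac <- aligned_curves(neurons[[i]]$density, onsets, window)
    tv <- attr(ac, "t")
    if (is.null(curves)) curves <- array(NA_real_, c(nn, 4, ncol(ac)),
                                         dimnames = list(NULL, conds, NULL))
    raw <- sapply(cell, function(rows)
      colMeans(ac[rows, , drop = FALSE], na.rm = TRUE))
    if (normalize_mode == "across") {
      sel <- tv >= norm_win[1] & tv <= norm_win[2]
      lo <- min(raw[sel, ]); hi <- max(raw[sel, ])
      norm <- if (hi > lo) (raw - lo) / (hi - lo) else raw * 0
    } else {
      norm <- apply(raw, 2, normalize_rate, t = tv, window = norm_win)
    }
    for (k in seq_len(4)) {
      curves[i, k, ] <- norm[, k]
      ep[i, k] <- mean(norm[tv >= epoch[1] & tv <= epoch[2], k])
    }
  }
  keep <- !dropped
  tests <- list(
    p_in = tryCatch(stats::t.test(ep[keep, "high_in"], ep[keep, "low_in"],
                                  paired = TRUE, alternative = "greater")$p.value,
                    error = function(e) NA_real_),
    p_opp = tryCatch(stats::t.test(ep[keep, "high_opp"], ep[keep, "low_opp"],
                                   paired = TRUE, alternative = "greater")$p.value,
                     error = function(e) NA_real_))
  tab <- data.frame(
    neuron = factor(rep(which(keep), 4)),
    saliency = factor(rep(rep(c("high", "low"), 2), each = sum(keep))),
    goal = factor(rep(c("in", "opp"), each = 2 * sum(keep))),
    epoch_mean = as.vector(ep[keep, ]))
  fit <- if (sum(keep) >= 2)
    stats::aov(epoch_mean ~ saliency * goal +
                 Error(neuron / (saliency * goal)), data = tab)
  else NULL
  tv <- attr(aligned_curves(neurons[[1]]$density, numeric(0), window), "t")
  divergence <- sapply(c("in", "opp"), function(g) {
    hi <- curves[keep, paste0("high_", substr(g, 1, 3)), , drop = FALSE]
    lo <- curves[keep, paste0("low_", substr(g, 1, 3)), , drop = FALSE]
    p <- vapply(seq_len(dim(curves)[3]), function(b) {
      a <- hi[, 1, b]; d <- lo[, 1, b]
      ok <- is.finite(a) & is.finite(d)
      if (sum(ok) < 5 || all(a[ok] == d[ok])) return(1)
      stats::wilcox.test(a[ok], d[ok], paired = TRUE, exact = FALSE)$p.value
    }, numeric(1))
    stats::p.adjust(p, "holm") < alpha
  })
  list(epoch = ep, curves = curves, t = tv, tests = tests, anova = fit,
       divergence = divergence, dropped = dropped, alignment = alignment)
}

#' Feature dependence matrix
#'
#' For every neuron and every high-level feature, the difference in
#' normalized activation evoked by high versus low feature saliency
#' (upper minus lower per-feature tertile of the epoch rates), with a
#' Bonferroni-corrected one-sided population test per feature.
#'
#' @param neurons list; `samples` must contain per-feature saliency
#'   columns named in `features` plus `rate` (epoch firing rate).
#' @param features names of the per-feature saliency columns.
#' @param alpha level before Bonferroni correction.
#' @return list with `matrix` (neurons x features), `p` (corrected per
#'   feature), `significant`.
#' @export
feature_dependence <- function(neurons,
                               features = c("lum", "rg", "by", "ori",
                                            "flicker", "motion"),
                               alpha = 0.05) {
  nn <- length(neurons)
  M <- matrix(NA_real_, nn, length(features),
              dimnames = list(NULL, features))
  for (i in seq_len(nn)) {
    s <- neurons[[i]]$samples
    s <- s[s$included, , drop = FALSE]
    rate <- s$rate
    rng <- range(rate)
    nrate <- if (diff(rng) > 0) (rate - rng[1]) / diff(rng) else rate * 0
    for (f in features) {
      tert <- assign_tertiles(s[[f]])
      M[i, f] <- mean(nrate[tert == "high"]) - mean(nrate[tert == "low"])
    }
  }
  p <- apply(M, 2, function(v)
    stats::t.test(v, mu = 0, alternative = "greater")$p.value)
  p_adj <- pmin(p * length(features), 1)
  list(matrix = M, p = p_adj, significant = p_adj < alpha)
}

#' Behavioural effects of RF saliency
#'
#' Counts saccades directed into the RF at high versus low RF saliency and
#' compares the reaction times (fixation durations) of RF-directed
#' saccades between the two saliency extremes (rank-sum test).
#'
#' @param samples data frame with columns `saliency`, `goal`, `duration`,
#'   `neuron` and `included`; tertiles are computed per neuron.
#' @return list with `counts` (`high`, `low`), `count_p` (two-sided
#'   binomial test of equal frequency), `rt_mean` (`high`, `low`, ms) and
#'   `rt_p` (Wilcoxon independent-samples).
#' @export
behavioural_saliency <- function(samples) {
  samples <- samples[samples$included & !is.na(samples$goal), , drop = FALSE]
  samples$tertile <- unsplit(lapply(split(samples$saliency, samples$neuron),
                                    assign_tertiles), samples$neuron)
  inrf <- samples[samples$goal == "in", , drop = FALSE]
  n_high <- sum(inrf$tertile == "high")
  n_low <- sum(inrf$tertile == "low")
  count_p <- stats::binom.test(n_high, n_high + n_low)$p.value
  rt_h <- inrf$duration[inrf$tertile == "high"]
  rt_l <- inrf$duration[inrf$tertile == "low"]
  rt_p <- stats::wilcox.test(rt_h, rt_l, exact = FALSE)$p.value
  list(counts = c(high = n_high, low = n_low), count_p = count_p,
       rt_mean = c(high = mean(rt_h), low = mean(rt_l)), rt_p = rt_p)
}
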