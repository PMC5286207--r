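#' Scene script for synthetic video
#'
#' A scene script lists timed, localized visual events on a textured
#' background.  Event kinds cover the model's six feature channels:
#' `lum-disk`, `colour-disk`, `grating`, `flicker-patch`, `moving-dot`.
#'
#' @param events data frame with columns `onset`, `duration` (ms), `x`,
#'   `y` (deg from screen centre), `kind`, `intensity` (0-1), `size`
#'   (deg), and optionally `dir` (deg) and `speed` (deg/s) for moving
#'   dots.
#' @param duration_ms clip duration.
#' @param geom a [screen_geometry()]; events must lie on the screen.
#' @param bg_level background grey level (0-1).
#' @return object of class `scene_script`.
#' @export
scene_script <- function(events, duration_ms, geom, bg_level = 0.35) {
  need <- c("onset", "duration", "x", "y", "kind", "intensity", "size")
  stopifnot(all(need %in% names(events)))
  if (any(abs(events$x) > geom$width_deg / 2 |
          abs(events$y) > geom$height_deg / 2))
    stop("event positions must lie within the screen extent")
  if (is.null(events$dir)) events$dir <- 0
  if (is.null(events$speed)) events$speed <- 0
  structure(list(events = events, duration_ms = duration_ms, geom = geom,
                 bg_level = bg_level),
            class = "scene_script")
}

#' Random scene script
#'
#' Draws events of all kinds at random times and positions; a convenience
#' generator for end-to-end tests.
#'
#' @param n_events number of events.
#' @param duration_ms clip duration.
#' @param geom screen geometry.
#' @param seed RNG seed.
#' @return a [scene_script()].
#' @export
random_scene_script <- function(n_events, duration_ms, geom, seed = 1) {
  set.seed(seed)
  kinds <- c("lum-disk", "colour-disk", "grating", "flicker-patch",
             "moving-dot")
  ev <- data.frame(
    onset = stats::runif(n_events, 0, duration_ms * 0.8),
    duration = stats::runif(n_events, 400, 1500),
    x = stats::runif(n_events, -geom$width_deg * 0.4, geom$width_deg * 0.4),
    y = stats::runif(n_events, -geom$height_deg * 0.4, geom$height_deg * 0.4),
    kind = sample(kinds, n_events, replace = TRUE),
    intensity = stats::runif(n_events, 0.5, 1),
    size = stats::runif(n_events, 2, 5),
    dir = stats::runif(n_events, 0, 360),
    speed = stats::runif(n_events, 5, 15))
  scene_script(ev, duration_ms, geom)
}

#' Render a scene script to RGB frames
#'
#' Deterministic given the seed.  The background is a static low-contrast
#' texture; each event paints its stimulus while active.
#'
#' @param script a [scene_script()].
#' @param fps display frame rate.
#' @param seed seed for the background texture.
#' @return list of `H x W x 3` arrays in \[0, 1\], with attribute `t_ms`
#'   (frame onset times).
#' @export
render_clip <- function(script, fps = 60, seed = 1) {
  geom <- script$geom
  W <- geom$width_px; H <- geom$height_px
  set.seed(seed)
  bg <- pmin(pmax(script$bg_level +
                    gauss_blur(matrix(stats::rnorm(H * W, 0, 0.15), H, W), 2),
                  0), 1)
  xs <- (seq_len(W) - (W + 1) / 2) / geom$ppd_x
  ys <- ((H + 1) / 2 - seq_len(H)) / geom$ppd_y
  xm <- matrix(xs, H, W, byrow = TRUE)
  ym <- matrix(ys, H, W)
  nframes <- max(1, floor(script$duration_ms / 1000 * fps))
  t_ms <- (seq_len(nframes) - 1) / fps * 1000
  ev <- script$events
  frames <- vector("list", nframes)
  for (fi in seq_len(nframes)) {
    t <- t_ms[fi]
    r <- bg; g <- bg; b <- bg
    act <- which(ev$onset <= t & t < ev$onset + ev$duration)
    for (k in act) {
      e <- ev[k, ]
      cx <- e$x; cy <- e$y
      if (e$kind == "moving-dot") {
        dt_s <- (t - e$onset) / 1000
        cx <- cx + cos(e$dir * pi / 180) * e$speed * dt_s
        cy <- cy + sin(e$dir * pi / 180) * e$speed * dt_s
      }
      d2 <- (xm - cx)^2 + (ym - cy)^2
      inside <- d2 <= (e$size / 2)^2
      if (!any(inside)) next
      amp <- e$intensity
      if (e$kind == "flicker-patch" && (floor(t / 50) %% 2 == 1)) amp <- -amp
      switch(e$kind,
        "colour-disk" = {
          r[inside] <- pmin(pmax(r[inside] + amp * 0.5, 0), 1)
          g[inside] <- pmin(pmax(g[inside] - amp * 0.5, 0), 1)
        },
        "grating" = {
          ph <- sin(2 * pi * 0.5 *
                      ((xm[inside] - cx) * cos(pi / 4) +
                       (ym[inside] - cy) * sin(pi / 4)))
          v <- pmin(pmax(bg[inside] + amp * 0.5 * ph, 0), 1)
          r[inside] <- v; g[inside] <- v; b[inside] <- v
        },
        {
          v <- pmin(pmax(bg[inside] + amp * 0.6, 0), 1)
          r[inside] <- v; g[inside] <- v; b[inside] <- v
        })
    }
    fr <- array(0, c(H, W, 3))
    fr[, , 1] <- r; fr[, , 2] <- g; fr[, , 3] <- b
    frames[[fi]] <- fr
  }
  attr(frames, "t_ms") <- t_ms
  frames
}

.fixdur_meanlog <- 5.428   # geometric centre of the 95-545 ms band
.fixdur_sdlog <- 0.446

#' Simulate free-viewing gaze over a scene script
#'
#' Alternates fixations (log-normal durations whose central 95% spans
#' roughly 95-545 ms) with 20-40 ms saccades.  With probability `p` the
#' next saccade targets the strongest currently active scripted event,
#' otherwise a uniform screen position.  When an RF is supplied, the
#' generator logs per-fixation ground truth (RF saliency proxy, next
#' saccade goal) and plants a reaction-time advantage: fixations with a
#' salient event near the RF are shortened by `rt_advantage` ms.
#'
#' @param script a [scene_script()].
#' @param p salience-seeking probability in \[0, 1\].
#' @param rate sampling rate, Hz.
#' @param seed RNG seed.
#' @param rf optional `c(R, phi)` of a neuron's RF (deg, retinal polar).
#' @param rf_radius spatial scale of the RF saliency proxy, deg: active
#'   events contribute with a Gaussian weight (sigma `rf_radius / 2`) of
#'   their distance to the RF centre.
#' @param rt_advantage planted RT shortening at unit RF saliency, ms.
#' @return list with `trace` (a [gaze_trace()]) and `truth` (per-fixation
#'   data frame: onset, duration, position, target event, `s_rf`, `goal`).
#' @export
simulate_gaze <- function(script, p = 0.8, rate = 200, seed = 1,
                          rf = NULL, rf_radius = 3, rt_advantage = 30) {
  set.seed(seed)
  geom <- script$geom
  dt <- 1000 / rate
  ev <- script$events
  pos <- c(0, 0)
  t <- 0
  fix <- list()
  seg_t <- c(); seg_x <- c(); seg_y <- c()
  while (t < script$duration_ms) {
    dur <- stats::rlnorm(1, .fixdur_meanlog, .fixdur_sdlog)
    dur <- min(max(dur, 60), 1500)
    s_rf <- 0
    if (!is.null(rf)) {
      rfx <- pos[1] + rf[1] * cos(rf[2] * pi / 180)
      rfy <- pos[2] + rf[1] * sin(rf[2] * pi / 180)
      act <- which(ev$onset <= t & t < ev$onset + ev$duration)
      for (k in act) {
        d2 <- (ev$x[k] - rfx)^2 + (ev$y[k] - rfy)^2
        s_rf <- s_rf + ev$intensity[k] * exp(-d2 / (2 * (rf_radius / 2)^2))
      }
      dur <- max(60, dur - rt_advantage * min(s_rf, 1))
    }
    ns <- max(1, round(dur / dt))
    ts <- t + dt * (seq_len(ns) - 1)
    seg_t <- c(seg_t, ts)
    seg_x <- c(seg_x, pos[1] + stats::rnorm(ns, 0, 0.02))
    seg_y <- c(seg_y, pos[2] + stats::rnorm(ns, 0, 0.02))
    t_end <- t + ns * dt
    ## choose the next target
    act <- which(ev$onset <= t_end & t_end < ev$onset + ev$duration)
    target_event <- NA_integer_
    if (length(act) && stats::runif(1) < p) {
      target_event <- act[which.max(ev$intensity[act])]
      tgt <- c(ev$x[target_event], ev$y[target_event]) +
        stats::rnorm(2, 0, 0.3)
    } else {
      tgt <- c(stats::runif(1, -geom$width_deg * 0.45, geom$width_deg * 0.45),
               stats::runif(1, -geom$height_deg * 0.45, geom$height_deg * 0.45))
    }
    goal <- NA_character_
    if (!is.null(rf)) {
      dirn <- atan2(tgt[2] - pos[2], tgt[1] - pos[1]) * 180 / pi
      goal <- label_saccade_goal(dirn, rf[2], rf[1])
    }
    fix[[length(fix) + 1]] <- data.frame(
      t_on = t, duration = ns * dt, x = pos[1], y = pos[2],
      target_event = target_event, s_rf = s_rf, goal = goal)
    ## saccade: raised-cosine trajectory
    sdur <- stats::runif(1, 20, 40)
    nss <- max(2, round(sdur / dt))
    frac <- (1 - cos(pi * seq_len(nss) / nss)) / 2
    seg_t <- c(seg_t, t_end + dt * (seq_len(nss) - 1))
    seg_x <- c(seg_x, pos[1] + frac * (tgt[1] - pos[1]))
    seg_y <- c(seg_y, pos[2] + frac * (tgt[2] - pos[2]))
    pos <- tgt
    t <- t_end + nss * dt
  }
  keep <- seg_t < script$duration_ms
  trace <- gaze_trace(seg_t[keep], seg_x[keep], seg_y[keep])
  list(trace = trace, truth = do.call(rbind, fix))
}

#' Specification of a synthetic SC neuron
#'
#' @param rf_R,rf_phi RF centre eccentricity and polar angle, deg.
#' @param layer_class `"SCs"` or `"SCi"`.
#' @param baseline baseline rate, spikes/s.
#' @param gain saliency gain, spikes/s per unit RF saliency.  For SCi
#'   neurons the gain acts only when the next saccade is directed into
#'   the RF (goal gating).
#' @param latency response latency, ms (25-125).
#' @param goal_gain additive rate increase when the goal is in the RF,
#'   spikes/s (intermediate-layer neurons).
#' @param seed per-neuron RNG seed.
#' @return list of class `synthetic_neuron_spec`.
#' @export
synthetic_neuron_spec <- function(rf_R = 10, rf_phi = 0,
                                  layer_class = c("SCs", "SCi"),
                                  baseline = 20, gain = 40, latency = 75,
                                  goal_gain = 0, seed = 1) {
  layer_class <- match.arg(layer_class)
  stopifnot(latency >= 25, latency <= 125, baseline >= 0, gain >= 0)
  structure(list(rf_R = rf_R, rf_phi = rf_phi, layer_class = layer_class,
                 baseline = baseline, gain = gain, latency = latency,
                 goal_gain = goal_gain, seed = seed),
            class = "synthetic_neuron_spec")
}

#' Simulate spikes from an RF saliency series
#'
#' Inhomogeneous Poisson spiking with rate
#' `baseline + gain * saliency(t - latency) * gate + goal_gain * goal_in`,
#' where the gate is the goal-in indicator for SCi neurons and 1 for SCs
#' neurons.  Negative instantaneous rates are clamped to zero.
#'
#' @param spec a [synthetic_neuron_spec()].
#' @param saliency RF saliency series at 200 Hz.
#' @param goal per-sample goal labels (`"in"`, `"opposite"`, `"other"` or
#'   `NA`); optional for SCs neurons.
#' @param dt sample interval, ms.
#' @return sorted spike times (ms) with the ground-truth rate as
#'   attribute `rate`.
#' @export
simulate_spikes <- function(spec, saliency, goal = NULL, dt = 5) {
  n <- length(saliency)
  k <- round(spec$latency / dt)
  lag <- c(rep(saliency[1], k), saliency)[seq_len(n)]
  gate <- rep(1, n)
  goal_in <- rep(0, n)
  if (!is.null(goal)) {
    goal_in <- as.numeric(!is.na(goal) & goal == "in")
    if (spec$layer_class == "SCi") gate <- goal_in
  } else if (spec$layer_class == "SCi") gate <- rep(0, n)
  rate <- pmax(spec$baseline + spec$gain * lag * gate +
                 spec$goal_gain * goal_in, 0)
  set.seed(spec$seed)
  counts <- stats::rpois(n, rate * dt / 1000)
  idx <- rep(seq_len(n), counts)
  times <- (idx - 1) * dt + stats::runif(length(idx), 0, dt)
  structure(sort(times), rate = rate)
}

#' Simulate a complete free-viewing session for one synthetic neuron
#'
#' Generates a fixation/saccade sequence (no video required), a
#' per-fixation RF saliency value, the 200 Hz saliency and goal series,
#' Poisson spikes via [simulate_spikes()], the full-session spike density
#' and the per-fixation sample table the analysis pipeline consumes.
#' Per-feature saliency columns are correlated with the combined saliency
#' (`feature_mode = "combined"`) or independent with one feature carrying
#' the drive (`feature_mode = "motion"`).
#'
#' @param spec a [synthetic_neuron_spec()].
#' @param n_fix number of fixations.
#' @param seed session seed.
#' @param goal_probs probabilities of goal `in`, `opposite`, `other`.
#' @param feature_mode see above.
#' @return list with `spec`, `samples` (per-fixation data frame),
#'   `density`, `spikes`, and the 200 Hz `saliency` and `goal` series.
#' @export
synthetic_session <- function(spec, n_fix = 300, seed = 1,
                              goal_probs = c(0.3, 0.3, 0.4),
                              feature_mode = c("combined", "motion")) {
  feature_mode <- match.arg(feature_mode)
  set.seed(seed)
  dt <- 5
  dur <- pmin(stats::rlnorm(n_fix, .fixdur_meanlog, .fixdur_sdlog), 1500)
  dur <- pmax(round(dur / dt) * dt, 60)
  gap <- 30                                  # saccade duration, ms
  t_on <- cumsum(c(0, (dur + gap)[-n_fix]))
  s_f <- pmin(stats::rgamma(n_fix, shape = 2, scale = 0.15), 1.2)
  goal_f <- sample(c("in", "opposite", "other"), n_fix, replace = TRUE,
                   prob = goal_probs)
  total <- t_on[n_fix] + dur[n_fix] + gap
  nsamp <- ceiling(total / dt)
  tgrid <- (seq_len(nsamp) - 1) * dt
  fix_of <- findInterval(tgrid, t_on)
  saliency <- s_f[fix_of]
  goal <- goal_f[fix_of]
  spec$seed <- seed + 1
  spikes <- simulate_spikes(spec, saliency, goal, dt = dt)
  density <- spike_density(spikes, c(0, total), kernel = "epsp")
  feats <- c("lum", "rg", "by", "ori", "flicker", "motion")
  fmat <- sapply(feats, function(f) {
    if (feature_mode == "combined")
      s_f * stats::runif(n_fix, 0.6, 1.4)
    else if (f == "motion") s_f
    else pmin(stats::rgamma(n_fix, 2, scale = 0.15), 1.2)
  })
  samples <- data.frame(t_on = t_on, sacc_on = t_on + dur, duration = dur,
                        saliency = s_f, goal = goal_f,
                        included = dur >= 200,
                        rate = window_rate(spikes, t_on, c(0, 200)))
  samples <- cbind(samples, as.data.frame(fmat))
  list(spec = spec, samples = samples, density = density, spikes = spikes,
       saliency = saliency, goal = goal, t = tgrid)
}

#' Generate the default synthetic neuron population
#'
#' The study-condition population: visual SCs-like neurons whose saliency
#' gain is goal-independent, and visuomotor SCi-like neurons whose gain is
#' gated by the saccade goal and which carry an additive goal signal.
#'
#' @param n_scs,n_sci numbers of neurons of each class.
#' @param n_fix fixations per neuron.
#' @param seed master seed.
#' @return list of sessions (see [synthetic_session()]); each element also
#'   carries `layer_class`.
#' @export
synthetic_population <- function(n_scs = 30, n_sci = 25, n_fix = 300,
                                 seed = 1) {
  set.seed(seed)
  n <- n_scs + n_sci
  cls <- c(rep("SCs", n_scs), rep("SCi", n_sci))
  lat <- stats::runif(n, 50, 100)
  rf_R <- stats::runif(n, 5, 25)
  rf_phi <- stats::runif(n, -90, 90)
  lapply(seq_len(n), function(i) {
    spec <- synthetic_neuron_spec(rf_R = rf_R[i], rf_phi = rf_phi[i],
                                  layer_class = cls[i], baseline = 20,
                                  gain = 40, latency = lat[i],
                                  goal_gain = if (cls[i] == "SCi") 10 else 0,
                                  seed = seed * 1000 + i)
    ses <- synthetic_session(spec, n_fix = n_fix, seed = seed * 1000 + i)
    ses$layer_class <- cls[i]
    ses
  })
}
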