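#' Construct a gaze trace
#'
#' A gaze trace is a data frame of uniformly sampled eye positions: time
#' in ms, x/y in degrees of visual angle from screen centre, and a
#' per-sample validity flag (FALSE during blinks or signal loss).
#'
#' @param t time stamps in ms, strictly increasing and uniformly spaced.
#' @param x,y gaze position, degrees.
#' @param valid logical validity flags (recycled).
#' @return data frame of class `gaze_trace` with attribute `rate_hz`.
#' @export
gaze_trace <- function(t, x, y, valid = TRUE) {
  stopifnot(length(t) == length(x), length(x) == length(y))
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("time stamps must be strictly increasing")
    if (max(abs(dt - stats::median(dt))) > 1e-6 * stats::median(dt) + 1e-9) {
      bad <- which(abs(dt - stats::median(dt)) > 1e-6 * stats::median(dt) + 1e-9)
      stop(sprintf("non-uniform sampling: %d gap(s), first at t=%g ms (dt=%g)",
                   length(bad), t[bad[1]], dt[bad[1]]))
    }
  }
  valid <- rep_len(as.logical(valid), length(t))
  if (any(!is.finite(x[valid])) || any(!is.finite(y[valid])))
    stop("x and y must be finite wherever valid")
  df <- data.frame(t = t, x = x, y = y, valid = valid)
  attr(df, "rate_hz") <- if (length(t) > 1) 1000 / stats::median(diff(t)) else NA_real_
  class(df) <- c("gaze_trace", "data.frame")
  df
}

#' Down-sample a gaze trace by decimation
#'
#' Keeps the native sample closest to each target-rate instant (pure
#' decimation, no smoothing); invalid spans propagate to the samples they
#' overlap.  The native rate must be an integer multiple of the target.
#'
#' @param trace a [gaze_trace()].
#' @param target_rate target sampling rate, Hz (default 200).
#' @return decimated `gaze_trace`.
#' @export
resample_gaze <- function(trace, target_rate = 200) {
  native <- attr(trace, "rate_hz")
  stopifnot(native >= target_rate)
  factor <- native / target_rate
  if (abs(factor - round(factor)) > 1e-6)
    stop("target rate must divide the native rate")
  idx <- seq(1, nrow(trace), by = round(factor))
  out <- trace[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rate_hz") <- target_rate
  class(out) <- c("gaze_trace", "data.frame")
  out
}

#' Interpolate blinks in a gaze trace
#'
#' Each interior run of invalid samples is filled by linear interpolation
#' between the flanking valid samples and marked valid.  Runs touching the
#' trace boundary cannot be interpolated and remain invalid (reported via
#' a message).
#'
#' @param trace a [gaze_trace()].
#' @return trace with interior invalid spans filled.
#' @export
interpolate_blinks <- function(trace) {
  v <- trace$valid
  if (all(v)) return(trace)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  n_boundary <- 0
  for (i in which(!r$values)) {
    if (starts[i] == 1 || ends[i] == nrow(trace)) {
      n_boundary <- n_boundary + 1
      next
    }
    i0 <- starts[i] - 1; i1 <- ends[i] + 1
    span <- starts[i]:ends[i]
    w <- (trace$t[span] - trace$t[i0]) / (trace$t[i1] - trace$t[i0])
    trace$x[span] <- trace$x[i0] + w * (trace$x[i1] - trace$x[i0])
    trace$y[span] <- trace$y[i0] + w * (trace$y[i1] - trace$y[i0])
    trace$valid[span] <- TRUE
  }
  if (n_boundary > 0)
    message(sprintf("%d invalid span(s) at the trace boundary left as is",
                    n_boundary))
  trace
}

#' Instantaneous gaze speed
#'
#' Central differences with a 2-sample smoothing window on the resampled
#' trace.
#'
#' @param trace a [gaze_trace()].
#' @return speed in deg/s per sample.
#' @export
gaze_speed <- function(trace) {
  n <- nrow(trace)
  dt <- 1 / attr(trace, "rate_hz")          # seconds
  vx <- c(0, (trace$x[-(1:2)] - trace$x[1:(n - 2)]) / (2 * dt), 0)
  vy <- c(0, (trace$y[-(1:2)] - trace$y[1:(n - 2)]) / (2 * dt), 0)
  sp <- sqrt(vx^2 + vy^2)
  (sp + c(sp[1], sp[-n])) / 2               # 2-sample smoothing
}

#' Detect saccades by a velocity and amplitude criterion
#'
#' Maximal contiguous spans where speed exceeds `vel_thresh` become
#' candidate saccades; those whose start-to-end displacement is at least
#' `min_amp` are kept.
#'
#' @param trace resampled, blink-interpolated [gaze_trace()].
#' @param vel_thresh velocity criterion, deg/s.
#' @param min_amp minimum amplitude, degrees.
#' @return data frame with `t_on`, `t_off` (ms), `x_on`, `y_on`, `x_off`,
#'   `y_off`, `amplitude` (deg), `direction` (deg, CCW from rightward) and
#'   `peak_vel` (deg/s); zero rows when the trace is empty or stationary.
#' @export
detect_saccades <- function(trace, vel_thresh = 50, min_amp = 1) {
  empty <- data.frame(t_on = numeric(0), t_off = numeric(0),
                      x_on = numeric(0), y_on = numeric(0),
                      x_off = numeric(0), y_off = numeric(0),
                      amplitude = numeric(0), direction = numeric(0),
                      peak_vel = numeric(0))
  if (nrow(trace) < 3) return(empty)
  sp <- gaze_speed(trace)
  above <- sp > vel_thresh
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- empty
  n <- nrow(trace)
  for (i in keep) {
    i0 <- starts[i]; i1 <- ends[i]
    ## extend to the flanking velocity troughs so the displacement covers
    ## the full movement, not only the supra-threshold core
    while (i0 > 1 && sp[i0 - 1] < sp[i0] && !above[i0 - 1]) i0 <- i0 - 1
    while (i1 < n && sp[i1 + 1] < sp[i1] && !above[i1 + 1]) i1 <- i1 + 1
    dx <- trace$x[i1] - trace$x[i0]
    dy <- trace$y[i1] - trace$y[i0]
    amp <- sqrt(dx^2 + dy^2)
    if (amp < min_amp) next
    out <- rbind(out, data.frame(
      t_on = trace$t[i0], t_off = trace$t[i1],
      x_on = trace$x[i0], y_on = trace$y[i0],
      x_off = trace$x[i1], y_off = trace$y[i1],
      amplitude = amp, direction = atan2(dy, dx) * 180 / pi,
      peak_vel = max(sp[i0:i1])))
  }
  out
}

#' Extract fixations as inter-saccadic intervals
#'
#' The intervals between consecutive saccades (plus the leading and
#' trailing intervals) become fixations.  Fixations shorter than `min_dur`
#' are retained but flagged `included = FALSE` so analyses can exclude
#' them; the clip-final fixation has no terminating saccade
#' (`next_saccade = NA`) and is ineligible for saccade-goal labelling.
#'
#' @param trace a [gaze_trace()].
#' @param saccades output of [detect_saccades()] on the same trace.
#' @param min_dur inclusion cutoff, ms (default 200).
#' @return data frame with `t_on`, `t_off`, `duration`, `x`, `y` (mean
#'   position), `next_saccade` (row index into `saccades`) and `included`.
#' @export
extract_fixations <- function(trace, saccades, min_dur = 200) {
  bounds_on <- c(trace$t[1], saccades$t_off)
  bounds_off <- c(saccades$t_on, trace$t[nrow(trace)])
  next_sac <- c(seq_len(nrow(saccades)), NA_integer_)
  keep <- bounds_off > bounds_on
  out <- data.frame(t_on = bounds_on[keep], t_off = bounds_off[keep],
                    next_saccade = next_sac[keep])
  out$duration <- out$t_off - out$t_on
  pos <- t(vapply(seq_len(nrow(out)), function(i) {
    sel <- trace$t >= out$t_on[i] & trace$t <= out$t_off[i] & trace$valid
    if (!any(sel)) return(c(NA_real_, NA_real_))
    c(mean(trace$x[sel]), mean(trace$y[sel]))
  }, numeric(2)))
  out$x <- pos[, 1]; out$y <- pos[, 2]
  out$included <- out$duration >= min_dur
  out[, c("t_on", "t_off", "duration", "x", "y", "next_saccade", "included")]
}

#' Mode of a 2-D point cloud by mean shift, with bandwidth escalation
#'
#' Runs flat-kernel mean shift from every point, groups the converged
#' modes, and returns the mode of the largest cluster.  When two clusters
#' tie in count the bandwidth is increased in 0.05 deg steps and the
#' procedure repeated; if no dominant cluster emerges by `max_bandwidth`
#' the location is rejected (a regular outcome, not an error).
#'
#' @param points n x 2 matrix of positions, degrees.
#' @param bandwidth starting kernel radius, degrees.
#' @param max_bandwidth largest bandwidth tried, degrees.
#' @param step bandwidth increment, degrees.
#' @return list with `mode` (length-2 vector or `NULL`), `rejected`,
#'   `bandwidth` (the one that produced the decision) and `count`.
#' @export
mean_shift_mode <- function(points, bandwidth = 0.5, max_bandwidth = 0.75,
                            step = 0.05) {
  points <- matrix(points, ncol = 2)
  stopifnot(nrow(points) >= 1)
  if (nrow(points) == 1)
    return(list(mode = as.vector(points[1, ]), rejected = FALSE,
                bandwidth = bandwidth, count = 1L))
  h <- bandwidth
  repeat {
    modes <- t(apply(points, 1, function(p) {
      for (it in 1:200) {
        d2 <- (points[, 1] - p[1])^2 + (points[, 2] - p[2])^2
        inw <- d2 <= h^2
        newp <- colMeans(points[inw, , drop = FALSE])
        if (sum((newp - p)^2) < 1e-12) break
        p <- newp
      }
      p
    }))
    ## group converged modes within h/4
    grp <- integer(nrow(modes)); g <- 0
    for (i in seq_len(nrow(modes))) {
      if (grp[i] > 0) next
      g <- g + 1
      d2 <- (modes[, 1] - modes[i, 1])^2 + (modes[, 2] - modes[i, 2])^2
      grp[grp == 0 & d2 <= (h / 4)^2] <- g
    }
    counts <- tabulate(grp)
    top <- which(counts == max(counts))
    if (length(top) == 1)
      return(list(mode = colMeans(modes[grp == top, , drop = FALSE]),
                  rejected = FALSE, bandwidth = h, count = max(counts)))
    h <- h + step
    if (h > max_bandwidth + 1e-9)
      return(list(mode = NULL, rejected = TRUE, bandwidth = h - step,
                  count = max(counts)))
  }
}

angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Label the goal of a fixation's next saccade relative to the RF
#'
#' The RF is gaze-anchored, so the direction from the fixation toward the
#' RF is the RF's own polar angle in retinal coordinates.  The next
#' saccade is labelled `"in"` when its direction lies within
#' `cone_halfwidth` of that angle, `"opposite"` within the same cone
#' around the antipode, and `"other"` elsewhere (dropped from the goal
#' analysis).
#'
#' @param direction next-saccade direction(s), degrees.
#' @param rf_phi RF polar angle, degrees.
#' @param rf_R RF eccentricity, degrees; must be >= 2 (neurons with
#'   near-foveal RFs are excluded from direction analyses).
#' @param cone_halfwidth half-width of the in/opposite cones, degrees.
#' @return character vector in `{"in", "opposite", "other"}`.
#' @export
label_saccade_goal <- function(direction, rf_phi, rf_R,
                               cone_halfwidth = 45) {
  if (rf_R < 2)
    stop("RF eccentricity < 2 deg: neuron excluded from saccade-goal analysis")
  d <- abs(angle_diff(direction, rf_phi))
  ifelse(d <= cone_halfwidth, "in",
         ifelse(d >= 180 - cone_halfwidth, "opposite", "other"))
}
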