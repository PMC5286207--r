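#' A visual-space plane containing a luminance disk
#'
#' Square plane covering `field_deg` degrees centred on gaze, zero
#' background, with a disk of the given diameter and amplitude.
#'
#' @param diam disk diameter, degrees.
#' @param centre `c(x, y)` disk centre, degrees.
#' @param ppd resolution, px/deg.
#' @param field_deg plane extent, degrees.
#' @param amplitude disk value.
#' @return matrix plane.
#' @export
disk_plane <- function(diam, centre = c(0, 0), ppd = 4, field_deg = 100,
                       amplitude = 1) {
  P <- round(field_deg * ppd)
  xs <- (seq_len(P) - (P + 1) / 2) / ppd
  xm <- matrix(xs, P, P, byrow = TRUE)
  ym <- -matrix(xs, P, P)
  m <- matrix(0, P, P)
  m[(xm - centre[1])^2 + (ym - centre[2])^2 <= (diam / 2)^2] <- amplitude
  m
}

#' Disk-diameter tuning of an eccentricity-matched DoG detector
#'
#' Builds the DoG detector of a model unit at the given eccentricity (its
#' optimal size from the eccentricity law), presents centred luminance
#' disks of increasing diameter through the Gaussian scale-space path, and
#' reports the response curve and the diameter maximizing it.
#'
#' @param ecc unit eccentricity, degrees.
#' @param K DoG ratio (chromatic/luminance value by default).
#' @param diams diameters to sweep, degrees; default a fine grid around
#'   the design size.
#' @param ppd plane resolution, px/deg.
#' @param field_deg plane extent, degrees.
#' @return list with `diams`, `response`, `preferred` (argmax diameter)
#'   and `S_design`.
#' @export
dog_size_tuning <- function(ecc, K = 6.7, diams = NULL, ppd = 4,
                            field_deg = 100) {
  S <- eccentricity_size_law(ecc)
  if (is.null(diams)) diams <- seq(0.25 * S, 3 * S, by = 0.025 * S)
  d <- make_dog(S, K)
  resp <- vapply(diams, function(dd) {
    plane <- disk_plane(dd, centre = c(ecc, 0), ppd = ppd,
                        field_deg = field_deg)
    ss <- scale_space(plane, sigma0 = 0.4)
    p <- deg_to_px(ecc, 0, nrow(plane), ppd)
    ss_sample(ss, d$sigma_c * ppd, p$row, p$col) -
      ss_sample(ss, d$sigma_s * ppd, p$row, p$col)
  }, numeric(1))
  list(diams = diams, response = resp, preferred = diams[which.max(resp)],
       S_design = S)
}

#' Activation-field probe sweep
#'
#' Measures the simulated activation field of the model unit centred at a
#' given eccentricity on the horizontal meridian: a small luminance probe
#' is swept along the meridian, each probe is passed through the
#' eccentricity-dependent DoG stage, the unit's circular pooling
#' neighbourhood is summed, and the activation field diameter is the span
#' of probe positions evoking at least half of the maximal response.
#'
#' @param ecc eccentricity of the probed unit, degrees.
#' @param grid the model grid.
#' @param cfg an [sc_config()].
#' @param probe_diam probe diameter, degrees.
#' @param span half-width of the swept position range, degrees.
#' @param step probe position step, degrees.
#' @return list with `positions`, `response`, `diameter` (half-max span,
#'   deg) and `unit` (grid index).
#' @export
activation_field_sweep <- function(ecc, grid, cfg = sc_config(),
                                   probe_diam = 1, span = NULL,
                                   step = NULL) {
  if (is.null(span)) span <- max(4, ecc * 0.4)
  if (is.null(step)) step <- span / 40
  unit <- grid_unit_at(grid, ecc, 0)
  n <- grid$n
  uc <- arrayInd(unit, c(n, n))
  rs <- outer(seq_len(n) - uc[1], rep(1, n))
  cs <- outer(rep(1, n), seq_len(n) - uc[2])
  disc <- which(rs^2 + cs^2 <= grid$pool_radius^2)
  positions <- seq(ecc - span, ecc + span, by = step)
  resp <- vapply(positions, function(px) {
    plane <- disk_plane(probe_diam, centre = c(px, 0), ppd = cfg$px_per_deg,
                        field_deg = cfg$field_deg)
    sum(dog_response(plane, grid, cfg$K_chrom, cfg$px_per_deg, units = disc,
                     rectify = "abs"))
  }, numeric(1))
  half <- max(resp) / 2
  above <- which(resp >= half)
  lo <- min(above); hi <- max(above)
  x_lo <- if (lo > 1) {
    positions[lo - 1] + (half - resp[lo - 1]) / (resp[lo] - resp[lo - 1]) * step
  } else positions[1]
  x_hi <- if (hi < length(resp)) {
    positions[hi] + (resp[hi] - half) / (resp[hi] - resp[hi + 1]) * step
  } else positions[length(positions)]
  list(positions = positions, response = resp, diameter = x_hi - x_lo,
       unit = unit)
}

#' Run the saliency model over a short frame sequence
#'
#' Converts each display frame to a gaze-centred retinal frame, maintains
#' the 9-frame buffer, and emits per-step feature stacks, high-level maps
#' and the saliency map once the buffer is full.
#'
#' @param frames list of RGB arrays (one per model step, 200 Hz).
#' @param gaze matrix (steps x 2) of gaze positions, degrees.
#' @param geom a [screen_geometry()].
#' @param grid the model grid.
#' @param cfg an [sc_config()].
#' @return list of per-step results (`NULL` while the buffer fills), each
#'   with `stack`, `high`, `saliency`.
#' @export
run_model <- function(frames, gaze, geom, grid, cfg = sc_config()) {
  gaze <- matrix(gaze, ncol = 2)
  out <- vector("list", length(frames))
  buf <- list()
  for (i in seq_along(frames)) {
    rf <- retinal_frame(frames[[i]], gaze[i, ], geom, cfg)
    buf <- c(buf, list(rf))
    if (length(buf) > 9) buf <- buf[-1]
    if (length(buf) < 9) next
    st <- feature_stack(buf, grid, cfg)
    hi <- combine_high_level(st)
    out[[i]] <- list(stack = st, high = hi, saliency = saliency_map(hi))
  }
  out
}
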