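#' Model configuration
#'
#' Collects the tunable constants of the saliency model in one place.
#'
#' @param px_per_deg working resolution of the retinal (visual-space) planes
#'   after decimation, pixels per degree.
#' @param field_deg extent of the simulated retinal field (square), degrees.
#' @param grid_n side length of the model SC grid, units.
#' @param K_chrom surround/centre DoG ratio for luminance and chromatic
#'   features (retinal-ganglion-cell value).
#' @param K_st surround/centre DoG ratio for the spatiotemporal features
#'   (V1 value).
#' @param speeds motion-filter drift speeds, pixels per frame at the
#'   working resolution and 200 Hz frame rate.
#' @param ori_sigma spatial sigmas (px) of the two steerable-filter scales
#'   (working resolution and half of it).
#' @param comp_exc_deg,comp_inh_deg excitatory/inhibitory Gaussian sizes of
#'   the long-range competition DoG, degrees.
#' @param gi_frac global-inhibition constant of the competition operator,
#'   as a fraction of the post-addback map maximum.
#' @param pool_radius activation-field pooling radius, grid pixels.
#' @param decimations number of binomial decimation passes applied between
#'   the embedded retinal image and the working resolution.
#' @return a list of class `sc_config`.
#' @export
sc_config <- function(px_per_deg = 4, field_deg = 100, grid_n = 200,
                      K_chrom = 6.7, K_st = 3.2,
                      speeds = c(1, 4, 16), ori_sigma = c(1, 2),
                      comp_exc_deg = 3, comp_inh_deg = 9, gi_frac = 0.02,
                      pool_radius = 3, decimations = 1) {
  structure(list(px_per_deg = px_per_deg, field_deg = field_deg,
                 grid_n = grid_n, K_chrom = K_chrom, K_st = K_st,
                 speeds = speeds, ori_sigma = ori_sigma,
                 comp_exc_deg = comp_exc_deg, comp_inh_deg = comp_inh_deg,
                 gi_frac = gi_frac, pool_radius = pool_radius,
                 decimations = decimations),
            class = "sc_config")
}

#' Linear eccentricity law for the optimal stimulus size
#'
#' Optimal (preferred) stimulus size grows linearly with eccentricity, from
#' 0.75 degrees at the fovea to 5 degrees at 40 degrees eccentricity, and
#' extrapolates linearly beyond.
#'
#' @param R eccentricity, degrees (vector).
#' @return optimal stimulus size, degrees.
#' @export
eccentricity_size_law <- function(R) {
  stopifnot(all(R >= 0))
  0.75 + R * (5 - 0.75) / 40
}

#' Difference-of-Gaussians detector for a given optimal stimulus size
#'
#' For unit-mass centre and surround Gaussians with sigma ratio `K`, the
#' response to a centred disk of radius `r` is
#' \eqn{e^{-r^2/2\sigma_s^2} - e^{-r^2/2\sigma_c^2}} (in magnitude), which
#' peaks at diameter
#' \eqn{S = 4 \sigma_c K \sqrt{\ln K / (K^2 - 1)}}.  Solving for the centre
#' sigma gives
#' \deqn{\sigma_c = \frac{S \sqrt{K^2 - 1}}{4 K \sqrt{\ln K}}, \qquad
#'       \sigma_s = K \sigma_c,}
#' so the detector is maximally driven by a disk of diameter `S` and is
#' silenced by a uniform field.
#'
#' @param S optimal stimulus size (disk diameter), degrees.
#' @param K surround/centre sigma ratio (> 1).
#' @return list with `S`, `K`, `sigma_c`, `sigma_s` (degrees).
#' @export
make_dog <- function(S, K) {
  stopifnot(all(S > 0), K > 1)
  sigma_c <- S * sqrt(K^2 - 1) / (4 * K * sqrt(log(K)))
  list(S = S, K = K, sigma_c = sigma_c, sigma_s = K * sigma_c)
}

## visual degrees -> plane pixel coordinates (row, col); y positive up
deg_to_px <- function(x, y, npx, ppd) {
  list(row = (npx + 1) / 2 - y * ppd, col = x * ppd + (npx + 1) / 2)
}

## sample a scale space at per-point sigmas with linear level interpolation
ss_sample <- function(ss, sigma, row, col) {
  br <- ss_bracket(ss, sigma)
  v0 <- numeric(length(sigma)); v1 <- numeric(length(sigma))
  for (k in unique(br$k0)) {
    idx <- br$k0 == k
    v0[idx] <- bilinear_sample(ss_level(ss, k), row[idx], col[idx])
    v1[idx] <- bilinear_sample(ss_level(ss, k + 1L), row[idx], col[idx])
  }
  (1 - br$w) * v0 + br$w * v1
}

#' Eccentricity-dependent DoG responses of the grid units to an image plane
#'
#' Realizes every grid unit's DoG detector by sampling a Gaussian scale
#' space of the visual-space plane at the unit's RF centre: the response is
#' the sample at the centre sigma minus the sample at the surround sigma
#' (unit-mass blurs, so a uniform plane gives zero everywhere).  Each
#' unit's optimal stimulus size follows [eccentricity_size_law()].
#'
#' @param plane visual-space image plane (square matrix covering
#'   `field_deg` degrees, centred on gaze).
#' @param grid an [build_sc_grid()] object.
#' @param K DoG sigma ratio.
#' @param ppd plane resolution, pixels per degree.
#' @param units optional integer vector restricting the computation to a
#'   subset of grid units (returns a vector in that case).
#' @param rectify `"none"` (signed), `"abs"` (double opponency) or
#'   `"halfwave"`.
#' @return `grid_n` x `grid_n` matrix of responses, or a vector when
#'   `units` is given.
#' @export
dog_response <- function(plane, grid, K, ppd, units = NULL,
                         rectify = c("none", "abs", "halfwave")) {
  rectify <- match.arg(rectify)
  full <- is.null(units)
  if (full) units <- seq_along(grid$x)
  S <- grid$S[units]
  d <- make_dog(S, K)
  p <- deg_to_px(grid$x[units], grid$y[units], nrow(plane), ppd)
  ss <- scale_space(plane, sigma0 = 0.4)
  vc <- ss_sample(ss, d$sigma_c * ppd, p$row, p$col)
  vs <- ss_sample(ss, d$sigma_s * ppd, p$row, p$col)
  r <- vc - vs
  r <- switch(rectify, none = r, abs = abs(r), halfwave = pmax(r, 0))
  if (full) matrix(r, grid$n, grid$n) else r
}

#' Luminance and colour double-opponency maps
#'
#' Applies the eccentricity-dependent DoG (ratio `K_chrom`) to the
#' luminance, red-green and blue-yellow planes of a retinal frame and takes
#' the absolute value, yielding double-opponent responses (red-in-green and
#' green-in-red drive the same unit equally).
#'
#' @param retinal a `retinal_frame` (see [retinal_frame()]).
#' @param grid model grid.
#' @param cfg an [sc_config()].
#' @return array `grid_n` x `grid_n` x 3 (`lum`, `rg`, `by`).
#' @export
chromatic_luminance_maps <- function(retinal, grid, cfg = sc_config()) {
  out <- array(0, c(grid$n, grid$n, 3),
               dimnames = list(NULL, NULL, c("lum", "rg", "by")))
  for (pl in c("lum", "rg", "by"))
    out[, , pl] <- dog_response(retinal[[pl]], grid, cfg$K_chrom,
                                retinal$ppd, rectify = "abs")
  out
}

## ------------------------------------------------------------------
## Steerable second-derivative-of-Gaussian quadrature pair
## ------------------------------------------------------------------

g2h2_kernels <- function(theta_deg, sigma) {
  r <- max(2L, as.integer(ceiling(3.2 * sigma)))
  xs <- seq(-r, r)
  x <- matrix(xs, 2 * r + 1, 2 * r + 1, byrow = TRUE)   # col -> +x
  y <- -matrix(xs, 2 * r + 1, 2 * r + 1)                # row 1 -> +y
  th <- theta_deg * pi / 180
  u <- (x * cos(th) + y * sin(th)) / (sigma * sqrt(2))
  v <- (-x * sin(th) + y * cos(th)) / (sigma * sqrt(2))
  env <- exp(-(u^2 + v^2))
  g2 <- (2 * u^2 - 1) * env
  g2 <- g2 - mean(g2)                        # exact zero DC on the lattice
  h2 <- (u^3 - 2.254 * u) * env
  list(g2 = g2 / sqrt(sum(g2^2)), h2 = h2 / sqrt(sum(h2^2)))
}

## integer-pixel spatial shift with replicate borders
shift_plane <- function(img, dx, dy) {
  n1 <- nrow(img); n2 <- ncol(img)
  ri <- pmin(pmax(seq_len(n1) + round(dy), 1L), n1)  # +dy shifts content up
  ci <- pmin(pmax(seq_len(n2) - round(dx), 1L), n2)
  img[ri, ci, drop = FALSE]
}

## temporal envelopes over the 9-frame buffer (index 1 = oldest)
.t_support <- function() seq(-4, 4)
.t_env <- function() { w <- exp(-.t_support()^2 / (2 * 2^2)); w / sum(w) }
.flicker_pair <- function() {
  t <- .t_support(); w <- exp(-t^2 / (2 * 1.5^2))
  fe <- w * cos(pi / 2 * t); fe <- fe - w * sum(fe) / sum(w)
  fo <- w * sin(pi / 2 * t)
  list(even = fe / sqrt(sum(fe^2)), odd = fo / sqrt(sum(fo^2)))
}

st_labels <- function(cfg) {
  ori <- as.vector(outer(c(0, 45, 90, 135), seq_along(cfg$ori_sigma),
                         function(o, s) sprintf("ori%d_s%d", o, s)))
  mot <- character(0)
  for (s in seq_along(cfg$ori_sigma))
    for (v in cfg$speeds)
      for (o in c(0, 45, 90, 135))
        mot <- c(mot, sprintf("mot%d_v%g_s%d", o, v, s))
  list(ori = ori, mot = mot)
}

#' Spatiotemporal energy maps: oriented edges, flicker and raw motion
#'
#' A nine-frame luminance buffer is processed by quadrature pairs of
#' oriented second-derivative-of-Gaussian filters.  Static edge energy is
#' the quadrature magnitude of the temporally low-passed buffer at 4
#' orientations and 2 spatial scales; flicker is the quadrature magnitude
#' of a zero-mean temporal band-pass pair; motion energy is computed by
#' shifting the buffer frames along the filter's drift direction before
#' temporal integration, so that stimuli translating at the matched
#' velocity remain aligned (opposite directions are kept separately for
#' later opponency).  All responses are phase invariant, responding to both
#' step edges and bars.  Each energy plane is then passed through the
#' eccentricity-dependent DoG (`K_st`), half-wave rectified for edge and
#' flicker maps and kept signed for the motion maps (the opponent stage
#' rectifies).
#'
#' @param buffer list of 9 luminance planes (oldest first), matched sizes.
#' @param grid model grid.
#' @param cfg an [sc_config()].
#' @param ppd plane resolution, pixels per degree.
#' @return list with `ori` (`n` x `n` x 8, rectified), `flicker`
#'   (`n` x `n`), `motion_fwd` and `motion_bwd` (`n` x `n` x 24, signed DoG
#'   responses) and the map labels.
#' @export
spatiotemporal_energy <- function(buffer, grid, cfg = sc_config(), ppd) {
  stopifnot(length(buffer) == 9)
  n <- grid$n
  labs <- st_labels(cfg)
  w <- .t_env()
  orients <- c(0, 45, 90, 135)

  ## static: temporal low-pass then oriented quadrature energy
  lp <- Reduce(`+`, Map(`*`, buffer, as.list(w)))
  ori <- array(0, c(n, n, length(labs$ori)), dimnames = list(NULL, NULL, labs$ori))
  i <- 0
  for (s in cfg$ori_sigma) for (o in orients) {
    i <- i + 1
    kk <- g2h2_kernels(o, s)
    e <- sqrt(conv2_replicate(lp, kk$g2)^2 + conv2_replicate(lp, kk$h2)^2)
    ori[, , i] <- dog_response(e, grid, cfg$K_st, ppd, rectify = "halfwave")
  }

  ## flicker: temporal band-pass quadrature energy
  fp <- .flicker_pair()
  fe <- Reduce(`+`, Map(`*`, buffer, as.list(fp$even)))
  fo <- Reduce(`+`, Map(`*`, buffer, as.list(fp$odd)))
  flick <- dog_response(sqrt(fe^2 + fo^2), grid, cfg$K_st, ppd,
                        rectify = "halfwave")

  ## motion: align-and-integrate directed energy
  tt <- .t_support()
  nm <- length(labs$mot)
  fwd <- array(0, c(n, n, nm), dimnames = list(NULL, NULL, labs$mot))
  bwd <- fwd
  i <- 0
  for (s in cfg$ori_sigma) for (v in cfg$speeds) for (o in orients) {
    i <- i + 1
    kk <- g2h2_kernels(o, s)
    dx <- cos(o * pi / 180) * v; dy <- sin(o * pi / 180) * v
    cf <- matrix(0, nrow(buffer[[1]]), ncol(buffer[[1]])); cb <- cf
    for (j in seq_along(tt)) {
      cf <- cf + w[j] * shift_plane(buffer[[j]], -dx * tt[j], -dy * tt[j])
      cb <- cb + w[j] * shift_plane(buffer[[j]], dx * tt[j], dy * tt[j])
    }
    ef <- sqrt(conv2_replicate(cf, kk$g2)^2 + conv2_replicate(cf, kk$h2)^2)
    eb <- sqrt(conv2_replicate(cb, kk$g2)^2 + conv2_replicate(cb, kk$h2)^2)
    fwd[, , i] <- dog_response(ef, grid, cfg$K_st, ppd, rectify = "none")
    bwd[, , i] <- dog_response(eb, grid, cfg$K_st, ppd, rectify = "none")
  }
  list(ori = ori, flicker = flick, motion_fwd = fwd, motion_bwd = bwd,
       labels = labs)
}

#' Opponent-motion maps from raw directed motion responses
#'
#' For each of the 24 raw motion configurations (3 speeds x 4 orientations
#' x 2 scales) the two signed differences between the forward- and
#' backward-preferring DoG responses are formed and half-wave rectified,
#' giving 48 opponent motion maps.  Identical opposed-direction responses
#' cancel exactly.
#'
#' @param st result of [spatiotemporal_energy()].
#' @return array `n` x `n` x 48, non-negative.
#' @export
opponent_motion <- function(st) {
  nm <- dim(st$motion_fwd)[3]
  n <- dim(st$motion_fwd)[1]
  out <- array(0, c(n, n, 2 * nm))
  nms <- character(2 * nm)
  for (i in seq_len(nm)) {
    d <- st$motion_fwd[, , i] - st$motion_bwd[, , i]
    out[, , 2 * i - 1] <- pmax(d, 0)
    out[, , 2 * i] <- pmax(-d, 0)
    nms[2 * i - 1] <- paste0(st$labels$mot[i], "_fwd")
    nms[2 * i] <- paste0(st$labels$mot[i], "_bwd")
  }
  dimnames(out) <- list(NULL, NULL, nms)
  out
}

#' Long-range salience competition operator
#'
#' One iteration of the non-linear within-map competition: the map is
#' filtered with a large DoG (3 deg excitatory, 9 deg inhibitory, converted
#' to grid pixels at the nominal grid scale), the result is added back to
#' the map, a global-inhibition constant is subtracted, and the map is
#' half-wave rectified.  A lone peak survives in place; many equal peaks
#' suppress one another.
#'
#' @param map non-negative map on the model grid.
#' @param cfg an [sc_config()].
#' @return processed map, non-negative.
#' @export
competition_operator <- function(map, cfg = sc_config()) {
  stopifnot(all(map >= 0))
  px_per_deg_grid <- cfg$grid_n / cfg$field_deg
  f <- gauss_blur(map, cfg$comp_exc_deg * px_per_deg_grid) -
    gauss_blur(map, cfg$comp_inh_deg * px_per_deg_grid)
  m <- map + f
  gi <- cfg$gi_frac * max(m)
  pmax(m - gi, 0)
}

#' Activation-field pooling
#'
#' Replaces each grid point by the sum over a circular neighbourhood
#' (default radius 3 grid pixels), simulating the SC's large but
#' size-selective activation fields.  Because the pooling footprint is
#' fixed on the space-variant grid, the corresponding visual-space
#' activation fields widen with eccentricity and narrow toward the fovea.
#'
#' @param map map on the model grid.
#' @param radius neighbourhood radius in grid pixels.
#' @return pooled map.
#' @export
pool_activation_field <- function(map, radius = 3) {
  out <- matrix(0, nrow(map), ncol(map))
  for (dx in seq(-radius, radius)) for (dy in seq(-radius, radius))
    if (dx^2 + dy^2 <= radius^2)
      out <- out + shift_plane(map, dx, dy)
  out
}

#' Compute the full 60-map low-level feature stack for one model frame
#'
#' Runs the chromatic/luminance double-opponency maps on the newest frame
#' and the spatiotemporal maps on the 9-frame luminance buffer, then passes
#' every map through the competition operator and activation-field pooling.
#'
#' @param buffer list of 9 `retinal_frame` objects (oldest first).
#' @param grid model grid.
#' @param cfg an [sc_config()].
#' @return object of class `feature_stack`: array `low`
#'   (`n` x `n` x 60, named), plus the configuration used.
#' @export
feature_stack <- function(buffer, grid, cfg = sc_config()) {
  stopifnot(length(buffer) == 9)
  ppd <- buffer[[9]]$ppd
  chrom <- chromatic_luminance_maps(buffer[[9]], grid, cfg)
  st <- spatiotemporal_energy(lapply(buffer, `[[`, "lum"), grid, cfg, ppd)
  opp <- opponent_motion(st)
  n <- grid$n
  nmaps <- 3 + dim(st$ori)[3] + 1 + dim(opp)[3]
  low <- array(0, c(n, n, nmaps))
  nms <- c(dimnames(chrom)[[3]], dimnames(st$ori)[[3]], "flicker",
           dimnames(opp)[[3]])
  low[, , 1:3] <- chrom
  low[, , 3 + seq_len(dim(st$ori)[3])] <- st$ori
  low[, , 4 + dim(st$ori)[3]] <- st$flicker
  low[, , (4 + dim(st$ori)[3]) + seq_len(dim(opp)[3])] <- opp
  dimnames(low) <- list(NULL, NULL, nms)
  for (i in seq_len(nmaps))
    low[, , i] <- pool_activation_field(
      competition_operator(low[, , i], cfg), cfg$pool_radius)
  structure(list(low = low, cfg = cfg, n = n), class = "feature_stack")
}

#' Grouping of the low-level maps into the six high-level features
#'
#' @param stack a `feature_stack` or a character vector of map names.
#' @return factor of length 60 with levels `lum`, `rg`, `by`, `ori`,
#'   `flicker`, `motion`.
#' @export
feature_groups <- function(stack) {
  nms <- if (is.character(stack)) stack else dimnames(stack$low)[[3]]
  g <- ifelse(nms == "lum", "lum",
       ifelse(nms == "rg", "rg",
       ifelse(nms == "by", "by",
       ifelse(nms == "flicker", "flicker",
       ifelse(startsWith(nms, "ori"), "ori", "motion")))))
  factor(g, levels = c("lum", "rg", "by", "ori", "flicker", "motion"))
}
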