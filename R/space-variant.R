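#' Constants of the collicular log-polar mapping
#'
#' The afferent mapping from visual space onto the superior colliculus (SC)
#' is well described by a complex-logarithmic transform: logarithmic in
#' eccentricity and polar in angle, with a foveal shift constant `A` that
#' keeps the fovea regular.  `A` is in degrees of visual angle, `B_u` in mm
#' of collicular surface per log-unit of (shifted) eccentricity, and `B_v`
#' in mm per radian of polar angle.
#'
#' @param A foveal shift constant, degrees (default 3).
#' @param B_u rostral-caudal scale, mm (default 1.4).
#' @param B_v medial-lateral scale, mm per radian (default 1.8).
#' @return an object of class `ottes_params`.
#' @export
ottes_params <- function(A = 3, B_u = 1.4, B_v = 1.8) {
  stopifnot(A > 0, B_u > 0, B_v > 0)
  structure(list(A = A, B_u = B_u, B_v = B_v), class = "ottes_params")
}

#' Map visual coordinates onto the SC surface
#'
#' Forward complex-log mapping for one hemifield.  Input is eccentricity
#' `R` (degrees) and polar angle `phi` (degrees from the horizontal
#' meridian, positive upward); `phi` must lie in \[-90, 90\] (the mapping is
#' defined per hemifield; mirror the angle for the opposite hemifield).
#'
#' The fovea (`R = 0`) maps to the sheet origin `(0, 0)` and the horizontal
#' meridian (`phi = 0`) maps to the line `v = 0`.
#'
#' @param R eccentricity in degrees (vector).
#' @param phi polar angle in degrees (vector).
#' @param params an [ottes_params()] object.
#' @return list with components `u`, `v` in mm.
#' @seealso [ottes_inverse()] for the exact analytic inverse.
#' @export
ottes_forward <- function(R, phi, params = ottes_params()) {
  stopifnot(all(R >= 0), all(abs(phi) <= 90 + 1e-9))
  phir <- phi * pi / 180
  zx <- R * cos(phir) + params$A
  zy <- R * sin(phir)
  list(u = params$B_u * log(sqrt(zx^2 + zy^2) / params$A),
       v = params$B_v * atan2(zy, zx))
}

#' Map SC surface coordinates back to visual space
#'
#' Analytic inverse of [ottes_forward()]:
#' \deqn{R = A \sqrt{e^{2u/B_u} - 2 e^{u/B_u}\cos(v/B_v) + 1}}
#' \deqn{\Phi = \mathrm{atan2}\left(e^{u/B_u}\sin(v/B_v),\;
#'   e^{u/B_u}\cos(v/B_v) - 1\right)}
#'
#' @param u,v SC coordinates in mm (vectors).
#' @inheritParams ottes_forward
#' @return list with components `R` (degrees) and `phi` (degrees).
#' @export
ottes_inverse <- function(u, v, params = ottes_params()) {
  eu <- exp(u / params$B_u)
  cv <- cos(v / params$B_v)
  sv <- sin(v / params$B_v)
  R <- params$A * sqrt(pmax(eu^2 - 2 * eu * cv + 1, 0))
  phi <- atan2(eu * sv, eu * cv - 1) * 180 / pi
  phi[R < .Machine$double.eps^0.5] <- 0
  list(R = R, phi = phi)
}

## ------------------------------------------------------------------
## Variable-resolution resampling transform
##
## The model grid is a square image, so instead of the (discontinuous)
## conformal SC mapping we resample the retinal image with a radially
## log-scaled transform per hemifield:
##    R   = a * (exp(rho / b) - 1),     rho in [0, 1]  (radial grid coord)
##    Phi = c * eta,                    eta in [-1, 1] (angular grid coord)
## Its three scale constants (a, b, c) are fitted so that the visual-space
## image of the model grid matches the image of a square SC sheet under the
## inverse conformal mapping.
## ------------------------------------------------------------------

vr_inverse <- function(rho, eta, par) {
  R <- par[1] * (exp(rho / par[2]) - 1)
  phi <- par[3] * eta
  list(R = R, phi = phi)
}

#' Fit the scale constants of the variable-resolution transform
#'
#' Simulates a square sheet of SC surface (default 4.5 mm rostral-caudal by
#' 3.5 mm medial-lateral per hemifield), projects it to visual space with
#' the inverse conformal mapping, projects the corresponding model-grid
#' lattice through the inverse variable-resolution transform, and finds the
#' scale constants minimizing the summed squared visual-space distance
#' between the two point sets.  Minimization is a Nelder-Mead simplex with
#' random restarts; initial points are drawn log-uniformly over a factor of
#' 10 either side of unit scaling.
#'
#' @param params conformal mapping constants ([ottes_params()]).
#' @param sheet_mm extent of the simulated sheet per hemifield, mm
#'   (rostral-caudal, medial-lateral).
#' @param n_restarts number of random simplex restarts.
#' @param seed integer seed making the restart stream reproducible.
#' @param lattice_n lattice resolution (points per axis) used for the fit.
#' @return list with elements `par` (named vector `a`, `b`, `c`),
#'   `objective` (summed squared distance, deg^2), `degenerate` (TRUE when
#'   no restart improved on its initialization) and `sheet_mm`.
#' @export
fit_resampling_params <- function(params = ottes_params(),
                                  sheet_mm = c(4.5, 3.5),
                                  n_restarts = 1000,
                                  seed = 1,
                                  lattice_n = 15) {
  stopifnot(n_restarts >= 1, lattice_n >= 4)
  u <- seq(0, sheet_mm[1], length.out = lattice_n)
  v <- seq(-sheet_mm[2] / 2, sheet_mm[2] / 2, length.out = lattice_n)
  uu <- rep(u, times = lattice_n)
  vv <- rep(v, each = lattice_n)
  tgt <- ottes_inverse(uu, vv, params)
  tx <- tgt$R * cos(tgt$phi * pi / 180)
  ty <- tgt$R * sin(tgt$phi * pi / 180)
  rho <- uu / sheet_mm[1]
  eta <- vv / (sheet_mm[2] / 2)

  objective <- function(logpar) {
    p <- exp(logpar)
    m <- vr_inverse(rho, eta, p)
    mx <- m$R * cos(m$phi * pi / 180)
    my <- m$R * sin(m$phi * pi / 180)
    sum((mx - tx)^2 + (my - ty)^2)
  }

  unit <- c(a = 1, b = 1, c = 45)   # unit scaling of the three constants
  best <- NULL
  init_obj <- Inf
  set.seed(seed)
  for (k in seq_len(n_restarts)) {
    p0 <- log(unit) + runif(3, -log(10), log(10))
    init_obj <- min(init_obj, objective(p0))
    fit <- stats::optim(p0, objective, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(par = stats::setNames(exp(best$par), c("a", "b", "c")),
       objective = best$value,
       degenerate = best$value >= init_obj,
       sheet_mm = sheet_mm)
}

.sc_cache <- new.env(parent = emptyenv())

default_vr_fit <- function() {
  if (is.null(.sc_cache$fit)) {
    .sc_cache$fit <- fit_resampling_params(n_restarts = 50, seed = 20170124)
  }
  .sc_cache$fit
}

#' Build the 200 x 200 space-variant model grid
#'
#' Constructs the model SC surface: a square grid whose left and right
#' halves are the two hemifield sheets joined at the vertical meridian
#' (split at the centre column).  Each grid unit carries the visual-space
#' position of its receptive-field centre, obtained through the inverse of
#' the fitted variable-resolution transform, and its optimal stimulus size
#' from the linear eccentricity-size law.
#'
#' @param fit a fit from [fit_resampling_params()]; when `NULL` a cached
#'   default fit is used.
#' @param n grid side length in units (default 200).
#' @param pool_radius activation-field pooling radius in grid pixels.
#' @return an object of class `sc_grid` with matrices `x`, `y` (deg,
#'   screen-centred retinal coordinates), `R` (eccentricity), `phi` (global
#'   polar angle), `S` (optimal stimulus size, deg) and metadata.
#' @export
build_sc_grid <- function(fit = NULL, n = 200, pool_radius = 3) {
  if (is.null(fit)) fit <- default_vr_fit()
  par <- fit$par
  half <- n / 2
  col <- seq_len(n)
  row <- seq_len(n)
  ## radial coordinate per hemifield, half-pixel offset from the fovea
  rho_right <- (col[col > half] - half - 0.5) / half
  rho_left <- rev(rho_right)
  rho <- c(rho_left, rho_right)
  eta <- (row - (n + 1) / 2) / ((n - 1) / 2)
  rho_m <- matrix(rho, n, n, byrow = TRUE)
  eta_m <- matrix(eta, n, n)
  hemi <- matrix(rep(c(-1, 1), each = half), n, n, byrow = TRUE)

  m <- vr_inverse(rho_m, eta_m, par)
  R <- m$R
  phi_local <- m$phi
  x <- hemi * R * cos(phi_local * pi / 180)
  y <- R * sin(phi_local * pi / 180)
  phi <- atan2(y, x) * 180 / pi

  structure(list(n = n, x = x, y = y, R = R, phi = phi,
                 S = eccentricity_size_law(R),
                 hemi = hemi, par = par, pool_radius = pool_radius,
                 fit = fit),
            class = "sc_grid")
}

#' @export
print.sc_grid <- function(x, ...) {
  cat(sprintf("<sc_grid> %d x %d units, eccentricity %.2f-%.1f deg, pool radius %d px\n",
              x$n, x$n, min(x$R), max(x$R), x$pool_radius))
  cat(sprintf("  variable-resolution constants: a=%.4g b=%.4g c=%.4g\n",
              x$par[1], x$par[2], x$par[3]))
  invisible(x)
}

#' Index of the grid unit nearest a visual position
#'
#' @param grid an `sc_grid`.
#' @param x,y visual position, degrees.
#' @return single integer index into the grid matrices.
#' @export
grid_unit_at <- function(grid, x, y) {
  which.min((grid$x - x)^2 + (grid$y - y)^2)
}

#' Receptive-field boundary from a collicular point image
#'
#' The RF boundary of a neuron is modelled as the visual-space image of a
#' circular point image (default diameter 1.5 mm) centred on the SC
#' location of the neuron's RF centre.  The circle is traced in SC
#' coordinates and mapped back point by point through the inverse conformal
#' mapping.  Boundaries crossing the vertical meridian (u < 0) are clipped
#' to the hemifield with a warning.
#'
#' @param centre_R,centre_phi RF centre eccentricity (deg, must be >= 2) and
#'   global polar angle (deg; `|phi| > 90` denotes the left hemifield).
#' @param point_image_diam point image diameter in mm.
#' @param params mapping constants.
#' @param n_vertices number of polygon vertices.
#' @return a two-column matrix (x, y in degrees) tracing a closed simple
#'   polygon (first vertex not repeated).
#' @export
rf_boundary <- function(centre_R, centre_phi, point_image_diam = 1.5,
                        params = ottes_params(), n_vertices = 72) {
  if (centre_R < 2)
    stop("RF centre eccentricity < 2 deg: neuron excluded from RF-based analyses")
  left <- abs(centre_phi) > 90
  phi_local <- if (left) sign(centre_phi) * (180 - abs(centre_phi)) else centre_phi
  q0 <- ottes_forward(centre_R, phi_local, params)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  u <- q0$u + point_image_diam / 2 * cos(th)
  v <- q0$v + point_image_diam / 2 * sin(th)
  if (any(u < 0)) {
    warning("point image crosses the vertical meridian; clipped to hemifield")
    u <- pmax(u, 0)
  }
  p <- ottes_inverse(u, v, params)
  sx <- p$R * cos(p$phi * pi / 180) * if (left) -1 else 1
  sy <- p$R * sin(p$phi * pi / 180)
  cbind(x = sx, y = sy)
}

#' Which grid units fall inside a polygon
#'
#' Even-odd (ray casting) point-in-polygon test applied to every unit's RF
#' centre.
#'
#' @param grid an `sc_grid`.
#' @param poly two-column (x, y) polygon matrix.
#' @return logical matrix with the grid's dimensions.
#' @export
units_in_polygon <- function(grid, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  np <- length(px)
  x <- as.vector(grid$x); y <- as.vector(grid$y)
  inside <- logical(length(x))
  j <- np
  for (i in seq_len(np)) {
    crosses <- (py[i] > y) != (py[j] > y)
    xint <- (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i]
    inside <- xor(inside, crosses & (x < xint))
    j <- i
  }
  matrix(inside, grid$n, grid$n)
}
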