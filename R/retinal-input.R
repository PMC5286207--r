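#' Screen geometry
#'
#' Describes the display in pixels and degrees of visual angle.  The
#' default is a 1920 x 1080 panel subtending 82 x 52 degrees at 70 cm.
#' Pixels per degree are derived separately per axis (wide flat panels are
#' not angle-linear, so the axes may disagree noticeably; a warning is
#' issued beyond 15%).
#'
#' @param width_px,height_px panel resolution in pixels.
#' @param width_deg,height_deg subtended visual angle, degrees.
#' @return object of class `screen_geometry` with `ppd_x`, `ppd_y` and the
#'   mean `px_per_deg`.
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            width_deg = 82, height_deg = 52) {
  ppd_x <- width_px / width_deg
  ppd_y <- height_px / height_deg
  if (abs(ppd_x - ppd_y) / mean(c(ppd_x, ppd_y)) > 0.15)
    warning("pixel densities of the two axes differ by more than 15%")
  structure(list(width_px = width_px, height_px = height_px,
                 width_deg = width_deg, height_deg = height_deg,
                 ppd_x = ppd_x, ppd_y = ppd_y,
                 px_per_deg = mean(c(ppd_x, ppd_y))),
            class = "screen_geometry")
}

#' Shift a frame to gaze-centred coordinates and embed it in a black field
#'
#' The output is a square image representing `field_deg` x `field_deg`
#' degrees centred on the gaze position: the pixel under gaze lands at the
#' field centre, everything beyond the screen is black (matching a dark
#' viewing environment).  One such image is produced per gaze sample, so
#' identical display frames with different gaze give different retinal
#' images.  Gaze positions off the screen are processed like any other
#' (the screen content simply shifts further into the surround).
#'
#' @param frame RGB array (`height_px` x `width_px` x 3, values in
#'   \[0, 1\]) or a single luminance matrix.
#' @param gaze numeric `c(x, y)` gaze position, degrees from screen centre
#'   (y positive up).
#' @param geom a [screen_geometry()].
#' @param field_deg extent of the simulated field, degrees.
#' @param out_ppd output resolution, pixels per degree (defaults to the
#'   screen's mean pixel density).
#' @return gaze-centred array (`P` x `P` x 3) or matrix, `P = field_deg *
#'   out_ppd` (rounded).
#' @export
gaze_shift_embed <- function(frame, gaze, geom, field_deg = 100,
                             out_ppd = NULL) {
  stopifnot(length(gaze) == 2, all(is.finite(gaze)))
  if (is.null(out_ppd)) out_ppd <- geom$px_per_deg
  P <- round(field_deg * out_ppd)
  xs <- (seq_len(P) - (P + 1) / 2) / out_ppd + gaze[1]
  ys <- ((P + 1) / 2 - seq_len(P)) / out_ppd + gaze[2]
  W <- if (length(dim(frame)) == 3) dim(frame)[2] else ncol(frame)
  H <- if (length(dim(frame)) == 3) dim(frame)[1] else nrow(frame)
  sc <- round(xs * geom$ppd_x + (W + 1) / 2)
  sr <- round((H + 1) / 2 - ys * geom$ppd_y)
  okc <- sc >= 1 & sc <= W
  okr <- sr >= 1 & sr <= H
  take <- function(plane) {
    out <- matrix(0, P, P)
    if (any(okr) && any(okc))
      out[okr, okc] <- plane[sr[okr], sc[okc], drop = FALSE]
    out
  }
  if (length(dim(frame)) == 3) {
    out <- array(0, c(P, P, 3))
    for (ch in 1:3) out[, , ch] <- take(frame[, , ch])
    out
  } else take(frame)
}

#' Binomial decimation
#'
#' Smooths with a separable 3-tap binomial filter (\[1, 2, 1\] / 4 per
#' axis) and subsamples by 2.  Apply repeatedly to reach the working
#' resolution.
#'
#' @param img matrix or `H x W x 3` array.
#' @param times number of passes.
#' @return decimated image.
#' @export
decimate_frame <- function(img, times = 1) {
  dec1 <- function(m) {
    k <- c(1, 2, 1) / 4
    m <- conv_sep_shift(m, k)
    m[seq(1, nrow(m), by = 2), seq(1, ncol(m), by = 2), drop = FALSE]
  }
  for (i in seq_len(times)) {
    if (length(dim(img)) == 3) {
      planes <- lapply(1:3, function(ch) dec1(img[, , ch]))
      img <- array(0, c(dim(planes[[1]]), 3))
      for (ch in 1:3) img[, , ch] <- planes[[ch]]
    } else img <- dec1(img)
  }
  img
}

## sRGB (linear) -> XYZ (D65), then Hunt-Pointer-Estevez XYZ -> LMS
.rgb2lms <- local({
  rgb2xyz <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                      0.2126729, 0.7151522, 0.0721750,
                      0.0193339, 0.1191920, 0.9503041),
                    3, 3, byrow = TRUE)
  xyz2lms <- matrix(c(0.38971, 0.68898, -0.07868,
                      -0.22981, 1.18340, 0.04641,
                      0, 0, 1), 3, 3, byrow = TRUE)
  m <- xyz2lms %*% rgb2xyz
  white <- as.vector(m %*% c(1, 1, 1))
  sweep(m, 1, white, "/")         # von-Kries normalized: RGB grey g -> (g,g,g)
})

#' Convert an RGB image to DKL opponent planes
#'
#' Linearizes the display gamma, converts through sRGB to cone (LMS)
#' responses normalized at the display white, and forms the three DKL
#' opponent planes: luminance `(L+M)/2`, red-green `L-M`, and blue-yellow
#' `S-(L+M)/2`.  Achromatic inputs map to `rg = by = 0` exactly; black
#' maps all planes to 0.  The conversion matrix can be replaced by a
#' monitor-specific calibration.
#'
#' @param img `H x W x 3` RGB array in \[0, 1\] (values outside the range
#'   are clipped and counted in attribute `n_clipped`).
#' @param gamma display gamma used for linearization.
#' @param rgb2lms optional 3 x 3 replacement matrix (linear RGB to
#'   white-normalized LMS).
#' @return list with matrices `lum`, `rg`, `by`.
#' @export
rgb_to_dkl <- function(img, gamma = 2.2, rgb2lms = NULL) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  n_clip <- sum(img < 0 | img > 1)
  img <- pmin(pmax(img, 0), 1)
  lin <- img^gamma
  m <- if (is.null(rgb2lms)) .rgb2lms else rgb2lms
  L <- m[1, 1] * lin[, , 1] + m[1, 2] * lin[, , 2] + m[1, 3] * lin[, , 3]
  M <- m[2, 1] * lin[, , 1] + m[2, 2] * lin[, , 2] + m[2, 3] * lin[, , 3]
  S <- m[3, 1] * lin[, , 1] + m[3, 2] * lin[, , 2] + m[3, 3] * lin[, , 3]
  out <- list(lum = (L + M) / 2, rg = L - M, by = S - (L + M) / 2)
  attr(out, "n_clipped") <- n_clip
  out
}

#' Build a retinal frame: gaze-centred, decimated, DKL-converted
#'
#' The full retinal stage of the model: embed the frame in the simulated
#' field centred on gaze, decimate to the working resolution, and convert
#' to DKL opponent planes.
#'
#' @param frame RGB array.
#' @param gaze `c(x, y)` in degrees.
#' @param geom a [screen_geometry()].
#' @param cfg an [sc_config()]; the embed is done at `px_per_deg *
#'   2^decimations` and decimated `decimations` times.
#' @param t time stamp, ms.
#' @return object of class `retinal_frame`: matrices `lum`, `rg`, `by`,
#'   plus `ppd` and `t`.
#' @export
retinal_frame <- function(frame, gaze, geom, cfg = sc_config(), t = NA_real_) {
  ppd0 <- cfg$px_per_deg * 2^cfg$decimations
  emb <- gaze_shift_embed(frame, gaze, geom, cfg$field_deg, out_ppd = ppd0)
  dec <- decimate_frame(emb, cfg$decimations)
  dkl <- rgb_to_dkl(dec)
  structure(list(lum = dkl$lum, rg = dkl$rg, by = dkl$by,
                 ppd = cfg$px_per_deg, t = t),
            class = "retinal_frame")
}
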