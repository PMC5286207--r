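## Low-level image filtering: separable Gaussian blurs (shift-sum for small
## kernels, FFT for large ones), 2-D convolution with replicate padding, a
## Gaussian scale space with half-octave spacing, and bilinear sampling.

gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

pad_replicate <- function(img, r) {
  n1 <- nrow(img); n2 <- ncol(img)
  ri <- c(rep(1L, r), seq_len(n1), rep(n1, r))
  ci <- c(rep(1L, r), seq_len(n2), rep(n2, r))
  img[ri, ci, drop = FALSE]
}

## separable convolution by shift-and-add on the replicate-padded image
conv_sep_shift <- function(img, k) {
  r <- (length(k) - 1L) / 2L
  p <- pad_replicate(img, r)
  n1 <- nrow(img); n2 <- ncol(img)
  out <- matrix(0, n1, n2 + 2L * r)
  for (i in seq_along(k))
    out <- out + k[i] * p[(i - 1L) + seq_len(n1), ]
  res <- matrix(0, n1, n2)
  for (i in seq_along(k))
    res <- res + k[i] * out[, (i - 1L) + seq_len(n2)]
  res
}

conv_sep_fft <- function(img, k) {
  r <- (length(k) - 1L) / 2L
  p <- pad_replicate(img, r)
  n1 <- stats::nextn(nrow(p)); n2 <- stats::nextn(ncol(p))
  big <- matrix(0, n1, n2)
  big[seq_len(nrow(p)), seq_len(ncol(p))] <- p
  kx <- numeric(n2); ky <- numeric(n1)
  ky[c(seq_len(r + 1L), n1 - r + seq_len(r))] <- k[c((r + 1L):(2L * r + 1L), seq_len(r))]
  kx[c(seq_len(r + 1L), n2 - r + seq_len(r))] <- k[c((r + 1L):(2L * r + 1L), seq_len(r))]
  f <- stats::fft(big) * outer(stats::fft(ky), stats::fft(kx))
  res <- Re(stats::fft(f, inverse = TRUE)) / (n1 * n2)
  res[r + seq_len(nrow(img)), r + seq_len(ncol(img))]
}

#' Gaussian blur of an image plane
#'
#' Unit-mass separable Gaussian with replicate edge padding (so a constant
#' plane is invariant).  Small kernels are applied by shift-and-add, large
#' ones through the FFT.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; `0` returns `img` unchanged.
#' @return blurred matrix of the same dimensions.
#' @export
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel(sigma)
  if (length(k) <= 51L) conv_sep_shift(img, k) else conv_sep_fft(img, k)
}

## 2-D convolution with an arbitrary (small) kernel, replicate padding
conv2_replicate <- function(img, kern) {
  r1 <- (nrow(kern) - 1L) / 2L
  r2 <- (ncol(kern) - 1L) / 2L
  r <- max(r1, r2)
  p <- pad_replicate(img, r)
  n1 <- nrow(img); n2 <- ncol(img)
  out <- matrix(0, n1, n2)
  for (i in seq_len(nrow(kern))) {
    di <- r + (i - r1 - 1L)
    block <- p[di + seq_len(n1), , drop = FALSE]
    for (j in seq_len(ncol(kern))) {
      kv <- kern[i, j]
      if (kv == 0) next
      dj <- r + (j - r2 - 1L)
      out <- out + kv * block[, dj + seq_len(n2), drop = FALSE]
    }
  }
  out
}

#' Gaussian scale space with half-octave level spacing
#'
#' Levels are blurred lazily on first access and cached.
#'
#' @param img image plane.
#' @param sigma0 sigma of level 1, pixels.
#' @return closure-backed object; use [ss_level()] to fetch level `k`
#'   (sigma `sigma0 * 2^((k-1)/2)`).
#' @export
scale_space <- function(img, sigma0 = 0.5) {
  env <- new.env(parent = emptyenv())
  env$img <- img
  env$sigma0 <- sigma0
  env$levels <- list()
  structure(env, class = "scale_space")
}

ss_sigma <- function(ss, k) ss$sigma0 * 2^((k - 1) / 2)

#' @rdname scale_space
#' @param ss a `scale_space` object.
#' @param k level index (integer >= 1).
#' @export
ss_level <- function(ss, k) {
  key <- as.character(k)
  if (is.null(ss$levels[[key]]))
    ss$levels[[key]] <- gauss_blur(ss$img, ss_sigma(ss, k))
  ss$levels[[key]]
}

## index of the level pair bracketing sigma, with interpolation weight
ss_bracket <- function(ss, sigma) {
  sigma <- pmax(sigma, ss$sigma0)
  kf <- 1 + 2 * log2(sigma / ss$sigma0)
  k0 <- pmin(floor(kf), 60)
  w <- (sigma - ss_sigma(ss, k0)) / (ss_sigma(ss, k0 + 1) - ss_sigma(ss, k0))
  list(k0 = as.integer(k0), w = pmin(pmax(w, 0), 1))
}

#' Bilinear sampling of a matrix at fractional positions
#'
#' Positions are in matrix coordinates (`row`, `col`, 1-based); samples
#' outside the matrix are clamped to the border.
#'
#' @param img numeric matrix.
#' @param row,col numeric vectors of positions.
#' @return numeric vector of samples.
#' @export
bilinear_sample <- function(img, row, col) {
  n1 <- nrow(img); n2 <- ncol(img)
  row <- pmin(pmax(row, 1), n1)
  col <- pmin(pmax(col, 1), n2)
  r0 <- pmin(floor(row), n1 - 1L); c0 <- pmin(floor(col), n2 - 1L)
  fr <- row - r0; fc <- col - c0
  i00 <- (c0 - 1) * n1 + r0
  v00 <- img[i00];        v10 <- img[i00 + 1]
  v01 <- img[i00 + n1];   v11 <- img[i00 + n1 + 1]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}
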