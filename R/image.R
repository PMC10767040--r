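#' Square image and image-stack containers
#'
#' `tw_image()` wraps a square numeric matrix with its pixel size (Angstrom
#' per pixel) and free-form metadata; `tw_stack()` holds a list of images
#' sharing one pixel size plus a per-image metadata tibble. The image
#' origin (Angstrom coordinate 0) sits at pixel index `n/2 + 1`, matching
#' the centering convention of the discrete Fourier transform.
#'
#' @param data Square numeric matrix.
#' @param apix Pixel size in Angstrom, > 0.
#' @param meta List (image) or tibble (stack) of metadata.
#' @return A `tw_image` / `tw_stack` object.
#' @export
tw_image <- function(data, apix, meta = list()) {
  data <- as.matrix(data)
  if (nrow(data) != ncol(data)) abort("image must be square.")
  stopifnot_scalar(apix, "apix")
  if (apix <= 0) abort("`apix` must be > 0.")
  structure(list(data = data, apix = apix, meta = meta), class = "tw_image")
}

#' @rdname tw_image
#' @param images List of square matrices or `tw_image`s.
#' @export
tw_stack <- function(images, apix, meta = NULL) {
  images <- purrr::map(images, function(im) {
    if (inherits(im, "tw_image")) im$data else as.matrix(im)
  })
  if (length(images) > 0) {
    ns <- unique(unlist(purrr::map(images, dim)))
    if (length(ns) != 1L) abort("all stack images must share one square size.")
  }
  if (is.null(meta)) meta <- tibble(segment = seq_along(images))
  structure(list(images = images, apix = apix, meta = as_tibble(meta)),
            class = "tw_stack")
}

#' @export
print.tw_image <- function(x, ...) {
  cat(sprintf("<tw_image> %d x %d px, %.3f A/px\n",
              nrow(x$data), ncol(x$data), x$apix))
  invisible(x)
}

#' @export
print.tw_stack <- function(x, ...) {
  n <- length(x$images)
  sz <- if (n > 0) nrow(x$images[[1]]) else 0
  cat(sprintf("<tw_stack> %d images, %d x %d px, %.3f A/px\n",
              n, sz, sz, x$apix))
  invisible(x)
}

#' @export
length.tw_stack <- function(x) length(x$images)

fft2 <- function(m) stats::fft(m)
ifft2 <- function(M) stats::fft(M, inverse = TRUE) / length(M)

## centered frequency index -> cyclic matrix quadrant swap
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  m[c((s1 + 1):n1, 1:s1), c((s2 + 1):n2, 1:s2)]
}

## spatial frequencies (1/A) of an n-point axis, unshifted DFT order
fft_freqs <- function(n, apix) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n) / (n * apix)
}

#' Hard low-pass filter an image
#'
#' Zeroes all spatial frequencies with radial magnitude above
#' `1/resolution` and returns the real part of the inverse transform.
#'
#' @param image A [tw_image()].
#' @param resolution Cutoff resolution in Angstrom; must be at least twice
#'   the pixel size (Nyquist).
#' @return Band-limited [tw_image()].
#' @export
band_limit <- function(image, resolution) {
  stopifnot_scalar(resolution, "resolution")
  if (resolution < 2 * image$apix - 1e-9) {
    abort(sprintf("resolution %.3f A is below Nyquist (%.3f A).",
                  resolution, 2 * image$apix))
  }
  n <- nrow(image$data)
  f <- fft_freqs(n, image$apix)
  r2 <- outer(f^2, f^2, "+")
  keep <- r2 <= (1 / resolution)^2 + 1e-12
  out <- Re(ifft2(fft2(image$data) * keep))
  tw_image(out, image$apix, c(image$meta, list(resolution = resolution)))
}

## pixels considered "inside the tube": smoothed signal above 5% of max
tube_mask <- function(image, frac = 0.05) {
  a <- abs(image$data)
  a > frac * max(a)
}

#' Add white Gaussian noise at a target signal-to-noise ratio
#'
#' The noise variance is set so that
#' `var(signal within tube mask) / var(noise) = snr`, where the tube mask
#' contains the pixels whose absolute signal exceeds 5% of the maximum.
#' The seed fully determines the noise field.
#'
#' @param image A noiseless [tw_image()].
#' @param snr Target signal-to-noise ratio, > 0.
#' @param seed Integer seed for the noise field.
#' @return Noisy [tw_image()] with `noise_sd`, `snr` and `noise_seed`
#'   recorded in the metadata.
#' @export
add_noise <- function(image, snr, seed) {
  stopifnot_scalar(snr, "snr")
  if (snr <= 0) abort("`snr` must be > 0.")
  m <- tube_mask(image)
  sig_var <- stats::var(image$data[m])
  sd_n <- sqrt(sig_var / snr)
  n <- nrow(image$data)
  noise <- with_seed(as.integer(seed), matrix(stats::rnorm(n * n, 0, sd_n), n, n))
  tw_image(image$data + noise, image$apix,
           c(image$meta, list(snr = snr, noise_sd = sd_n,
                              noise_seed = as.integer(seed))))
}

#' Power spectrum of an image
#'
#' Squared modulus of the discrete Fourier transform, normalized by the
#' pixel count so that the spectrum sums to the image energy (Parseval),
#' with the zero frequency at the center.
#'
#' @param image A [tw_image()].
#' @return A [tw_image()] holding the centered power spectrum; pixel size
#'   metadata carries the original `apix` so frequency axes can be
#'   reconstructed as `i / (n * apix)`.
#' @export
power_spectrum <- function(image) {
  n <- nrow(image$data)
  ps <- fftshift2(Mod(fft2(image$data))^2) / (n * n)
  tw_image(ps, image$apix, list(kind = "power_spectrum"))
}

#' Average power spectrum of a stack
#'
#' @param stack A non-empty [tw_stack()].
#' @return A [tw_image()] with the arithmetic mean of the per-image
#'   centered power spectra.
#' @export
average_power_spectrum <- function(stack) {
  if (length(stack$images) == 0L) abort("empty stack.")
  acc <- NULL
  for (m in stack$images) {
    ps <- power_spectrum(tw_image(m, stack$apix))$data
    acc <- if (is.null(acc)) ps else acc + ps
  }
  tw_image(acc / length(stack$images), stack$apix,
           list(kind = "power_spectrum"))
}

#' Rotate an image in-plane
#'
#' Bilinear interpolation about the image origin (pixel `n/2 + 1`);
#' positive angles rotate counterclockwise. Samples falling outside the
#' source are zero.
#'
#' @param image A [tw_image()].
#' @param theta Angle in degrees.
#' @return Rotated [tw_image()].
#' @export
rotate_image <- function(image, theta) {
  if (abs(theta) < 1e-12) return(image)
  m <- image$data
  n <- nrow(m)
  cN <- n / 2 + 1
  idx <- seq_len(n) - cN
  X <- matrix(idx, n, n)           # row coordinate
  Y <- matrix(idx, n, n, byrow = TRUE)
  t <- deg2rad(-theta)             # inverse map
  Xs <- cos(t) * X - sin(t) * Y + cN
  Ys <- sin(t) * X + cos(t) * Y + cN
  out <- bilinear_sample(m, Xs, Ys)
  tw_image(out, image$apix, image$meta)
}

## vectorized bilinear lookup with zero padding outside
bilinear_sample <- function(m, Xs, Ys) {
  n1 <- nrow(m); n2 <- ncol(m)
  x0 <- floor(Xs); y0 <- floor(Ys)
  fx <- Xs - x0; fy <- Ys - y0
  val <- function(i, j) {
    ok <- i >= 1 & i <= n1 & j >= 1 & j <= n2
    ii <- pmin(pmax(i, 1L), n1); jj <- pmin(pmax(j, 1L), n2)
    v <- m[cbind(as.vector(ii), as.vector(jj))]
    v[!as.vector(ok)] <- 0
    matrix(v, nrow(i), ncol(i))
  }
  (1 - fx) * (1 - fy) * val(x0, y0) +
    fx * (1 - fy) * val(x0 + 1, y0) +
    (1 - fx) * fy * val(x0, y0 + 1) +
    fx * fy * val(x0 + 1, y0 + 1)
}
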