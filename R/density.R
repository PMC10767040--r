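#' Cubic density volume container
#'
#' @param data Cubic numeric 3D array.
#' @param apix Voxel size in Angstrom, > 0.
#' @param origin Angstrom coordinate of the first voxel corner (3-vector).
#' @return A `tw_volume` object.
#' @export
tw_volume <- function(data, apix, origin = c(0, 0, 0)) {
  d <- dim(data)
  if (length(d) != 3L || length(unique(d)) != 1L) {
    abort("volume must be a cubic 3D array.")
  }
  stopifnot_scalar(apix, "apix")
  if (apix <= 0) abort("`apix` must be > 0.")
  structure(list(data = data, apix = apix, origin = as.numeric(origin)),
            class = "tw_volume")
}

#' @export
print.tw_volume <- function(x, ...) {
  cat(sprintf("<tw_volume> %d^3 voxels, %.3f A/px\n", dim(x$data)[1], x$apix))
  invisible(x)
}

## gaussian splat of points (n x 3 or n x 2 matrix, A) with weights into a
## centered grid; origin at pixel n/2 + 1
splat_gaussian <- function(coords, weights, box, apix, sigma, ndim) {
  cN <- box / 2 + 1
  p <- ceiling(3 * sigma / apix)
  off <- -p:p
  n_out <- 0L
  if (ndim == 2L) {
    img <- matrix(0, box, box)
    for (k in seq_len(nrow(coords))) {
      ci <- coords[k, 1] / apix + cN
      cj <- coords[k, 2] / apix + cN
      i0 <- round(ci); j0 <- round(cj)
      ii <- i0 + off; jj <- j0 + off
      oki <- ii >= 1 & ii <= box; okj <- jj >= 1 & jj <= box
      if (!any(oki) || !any(okj)) { n_out <- n_out + 1L; next }
      di <- (ii[oki] - ci) * apix; dj <- (jj[okj] - cj) * apix
      g <- weights[k] * exp(-outer(di^2, dj^2, "+") / (2 * sigma^2))
      img[ii[oki], jj[okj]] <- img[ii[oki], jj[okj], drop = FALSE] + g
    }
    attr(img, "n_clipped") <- n_out
    img
  } else {
    vol <- array(0, c(box, box, box))
    for (k in seq_len(nrow(coords))) {
      cc <- coords[k, ] / apix + cN
      c0 <- round(cc)
      ii <- c0[1] + off; jj <- c0[2] + off; kk <- c0[3] + off
      oki <- ii >= 1 & ii <= box; okj <- jj >= 1 & jj <= box
      okk <- kk >= 1 & kk <= box
      if (!any(oki) || !any(okj) || !any(okk)) { n_out <- n_out + 1L; next }
      di <- (ii[oki] - cc[1]) * apix
      dj <- (jj[okj] - cc[2]) * apix
      dk <- (kk[okk] - cc[3]) * apix
      g1 <- exp(-di^2 / (2 * sigma^2))
      g2 <- exp(-dj^2 / (2 * sigma^2))
      g3 <- exp(-dk^2 / (2 * sigma^2))
      blk <- weights[k] * (g1 %o% g2 %o% g3)
      vol[ii[oki], jj[okj], kk[okk]] <-
        vol[ii[oki], jj[okj], kk[okk], drop = FALSE] + blk
    }
    attr(vol, "n_clipped") <- n_out
    vol
  }
}

model_coords_weights <- function(x) {
  if (inherits(x, "tube_model")) {
    a <- tube_atoms(x)
  } else if (inherits(x, "asym_unit")) {
    a <- x$atoms
  } else {
    abort("expected a tube_model or asym_unit.")
  }
  list(coords = as.matrix(a[, c("x", "y", "z")]),
       weights = element_weight(a$element))
}

#' Render a model as a 3D density volume
#'
#' Places one isotropic Gaussian blob per atom, with amplitude
#' proportional to atomic number (uniform for pseudo-atoms), on a centered
#' cubic grid. Total integrated density is proportional to the total
#' scattering mass. Atoms falling outside the box are clipped with a
#' warning.
#'
#' @param x A [build_tube()] model or [asym_unit()].
#' @param apix Voxel size in Angstrom.
#' @param box Box size in voxels, >= 8.
#' @param blob_sigma Gaussian sigma in Angstrom.
#' @return A [tw_volume()].
#' @export
render_volume <- function(x, apix, box, blob_sigma = 5) {
  stopifnot_scalar(apix, "apix"); stopifnot_scalar(box, "box")
  if (apix <= 0 || box < 8) abort("need apix > 0 and box >= 8.")
  cw <- model_coords_weights(x)
  vol <- splat_gaussian(cw$coords, cw$weights, box, apix, blob_sigma, 3L)
  if (attr(vol, "n_clipped") > 0) {
    warn(sprintf("%d atoms fell outside the box and were clipped.",
                 attr(vol, "n_clipped")))
  }
  attr(vol, "n_clipped") <- NULL
  tw_volume(vol, apix, origin = rep(-(box / 2) * apix, 3))
}

#' Project a model or volume to a 2D image
#'
#' The viewing direction is perpendicular to the tube axis: the model is
#' rotated by the azimuth `phi` about the helix axis and integrated along
#' the viewing axis; the image plane holds the equatorial coordinate
#' (image rows) and the axial coordinate (image columns). `psi` applies an
#' in-plane counterclockwise rotation and `shift` an in-plane translation
#' in Angstrom. For atomic models the projection is an analytic Gaussian
#' splat; for volumes it is a trilinear line integral (intended for small
#' toy boxes; the two code paths agree to interpolation accuracy).
#'
#' @param x A [build_tube()] model, [asym_unit()] or [tw_volume()].
#' @param phi Azimuth of the viewing direction, degrees.
#' @param psi In-plane rotation, degrees.
#' @param shift In-plane shift `(A, A)`.
#' @param apix,box Image sampling (Angstrom per pixel, pixels); for
#'   volumes these default to the volume's own grid.
#' @param blob_sigma Gaussian sigma in Angstrom (atomic path only).
#' @param ... Passed between methods.
#' @return A [tw_image()].
#' @export
project <- function(x, ...) UseMethod("project")

#' @rdname project
#' @export
project.tube_model <- function(x, phi = 0, psi = 0, shift = c(0, 0),
                               apix = 5, box = 128, blob_sigma = 5, ...) {
  cw <- model_coords_weights(x)
  project_atoms(cw$coords, cw$weights, phi, psi, shift, apix, box, blob_sigma)
}

#' @rdname project
#' @export
project.asym_unit <- function(x, phi = 0, psi = 0, shift = c(0, 0),
                              apix = 5, box = 128, blob_sigma = 5, ...) {
  cw <- model_coords_weights(x)
  project_atoms(cw$coords, cw$weights, phi, psi, shift, apix, box, blob_sigma)
}

project_atoms <- function(coords, weights, phi, psi, shift, apix, box,
                          blob_sigma) {
  q <- coords %*% t(rot_z(-phi))
  uv <- cbind(q[, 1], q[, 3]) %*% t(rot2(psi))
  uv <- sweep(uv, 2, -as.numeric(shift))
  img <- splat_gaussian(uv, weights * blob_sigma * sqrt(2 * pi), box, apix,
                        blob_sigma, 2L)
  attr(img, "n_clipped") <- NULL
  tw_image(img, apix, list(phi = phi, psi = psi, shift = as.numeric(shift)))
}

#' @rdname project
#' @export
project.tw_volume <- function(x, phi = 0, psi = 0, shift = c(0, 0),
                              apix = NULL, box = NULL, ...) {
  apix <- apix %||% x$apix
  box <- box %||% dim(x$data)[1]
  nv <- dim(x$data)[1]
  cV <- nv / 2 + 1
  cN <- box / 2 + 1
  idx <- (seq_len(box) - cN) * apix
  ## image-plane coordinates before psi/shift
  U <- matrix(idx, box, box)
  V <- matrix(idx, box, box, byrow = TRUE)
  R2i <- rot2(-psi)
  Xp <- R2i[1, 1] * (U - shift[1]) + R2i[1, 2] * (V - shift[2])
  Zp <- R2i[2, 1] * (U - shift[1]) + R2i[2, 2] * (V - shift[2])
  Rz <- rot_z(phi)
  acc <- matrix(0, box, box)
  ys <- (seq_len(nv) - cV) * x$apix
  for (y in ys) {
    px <- Rz[1, 1] * Xp + Rz[1, 2] * y
    py <- Rz[2, 1] * Xp + Rz[2, 2] * y
    pz <- Zp
    acc <- acc + trilinear_sample(x$data, px / x$apix + cV,
                                  py / x$apix + cV, pz / x$apix + cV)
  }
  tw_image(acc * x$apix, apix, list(phi = phi, psi = psi,
                                    shift = as.numeric(shift)))
}

trilinear_sample <- function(vol, Xs, Ys, Zs) {
  n <- dim(vol)[1]
  x0 <- floor(Xs); y0 <- floor(Ys); z0 <- floor(Zs)
  fx <- Xs - x0; fy <- Ys - y0; fz <- Zs - z0
  val <- function(i, j, k) {
    ok <- i >= 1 & i <= n & j >= 1 & j <= n & k >= 1 & k <= n
    ii <- pmin(pmax(i, 1L), n); jj <- pmin(pmax(j, 1L), n)
    kk <- pmin(pmax(k, 1L), n)
    v <- vol[cbind(as.vector(ii), as.vector(jj), as.vector(kk))]
    v[!as.vector(ok)] <- 0
    matrix(v, nrow(i), ncol(i))
  }
  (1 - fx) * (1 - fy) * (1 - fz) * val(x0, y0, z0) +
    fx * (1 - fy) * (1 - fz) * val(x0 + 1, y0, z0) +
    (1 - fx) * fy * (1 - fz) * val(x0, y0 + 1, z0) +
    (1 - fx) * (1 - fy) * fz * val(x0, y0, z0 + 1) +
    fx * fy * (1 - fz) * val(x0 + 1, y0 + 1, z0) +
    fx * (1 - fy) * fz * val(x0 + 1, y0, z0 + 1) +
    (1 - fx) * fy * fz * val(x0, y0 + 1, z0 + 1) +
    fx * fy * fz * val(x0 + 1, y0 + 1, z0 + 1)
}
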