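#' Lattice points of a wrapped tube within an axial window
#'
#' Rolls the 2D lattice onto the cylinder defined by wrapping (n1, n2) and
#' returns one entry per subunit with axial coordinate in
#' `[z_min, z_max)` (half-open, so stacked windows partition exactly).
#' Lattice points congruent modulo the wrapping vector describe the same
#' physical subunit and collapse to a single entry (seamlessness).
#'
#' @inheritParams wrapping_vector
#' @param z_min,z_max Axial window in Angstrom, `z_min < z_max`.
#' @param reference Wrapping index of the frame the asymmetric unit was
#'   built in (default `c(14, 14)`); the per-tube `spin` angle is measured
#'   relative to this frame.
#' @return Tibble with columns `u1`, `u2` (integer lattice coordinates of
#'   the canonical class representative), `azimuth` (degrees in [0, 360)),
#'   `z` (Angstrom) and `spin` (degrees; constant per tube: the angle
#'   between the reference equator and this tube's equator).
#' @export
lattice_points_in_window <- function(lattice, n1, n2, z_min, z_max,
                                     reference = c(14, 14)) {
  idx <- check_index(n1, n2)
  stopifnot_scalar(z_min, "z_min"); stopifnot_scalar(z_max, "z_max")
  if (!(z_min < z_max)) abort("need z_min < z_max.")
  hs <- helix_from_wrapping(lattice, idx[1], idx[2])
  href <- helix_from_wrapping(lattice, reference[1], reference[2])
  spin <- hs$pitch_angle - href$pitch_angle
  C <- hs$circumference
  ## (arc, z) = A %*% (u1, u2)
  A <- matrix(c(hs$x1, hs$y1, hs$x2, hs$y2), 2, 2)
  Ainv <- solve(A)
  corners <- cbind(c(0, z_min), c(C, z_min), c(0, z_max), c(C, z_max))
  uc <- Ainv %*% corners
  u1r <- floor(min(uc[1, ])):ceiling(max(uc[1, ]))
  u2r <- floor(min(uc[2, ])):ceiling(max(uc[2, ]))
  grid <- tidyr::expand_grid(u1 = u1r, u2 = u2r)
  arc <- grid$u1 * hs$x1 + grid$u2 * hs$x2
  z <- grid$u1 * hs$y1 + grid$u2 * hs$y2
  ## half-open window with a small tolerance so exact-boundary points are
  ## assigned to exactly one of two stacked windows
  tol <- 1e-7 * max(abs(z_min), abs(z_max), 1)
  keep <- z >= z_min - tol & z < z_max - tol
  grid <- grid[keep, ]; arc <- arc[keep]; z <- z[keep]
  ## canonical class representative: subtract whole wrapping vectors
  t_wrap <- floor((arc + 1e-9 * C) / C)
  grid$u1 <- grid$u1 - t_wrap * idx[1]
  grid$u2 <- grid$u2 - t_wrap * idx[2]
  out <- tibble(
    u1 = grid$u1, u2 = grid$u2,
    azimuth = wrap_pos(360 * (grid$u1 * hs$x1 + grid$u2 * hs$x2) / C, 360),
    z = grid$u1 * hs$y1 + grid$u2 * hs$y2,
    spin = spin
  )
  out |>
    dplyr::distinct(.data$u1, .data$u2, .keep_all = TRUE) |>
    dplyr::arrange(.data$z, .data$azimuth)
}

#' Build a 3D tube model by helical symmetry expansion
#'
#' Radially translates the asymmetric unit to the tube radius, then places
#' one copy per lattice point: each placement is rotated about the radial
#' axis by the tube's spin angle (accounting for the orientation of the 2D
#' lattice relative to this wrapping), rotated about the helix axis to its
#' azimuth, and translated to its axial position. Positive spin tilts the
#' lattice counterclockwise as seen from outside the tube.
#'
#' @param unit An [asym_unit()], supplied in the `reference` wrapping frame
#'   with `+x` outward, `+y` along the reference equator, `+z` along the
#'   helix axis.
#' @inheritParams lattice_points_in_window
#' @return An object of class `tube_model` with the radialized unit, a
#'   placements tibble (one row per subunit with center of mass and 3x3
#'   rotation), the [helix_from_wrapping()] symmetry, the lattice, and
#'   `flattening_scale = 1`.
#' @examples
#' u <- make_pseudo_unit(n_blobs = 6, seed = 1)
#' tube <- build_tube(u, vp39_lattice(), 14, 14, 0, 44)
#' nrow(tube$placements)  # 14 subunits in one ring
#' @export
build_tube <- function(unit, lattice, n1, n2, z_min, z_max,
                       reference = c(14, 14)) {
  pts <- lattice_points_in_window(lattice, n1, n2, z_min, z_max, reference)
  hs <- helix_from_wrapping(lattice, n1, n2)
  r <- hs$radius
  runit <- radialize(unit, r)
  if (nrow(pts) == 0L) {
    warn("axial window contains no lattice point; returning an empty tube.")
  }
  az_r <- deg2rad(pts$azimuth)
  spin0 <- if (nrow(pts) > 0L) pts$spin[1] else 0
  placements <- pts |>
    dplyr::mutate(
      com_x = r * cos(az_r),
      com_y = r * sin(az_r),
      com_z = .data$z,
      rot = purrr::map(.data$azimuth, ~ rot_z(.x) %*% rot_x(-spin0))
    )
  structure(list(
    unit = runit, unit_com = c(r, 0, 0),
    placements = placements,
    symmetry = hs, lattice = lattice,
    flattening_scale = 1, ellipse = NULL,
    reference = as.integer(reference)
  ), class = "tube_model")
}

#' @export
print.tube_model <- function(x, ...) {
  cat(sprintf("<tube_model> wrapping (%d, %d), %d subunits, %d atoms each\n",
              x$symmetry$n1, x$symmetry$n2, nrow(x$placements),
              nrow(x$unit$atoms)))
  cat(sprintf("  circumference %.1f A, C%d, flattening scale %.2f\n",
              x$symmetry$circumference, x$symmetry$order, x$flattening_scale))
  invisible(x)
}

## apply placement i of a tube to an n x 3 coordinate matrix
place_coords <- function(tube, coords, i) {
  R <- tube$placements$rot[[i]]
  com <- c(tube$placements$com_x[i], tube$placements$com_y[i],
           tube$placements$com_z[i])
  sweep(sweep(coords, 2, tube$unit_com) %*% t(R), 2, com, "+")
}

#' All atoms of a tube model
#'
#' Expands every placement to atom records. Subunits are labelled by their
#' lattice coordinates.
#'
#' @param tube A [build_tube()] model.
#' @return Tibble of atom records with `placement`, `u1`, `u2`, `chain`
#'   (derived from the lattice coordinates), coordinates and the unit's
#'   annotation columns.
#' @export
tube_atoms <- function(tube) {
  P <- as.matrix(tube$unit$atoms[, c("x", "y", "z")])
  rows <- purrr::map(seq_len(nrow(tube$placements)), function(i) {
    q <- place_coords(tube, P, i)
    a <- tube$unit$atoms
    a$x <- q[, 1]; a$y <- q[, 2]; a$z <- q[, 3]
    a$placement <- i
    a$u1 <- tube$placements$u1[i]
    a$u2 <- tube$placements$u2[i]
    a$chain <- sprintf("u%d.%d", a$u1[1], a$u2[1])
    a
  })
  dplyr::bind_rows(rows)
}

#' Subunit pairs in contact within a distance cutoff
#'
#' Finds all pairs of placements whose closest inter-atomic distance is at
#' most `cutoff`, together with the minimizing atom pair. Pairs are
#' reported once (`i < j`). A center-of-mass prefilter keeps the search
#' linear in practice.
#'
#' @param tube A [build_tube()] model.
#' @param cutoff Distance cutoff in Angstrom, > 0.
#' @param atoms Optional atom-name filter (e.g. `"CB"`) applied before the
#'   distance search, to express contact criteria such as a Cbeta-Cbeta
#'   cutoff between adjacent subunits.
#' @return Tibble with columns `i`, `j` (placement indices), `distance`
#'   (Angstrom), `atom_i`, `atom_j`, `resid_i`, `resid_j`.
#' @export
neighbor_pairs <- function(tube, cutoff, atoms = NULL) {
  stopifnot_scalar(cutoff, "cutoff")
  if (cutoff <= 0) abort("`cutoff` must be > 0.")
  ua <- tube$unit$atoms
  sel <- if (is.null(atoms)) seq_len(nrow(ua)) else which(ua$atom %in% atoms)
  if (length(sel) == 0L) abort("no atoms left after the `atoms` filter.")
  P <- as.matrix(ua[sel, c("x", "y", "z")])
  n <- nrow(tube$placements)
  coords <- purrr::map(seq_len(n), ~ place_coords(tube, P, .x))
  com <- cbind(tube$placements$com_x, tube$placements$com_y,
               tube$placements$com_z)
  rad <- sqrt(max(rowSums(sweep(P, 2, unit_center(tube$unit))^2)))
  out <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    dcom <- sqrt(rowSums(sweep(com[(i + 1):n, , drop = FALSE], 2, com[i, ])^2))
    for (j in ((i + 1):n)[dcom <= cutoff + 2 * rad]) {
      d2 <- outer(rowSums(coords[[i]]^2), rowSums(coords[[j]]^2), "+") -
        2 * coords[[i]] %*% t(coords[[j]])
      k <- arrayInd(which.min(d2), dim(d2))
      dmin <- sqrt(max(d2[k], 0))
      if (dmin <= cutoff) {
        out[[length(out) + 1L]] <- tibble(
          i = i, j = j, distance = dmin,
          atom_i = ua$atom[sel[k[1]]], atom_j = ua$atom[sel[k[2]]],
          resid_i = ua$resid[sel[k[1]]], resid_j = ua$resid[sel[k[2]]]
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(i = integer(), j = integer(), distance = double(),
                  atom_i = character(), atom_j = character(),
                  resid_i = integer(), resid_j = integer()))
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$distance)
}
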