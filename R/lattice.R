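#' 2D crystal lattice of a tubular assembly
#'
#' A helical tube can be described as a 2D crystal lattice rolled seamlessly
#' onto a cylinder. `lattice2d()` stores the two basis vectors of that
#' lattice. Components are given in the plane of the reference wrapping:
#' the first component is the equatorial (arc) direction, the second the
#' helix-axis direction, both in Angstrom.
#'
#' @param a,b Numeric length-2 basis vectors `(arc, axial)` in Angstrom.
#' @return An object of class `lattice2d` with elements `a`, `b` and the
#'   signed cell determinant `det` (cell area up to sign, in square
#'   Angstrom).
#' @examples
#' lat <- lattice2d(c(27.91, -43.86), c(72.31, 43.86))
#' lat$det
#' @export
lattice2d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 2L || length(b) != 2L || !all(is.finite(c(a, b)))) {
    abort("`a` and `b` must be finite numeric 2-vectors (arc, axial) in Angstrom.")
  }
  d <- a[1] * b[2] - a[2] * b[1]
  if (abs(d) <= 1e-9 * max(1, sum(abs(a)) * sum(abs(b)))) {
    abort("degenerate lattice: basis vectors `a` and `b` are collinear.")
  }
  structure(list(a = a, b = b, det = d), class = "lattice2d")
}

#' @export
print.lattice2d <- function(x, ...) {
  cat("<lattice2d>\n")
  cat(sprintf("  a = [%.2f, %.2f] A\n", x$a[1], x$a[2]))
  cat(sprintf("  b = [%.2f, %.2f] A\n", x$b[1], x$b[2]))
  cat(sprintf("  cell area = %.2f A^2\n", abs(x$det)))
  invisible(x)
}

#' Reference 2D lattice of the VP39 nucleocapsid
#'
#' Basis vectors of the 2D crystal lattice underlying the C14
#' baculovirus (AcMNPV) VP39 nucleocapsid tube, expressed in the frame of
#' the (14, 14) wrapping: a = (27.91, -43.86) A, b = (72.31, 43.86) A.
#'
#' @return A [lattice2d()] object.
#' @export
vp39_lattice <- function() {
  lattice2d(c(27.91, -43.86), c(72.31, 43.86))
}

check_index <- function(n1, n2) {
  if (length(n1) != 1L || length(n2) != 1L ||
      !is.finite(n1) || !is.finite(n2) ||
      n1 != round(n1) || n2 != round(n2)) {
    abort("wrapping index (n1, n2) must be two integers.")
  }
  if (n1 == 0 && n2 == 0) abort("wrapping index (0, 0) is not a tube.")
  c(as.integer(n1), as.integer(n2))
}

#' Wrapping vector of a tube polymorph
#'
#' The wrapping vector `w = n1 a + n2 b` is the lattice vector that is
#' rolled onto the tube equator; its length is the tube circumference.
#' Each integer pair (n1, n2) defines a distinct helical polymorph built
#' from the same local lattice.
#'
#' @param lattice A [lattice2d()].
#' @param n1,n2 Integer wrapping index, not both zero.
#' @return Numeric 2-vector `(arc, axial)` in Angstrom.
#' @examples
#' wrapping_vector(vp39_lattice(), 14, 14)
#' @export
wrapping_vector <- function(lattice, n1, n2) {
  idx <- check_index(n1, n2)
  idx[1] * lattice$a + idx[2] * lattice$b
}

#' Rotational symmetry order of a wrapping
#'
#' A wrapping (n1, n2) produces a tube with Cn rotational symmetry where
#' n = gcd(|n1|, |n2|): the lattice admits a seamless n-fold rotation
#' exactly when both indices share the factor n. (14, 14) gives C14;
#' (6, 13) gives C1, i.e. no rotational symmetry.
#'
#' @inheritParams wrapping_vector
#' @return Integer rotational order.
#' @export
rotational_order <- function(n1, n2) {
  idx <- abs(check_index(n1, n2))
  a <- idx[1]; b <- idx[2]
  while (b != 0L) { t <- a %% b; a <- b; b <- t }
  as.integer(a)
}

## extended gcd: returns c(g, s, t) with s*x + t*y == g, g >= 0 for x,y not both 0
ext_gcd <- function(x, y) {
  if (y == 0L) return(c(abs(x), sign(x), 0L))
  r <- ext_gcd(y, x %% y)
  c(r[1], r[3], r[2] - (x %/% y) * r[3])
}

#' Helical symmetry of a lattice wrapping
#'
#' Decomposes the two lattice basis vectors into arc and axial components
#' with respect to the wrapping vector, giving the per-basis helical
#' operators (twist_i, rise_i), the rotational order, and a canonical
#' one-start operator. The one-start operator is reported with positive
#' rise; the sign of its twist encodes the handedness of the one-start
#' family.
#'
#' The one-start rise follows from projecting the lattice onto the tube
#' axis: the axial coordinate of lattice point (u1, u2) is
#' `det(a,b) (n1 u2 - n2 u1) / C`, so consecutive subunit levels are
#' spaced by `order |det(a,b)| / C`. The generating lattice vector is
#' found by solving `n1 u2 - n2 u1 = order` with the extended Euclidean
#' algorithm, and its twist is reduced into `(-180/order, 180/order]`.
#'
#' @inheritParams wrapping_vector
#' @return An object of class `helical_symmetry` with fields
#'   `n1`, `n2`, `circumference`, `radius`, `diameter` (Angstrom),
#'   `x1`, `x2` (arc lengths, Angstrom), `y1`, `y2` (rises, Angstrom),
#'   `twist1`, `twist2` (degrees), `order` (Cn rotational order),
#'   `one_start_twist` (degrees), `one_start_rise` (Angstrom, positive),
#'   `pitch_angle` (degrees, angle of w to the reference equator) and
#'   `spin` (degrees, identical to `pitch_angle`; the in-plane rotation of
#'   this wrapping's frame relative to the reference frame).
#' @examples
#' hs <- helix_from_wrapping(vp39_lattice(), 14, 14)
#' hs$one_start_rise   # 43.86
#' hs$one_start_twist  # -7.16
#' @export
helix_from_wrapping <- function(lattice, n1, n2) {
  idx <- check_index(n1, n2)
  n1 <- idx[1]; n2 <- idx[2]
  w <- wrapping_vector(lattice, n1, n2)
  C <- sqrt(sum(w^2))
  what <- w / C
  nhat <- c(-what[2], what[1])  # axial unit vector, +90 deg CCW from w
  x1 <- sum(lattice$a * what); y1 <- sum(lattice$a * nhat)
  x2 <- sum(lattice$b * what); y2 <- sum(lattice$b * nhat)
  ord <- rotational_order(n1, n2)

  ## one-start operator: solve n1*u2 - n2*u1 = order * sign(det) so the
  ## generator has rise +order*|det|/C
  sgn <- if (lattice$det >= 0) 1L else -1L
  eg <- ext_gcd(n1, n2)           # s*n1 + t*n2 = order
  u1 <- -eg[3] * sgn; u2 <- eg[2] * sgn
  rise1s <- ord * abs(lattice$det) / C
  tw <- 360 * (u1 * x1 + u2 * x2) / C
  tw <- wrap_half(tw, 360 / ord)

  structure(list(
    n1 = n1, n2 = n2,
    circumference = C, radius = C / (2 * pi), diameter = C / pi,
    x1 = x1, y1 = y1, x2 = x2, y2 = y2,
    twist1 = 360 * x1 / C, twist2 = 360 * x2 / C,
    order = ord,
    one_start_twist = tw, one_start_rise = rise1s,
    pitch_angle = rad2deg(atan2(w[2], w[1])),
    spin = rad2deg(atan2(w[2], w[1]))
  ), class = "helical_symmetry")
}

#' @export
print.helical_symmetry <- function(x, ...) {
  cat(sprintf("<helical_symmetry> wrapping (%d, %d)\n", x$n1, x$n2))
  cat(sprintf("  circumference %.2f A, diameter %.1f A, C%d symmetry\n",
              x$circumference, x$diameter, x$order))
  cat(sprintf("  basis operators: twist1 %.3f deg / rise1 %.3f A; twist2 %.3f deg / rise2 %.3f A\n",
              x$twist1, x$y1, x$twist2, x$y2))
  cat(sprintf("  one-start: twist %.3f deg, rise %.3f A\n",
              x$one_start_twist, x$one_start_rise))
  invisible(x)
}

#' Tidy a helical symmetry description into a one-row tibble
#'
#' @param x A `helical_symmetry` object.
#' @param ... Unused.
#' @return A one-row tibble with all symmetry fields.
#' @method tidy helical_symmetry
#' @export
tidy.helical_symmetry <- function(x, ...) {
  tibble(
    n1 = x$n1, n2 = x$n2,
    circumference = x$circumference, radius = x$radius, diameter = x$diameter,
    x1 = x$x1, y1 = x$y1, x2 = x$x2, y2 = x$y2,
    twist1 = x$twist1, twist2 = x$twist2, order = x$order,
    one_start_twist = x$one_start_twist, one_start_rise = x$one_start_rise,
    pitch_angle = x$pitch_angle
  )
}

#' Default sector predicate for polymorph enumeration
#'
#' Keeps wrappings whose wrapping vector makes at most `max_pitch` degrees
#' with the reference equator and whose index sum is positive (each tube is
#' represented once; (n1, n2) and (-n1, -n2) describe the same tube).
#'
#' @param max_pitch Maximum absolute pitch angle in degrees.
#' @return A predicate `function(n1, n2, symmetry)`.
#' @export
sector_pitch <- function(max_pitch = 20) {
  force(max_pitch)
  function(n1, n2, symmetry) {
    abs(symmetry$pitch_angle) <= max_pitch && (n1 + n2) > 0
  }
}

#' Enumerate tube polymorphs within a circumference range
#'
#' Lists all wrapping indices whose circumference lies in
#' `[c_min, c_max]` and that pass the sector predicate, deduplicated under
#' the sign flip (n1, n2) <-> (-n1, -n2).
#'
#' @inheritParams wrapping_vector
#' @param c_min,c_max Circumference bounds in Angstrom, `0 < c_min < c_max`.
#' @param sector Predicate `function(n1, n2, symmetry)`; default
#'   [sector_pitch()].
#' @return A tibble ordered by circumference, then n1, then n2, with one
#'   row per polymorph and columns n1, n2, circumference, radius, diameter,
#'   order, one_start_twist, one_start_rise, pitch_angle.
#' @examples
#' enumerate_wrappings(vp39_lattice(), 1140, 1660)
#' @export
enumerate_wrappings <- function(lattice, c_min, c_max, sector = sector_pitch()) {
  stopifnot_scalar(c_min, "c_min"); stopifnot_scalar(c_max, "c_max")
  if (!(c_min > 0 && c_min < c_max)) abort("need 0 < c_min < c_max.")
  ## bound the index search box: |n1| <= c_max / h_a where h_a is the
  ## distance from a to the line through b (and vice versa)
  h_a <- abs(lattice$det) / sqrt(sum(lattice$b^2))
  h_b <- abs(lattice$det) / sqrt(sum(lattice$a^2))
  m1 <- ceiling(c_max / h_a); m2 <- ceiling(c_max / h_b)
  grid <- tidyr::expand_grid(n1 = -m1:m1, n2 = -m2:m2) |>
    dplyr::filter(!(.data$n1 == 0 & .data$n2 == 0)) |>
    dplyr::filter(.data$n1 + .data$n2 > 0 |
                    (.data$n1 + .data$n2 == 0 & .data$n1 > 0))
  rows <- purrr::pmap(grid, function(n1, n2) {
    w <- n1 * lattice$a + n2 * lattice$b
    C <- sqrt(sum(w^2))
    if (C < c_min || C > c_max) return(NULL)
    hs <- helix_from_wrapping(lattice, n1, n2)
    if (!isTRUE(sector(n1, n2, hs))) return(NULL)
    tidy(hs)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(n1 = integer(), n2 = integer(), circumference = double(),
                  radius = double(), diameter = double(), order = integer(),
                  one_start_twist = double(), one_start_rise = double(),
                  pitch_angle = double()))
  }
  out |>
    dplyr::select("n1", "n2", "circumference", "radius", "diameter", "order",
                  "one_start_twist", "one_start_rise", "pitch_angle") |>
    dplyr::arrange(.data$circumference, .data$n1, .data$n2)
}
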