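#' Asymmetric unit of a tubular assembly
#'
#' The rigid repeating unit (for the VP39 nucleocapsid, the VP39 dimer)
#' that is symmetry-expanded onto the wrapped lattice. Atoms live in a
#' tibble; `radial_reference` is the unit vector treated as "outward"
#' (toward the tube exterior) in the unit's own frame.
#'
#' @param atoms A data frame with at least columns `x`, `y`, `z`
#'   (Angstrom) and optionally `element`, `atom`, `resid`, `resname`,
#'   `chain`, `occupancy`, `b_factor`. Missing annotation columns are
#'   filled with defaults.
#' @param radial_reference Unit 3-vector, default `+x`.
#' @return An object of class `asym_unit`.
#' @export
asym_unit <- function(atoms, radial_reference = c(1, 0, 0)) {
  atoms <- as_tibble(atoms)
  if (!all(c("x", "y", "z") %in% names(atoms)) || nrow(atoms) < 1L) {
    abort("`atoms` needs >= 1 row and columns x, y, z.")
  }
  if (!all(is.finite(unlist(atoms[, c("x", "y", "z")])))) {
    abort("atom coordinates must be finite.")
  }
  defaults <- list(element = "C", atom = "CA", resid = seq_len(nrow(atoms)),
                   resname = "ALA", chain = "A", occupancy = 1, b_factor = 30)
  for (nm in names(defaults)) {
    if (!nm %in% names(atoms)) atoms[[nm]] <- defaults[[nm]]
  }
  rr <- as.numeric(radial_reference)
  nr <- sqrt(sum(rr^2))
  if (length(rr) != 3L || !all(is.finite(rr)) || nr < 1e-12) {
    abort("`radial_reference` must be a nonzero 3-vector.")
  }
  structure(list(atoms = atoms, radial_reference = rr / nr),
            class = "asym_unit")
}

#' @export
print.asym_unit <- function(x, ...) {
  com <- unit_center(x)
  cat(sprintf("<asym_unit> %d atoms, center of mass (%.1f, %.1f, %.1f) A\n",
              nrow(x$atoms), com[1], com[2], com[3]))
  invisible(x)
}

#' Scattering-weighted center of mass of an asymmetric unit
#'
#' @param unit An [asym_unit()].
#' @return Numeric 3-vector (Angstrom), weighted by atomic number.
#' @export
unit_center <- function(unit) {
  w <- element_weight(unit$atoms$element)
  c(sum(w * unit$atoms$x), sum(w * unit$atoms$y), sum(w * unit$atoms$z)) / sum(w)
}

#' Radially translate a unit onto the tube surface
#'
#' Moves the unit so its center of mass sits at `(radius, 0, 0)`, the
#' standard starting placement before helical symmetry expansion, and sets
#' its radial reference to `+x`. Orientation is unchanged.
#'
#' @param unit An [asym_unit()].
#' @param radius Target center-of-mass radius in Angstrom, > 0.
#' @return A translated [asym_unit()].
#' @export
radialize <- function(unit, radius) {
  stopifnot_scalar(radius, "radius")
  if (radius <= 0) abort("`radius` must be > 0.")
  com <- unit_center(unit)
  shift <- c(radius, 0, 0) - com
  atoms <- unit$atoms
  atoms$x <- atoms$x + shift[1]
  atoms$y <- atoms$y + shift[2]
  atoms$z <- atoms$z + shift[3]
  asym_unit(atoms, radial_reference = c(1, 0, 0))
}
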