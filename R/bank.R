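#' Rendering and scoring parameters for a reference bank
#'
#' @param apix Pixel size in Angstrom per pixel.
#' @param box Image size in pixels.
#' @param resolution Band limit for rendering and alignment in Angstrom
#'   (the classification operates at this resolution).
#' @param blob_sigma Gaussian blob sigma in Angstrom.
#' @param mask_radius Outer radius of the circular scoring mask in
#'   Angstrom; `NULL` sets it from the widest reference tube plus
#'   `3 * blob_sigma`. Must not exceed half the box.
#' @param arc_step Target equatorial arc motion per azimuth grid step, in
#'   Angstrom; the per-entry azimuth step is `arc_step / radius`. Smaller
#'   values give finer reference sampling.
#' @param psi_grid In-plane rotation search grid in degrees.
#' @param shift_max Shift search half-range in pixels; default box/4.
#' @param tube_pad Extra tube length beyond the box, Angstrom, so
#'   projections have no end effects.
#' @return A list of class `bank_params`.
#' @export
bank_params <- function(apix = 5, box = 128, resolution = 12, blob_sigma = 5,
                        mask_radius = NULL, arc_step = 25,
                        psi_grid = seq(-6, 6, by = 3), shift_max = NULL,
                        tube_pad = 50) {
  structure(list(
    apix = apix, box = as.integer(box), resolution = resolution,
    blob_sigma = blob_sigma, mask_radius = mask_radius,
    arc_step = arc_step, psi_grid = psi_grid,
    shift_max = as.integer(shift_max %||% (box %/% 4)),
    tube_pad = tube_pad
  ), class = "bank_params")
}

entry_key <- function(n1, n2, scale) sprintf("(%d,%d)@%.2f", n1, n2, scale)

## azimuthal period of a (possibly flattened) tube's projections
entry_phi_period <- function(order, scale) {
  if (scale > 1) {
    if (order %% 2L == 0L) 180 else 360
  } else {
    360 / order
  }
}

entry_phi_grid <- function(symmetry, scale, params) {
  period <- entry_phi_period(symmetry$order, scale)
  step <- min(period, rad2deg(params$arc_step / symmetry$radius))
  n <- max(1L, ceiling(period / step))
  period * (seq_len(n) - 1L) / n
}

#' Build a polymorph reference bank
#'
#' Builds one tube model per (wrapping, flattening scale), renders its
#' band-limited projections over a per-entry azimuth grid, and packages
#' them with the scoring mask for supervised classification. The azimuth
#' grid covers one rotational period of the tube (360/order for round
#' tubes; the flattening-axis orientation makes flattened tubes 360- or
#' 180-periodic) at a step that keeps the equatorial arc motion below
#' `arc_step`.
#'
#' @param unit An [asym_unit()] in the reference wrapping frame.
#' @param lattice A [lattice2d()].
#' @param wrappings A list of `c(n1, n2)` pairs, or a data frame with
#'   columns `n1`, `n2` (e.g. from [enumerate_wrappings()]).
#' @param scales Flattening scales, subset of `[1, 1.09]` by default
#'   semantics (scale 1 + k/100 = k% flattening).
#' @param params A [bank_params()].
#' @param reference Reference wrapping frame of the unit.
#' @return An object of class `reference_bank`: entries keyed by
#'   `(n1,n2)@scale` in sorted order, the common mask, and the parameters.
#' @export
build_reference_bank <- function(unit, lattice, wrappings,
                                 scales = 1 + (0:9) / 100,
                                 params = bank_params(),
                                 reference = c(14, 14)) {
  if (is.data.frame(wrappings)) {
    wrappings <- purrr::map2(wrappings$n1, wrappings$n2, c)
  }
  if (length(wrappings) == 0L) abort("`wrappings` must be non-empty.")
  if (any(scales < 1)) abort("flattening scales must be >= 1.")
  box_len <- params$box * params$apix
  entries <- list()
  max_semi_major <- 0
  for (widx in wrappings) {
    hs <- helix_from_wrapping(lattice, widx[1], widx[2])
    round_tube <- build_tube(unit, lattice, widx[1], widx[2],
                             -box_len / 2 - params$tube_pad,
                             box_len / 2 + params$tube_pad,
                             reference = reference)
    for (sc in scales) {
      tube <- if (sc == 1) round_tube else flatten(round_tube, sc)
      a_max <- if (sc == 1) hs$radius else tube$ellipse$semi_major
      max_semi_major <- max(max_semi_major, a_max)
      phi <- entry_phi_grid(hs, sc, params)
      projections <- purrr::map(phi, function(p) {
        img <- project(tube, phi = p, psi = 0, shift = c(0, 0),
                       apix = params$apix, box = params$box,
                       blob_sigma = params$blob_sigma)
        band_limit(img, params$resolution)$data
      })
      key <- entry_key(widx[1], widx[2], sc)
      entries[[key]] <- list(n1 = widx[1], n2 = widx[2], scale = sc,
                             key = key, symmetry = hs, phi = phi,
                             projections = projections)
    }
  }
  entries <- entries[order(names(entries))]
  mask_radius <- params$mask_radius %||%
    (max_semi_major + 3 * params$blob_sigma)
  if (mask_radius > box_len / 2) {
    abort(sprintf("mask radius %.1f A exceeds half the box (%.1f A).",
                  mask_radius, box_len / 2))
  }
  mask <- circular_mask(params$box, params$apix, mask_radius)
  bank <- structure(list(entries = entries, params = params,
                         lattice = lattice, mask = mask,
                         mask_radius = mask_radius,
                         cache = new.env(parent = emptyenv())),
                    class = "reference_bank")
  bank
}

circular_mask <- function(box, apix, radius) {
  cN <- box / 2 + 1
  idx <- (seq_len(box) - cN) * apix
  outer(idx^2, idx^2, "+") <= radius^2
}

#' @export
print.reference_bank <- function(x, ...) {
  np <- sum(purrr::map_int(x$entries, ~ length(.x$projections)))
  cat(sprintf("<reference_bank> %d entries, %d projections, %d px @ %.2f A/px, band limit %.1f A\n",
              length(x$entries), np, x$params$box, x$params$apix,
              x$params$resolution))
  cat(sprintf("  mask radius %.1f A\n", x$mask_radius))
  invisible(x)
}

## cached conj-FFT and norm of the masked, mean-subtracted reference
## projection p of entry `key`
ref_fa <- function(bank, key, p) {
  id <- sprintf("%s#%d", key, p)
  hit <- bank$cache[[id]]
  if (!is.null(hit)) return(hit)
  R <- bank$entries[[key]]$projections[[p]]
  M <- bank$mask
  mu <- sum(R[M]) / sum(M)
  A <- (R - mu) * M
  normA <- sqrt(sum(A[M]^2))
  out <- list(FA = Conj(fft2(A)), normA = normA)
  bank$cache[[id]] <- out
  out
}
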