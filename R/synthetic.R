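#' Generate a reproducible pseudo-atomic asymmetric unit
#'
#' Draws a cluster of Gaussian-blob pseudo-atoms inside a stated bounding
#' extent, as a stand-in for a compact dimeric repeat unit (the default
#' extent echoes a roughly 100 x 50 x 45 Angstrom footprint: tangential,
#' axial, radial). A random cluster of four or more points is chiral with
#' probability one, so handedness is testable; the same seed always gives
#' the same unit via the dedicated "unit" random stream.
#'
#' @param n_blobs Number of pseudo-atoms, >= 3.
#' @param extent Bounding extents in Angstrom as `(tangential, axial,
#'   radial)`; all > 0.
#' @param seed Master seed.
#' @return An [asym_unit()] centered on its center of mass, with
#'   radial reference `+x`; the unit frame is (x radial/outward,
#'   y tangential, z axial).
#' @export
make_pseudo_unit <- function(n_blobs = 12, extent = c(100, 50, 45), seed = 1) {
  if (n_blobs < 3) abort("`n_blobs` must be >= 3 for pose discrimination.")
  extent <- as.numeric(extent)
  if (length(extent) != 3L || any(!is.finite(extent)) || any(extent <= 0)) {
    abort("`extent` must be three positive lengths (Angstrom).")
  }
  pos <- with_seed(stream_seed(seed, "unit"), {
    ## rejection-sample a minimum spacing so the unit has structure at
    ## blob scale rather than collapsing into one lump
    min_d <- 0.45 * (prod(extent) / n_blobs)^(1 / 3)
    pts <- matrix(NA_real_, n_blobs, 3)
    k <- 0L
    while (k < n_blobs) {
      cand <- (stats::runif(3) - 0.5) * extent
      if (k == 0L ||
          min(sqrt(colSums((t(pts[seq_len(k), , drop = FALSE]) - cand)^2))) >= min_d) {
        k <- k + 1L
        pts[k, ] <- cand
      }
    }
    pts
  })
  ## unit frame: x radial, y tangential, z axial
  atoms <- tibble(element = "X", atom = "PSE",
                  resid = seq_len(n_blobs), resname = "BLB", chain = "A",
                  x = pos[, 3], y = pos[, 1], z = pos[, 2],
                  occupancy = 1, b_factor = 30)
  atoms$x <- atoms$x - mean(atoms$x)
  atoms$y <- atoms$y - mean(atoms$y)
  atoms$z <- atoms$z - mean(atoms$z)
  asym_unit(atoms, radial_reference = c(1, 0, 0))
}

#' Ground-truth specification for a synthetic segment dataset
#'
#' @param classes Data frame with columns `n1`, `n2`, `scale`, `count`
#'   (counts >= 1): how many segments to draw from each polymorph and
#'   flattening level.
#' @param snr Signal-to-noise ratio of the segments.
#' @param seed Master seed; every random stage (unit, poses, per-segment
#'   noise) derives its own stream from it.
#' @param lattice 2D lattice; defaults to [vp39_lattice()].
#' @param params A [bank_params()] holding the render settings.
#' @param psi_range Half-range of the in-plane angle prior, degrees
#'   (segments are drawn with psi uniform in `[-psi_range, psi_range]`,
#'   emulating filament segments pre-rotated to near-vertical).
#' @param shift_range Half-range of the in-plane shift prior, Angstrom.
#' @param unit Optional [asym_unit()]; default a [make_pseudo_unit()]
#'   drawn from the spec's unit stream.
#' @return A list of class `truth_spec`.
#' @export
truth_spec <- function(classes, snr = 0.3, seed = 20240104,
                       lattice = vp39_lattice(), params = bank_params(),
                       psi_range = 6, shift_range = 15, unit = NULL) {
  classes <- as_tibble(classes)
  need <- c("n1", "n2", "scale", "count")
  if (!all(need %in% names(classes)) || nrow(classes) == 0L) {
    abort("`classes` needs columns n1, n2, scale, count.")
  }
  if (any(classes$count < 1)) abort("class counts must be >= 1.")
  structure(list(classes = classes, snr = snr, seed = as.integer(seed),
                 lattice = lattice, params = params,
                 psi_range = psi_range, shift_range = shift_range,
                 unit = unit),
            class = "truth_spec")
}

#' The standard desk-scale synthetic suite
#'
#' Six wrappings (the reference (14, 14), its single-subunit
#' insertion/deletion neighbours, and the asymmetric (6, 13)), three
#' flattening levels, 20 segments per class at 128 px / 5 Angstrom per
#' pixel and snr 0.3.
#'
#' @param seed Master seed (default 20240104).
#' @param n_per_class Segments per class (default 20).
#' @return A [truth_spec()].
#' @export
standard_suite_spec <- function(seed = 20240104, n_per_class = 20) {
  wr <- list(c(13, 13), c(14, 14), c(15, 15), c(13, 14), c(14, 15), c(6, 13))
  classes <- tidyr::expand_grid(
    w = wr, scale = c(1.00, 1.02, 1.05)
  ) |>
    dplyr::mutate(n1 = purrr::map_int(.data$w, ~ as.integer(.x[1])),
                  n2 = purrr::map_int(.data$w, ~ as.integer(.x[2])),
                  count = n_per_class) |>
    dplyr::select("n1", "n2", "scale", "count")
  truth_spec(classes, snr = 0.3, seed = seed)
}

#' Generate a labeled synthetic segment dataset
#'
#' For every requested segment: build the round tube, flatten it to the
#' class's scale, project it at a seeded random pose (azimuth uniform in
#' [0, 360), in-plane angle and shifts from the spec's priors), band-limit
#' to the render resolution and add white noise at the spec's snr. The
#' whole dataset is a pure function of the spec (including its seed).
#'
#' @param spec A [truth_spec()].
#' @return A list of class `tw_dataset` with `stack` (a [tw_stack()]) and
#'   `labels` (tibble: segment, n1, n2, scale, phi, psi, dx, dy in
#'   Angstrom, noise_seed).
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "truth_spec")) abort("`spec` must be a truth_spec.")
  p <- spec$params
  unit <- spec$unit %||% make_pseudo_unit(seed = spec$seed)
  n_total <- sum(spec$classes$count)
  poses <- with_seed(stream_seed(spec$seed, "pose"), tibble(
    phi = stats::runif(n_total, 0, 360),
    psi = stats::runif(n_total, -spec$psi_range, spec$psi_range),
    dx = stats::runif(n_total, -spec$shift_range, spec$shift_range),
    dy = stats::runif(n_total, -spec$shift_range, spec$shift_range)
  ))
  box_len <- p$box * p$apix
  images <- vector("list", n_total)
  labels <- vector("list", n_total)
  s <- 0L
  for (ci in seq_len(nrow(spec$classes))) {
    cl <- spec$classes[ci, ]
    round_tube <- build_tube(unit, spec$lattice, cl$n1, cl$n2,
                             -box_len / 2 - p$tube_pad,
                             box_len / 2 + p$tube_pad)
    tube <- if (cl$scale == 1) round_tube else flatten(round_tube, cl$scale)
    for (k in seq_len(cl$count)) {
      s <- s + 1L
      pose <- poses[s, ]
      img <- project(tube, phi = pose$phi, psi = pose$psi,
                     shift = c(pose$dx, pose$dy),
                     apix = p$apix, box = p$box, blob_sigma = p$blob_sigma)
      img <- band_limit(img, p$resolution)
      nseed <- stream_seed(spec$seed, "noise", index = s)
      img <- if (is.finite(spec$snr)) add_noise(img, spec$snr, nseed) else img
      images[[s]] <- img$data
      labels[[s]] <- tibble(segment = s, n1 = cl$n1, n2 = cl$n2,
                            scale = cl$scale, phi = pose$phi, psi = pose$psi,
                            dx = pose$dx, dy = pose$dy, noise_seed = nseed)
    }
  }
  structure(list(stack = tw_stack(images, p$apix),
                 labels = dplyr::bind_rows(labels),
                 spec = spec),
            class = "tw_dataset")
}

#' @export
print.tw_dataset <- function(x, ...) {
  cat(sprintf("<tw_dataset> %d segments, %d classes, snr %.2f, seed %d\n",
              nrow(x$labels), nrow(x$spec$classes), x$spec$snr, x$spec$seed))
  invisible(x)
}

#' Compare assignments with ground-truth labels
#'
#' @param assignments A [classify()] result.
#' @param labels The `labels` table of a [generate_dataset()] dataset.
#' @return A list of class `recovery_report`: `overall` (one row:
#'   lattice accuracy, flattening accuracy within correctly assigned
#'   lattices, adjacent-scale confusion rate), `per_class` (per true
#'   class), and `confusion` (true vs assigned class counts).
#' @export
recovery_report <- function(assignments, labels) {
  j <- dplyr::inner_join(
    labels |> dplyr::rename(true_n1 = "n1", true_n2 = "n2",
                            true_scale = "scale"),
    as_tibble(assignments)[, c("segment", "n1", "n2", "scale", "score",
                               "margin")],
    by = "segment"
  ) |>
    dplyr::mutate(
      lattice_ok = .data$n1 == .data$true_n1 & .data$n2 == .data$true_n2,
      scale_ok = .data$lattice_ok & .data$scale == .data$true_scale
    )
  overall <- j |>
    dplyr::summarise(
      n = dplyr::n(),
      lattice_accuracy = mean(.data$lattice_ok),
      scale_accuracy_given_lattice =
        mean(.data$scale_ok[.data$lattice_ok]),
      mean_score = mean(.data$score),
      mean_margin = mean(.data$margin)
    )
  per_class <- j |>
    dplyr::group_by(.data$true_n1, .data$true_n2, .data$true_scale) |>
    dplyr::summarise(
      n = dplyr::n(),
      lattice_accuracy = mean(.data$lattice_ok),
      scale_accuracy_given_lattice =
        ifelse(any(.data$lattice_ok),
               mean(.data$scale_ok[.data$lattice_ok]), NA_real_),
      .groups = "drop"
    )
  confusion <- j |>
    dplyr::count(.data$true_n1, .data$true_n2, .data$true_scale,
                 .data$n1, .data$n2, .data$scale, name = "count")
  structure(list(overall = overall, per_class = per_class,
                 confusion = confusion, joined = j),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(as.data.frame(x$overall), row.names = FALSE)
  invisible(x)
}
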