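## Masked normalized cross-correlation machinery.
##
## The score between a segment S and a reference projection R is the
## maximum over integer pixel shifts d (|d| <= shift_max) and over the
## rotation grids of
##
##   NCC(d) = sum_M (R - muR)(S_d - muS(d)) / (||R - muR||_M ||S_d - muS(d)||_M)
##
## where M is the circular mask (applied to the reference, i.e. the
## comparison window), S_d the segment shifted by d, and muS(d), sigmaS(d)
## the segment mean and norm inside the shifted window. All shift maps are
## computed at once with FFT cross-correlations.

## per-(segment, psi) precomputation against the common mask
prep_segment_psi <- function(segment_mat, apix, psi, mask, FMc, Nm) {
  S <- if (abs(psi) < 1e-12) segment_mat else
    rotate_image(tw_image(segment_mat, apix), -psi)$data
  FS <- fft2(S)
  sumS <- Re(ifft2(FMc * FS))
  sumS2 <- Re(ifft2(FMc * fft2(S * S)))
  den <- sqrt(pmax(sumS2 - sumS^2 / Nm, 0))
  list(FS = FS, den = den)
}

## segments are compared at the bank's resolution limit: band-limit first,
## then precompute the shifted-window statistics per candidate psi
prep_segment <- function(segment_mat, apix, psi_grid, mask,
                         resolution = NULL) {
  if (!is.null(resolution)) {
    segment_mat <- band_limit(tw_image(segment_mat, apix), resolution)$data
  }
  FMc <- Conj(fft2(mask + 0))
  Nm <- sum(mask)
  preps <- purrr::map(psi_grid, ~ prep_segment_psi(segment_mat, apix, .x,
                                                   mask, FMc, Nm))
  list(psi_grid = psi_grid, preps = preps, Nm = Nm)
}

## wrapped shift-window indices and their signed shifts
shift_window <- function(n, smax) {
  idx <- c(1:(smax + 1L), (n - smax + 1L):n)
  shifts <- c(0:smax, -(smax:1))
  list(idx = idx, shifts = shifts)
}

## max masked NCC over the shift window for one (psi, reference) pair
ncc_max <- function(prep_psi, fa, win) {
  cc <- Re(ifft2(fa$FA * prep_psi$FS))
  sub <- cc[win$idx, win$idx] /
    pmax(fa$normA * prep_psi$den[win$idx, win$idx], 1e-12)
  k <- arrayInd(which.max(sub), dim(sub))
  list(score = min(max(sub), 1),
       dx = win$shifts[k[1]], dy = win$shifts[k[2]])
}

## score one segment against one entry; `prep` from prep_segment()
score_entry <- function(prep, bank, key, mode) {
  entry <- bank$entries[[key]]
  nphi <- length(entry$phi)
  win <- shift_window(bank$params$box, bank$params$shift_max)
  psi0 <- which.min(abs(prep$psi_grid))
  best <- list(score = -Inf, phi = entry$phi[1], psi = prep$psi_grid[psi0],
               dx = 0, dy = 0)
  eval_one <- function(p, ipsi) {
    r <- ncc_max(prep$preps[[ipsi]], ref_fa(bank, key, p), win)
    if (r$score > best$score) {
      best <<- list(score = r$score, phi = entry$phi[p],
                    psi = prep$psi_grid[ipsi], dx = r$dx, dy = r$dy)
    }
    r$score
  }
  if (mode == "exhaustive") {
    for (p in seq_len(nphi)) for (ipsi in seq_along(prep$psi_grid)) {
      eval_one(p, ipsi)
    }
    return(best)
  }
  ## two-stage: coarse azimuth at the central psi, then local refinement of
  ## the two best coarse candidates, then one sweep of coordinate descent
  ## over (azimuth, psi)
  stride <- if (nphi > 8L) 3L else 1L
  coarse <- seq(1L, nphi, by = stride)
  s1 <- vapply(coarse, function(p) eval_one(p, psi0), 0)
  if (stride > 1L) {
    top <- coarse[order(s1, decreasing = TRUE)[seq_len(min(2L, length(s1)))]]
    around <- setdiff(unique(as.integer(outer(
      top, (-stride + 1L):(stride - 1L), "+") - 1L) %% nphi + 1L), coarse)
    for (p in around) eval_one(p, psi0)
  }
  p_fine <- which(entry$phi == best$phi)[1]
  for (ipsi in setdiff(seq_along(prep$psi_grid), psi0)) {
    eval_one(p_fine, ipsi)
  }
  if (nphi > 1L) {
    ipsi_best <- which(prep$psi_grid == best$psi)[1]
    p_now <- which(entry$phi == best$phi)[1]
    if (ipsi_best != psi0) {
      for (p in setdiff(unique((p_now + c(-1L, 1L) - 1L) %% nphi + 1L), p_now)) {
        eval_one(p, ipsi_best)
      }
    }
  }
  best
}

#' Align a segment image to one reference-bank entry
#'
#' Computes the maximum masked, band-limited normalized cross-correlation
#' between the segment and the entry's projections over the azimuth grid,
#' the in-plane rotation grid and all integer pixel shifts up to the
#' configured range, and reports the score with the maximizing pose.
#'
#' @param segment A [tw_image()] with the bank's pixel size and box.
#' @param bank A [build_reference_bank()].
#' @param key Entry key string (see `names(bank$entries)`).
#' @param psi_grid In-plane rotation candidates in degrees; default from
#'   the bank parameters.
#' @param mode `"exhaustive"` (default here) scores every grid point;
#'   `"two_stage"` uses the coarse-to-fine search that [classify()] uses.
#' @return List with `score` (in [-1, 1]), `phi`, `psi` (degrees), `dx`,
#'   `dy` (pixels, segment relative to reference).
#' @export
align_and_score <- function(segment, bank, key,
                            psi_grid = NULL,
                            mode = c("exhaustive", "two_stage")) {
  mode <- match.arg(mode)
  check_segment(segment, bank)
  if (!key %in% names(bank$entries)) abort(sprintf("unknown entry '%s'.", key))
  psi_grid <- psi_grid %||% bank$params$psi_grid
  prep <- prep_segment(segment$data, bank$params$apix, psi_grid, bank$mask,
                       bank$params$resolution)
  score_entry(prep, bank, key, mode)
}

check_segment <- function(segment, bank) {
  if (!inherits(segment, "tw_image")) abort("`segment` must be a tw_image.")
  if (nrow(segment$data) != bank$params$box) {
    abort("segment box size does not match the bank.")
  }
  if (abs(segment$apix - bank$params$apix) > 1e-6) {
    abort("segment pixel size does not match the bank.")
  }
}

#' Classify segment images against a reference bank
#'
#' Assigns each segment of the stack to the bank entry with the highest
#' alignment score. Ties break deterministically to the first key in
#' sorted order; the margin between the best and runner-up scores is
#' recorded so users can apply their own confidence cutoffs.
#'
#' @param stack A [tw_stack()] of segment images.
#' @param bank A [build_reference_bank()].
#' @param psi_grid In-plane rotation candidates (degrees); default from
#'   the bank parameters.
#' @param mode Search mode per entry, `"two_stage"` (default) or
#'   `"exhaustive"`.
#' @param progress Print a line every 50 segments.
#' @return A tibble of class `tube_classification` with one row per
#'   segment: `segment`, `n1`, `n2`, `scale`, `score`, `phi`, `psi`,
#'   `dx`, `dy` (pixels), `margin`.
#' @export
classify <- function(stack, bank, psi_grid = NULL,
                     mode = c("two_stage", "exhaustive"), progress = FALSE) {
  mode <- match.arg(mode)
  if (length(stack$images) == 0L) abort("empty stack.")
  if (length(bank$entries) == 0L) abort("empty bank.")
  psi_grid <- psi_grid %||% bank$params$psi_grid
  keys <- names(bank$entries)   # sorted at build time
  rows <- vector("list", length(stack$images))
  for (s in seq_along(stack$images)) {
    prep <- prep_segment(stack$images[[s]], bank$params$apix, psi_grid,
                         bank$mask, bank$params$resolution)
    best <- NULL; second <- -Inf
    for (key in keys) {
      r <- score_entry(prep, bank, key, mode)
      if (is.null(best) || r$score > best$score) {
        second <- if (is.null(best)) -Inf else max(second, best$score)
        best <- c(r, list(key = key))
      } else {
        second <- max(second, r$score)
      }
    }
    e <- bank$entries[[best$key]]
    rows[[s]] <- tibble(
      segment = s, n1 = e$n1, n2 = e$n2, scale = e$scale,
      score = best$score, phi = best$phi, psi = best$psi,
      dx = best$dx, dy = best$dy,
      margin = best$score - second
    )
    if (progress && s %% 50 == 0) {
      message(sprintf("classified %d / %d segments", s, length(stack$images)))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tube_classification", class(out))
  attr(out, "bank_keys") <- keys
  attr(out, "params") <- bank$params
  out
}

#' Summarize a classification into polymorph and flattening histograms
#'
#' @param x A [classify()] result.
#' @return A list of class `tube_class_summary` with `lattice` (counts and
#'   fractions per wrapping) and `flattening` (within each wrapping,
#'   counts and fractions per flattening scale). Fractions sum to one in
#'   each table.
#' @export
summarize_assignments <- function(x) {
  if (nrow(x) == 0L) abort("empty assignment table.")
  lattice <- x |>
    dplyr::count(.data$n1, .data$n2, name = "count") |>
    dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$count))
  flattening <- x |>
    dplyr::count(.data$n1, .data$n2, .data$scale, name = "count") |>
    dplyr::group_by(.data$n1, .data$n2) |>
    dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$n1, .data$n2, .data$scale)
  structure(list(lattice = lattice, flattening = flattening),
            class = "tube_class_summary")
}

#' @export
print.tube_class_summary <- function(x, ...) {
  cat("<tube_class_summary>\n== polymorph distribution ==\n")
  print(as.data.frame(x$lattice), row.names = FALSE)
  cat("== flattening within each polymorph ==\n")
  print(as.data.frame(x$flattening), row.names = FALSE)
  invisible(x)
}
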