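## Shared fixtures and independent oracles. Everything here is built in
## code at test time; no binary fixtures ship with the package.

## the printed nucleocapsid lattice, used throughout
fix_lattice <- function() vp39_lattice()

## a small, cheap pseudo-unit for geometry tests
fix_unit <- function(seed = 11) {
  make_pseudo_unit(n_blobs = 6, extent = c(60, 40, 30), seed = seed)
}

## a 64 px bank over two well-separated polymorphs, cached per session
fix_small_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) {
      par <- bank_params(apix = 5, box = 64, shift_max = 6,
                        psi_grid = c(-4, 0, 4), mask_radius = 150)
      bank <<- build_reference_bank(fix_unit(), fix_lattice(),
                                    list(c(14, 14), c(6, 13)),
                                    scales = 1, params = par)
    }
    bank
  }
})

## brute-force masked NCC oracle: explicit loops over the same search
## grid, Pearson correlation inside the shifted mask window
oracle_masked_ncc <- function(segment_mat, ref_mat, mask, smax) {
  n <- nrow(segment_mat)
  idx_mask <- which(mask)
  R <- ref_mat[idx_mask]
  R <- R - mean(R)
  nR <- sqrt(sum(R^2))
  mi <- ((idx_mask - 1) %% n) + 1
  mj <- ((idx_mask - 1) %/% n) + 1
  best <- list(score = -Inf, dx = 0L, dy = 0L)
  for (dx in -smax:smax) for (dy in -smax:smax) {
    si <- ((mi - 1 + dx) %% n) + 1
    sj <- ((mj - 1 + dy) %% n) + 1
    S <- segment_mat[cbind(si, sj)]
    S <- S - mean(S)
    nS <- sqrt(sum(S^2))
    sc <- sum(R * S) / max(nR * nS, 1e-12)
    if (sc > best$score) best <- list(score = sc, dx = dx, dy = dy)
  }
  best
}

## dense-polyline ellipse oracles
oracle_ellipse_perimeter <- function(a, b, n = 2e5) {
  t <- seq(0, 2 * pi, length.out = n + 1)
  sum(sqrt(diff(a * cos(t))^2 + diff(b * sin(t))^2))
}

oracle_arc_to_t <- function(a, b, s, n = 2e5) {
  t <- seq(0, 2 * pi, length.out = n + 1)
  seg <- sqrt(diff(a * cos(t))^2 + diff(b * sin(t))^2)
  cs <- c(0, cumsum(seg))
  stats::approx(cs, t, xout = s)$y
}

## gcd oracle by enumeration of common divisors
oracle_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  if (a == 0) return(b)
  if (b == 0) return(a)
  max(Filter(function(d) a %% d == 0 && b %% d == 0, seq_len(min(a, b))))
}

rms <- function(m) sqrt(mean(m^2))

wrap_pos <- function(x, p) x - p * floor(x / p)
wrap_half <- function(x, p) x - p * floor(x / p + 0.5)
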