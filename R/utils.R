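#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map2 pmap
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about the z axis
#'
#' @param theta Angle in degrees; positive rotates +x toward +y
#'   (right-handed, looking down the +z axis).
#' @return A 3x3 rotation matrix.
#' @keywords internal
rot_z <- function(theta) {
  t <- deg2rad(theta)
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix about the x axis
#'
#' @param theta Angle in degrees; positive rotates +y toward +z.
#' @return A 3x3 rotation matrix.
#' @keywords internal
rot_x <- function(theta) {
  t <- deg2rad(theta)
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}

## 2x2 in-plane rotation, degrees, CCW
rot2 <- function(theta) {
  t <- deg2rad(theta)
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
}

## reduce x into (-p/2, p/2]
wrap_half <- function(x, p) x - p * floor(x / p + 0.5)

## reduce x into [0, p)
wrap_pos <- function(x, p) x - p * floor(x / p)

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar.", name))
  }
}

#' Derive a named pseudo-random stream seed from a master seed
#'
#' Each pipeline stage (unit generation, pose drawing, per-segment noise)
#' uses its own stream so stages can be varied independently while staying
#' fully reproducible from one master seed.
#'
#' @param seed Master integer seed.
#' @param stream Stream name, one of "unit", "pose", "noise".
#' @param index Optional non-negative offset within the stream.
#' @return An integer seed below 2^31.
#' @export
stream_seed <- function(seed, stream = c("unit", "pose", "noise"), index = 0L) {
  stream <- match.arg(stream)
  base <- c(unit = 101L, pose = 211L, noise = 307L)[[stream]]
  ## splitmix-style integer mix, kept in double precision below 2^31
  x <- (as.numeric(seed) %% 2147483647) + base * 9973 + as.numeric(index)
  x <- (x * 48271) %% 2147483647
  as.integer(x)
}

## run code with a local RNG state
with_seed <- function(seed, code) withr::with_seed(seed, code)

## atomic-number lookup for common elements; generic scatterer weight 6
element_weight <- function(element) {
  tab <- c(
    H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, ZN = 30, FE = 26,
    MG = 12, "NA" = 11, K = 19, CL = 17, CA = 20, X = 6
  )
  w <- tab[toupper(element)]
  w[is.na(w)] <- 6
  unname(w)
}
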