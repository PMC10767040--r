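test_that("radialize puts the center of mass on the +x axis and is idempotent", {
  u <- fix_unit()
  ru <- radialize(u, 223.3)
  expect_equal(unit_center(ru), c(223.3, 0, 0), tolerance = 1e-9)
  ru2 <- radialize(ru, 223.3)
  expect_equal(ru2$atoms$x, ru$atoms$x, tolerance = 1e-12)
  expect_equal(ru$radial_reference, c(1, 0, 0))
  expect_error(radialize(u, 0), "> 0")
  expect_error(radialize(u, -5), "> 0")
})

test_that("a one-rise window of the C14 tube holds exactly 14 subunits at one level", {
  lat <- fix_lattice()
  hs <- helix_from_wrapping(lat, 14, 14)
  pts <- lattice_points_in_window(lat, 14, 14, 0, hs$one_start_rise)
  expect_identical(nrow(pts), 14L)
  expect_equal(diff(range(pts$z)), 0)
  expect_equal(sort(pts$azimuth), (0:13) * 360 / 14, tolerance = 1e-9)
})

test_that("lattice points congruent modulo the wrapping vector collapse to one subunit", {
  lat <- fix_lattice()
  for (idx in list(c(14, 14), c(6, 13))) {
    pts <- lattice_points_in_window(lat, idx[1], idx[2], -60, 60)
    key <- sprintf("%.6f_%.6f", wrap_pos(pts$azimuth, 360), pts$z)
    expect_identical(anyDuplicated(key), 0L)
    ## class invariant n1*u2 - n2*u1 is untouched by adding the wrapping vector
    expect_identical(anyDuplicated(cbind(pts$u1, pts$u2)), 0L)
  }
})

test_that("the spin angle equals the pitch of the wrapping vector in the reference frame", {
  pts <- lattice_points_in_window(fix_lattice(), 6, 13, -20, 20)
  expect_equal(pts$spin[1], atan2(307.02, 1107.49) * 180 / pi,
               tolerance = 1e-4)
  pts14 <- lattice_points_in_window(fix_lattice(), 14, 14, -20, 20)
  expect_equal(pts14$spin[1], 0)
})

test_that("all subunit centers sit on the tube surface at the helix radius", {
  lat <- fix_lattice()
  tube <- build_tube(fix_unit(), lat, 14, 14, -100, 100)
  r <- sqrt(tube$placements$com_x^2 + tube$placements$com_y^2)
  expect_equal(r, rep(1403.08 / (2 * pi), nrow(tube$placements)),
               tolerance = 1e-9)
  expect_equal(max(abs(tube$placements$spin)), 0)
})

test_that("symmetry expansion is rigid: intra-subunit distances are identical everywhere", {
  tube <- build_tube(fix_unit(), fix_lattice(), 6, 13, -60, 60)
  ta <- tube_atoms(tube)
  ids <- unique(ta$placement)
  d_ref <- dist(as.matrix(ta[ta$placement == ids[1], c("x", "y", "z")]))
  for (i in ids[-1]) {
    d_i <- dist(as.matrix(ta[ta$placement == i, c("x", "y", "z")]))
    expect_lt(max(abs(d_i - d_ref)), 1e-6)
  }
})

test_that("building a C_k tube equals iterating the one-start screw plus the k-fold rotation", {
  lat <- fix_lattice()
  k <- 14
  hs <- helix_from_wrapping(lat, k, k)
  tube <- build_tube(fix_unit(), lat, k, k, 0, 2 * hs$one_start_rise)
  got <- tube_atoms(tube)
  got_set <- got[order(round(got$x, 4), round(got$y, 4), round(got$z, 4)),
                 c("x", "y", "z")]
  ## independent path: apply the screw operator m times, then the rotation
  ru <- radialize(fix_unit(), hs$radius)
  P0 <- as.matrix(ru$atoms[, c("x", "y", "z")])
  Rz <- function(th) {
    t <- th * pi / 180
    matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  }
  exp_rows <- list()
  for (m in 0:1) {
    Pm <- P0
    for (s in seq_len(m)) {
      Pm <- Pm %*% t(Rz(hs$one_start_twist))
      Pm[, 3] <- Pm[, 3] + hs$one_start_rise
    }
    for (j in 0:(k - 1)) {
      exp_rows[[length(exp_rows) + 1L]] <- Pm %*% t(Rz(j * 360 / k))
    }
  }
  exp_all <- do.call(rbind, exp_rows)
  exp_set <- exp_all[order(round(exp_all[, 1], 4), round(exp_all[, 2], 4),
                           round(exp_all[, 3], 4)), ]
  expect_equal(nrow(got_set), nrow(exp_set))
  expect_lt(max(abs(as.matrix(got_set) - exp_set)), 1e-6)
})

test_that("local packing is invariant across polymorphs (nearest-neighbour distances)", {
  lat <- fix_lattice()
  knn <- function(idx) {
    tube <- build_tube(fix_unit(), lat, idx[1], idx[2], -120, 120)
    com <- cbind(tube$placements$com_x, tube$placements$com_y,
                 tube$placements$com_z)
    ## central subunit: closest to azimuth 0, z 0
    i <- which.min(abs(tube$placements$z) + abs(tube$placements$com_y))
    d <- sqrt(colSums((t(com) - com[i, ])^2))
    sort(d[-i])[1:6]
  }
  ref <- knn(c(14, 14))
  for (idx in list(c(13, 13), c(15, 15), c(13, 14), c(6, 13))) {
    expect_lt(max(abs(knn(idx) - ref) / ref), 0.03)
  }
})

test_that("lattice basis vectors are recoverable from a built tube", {
  lat <- fix_lattice()
  tube <- build_tube(fix_unit(), lat, 14, 14, -120, 120)
  pl <- tube$placements
  r <- tube$symmetry$radius
  arc <- r * pl$azimuth * pi / 180
  C <- tube$symmetry$circumference
  recover <- function(du1, du2) {
    hits <- NULL
    for (i in seq_len(nrow(pl))) {
      j <- which(pl$u1 == pl$u1[i] + du1 & pl$u2 == pl$u2[i] + du2)
      if (length(j) == 1L) hits <- rbind(hits, c(
        wrap_half(arc[j] - arc[i], C), pl$z[j] - pl$z[i]))
    }
    colMeans(hits)
  }
  expect_equal(recover(1, 0), lat$a, tolerance = 1e-3)
  expect_equal(recover(0, 1), lat$b, tolerance = 1e-3)
})

test_that("an axial window with no lattice point yields an empty tube with a warning", {
  expect_warning(
    tube <- build_tube(fix_unit(), fix_lattice(), 14, 14, 10, 12),
    "no lattice point")
  expect_identical(nrow(tube$placements), 0L)
})

test_that("neighbor_pairs agrees with the brute-force all-pairs oracle", {
  tube <- build_tube(fix_unit(), fix_lattice(), 14, 14, 0, 43.86)
  np <- neighbor_pairs(tube, cutoff = 110)
  expect_gt(nrow(np), 0)
  ## oracle: direct pairwise distances over all expanded atoms
  ta <- tube_atoms(tube)
  ids <- sort(unique(ta$placement))
  for (row in seq_len(min(nrow(np), 5))) {
    pi_ <- as.matrix(ta[ta$placement == np$i[row], c("x", "y", "z")])
    pj_ <- as.matrix(ta[ta$placement == np$j[row], c("x", "y", "z")])
    dmat <- outer(rowSums(pi_^2), rowSums(pj_^2), "+") - 2 * pi_ %*% t(pj_)
    expect_equal(np$distance[row], sqrt(min(dmat)), tolerance = 1e-9)
  }
  ## symmetric, deduplicated, sorted by distance
  expect_true(all(np$i < np$j))
  expect_true(!is.unsorted(np$distance))
  ## cutoff below the closest approach yields nothing
  expect_identical(nrow(neighbor_pairs(tube, cutoff = 1e-3)), 0L)
  expect_error(neighbor_pairs(tube, cutoff = -1), "> 0")
})
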