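test_that("volume rendering places isotropic blobs with mass-proportional density", {
  one <- asym_unit(data.frame(x = 0, y = 0, z = 0, element = "C"))
  v <- render_volume(one, apix = 2, box = 32, blob_sigma = 4)
  k <- which(v$data == max(v$data), arr.ind = TRUE)
  expect_equal(as.integer(k[1, ]), rep(17L, 3))   # box/2 + 1
  ## isotropy: profiles along the three axes through the center agree
  px <- v$data[, 17, 17]; py <- v$data[17, , 17]; pz <- v$data[17, 17, ]
  expect_equal(px, py, tolerance = 1e-12)
  expect_equal(px, pz, tolerance = 1e-12)
  ## linearity: nitrogen (Z=7) vs carbon (Z=6)
  oneN <- asym_unit(data.frame(x = 0, y = 0, z = 0, element = "N"))
  vN <- render_volume(oneN, apix = 2, box = 32, blob_sigma = 4)
  expect_equal(sum(vN$data) / sum(v$data), 7 / 6, tolerance = 1e-12)
  expect_error(render_volume(one, apix = -1, box = 32), "apix")
  expect_error(render_volume(one, apix = 2, box = 4), "box")
})

test_that("a C14 ring renders a 14-fold symmetric central slice", {
  tube <- build_tube(fix_unit(), fix_lattice(), 14, 14, 0, 43.86)
  v <- render_volume(tube, apix = 6, box = 96, blob_sigma = 10)
  slice <- tw_image(v$data[, , 49], 6)
  rot <- rotate_image(slice, 360 / 14)
  ## compare inside the annulus actually covered by both
  m <- slice$data; mr <- rot$data
  keep <- abs(m) + abs(mr) > 0.01 * max(abs(m))
  expect_lt(rms(m[keep] - mr[keep]) / rms(m[keep]), 0.05)
})

test_that("projections honour rotational symmetry and in-plane flips", {
  tube <- build_tube(fix_unit(), fix_lattice(), 14, 14, -120, 120)
  p0 <- project(tube, phi = 0, apix = 6, box = 96)
  p1 <- project(tube, phi = 360 / 14, apix = 6, box = 96)
  expect_lt(max(abs(p0$data - p1$data)) / max(abs(p0$data)), 1e-9)
  ## psi = 180 equals the doubly flipped image (flip about the image
  ## origin at pixel n/2 + 1, i.e. index i -> 2 (n/2 + 1) - i)
  pa <- project(tube, phi = 20, psi = 180, apix = 6, box = 96)
  pb <- project(tube, phi = 20, psi = 0, apix = 6, box = 96)
  expect_lt(max(abs(pa$data[2:96, 2:96] - pb$data[96:2, 96:2])) /
              max(abs(pb$data)), 1e-6)
})

test_that("atom-splat and volume-projection code paths agree on a toy", {
  atoms <- data.frame(x = c(10, -15, 5), y = c(0, 10, -12), z = c(8, -5, 0),
                      element = "C")
  u <- asym_unit(atoms)
  vol <- render_volume(u, apix = 2, box = 64, blob_sigma = 6)
  for (view in list(c(0, 0), c(20, 7))) {
    p1 <- project(vol, phi = view[1], psi = view[2], shift = c(3, -2))
    p2 <- project(u, phi = view[1], psi = view[2], shift = c(3, -2),
                  apix = 2, box = 64, blob_sigma = 6)
    expect_lt(rms(p1$data - p2$data) / rms(p2$data), 0.02)
  }
})

test_that("band limiting is idempotent, Nyquist-safe and rejects sub-Nyquist requests", {
  img <- project(build_tube(fix_unit(), fix_lattice(), 14, 14, -120, 120),
                 apix = 5, box = 64)
  b1 <- band_limit(img, 15)
  b2 <- band_limit(b1, 15)
  expect_equal(b2$data, b1$data, tolerance = 1e-12)
  ## an already radially band-limited image passes Nyquist filtering intact
  nyq <- band_limit(band_limit(img, 10), 10)   # 10 A = 2 * apix
  expect_equal(nyq$data, band_limit(img, 10)$data, tolerance = 1e-12)
  expect_error(band_limit(img, 8), "Nyquist")
})

test_that("noise injection is seeded, reproducible and hits the requested snr", {
  img <- band_limit(project(build_tube(fix_unit(), fix_lattice(), 14, 14,
                                       -370, 370),
                            apix = 5, box = 128), 12)
  n1 <- add_noise(img, 0.3, seed = 99)
  n2 <- add_noise(img, 0.3, seed = 99)
  expect_identical(n1$data, n2$data)
  n3 <- add_noise(img, 0.3, seed = 100)
  noise_a <- n1$data - img$data
  noise_b <- n3$data - img$data
  expect_lt(abs(stats::cor(as.vector(noise_a), as.vector(noise_b))), 0.05)
  ## measured variance ratio within 5% of the requested snr
  mask <- abs(img$data) > 0.05 * max(abs(img$data))
  snr_meas <- stats::var(img$data[mask]) / stats::var(as.vector(noise_a))
  expect_lt(abs(snr_meas - 0.3) / 0.3, 0.05)
  expect_error(add_noise(img, -1, 1), "> 0")
})

test_that("power spectra satisfy Parseval and point symmetry", {
  img <- project(build_tube(fix_unit(), fix_lattice(), 14, 14, -120, 120),
                 apix = 5, box = 64)
  ps <- power_spectrum(img)
  expect_equal(sum(ps$data), sum(img$data^2), tolerance = 1e-9)
  ## real input: spectrum is symmetric under point reflection about the origin
  n <- 64; cN <- n / 2 + 1
  for (k in list(c(3, 7), c(-11, 2), c(9, -13))) {
    expect_equal(ps$data[cN + k[1], cN + k[2]],
                 ps$data[cN - k[1], cN - k[2]], tolerance = 1e-9)
  }
  expect_error(average_power_spectrum(tw_stack(list(), 5)), "empty")
})

test_that("the tube rise prints a layer line at the expected spatial frequency", {
  ## rise 43.86 A in a 128 px / 5 A image: meridional peak at bin
  ## round(640 / 43.86) = 15 from the center
  tube <- build_tube(fix_unit(), fix_lattice(), 14, 14, -370, 370)
  st <- tw_stack(purrr::map(c(0, 5, 10, 15), function(ph)
    project(tube, phi = ph, apix = 5, box = 128)$data), 5)
  aps <- average_power_spectrum(st)
  cN <- 65
  ## meridian: axial frequency axis (image columns hold z)
  merid <- colSums(aps$data[(cN - 3):(cN + 3), ])
  search <- 5:30
  peak <- search[which.max(merid[cN + search])]
  expect_identical(peak, as.integer(round(128 * 5 / 43.86)))
})

test_that("average power spectrum is the mean of the per-image spectra", {
  set.seed(5)
  ims <- purrr::map(1:3, ~ matrix(stats::rnorm(32 * 32), 32))
  st <- tw_stack(ims, 4)
  aps <- average_power_spectrum(st)
  manual <- (power_spectrum(tw_image(ims[[1]], 4))$data +
               power_spectrum(tw_image(ims[[2]], 4))$data +
               power_spectrum(tw_image(ims[[3]], 4))$data) / 3
  expect_equal(aps$data, manual, tolerance = 1e-12)
})
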