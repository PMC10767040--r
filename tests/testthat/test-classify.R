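test_that("bank construction enumerates (wrapping x scale) entries with composed projections", {
  par <- bank_params(apix = 5, box = 64, shift_max = 6, mask_radius = 150)
  bank <- build_reference_bank(fix_unit(), fix_lattice(),
                               list(c(14, 14), c(13, 14), c(6, 13)),
                               scales = c(1, 1.04), params = par)
  expect_identical(length(bank$entries), 6L)
  expect_identical(names(bank$entries), sort(names(bank$entries)))
  ## entry projection at its first azimuth equals project() + band_limit()
  e <- bank$entries[["(14,14)@1.00"]]
  tube <- build_tube(fix_unit(), fix_lattice(), 14, 14,
                     -64 * 5 / 2 - par$tube_pad, 64 * 5 / 2 + par$tube_pad)
  direct <- band_limit(project(tube, phi = e$phi[1], apix = 5, box = 64,
                               blob_sigma = par$blob_sigma),
                       par$resolution)
  expect_equal(e$projections[[1]], direct$data, tolerance = 1e-12)
  ## flattened entries sample the flattening-axis orientation more densely
  expect_gt(length(bank$entries[["(14,14)@1.04"]]$phi),
            length(bank$entries[["(14,14)@1.00"]]$phi))
  expect_error(build_reference_bank(fix_unit(), fix_lattice(), list(),
                                    params = par), "non-empty")
  expect_error(build_reference_bank(fix_unit(), fix_lattice(),
                                    list(c(14, 14)), scales = 0.95,
                                    params = par), ">= 1")
})

test_that("a reference's own projection aligns to itself with a near-perfect score", {
  bank <- fix_small_bank()
  key <- names(bank$entries)[2]
  e <- bank$entries[[key]]
  seg <- tw_image(e$projections[[min(2, length(e$phi))]], 5)
  r <- align_and_score(seg, bank, key, mode = "exhaustive")
  expect_gte(r$score, 0.999)
  expect_equal(r$phi, e$phi[min(2, length(e$phi))])
  expect_identical(c(r$dx, r$dy), c(0L, 0L))
  ## and it beats the wrong-symmetry entry
  other <- setdiff(names(bank$entries), key)[1]
  r2 <- align_and_score(seg, bank, other, mode = "exhaustive")
  expect_gt(r$score, r2$score + 0.2)
})

test_that("the FFT scoring equals the brute-force masked correlation oracle", {
  bank <- fix_small_bank()
  key <- names(bank$entries)[1]
  ## a noisy segment off the reference grid
  tube <- build_tube(fix_unit(), fix_lattice(), 14, 14,
                     -160 - 50, 160 + 50)
  seg <- add_noise(band_limit(project(tube, phi = 3.7, psi = 0,
                                      shift = c(7, -9), apix = 5, box = 64),
                              12), 0.5, seed = 17)
  r <- align_and_score(seg, bank, key, psi_grid = 0, mode = "exhaustive")
  ## oracle: explicit loops over every projection and shift of the same
  ## grid; the score contract compares at the bank's resolution limit, so
  ## the oracle sees the band-limited segment
  seg_bl <- band_limit(seg, bank$params$resolution)$data
  e <- bank$entries[[key]]
  best <- list(score = -Inf)
  for (p in seq_along(e$phi)) {
    o <- oracle_masked_ncc(seg_bl, e$projections[[p]], bank$mask,
                           bank$params$shift_max)
    if (o$score > best$score) best <- c(o, list(phi = e$phi[p]))
  }
  expect_equal(r$score, best$score, tolerance = 1e-10)
  expect_equal(r$phi, best$phi)
  expect_identical(c(r$dx, r$dy), c(best$dx, best$dy))
})

test_that("scores against pure noise are small", {
  bank <- fix_small_bank()
  key <- names(bank$entries)[1]
  n_mask <- sum(bank$mask)
  scores <- purrr::map_dbl(1:20, function(s) {
    noise <- tw_image(withr::with_seed(1000 + s, matrix(stats::rnorm(64^2), 64)), 5)
    ## single-pose evaluation: no max-over-grid inflation
    prepped <- align_and_score(noise, bank, key, psi_grid = 0,
                               mode = "exhaustive")
    prepped$score
  })
  ## max over the search grid inflates the null; the single largest scores
  ## stay an order of magnitude below a genuine match
  expect_lt(stats::median(abs(scores)), 3 / sqrt(n_mask) * 3)
  expect_lt(max(abs(scores)), 0.2)
})

test_that("zero-noise segments from bank entries classify perfectly with positive margins", {
  bank <- fix_small_bank()
  segs <- list(bank$entries[[1]]$projections[[1]],
               bank$entries[[1]]$projections[[3]],
               bank$entries[[2]]$projections[[1]])
  truth <- c(names(bank$entries)[1], names(bank$entries)[1],
             names(bank$entries)[2])
  st <- tw_stack(segs, 5)
  cl <- classify(st, bank, mode = "exhaustive")
  got <- sprintf("(%d,%d)@%.2f", cl$n1, cl$n2, cl$scale)
  expect_identical(got, truth)
  expect_true(all(cl$margin > 0.1))
  expect_true(all(cl$score >= 0.999))
})

test_that("two-stage search matches exhaustive search on self segments", {
  bank <- fix_small_bank()
  st <- tw_stack(list(bank$entries[[1]]$projections[[2]],
                      bank$entries[[2]]$projections[[4]]), 5)
  c1 <- classify(st, bank, mode = "exhaustive")
  c2 <- classify(st, bank, mode = "two_stage")
  expect_identical(c1$n1, c2$n1)
  expect_identical(c1$n2, c2$n2)
  expect_equal(c1$score, c2$score, tolerance = 1e-9)
})

test_that("in-plane rotated segments are recovered through the psi search", {
  bank <- fix_small_bank()
  key <- names(bank$entries)[1]
  seg <- rotate_image(tw_image(bank$entries[[key]]$projections[[1]], 5), 4)
  r <- align_and_score(seg, bank, key, psi_grid = c(-4, 0, 4),
                       mode = "exhaustive")
  expect_equal(r$psi, 4)
  expect_gt(r$score, 0.97)   # bilinear interpolation costs a little
})

test_that("ties break to the lexicographically first bank key", {
  bank <- fix_small_bank()
  ## graft a duplicate of the first entry under a later-sorting key
  dup <- bank$entries[[1]]
  dup$key <- "(99,99)@1.00"
  bank2 <- bank
  bank2$entries[["(99,99)@1.00"]] <- dup
  bank2$entries <- bank2$entries[order(names(bank2$entries))]
  bank2$cache <- new.env(parent = emptyenv())
  st <- tw_stack(list(bank$entries[[1]]$projections[[1]]), 5)
  cl <- classify(st, bank2, mode = "exhaustive")
  expect_identical(cl$n1[1], bank$entries[[1]]$n1)
  expect_equal(cl$margin[1], 0, tolerance = 1e-12)
})

test_that("summaries conserve probability and expose the modal class", {
  bank <- fix_small_bank()
  st <- tw_stack(list(bank$entries[[1]]$projections[[1]],
                      bank$entries[[1]]$projections[[2]],
                      bank$entries[[2]]$projections[[1]]), 5)
  cl <- classify(st, bank, mode = "exhaustive")
  sm <- summarize_assignments(cl)
  expect_equal(sum(sm$lattice$fraction), 1, tolerance = 1e-12)
  fl <- sm$flattening |> dplyr::group_by(n1, n2) |>
    dplyr::summarise(s = sum(fraction), .groups = "drop")
  expect_equal(fl$s, rep(1, nrow(fl)), tolerance = 1e-12)
  g <- glance(cl)
  expect_identical(g$n_segments, 3L)
  expect_equal(g$top_fraction, 2 / 3, tolerance = 1e-12)
  td <- tidy(cl)
  expect_false(inherits(td, "tube_classification"))
  expect_identical(nrow(td), 3L)
  ## single-class degenerate summary
  sm1 <- summarize_assignments(cl[cl$n1 == cl$n1[1] & cl$n2 == cl$n2[1], ])
  expect_identical(nrow(sm1$lattice), 1L)
  expect_equal(sm1$lattice$fraction, 1)
})

test_that("segment/bank mismatches are rejected", {
  bank <- fix_small_bank()
  expect_error(align_and_score(tw_image(matrix(0, 32, 32), 5), bank,
                               names(bank$entries)[1]), "box size")
  expect_error(align_and_score(tw_image(matrix(0, 64, 64), 4), bank,
                               names(bank$entries)[1]), "pixel size")
  expect_error(align_and_score(tw_image(matrix(0, 64, 64), 5), bank,
                               "nope"), "unknown entry")
  expect_error(classify(tw_stack(list(), 5), bank), "empty")
})

test_that("segment power spectra match their assigned reference's spectrum best", {
  ## mirrors the method's verification step: compare the averaged power
  ## spectrum of segments with the averaged spectra of each entry's
  ## projections; the true entry must fit best
  bank <- fix_small_bank()
  apix <- bank$params$apix
  for (true_key in names(bank$entries)) {
    e <- bank$entries[[true_key]]
    take <- unique(round(seq(1, length(e$phi), length.out = 4)))
    seg_aps <- average_power_spectrum(
      tw_stack(e$projections[take], apix))$data
    fits <- purrr::map_dbl(names(bank$entries), function(k) {
      pr <- bank$entries[[k]]$projections
      ref_aps <- average_power_spectrum(tw_stack(pr, apix))$data
      stats::cor(as.vector(seg_aps), as.vector(ref_aps))
    })
    expect_identical(names(bank$entries)[which.max(fits)], true_key)
  }
})
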