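test_that("gridding PSF matches the direct DFT oracle", {
  ro <- ro_small()
  s <- raga_scheme(1, 7)      # 13 spokes
  tr <- raga_trajectory(s, 13, ro)
  p_fft <- psf(tr, grid_size = 64)
  p_dir <- psf(tr, grid_size = 64, method = "direct")
  ctr <- p_dir$grid[33, 33]
  expect_lt(max(abs(p_fft$grid - p_dir$grid)) / ctr, 1e-3)
  # smaller windows as well
  for (w in list(1:5, 3:9)) {
    pf <- psf(tr, spokes = w, grid_size = 64)
    pd <- psf(tr, spokes = w, grid_size = 64, method = "direct")
    expect_lt(max(abs(pf$grid - pd$grid)) / pd$grid[33, 33], 1e-3)
  }
})

test_that("PSF center equals the number of samples", {
  ro <- ro_small()
  tr <- equidistant_trajectory(7, ro)
  p <- psf(tr, grid_size = 64, method = "direct")
  expect_equal(p$grid[p$center[1], p$center[2]], 7 * ro$n_samples)
  expect_equal(p$n_samples, 7 * ro$n_samples)
})

test_that("a single spoke gives a unit-SPR ridge through the center", {
  ro <- ro_small()
  tr <- equidistant_trajectory(1, ro)   # spoke along kx
  p <- psf(tr, grid_size = 64, method = "direct")
  ctr <- p$grid[33, 33]
  # the ridge runs perpendicular to the spoke: along y at x = 0
  expect_equal(p$grid[33, ], rep(ctr, 64))
  expect_equal(spr(p), 1)
})

test_that("SPR of a discrete delta is zero and errors are raised sensibly", {
  delta <- matrix(0, 32, 32)
  delta[17, 17] <- 1
  pm <- structure(list(grid = delta, grid_size = 32, center = c(17, 17),
                       n_samples = 1), class = "psf_map")
  expect_identical(spr(pm), 0)
  expect_error(spr(pm, exclusion_radius = 100), "whole grid")
  expect_error(psf(equidistant_trajectory(3, ro_tiny()), spokes = integer(0)),
               "empty")
})

test_that("SPR is invariant under global rotation and data scaling", {
  ro <- ro_small()
  s <- raga_scheme(1, 6)   # 8 spokes
  tr <- raga_trajectory(s, 8, ro)
  p0 <- psf(tr, grid_size = 48, method = "direct")
  # rotate all spokes by 90 degrees: pixels map to pixels
  tr90 <- tr
  tr90$coords <- array(c(-tr$coords[, , 2], tr$coords[, , 1]),
                       dim = dim(tr$coords))
  p90 <- psf(tr90, grid_size = 48, method = "direct")
  expect_lt(abs(spr(p0) - spr(p90)), 1e-6)
  # normalization independence: scaling all samples cancels in the ratio
  pm <- p0
  pm$grid <- 7.3 * pm$grid
  expect_equal(spr(pm), spr(p0))
})

test_that("RAGA full frame and equidistant frame have exactly equal SPR", {
  ro <- ro_small()
  s <- raga_scheme(1, 7)
  trR <- raga_trajectory(s, 13, ro)
  trE <- equidistant_trajectory(13, ro)
  pR <- psf(trR, grid_size = 64)
  pE <- psf(trE, grid_size = 64)
  expect_identical(pR$grid, pE$grid)   # same sample multiset, fixed order
  expect_identical(spr(pR), spr(pE))
})

test_that("equidistant patterns beat golden windows at small odd sizes", {
  ro <- ro_small()
  g <- golden_trajectory(1, 40, ro)
  for (sz in c(5, 9, 15)) {
    p_eq <- spr(psf(equidistant_trajectory(sz, ro), grid_size = 64))
    sw <- sliding_window_spr(g, window_sizes = sz, total_spokes = 40,
                             readout = ro, grid_size = 64, max_windows = 8)
    expect_lte(p_eq, min(sw$spr) + 1e-9)
  }
})

test_that("sliding-window sweep returns one SPR per window start", {
  ro <- ro_small()
  s <- raga_scheme(1, 7)
  sw <- sliding_window_spr(s, window_sizes = c(5, 8), total_spokes = 13,
                           readout = ro, grid_size = 64)
  expect_identical(nrow(sw[sw$window_size == 5, ]), 9L)
  expect_identical(nrow(sw[sw$window_size == 8, ]), 6L)
  m <- max_spr(sw)
  expect_identical(m$window_size, c(5, 8))
  expect_true(all(m$max_spr > 0))
  agg <- as.numeric(tapply(sw$spr, sw$window_size, max))
  expect_equal(agg, m$max_spr)
})
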