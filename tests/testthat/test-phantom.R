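test_that("analytic k-space at DC equals the phantom integral", {
  ph <- shepp_logan()
  ro <- ro_small()
  tr <- equidistant_trajectory(3, ro)
  kd <- analytic_kspace(ph, tr)
  i0 <- which(ro$radii == 0)
  expect_equal(Re(kd$samples[, i0]), rep(phantom_integral(ph), 3))
  expect_equal(Im(kd$samples[, i0]), rep(0, 3))
  # cross-check against a rasterized integral
  raster <- rasterize_phantom(ph, 512)
  expect_equal(sum(raster) / 512^2, phantom_integral(ph), tolerance = 1e-3)
})

test_that("noiseless k-space is conjugate-symmetric", {
  ph <- shepp_logan()
  ro <- ro_small()
  tr <- equidistant_trajectory(5, ro)
  kd <- analytic_kspace(ph, tr)
  # within one spoke, sample j and its mirror sit at +-k
  n <- ro$n_samples
  for (sp in 1:5) {
    a <- kd$samples[sp, 2:(n / 2)]
    b <- kd$samples[sp, n:(n / 2 + 2)]
    expect_equal(a, Conj(b), tolerance = 1e-12)
  }
})

test_that("a centered disc has a radially symmetric magnitude", {
  disc <- data.frame(x = 0, y = 0, a = 0.2, b = 0.2, phi_deg = 0, A = 1)
  ro <- ro_small()
  tr <- equidistant_trajectory(9, ro)
  kd <- analytic_kspace(disc, tr)
  mags <- Mod(kd$samples)
  for (sp in 2:9) expect_equal(mags[sp, ], mags[1, ], tolerance = 1e-12)
})

test_that("noise is reproducible under a seed and absent by default", {
  ph <- shepp_logan()
  tr <- equidistant_trajectory(3, ro_tiny())
  k0 <- analytic_kspace(ph, tr)
  k1 <- analytic_kspace(ph, tr, noise_sd = 0.01, seed = 11)
  k2 <- analytic_kspace(ph, tr, noise_sd = 0.01, seed = 11)
  expect_identical(k1$samples, k2$samples)
  expect_false(identical(k0$samples, k1$samples))
  expect_error(analytic_kspace(ph, tr, noise_sd = 0.01), "seed")
})

test_that("adjoint reconstruction: gridding matches the direct oracle", {
  ph <- shepp_logan()
  ro <- ro_small()
  s <- raga_scheme(1, 10)    # 55 spokes
  tr <- raga_trajectory(s, 55, ro)
  kd <- analytic_kspace(ph, tr)
  r_fft <- adjoint_reconstruct(kd, grid_size = 64)
  r_dir <- adjoint_reconstruct(kd, grid_size = 64, method = "direct")
  expect_lt(max(abs(r_fft$image - r_dir$image)) / max(r_dir$image), 1e-3)
})

test_that("reconstruction is linear in the data", {
  ph <- shepp_logan()
  disc <- data.frame(x = 0.1, y = -0.05, a = 0.15, b = 0.1, phi_deg = 30,
                     A = 0.5)
  ro <- ro_small()
  tr <- equidistant_trajectory(21, ro)
  k1 <- analytic_kspace(ph, tr)
  k2 <- analytic_kspace(disc, tr)
  r1 <- adjoint_reconstruct(k1, grid_size = 32)$complex_image
  r2 <- adjoint_reconstruct(k2, grid_size = 32)$complex_image
  rsum <- adjoint_reconstruct(k1$samples + k2$samples, tr,
                              grid_size = 32)$complex_image
  expect_equal(rsum, r1 + r2, tolerance = 1e-10)
})

test_that("reconstructed energy scales linearly with the sample count", {
  # doubling the spokes of an equidistant frame doubles the raw adjoint
  # energy of the (density-compensated) unit data once weights are held fixed
  ro <- ro_small()
  tr1 <- equidistant_trajectory(16, ro)
  tr2 <- equidistant_trajectory(32, ro)
  p1 <- psf(tr1, grid_size = 32, method = "direct")
  p2 <- psf(tr2, grid_size = 32, method = "direct")
  expect_equal(p2$grid[17, 17] / p1$grid[17, 17], 2)
})

test_that("full-frame RAGA and equidistant reconstructions are identical", {
  ph <- shepp_logan()
  ro <- ro_small()
  s <- raga_scheme(1, 11)     # S = 89 fulfills Nyquist for m = 32 (51)
  trR <- raga_trajectory(s, 89, ro)
  trE <- equidistant_trajectory(89, ro)
  rR <- adjoint_reconstruct(analytic_kspace(ph, trR))
  rE <- adjoint_reconstruct(analytic_kspace(ph, trE))
  expect_lt(max(abs(rR$image - rE$image)) / max(rE$image), 1e-6)
})

test_that("reconstruction error shrinks as spokes approach the Nyquist count", {
  ph <- shepp_logan()
  ro <- ro_small()
  s <- raga_scheme(1, 11)
  gt <- rasterize_phantom(ph, 32)
  errs <- vapply(c(22, 45, 89), function(n) {
    kd <- analytic_kspace(ph, raga_trajectory(s, n, ro))
    nrmse(adjoint_reconstruct(kd)$image, gt)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("PSF sharing: periodic schemes reuse a handful of patterns", {
  s <- raga_scheme(2, 13)
  out <- psf_sharing_demo(s, 29, 100)
  expect_identical(out$n_distinct_psfs, 13)
  expect_identical(out$golden_equivalent, 100)
  out2 <- psf_sharing_demo(s, s$period, 40)
  expect_identical(out2$n_distinct_psfs, 1)
})
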