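test_that("EST handles degenerate sinograms", {
  N <- 32
  ang <- equally_sloped_angles(N, c(-79.4, 79.4))
  sino <- matrix(0, N, sum(ang$measured))
  r <- est_slice(sino, ang, est_config(n_iter = 5))
  expect_true(all(r$slice == 0))
  expect_true(all(r$error$error == 0))

  expect_error(est_slice(matrix(0, 16, 3), ang), "grid size")
})

test_that("fully determined EST is exact and matches the direct inverse", {
  N <- 64
  x <- blurred_feature_slice(N, sigma = 2.5)
  ang <- equally_sloped_angles(N)               # all 2N angles measured
  sino <- pp_consistent_sinogram(x, ang, voxel_size_nm = 1e3)
  r <- est_slice(sino, ang, est_config(n_iter = 30, record_error_every = 5))
  expect_lt(nrmse(r$slice, x), 1e-3)

  # error metric decreases and ends below its first recorded value
  expect_lte(r$error$error[nrow(r$error)], r$error$error[1])

  # on a strictly band-limited slice the constraints are inactive and EST
  # coincides with the least-squares inverse of the same measured spectrum
  xb <- gauss_blob_slice(N)
  sb <- pp_consistent_sinogram(xb, ang, voxel_size_nm = 1e3)
  rb <- est_slice(sb, ang, est_config(n_iter = 30))
  a <- esttomo:::assemble_measured(array(sb, c(N, ncol(sb), 1)), ang)
  spec <- esttomo:::new_pp_spectrum(a$mBH[, , 1], a$mBV[, , 1], N)
  direct <- ppfft2_inverse(spec, tol = 1e-12)
  expect_lt(nrmse(rb$slice, direct), 1e-6)
  expect_lt(nrmse(rb$slice, xb), 1e-6)
})

test_that("missing-wedge EST beats zero-filled direct inversion per slice", {
  N <- 64
  x <- blurred_feature_slice(N, sigma = 1.5)
  ang <- equally_sloped_angles(N, c(-79.4, 79.4))
  sino <- pp_consistent_sinogram(x, ang, voxel_size_nm = 1e3)
  r <- est_slice(sino, ang, est_config(n_iter = 150))
  zf <- ppfft2_inverse(masked_spectrum(x, ang), tol = 1e-10)
  expect_lt(nrmse(r$slice, x), nrmse(zf, x))
  expect_lt(nrmse(r$slice, x), 0.05)

  # a tight support never hurts on noiseless data
  supp <- x > 1e-3 * max(x)
  for (i in 1:2) supp <- dilate2(supp)
  rs <- est_slice(sino, ang, est_config(n_iter = 150, support = supp))
  expect_lte(nrmse(rs$slice, x), nrmse(r$slice, x) * 1.05)
})

test_that("the error metric is the normalized L1 Fourier distance", {
  N <- 16
  set.seed(6)
  x <- matrix(stats::runif(N * N), N, N)
  y <- matrix(stats::runif(N * N), N, N)
  a <- ppfft2(x); b <- ppfft2(y)
  expect_equal(error_metric(a, a), 0)
  two <- a; two$BH <- 2 * a$BH; two$BV <- 2 * a$BV
  expect_equal(error_metric(two, a), 1, tolerance = 1e-12)
  direct <- (sum(abs(a$BH - b$BH)) + sum(abs(a$BV - b$BV))) /
    (sum(abs(b$BH)) + sum(abs(b$BV)))
  expect_equal(error_metric(a, b), direct, tolerance = 1e-12)
  z <- a; z$BH[] <- 0; z$BV[] <- 0
  expect_equal(error_metric(z, z), 0)
  expect_error(error_metric(a, z), "all zero")
})

test_that("volume reconstruction stacks independent slices", {
  N <- 32
  ang <- equally_sloped_angles(N, c(-75, 75))
  z <- esttomo:::new_tilt_series(array(0, c(N, N, sum(ang$measured))), ang,
                                 1186, 50, "od")
  rec <- reconstruct_volume(z, est_config(n_iter = 2))
  expect_true(all(rec$volume$data == 0))

  noI0 <- esttomo:::new_tilt_series(array(1, c(N, N, sum(ang$measured))), ang,
                                    1186, 50, "intensity")
  expect_error(reconstruct_volume(noI0), "incident_counts")
})

test_that("R-factors flag inconsistent volumes and improve with iterations", {
  gt <- render_phantom(default_cell_phantom(32, seed = 9))
  ang <- equally_sloped_angles(32, c(-79.4, 79.4))
  sim <- simulate_tilt_series(gt, acquisition_spec(angles = ang, seed = 2))
  zero_vol <- volume3d(array(0, dim(gt$mu_below)), 50)
  rf0 <- rfactor_projections(zero_vol, sim$below)
  expect_equal(rf0$rfactor, rep(1, nrow(rf0)))

  rec10 <- reconstruct_volume(sim$below, est_config(n_iter = 10))
  rec300 <- reconstruct_volume(sim$below, est_config(n_iter = 300))
  r10 <- mean(rfactor_projections(rec10, sim$below)$rfactor)
  r300 <- mean(rfactor_projections(rec300, sim$below)$rfactor)
  expect_lt(r300, r10)
})

test_that("Fourier shell correlation measures agreement by frequency", {
  gt <- render_phantom(default_cell_phantom(32, seed = 9))
  v <- volume3d(gt$mu_below, 50)
  r <- fsc_resolution(v, v)
  expect_true(all(abs(r$curve$fsc - 1) < 1e-12))
  expect_equal(r$resolution_nm, 100)        # Nyquist: two voxels

  # independent white noise decorrelates beyond DC
  set.seed(10)
  n1 <- array(stats::rnorm(32^3), rep(32, 3))
  n2 <- array(stats::rnorm(32^3), rep(32, 3))
  rn <- fsc_resolution(n1, n2, voxel_size_nm = 50)
  sh <- rn$curve[rn$curve$shell > 0, ]
  expect_gte(mean(abs(sh$fsc) < 3 / sqrt(sh$n)), 0.9)

  # shared band-limited signal: crossing lands at the imposed cutoff
  cut <- 6
  f <- c(0:16, 15:1) / 32
  H <- (sqrt(outer(outer(f^2, f^2, "+"), f^2, "+")) * 32) <= cut
  sig <- Re(stats::fft(stats::fft(n1) * H, inverse = TRUE)) / 32^3
  sig <- sig / stats::sd(sig)
  a <- sig + 0.05 * array(stats::rnorm(32^3), rep(32, 3))
  b <- sig + 0.05 * array(stats::rnorm(32^3), rep(32, 3))
  rb <- fsc_resolution(a, b, voxel_size_nm = 50)
  cross <- min(rb$curve$shell[rb$curve$fsc < 0.5 & rb$curve$shell > 0])
  expect_lte(abs(cross - cut), 1)
  expect_error(fsc_resolution(n1, array(0, rep(16, 3))), "grid")
})
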