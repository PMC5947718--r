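test_that("volume registration recovers known shifts to subvoxel accuracy", {
  gt <- render_phantom(default_cell_phantom(48, seed = 6))
  v <- volume3d(gt$mu_below, 50)
  r0 <- register_volumes(v, v)
  expect_equal(r0$shift, c(0, 0, 0), tolerance = 1e-6)

  sh <- c(3, -2, 1)
  moved <- volume3d(esttomo:::fourier_shift3(gt$mu_below, sh), 50)
  r <- register_volumes(moved, v)
  expect_lt(max(abs(r$shift + sh)), 0.25)
  expect_lt(nrmse(r$above$data, v$data), 0.02)

  # the element signal itself does not drag registration around
  va <- volume3d(gt$mu_above, 50)
  rg <- register_volumes(va, v)
  expect_lt(max(abs(rg$shift)), 0.5)

  expect_error(register_volumes(volume3d(array(0, rep(16, 3)), 50),
                                volume3d(array(0, rep(16, 3)), 50)),
               "all-zero")
})

test_that("difference maps isolate and scale with the element", {
  gt1 <- render_phantom(default_cell_phantom(48, seed = 6,
                                             gd_density_g_cm3 = 1))
  gt2 <- render_phantom(default_cell_phantom(48, seed = 6,
                                             gd_density_g_cm3 = 2))
  mk <- function(gt) {
    diff_map(list(above = volume3d(gt$mu_above, 50),
                  below = volume3d(gt$mu_below, 50), shift = c(0, 0, 0)),
             gt$edge)
  }
  m0 <- mk(gt1)
  expect_equal(dim(m0$delta_mu), dim(gt1$mu_below))
  expect_lt(max(abs(2 * m0$delta_mu - mk(gt2)$delta_mu)), 1e-9)

  same <- diff_map(list(above = volume3d(gt1$mu_below, 50),
                        below = volume3d(gt1$mu_below, 50)), gt1$edge)
  expect_true(all(same$delta_mu == 0))

  # difference is confined to the element neighbourhood
  far <- gt1$gd_density < 1e-6 * max(gt1$gd_density)
  for (i in 1:4) far <- far & !esttomo:::dilate_mask(!far)
  expect_lt(max(abs(m0$delta_mu[far])), 1e-3 * max(m0$delta_mu))
})

test_that("histogram thresholding separates a bimodal difference", {
  set.seed(12)
  m <- 0.2
  dm <- array(stats::rnorm(40^3, 0, m / 20), rep(40, 3))
  signal <- array(FALSE, rep(40, 3)); signal[15:25, 15:25, 15:25] <- TRUE
  dm[signal] <- stats::rnorm(sum(signal), m, m / 20)
  th <- threshold_from_histogram(dm)
  expect_gt(th$threshold, 3 * m / 20)
  expect_lt(th$threshold, m - 3 * m / 20)
  expect_lt(mean(th$mask != signal), 0.01)

  # raising the percentile never grows the mask
  t90 <- threshold_from_histogram(dm, "percentile", percentile = 90)
  t99 <- threshold_from_histogram(dm, "percentile", percentile = 99)
  expect_true(all(t99$mask <= t90$mask))

  expect_error(threshold_from_histogram(array(1, rep(8, 3))), "constant")

  # pure noise is flagged element-free
  noise <- array(stats::rnorm(30^3, 0, 1e-3), rep(30, 3))
  tn <- threshold_from_histogram(noise)
  expect_true(tn$no_element)
  expect_true(!any(tn$mask))
})

test_that("projected element masks verify against 2D differences", {
  gt <- render_phantom(default_cell_phantom(48, seed = 6))
  map <- diff_map(list(above = volume3d(gt$mu_above, 50),
                       below = volume3d(gt$mu_below, 50)), gt$edge)
  map <- threshold_from_histogram(map)
  d2 <- apply(gt$mu_above - gt$mu_below, c(1, 2), sum) * 0.05
  expect_gt(verify_threshold_projection(map, d2), 0.95)

  empty <- map
  empty$mask <- array(FALSE, dim(map$mask))
  expect_equal(verify_threshold_projection(empty, matrix(0, 48, 48)), 1)

  own <- apply(map$mask, c(1, 2), any)
  expect_equal(verify_threshold_projection(map, own), 1)
})

test_that("quantification closes on constructed densities", {
  # uniform sphere of known density
  rho <- 1.3; rad <- 8
  sph <- structure(list(
    primitives = list(esttomo:::new_primitive("sphere", c(0, 0, 0), rad, 0.2,
                                              "gd_vesicle_core",
                                              gd_density = rho)),
    grid_shape = rep(32, 3), voxel_size_nm = 50, seed = 1,
    edge = edge_constants(), band_limit_sigma_px = 0), class = "phantom_spec")
  gt <- render_phantom(sph)
  map <- threshold_from_histogram(diff_map(
    list(above = volume3d(gt$mu_above, 50), below = volume3d(gt$mu_below, 50)),
    gt$edge))
  cell <- array(TRUE, rep(32, 3))
  q <- quantify(map, cell)
  want <- rho * 4 / 3 * pi * (rad * 50 * 1e-7)^3
  expect_lt(abs(q$mass_g - want) / want, 0.05)
  expect_equal(q$volume_fraction, sum(map$mask) / length(cell))

  # empty mask: zero mass, zero fraction
  none <- map; none$mask <- array(FALSE, dim(map$mask)); none$density[] <- 0
  q0 <- quantify(none, cell)
  expect_equal(q0$mass_g, 0)
  expect_equal(q0$volume_fraction, 0)
  expect_error(quantify(map, array(FALSE, rep(32, 3))), "empty")

  # explicit unit conversion: 0.2 /um over an edge jump of 2000 cm^2/g
  # is 1e4 * 0.2 / 2000 = 1 g/cm^3
  expect_equal(esttomo:::density_from_delta_mu(0.2, 2000), 1)
  expect_equal(esttomo:::voxel_cm3(50), (50e-7)^3)
})
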