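mu_intervals <- function() {
  data.frame(name = c("vacuole", "cytoplasm", "nucleus", "lysosome"),
             mu_min = c(0.05, 0.25, 0.40, 0.80),
             mu_max = c(0.25, 0.40, 0.80, 10))
}

test_that("mu-interval segmentation partitions the cell", {
  gt <- render_phantom(default_cell_phantom(64, seed = 6))
  labs <- segment_by_mu(volume3d(gt$mu_below, 50), mu_intervals())
  # lysosome class against ground-truth labels (blurred edges allowed)
  lys_t <- gt$labels == 4L
  lys_s <- labs$labels == labs$classes$label[labs$classes$name == "lysosome"]
  expect_gt(sum(lys_t & lys_s) / sum(lys_t | lys_s), 0.6)

  # partition conservation: class volumes sum to the cell-mask volume
  cell <- labs$labels > 0
  expect_equal(sum(vapply(labs$classes$label,
                          function(l) sum(labs$labels == l), numeric(1))),
               sum(cell))

  one <- segment_by_mu(volume3d(gt$mu_below, 50),
                       data.frame(name = "cell", mu_min = 0.05, mu_max = 10))
  expect_equal(sum(one$labels == 1), sum(gt$mu_below >= 0.05))

  expect_true(all(segment_by_mu(volume3d(array(0, rep(16, 3)), 50),
                                mu_intervals())$labels == 0))
  bad <- mu_intervals(); bad$mu_min[2] <- 0.1
  expect_error(segment_by_mu(volume3d(gt$mu_below, 50), bad), "overlap")
})

test_that("component statistics recover constructed geometry", {
  sph <- structure(list(
    primitives = list(esttomo:::new_primitive("sphere", c(0, 0, 0), 8, 1,
                                              "lysosome")),
    grid_shape = rep(32, 3), voxel_size_nm = 50, seed = 1,
    edge = edge_constants(), band_limit_sigma_px = 0), class = "phantom_spec")
  gt <- render_phantom(sph)
  labs <- segment_by_mu(volume3d(gt$mu_below, 50),
                        data.frame(name = "lysosome", mu_min = 0.5, mu_max = 2))
  st <- component_stats(labs)
  expect_equal(nrow(st), 1)
  expect_lt(abs(st$diameter_nm - 2 * 8 * 50) / (2 * 8 * 50), 0.05)
  expect_equal(st$volume_um3, st$n_voxels * 0.05^3)

  empty <- component_stats(labs, classes = "absent")
  expect_equal(nrow(empty), 0)
})

test_that("rim fractions separate shell from filled element distributions", {
  mk <- function(shell) {
    prim <- if (shell) {
      esttomo:::new_primitive("spherical-shell", c(0, 0, 0), c(10, 12), 0.5,
                              "gd_vesicle_rim", gd_density = 1)
    } else {
      esttomo:::new_primitive("sphere", c(0, 0, 0), 12, 0.5,
                              "gd_vesicle_core", gd_density = 1)
    }
    # vesicle body + element distribution
    body <- esttomo:::new_primitive("sphere", c(0, 0, 0), 12, 0.5, "vacuole")
    structure(list(primitives = list(body, prim), grid_shape = rep(32, 3),
                   voxel_size_nm = 50, seed = 1, edge = edge_constants(),
                   band_limit_sigma_px = 0), class = "phantom_spec")
  }
  stats_for <- function(shell) {
    gt <- render_phantom(mk(shell))
    labs <- segment_by_mu(volume3d(gt$mu_below, 50),
                          data.frame(name = "vesicle", mu_min = 0.25,
                                     mu_max = 2))
    map <- threshold_from_histogram(diff_map(
      list(above = volume3d(gt$mu_above, 50),
           below = volume3d(gt$mu_below, 50)), gt$edge))
    component_stats(labs, element = map)
  }
  st_rim <- stats_for(TRUE)
  st_fill <- stats_for(FALSE)
  expect_gt(st_rim$rim_fraction, 0.8)
  expect_lt(st_fill$rim_fraction, 0.5)
})

test_that("vesicle typing follows size, density and rim distribution", {
  st <- data.frame(
    class = "vesicle", component = 1:3, n_voxels = c(50, 300, 2000),
    volume_um3 = c(0.006, 0.04, 0.25), diameter_nm = c(230, 420, 780),
    centroid_x = 0, centroid_y = 0, centroid_z = 0,
    mean_delta_mu = c(0.2, 0.1, 0.04), rim_fraction = c(0.3, 0.6, 0.9))
  ty <- classify_vesicles(st)
  expect_equal(ty$type, c("A", "B", "C"))

  same <- st[c(1, 1, 1), ]; same$component <- 1:3
  expect_equal(unique(classify_vesicles(same)$type), "A")

  perm <- classify_vesicles(st[c(3, 1, 2), ])
  expect_equal(perm$type, c("C", "A", "B"))
})

test_that("pipeline reports round-trip through JSON exactly", {
  q <- structure(list(mass_g = 1.234567890123e-13,
                      volume_fraction = 0.07654321098,
                      vesicle_volume_fraction = NA_real_,
                      threshold = 0.0123456789, n_mask_voxels = 2193L),
                 class = "gd_quant")
  comp <- data.frame(class = "lysosome", component = 1L, n_voxels = 57L,
                     volume_um3 = 57 * 0.05^3, diameter_nm = 238.1,
                     centroid_x = 1.5, centroid_y = 2.5, centroid_z = 3.5,
                     mean_delta_mu = 0.11, rim_fraction = 0.91)
  f <- withr::local_tempfile(fileext = ".json")
  pipeline_report(quant = q, components = comp, path = f)
  back <- read_report(f)
  expect_identical(back$schema, "esttomo-report/1")
  expect_identical(back$quant$mass_g, q$mass_g)
  expect_identical(back$quant$threshold, q$threshold)
  expect_identical(back$components$volume_um3, comp$volume_um3)

  empty <- pipeline_report()
  expect_identical(empty$schema, "esttomo-report/1")
})
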