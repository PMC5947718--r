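# Shared end-to-end fixtures (memoized): the acquisition geometry of the
# study - 64^3 grid, equally sloped angles in +-79.4 deg (117 of 128 lines,
# ~21 deg wedge), two energies, 300 EST iterations. Built once and reused
# across test files.

.fix_cache <- new.env(parent = emptyenv())

fix_get <- function(name, build) {
  if (!exists(name, envir = .fix_cache)) {
    assign(name, build(), envir = .fix_cache)
  }
  get(name, envir = .fix_cache)
}

study_angles <- function(N = 64) equally_sloped_angles(N, c(-79.4, 79.4))

fix_noiseless <- function() {
  fix_get("noiseless", function() {
    ang <- study_angles()
    gt <- render_phantom(default_cell_phantom(64, seed = 7))
    acq <- acquisition_spec(angles = ang, noise = "none", seed = 3)
    sim <- simulate_tilt_series(gt, acq, model = "pp")
    cfg <- est_config(n_iter = 300)
    list(gt = gt, sim = sim, angles = ang,
         rec_below = reconstruct_volume(sim$below, cfg),
         rec_above = reconstruct_volume(sim$above, cfg))
  })
}

fix_poisson <- function() {
  fix_get("poisson", function() {
    ang <- study_angles()
    gt <- fix_noiseless()$gt
    acq <- acquisition_spec(angles = ang, noise = "poisson",
                            incident_counts = 1e4, seed = 3)
    sim <- simulate_tilt_series(gt, acq, model = "pp")
    cfg <- est_config(n_iter = 300)
    list(gt = gt, sim = sim,
         rec_below = reconstruct_volume(sim$below, cfg),
         rec_above = reconstruct_volume(sim$above, cfg))
  })
}

# Null specimen carrying no element, imaged with Poisson noise so the two
# energy series are independent noise realizations of identical physics (the
# demanding case for the element-presence detector; noiseless null series are
# bit-identical and never reach the histogram).
fix_null <- function() {
  fix_get("null", function() {
    ang <- study_angles()
    gt <- render_phantom(default_cell_phantom(64, seed = 7,
                                              gd_density_g_cm3 = 0))
    acq <- acquisition_spec(angles = ang, noise = "poisson",
                            incident_counts = 1e4, seed = 3)
    sim <- simulate_tilt_series(gt, acq, model = "pp")
    cfg <- est_config(n_iter = 300)
    list(gt = gt, sim = sim,
         rec_below = reconstruct_volume(sim$below, cfg),
         rec_above = reconstruct_volume(sim$above, cfg))
  })
}

# Realistic forward model (rotation + bilinear ray integration), noiseless.
fix_ray <- function() {
  fix_get("ray", function() {
    ang <- study_angles()
    gt <- fix_noiseless()$gt
    acq <- acquisition_spec(angles = ang, noise = "none", seed = 3)
    sim <- simulate_tilt_series(gt, acq, model = "ray")
    list(gt = gt, sim = sim,
         rec_below = reconstruct_volume(sim$below, est_config(n_iter = 300)))
  })
}

# Dual-energy element map + quantification from a fixture, with the same
# operational definitions used on the ground truth.
fix_demap <- function(fx) {
  reg <- register_volumes(fx$rec_above$volume, fx$rec_below$volume)
  map <- threshold_from_histogram(diff_map(reg, fx$gt$edge))
  cell <- fx$rec_below$volume$data > 0.175   # half the cytoplasm mu
  list(map = map, cell = cell, quant = quantify(map, cell))
}

# Ground-truth element mask/fraction under the same histogram rule.
truth_element_fraction <- function(gt) {
  tmask <- threshold_from_histogram(gt$mu_above - gt$mu_below)$mask
  sum(tmask) / sum(gt$labels > 0)
}
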