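# Jitter recovery is assessed modulo the unidentifiable components of the COM
# method: a cos/sin sinusoid in x (a rigid object offset) and a constant in y.
shift_residual <- function(recovered, truth, theta_deg) {
  th <- theta_deg * pi / 180
  rx <- recovered[, 1] + truth[, 1]     # perfect recovery: dx = -true dx
  ry <- recovered[, 2] + truth[, 2]
  rx <- stats::lm.fit(cbind(cos(th), sin(th)), rx)$residuals
  cbind(rx, ry - mean(ry))
}

test_that("centre-of-mass alignment recovers injected jitter", {
  gt <- render_phantom(default_cell_phantom(64, seed = 7))
  ang <- study_angles()
  acq <- acquisition_spec(angles = ang, shift_jitter_px = 5, seed = 21)
  sim <- simulate_tilt_series(gt, acq)
  al <- com_align(sim$below)
  res <- shift_residual(al$result$shifts, sim$true_shifts,
                        al$result$angles_deg)
  expect_lt(sqrt(mean(res^2)), 0.5)

  # and still under 1 px with Poisson noise at 1e4 incident counts
  acqp <- acquisition_spec(angles = ang, shift_jitter_px = 5, seed = 21,
                           noise = "poisson", incident_counts = 1e4)
  simp <- simulate_tilt_series(gt, acqp)
  alp <- com_align(simp$below)
  resp <- shift_residual(alp$result$shifts, simp$true_shifts,
                         alp$result$angles_deg)
  expect_lt(sqrt(mean(resp^2)), 1)
})

test_that("alignment is a fixed point on centred series and idempotent", {
  gt <- render_phantom(default_cell_phantom(64, seed = 7))
  ang <- study_angles()
  sim <- simulate_tilt_series(gt, acquisition_spec(angles = ang, seed = 1))
  al1 <- com_align(sim$below)
  al2 <- com_align(al1$aligned)
  expect_lt(max(abs(al2$result$shifts)), 1e-6)

  # equivariance: a common translation of every projection shows up in the
  # recovered x shifts as its negative (y absorbs it into the series mean)
  shifted <- as_od(sim$below)
  for (i in seq_len(dim(shifted$data)[3])) {
    shifted$data[, , i] <- esttomo:::fourier_shift2(shifted$data[, , i], 2.5, 0)
  }
  al3 <- com_align(shifted)
  expect_equal(al3$result$shifts[, 1], al1$result$shifts[, 1] - 2.5,
               tolerance = 1e-4)
})

test_that("alignment rejects projections without mass", {
  ang <- equally_sloped_angles(16, c(-60, 60))
  dat <- array(1, c(16, 16, sum(ang$measured)))
  dat[, , 3] <- 0
  ser <- esttomo:::new_tilt_series(dat, ang, 1186, 50, "od")
  expect_error(com_align(ser), "projection 3")
})

test_that("the damage check measures projection discrepancy", {
  gt <- render_phantom(default_cell_phantom(48, seed = 4))
  a <- project_volume(gt$mu_below, 0, 50)
  expect_equal(as.numeric(damage_check(a, a)), 0)

  # constant offset: closed form once registration is a no-op (centred a)
  ac <- a - 0  # projections of the centred phantom are near-centred already
  cst <- 0.05
  r <- damage_check(ac, ac + cst)
  npx <- length(ac)
  expect_equal(as.numeric(r), cst * npx / sum(ac + cst / 2), tolerance = 0.02)

  # two Poisson realizations: discrepancy shrinks with incident counts
  set.seed(8)
  rs <- vapply(c(1e3, 1e5), function(I0) {
    i1 <- matrix(stats::rpois(length(a), I0 * exp(-a)), nrow(a))
    i2 <- matrix(stats::rpois(length(a), I0 * exp(-a)), nrow(a))
    as.numeric(damage_check(-log(pmax(i1, 1) / I0), -log(pmax(i2, 1) / I0)))
  }, numeric(1))
  expect_lt(rs[2], rs[1])
  expect_lt(rs[2], 0.05)
})
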