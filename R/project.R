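#' Ray-model projection of a volume
#'
#' Beer-Lambert line integrals of the linear absorption coefficient along the
#' beam after rotating the volume about the y tilt axis (angle measured in the
#' x-z plane, 0 degrees = beam along z). Integration steps one voxel at a time
#' with bilinear interpolation in the x-z plane; samples outside the grid are
#' zero. This is the realistic, deliberately model-mismatched projector; the
#' exact counterpart matched to the reconstruction operator is
#' [pp_consistent_sinogram()].
#'
#' @param volume 3D array `[x, y, z]` of absorption (1/um), or a `volume3d`.
#' @param angle_deg Tilt angle(s) in degrees.
#' @param voxel_size_nm Voxel edge (nm); taken from `volume` if available.
#' @return Optical-density matrix `[x, y]` (dimensionless), or a 3D array
#'   `[x, y, angle]` when several angles are given.
#' @export
project_volume <- function(volume, angle_deg, voxel_size_nm = NULL) {
  v <- as_volume_array(volume)
  if (is.null(voxel_size_nm)) voxel_size_nm <- attr_or(volume, "voxel_size_nm", 1)
  out <- cpp_project(v, angle_deg * pi / 180) * (voxel_size_nm * 1e-3)
  if (length(angle_deg) == 1L) {
    out <- out[, , 1, drop = FALSE]
    dim(out) <- dim(out)[1:2]           # keep [x, y] even when NY = 1
  }
  out
}

as_volume_array <- function(v) {
  if (inherits(v, "volume3d")) v <- v$data
  stopifnot(is.array(v), length(dim(v)) == 3)
  v
}

attr_or <- function(x, name, default) {
  if (inherits(x, "volume3d") && !is.null(x[[name]])) return(x[[name]])
  a <- attr(x, name)
  if (is.null(a)) default else a
}

#' Pseudo-polar-consistent sinogram of a slice
#'
#' Projections generated through the exact forward model of the EST
#' reconstruction: the slice's pseudo-polar spectrum is computed with
#' [ppfft2()] and each measured line is mapped back to a length-`N` real
#' projection by least squares against the fractional-transform operator of
#' [projection_to_pp_line()]. Pushing these projections forward again
#' reproduces the pseudo-polar lines up to the band-limitation residual of the
#' slice, so reconstructions from them are near-exact for band-limited slices.
#' Used by oracle tests and the `model = "pp"` simulator path.
#'
#' @param slice `N` x `N` real matrix (absorption, 1/um).
#' @param angles A `pp_angles` set for the same `N`.
#' @param voxel_size_nm Voxel edge (nm); projections are returned as optical
#'   density (`mu` times length).
#' @return Matrix `N` x `n_measured`, columns ordered as the measured rows of
#'   `angles`.
#' @export
pp_consistent_sinogram <- function(slice, angles, voxel_size_nm = 1e3) {
  slice <- check_slice(slice)
  N <- nrow(slice)
  vol <- array(slice, c(N, 1, N))
  pp_sino_volume(vol, angles, voxel_size_nm)[, 1, ]
}

# Volume version: one forward PPFFT over all slices, one QR per line.
# vol [x, y, z]; returns [N, NY, n_measured] (zero rows stay zero).
pp_sino_volume <- function(vol, angles, voxel_size_nm) {
  N <- dim(vol)[1]
  NY <- dim(vol)[2]
  stopifnot(attr(angles, "grid_size_N") == N, dim(vol)[3] == N)
  rows <- which(apply(vol != 0, 2, any))
  m <- angles[angles$measured, ]
  out <- array(0, c(N, NY, nrow(m)))
  if (length(rows) == 0) return(out)
  slices <- aperm(vol[, rows, , drop = FALSE], c(1, 3, 2))
  f <- cpp_ppfft_forward(slices)
  t_idx <- seq_len(N) - 1 - N / 2
  ks <- seq(-N, N - 1)
  for (i in seq_len(nrow(m))) {
    col <- pp_line_col(m$slope[i], N)
    Fl <- matrix(if (m$sector[i] == "BH") f$BH[, col, ] else f$BV[, col, ],
                 nrow = 2 * N)
    s <- 2 * m$slope[i] / N
    sgn <- if (pp_line_flipped(m$sector[i], m$slope[i])) -1 else 1
    C <- exp(-2i * pi * (sqrt(1 + s^2) / (2 * N)) * outer(sgn * ks, t_idx))
    out[, rows, i] <- Re(qr.coef(qr(C, LAPACK = TRUE), Fl))
  }
  out * (voxel_size_nm * 1e-3)
}

#' Acquisition descriptor for simulated tilt series
#'
#' @param energies Pair `(E_below, E_above)` in eV.
#' @param angles A `pp_angles` set (geometry of the scan).
#' @param pixel_size_nm Detector step (nm).
#' @param incident_counts Incident photons per pixel (sets Poisson noise
#'   level).
#' @param shift_jitter_px Maximum per-projection misalignment; each measured
#'   angle receives one (x, y) shift drawn uniformly in `+-shift_jitter_px`,
#'   applied identically at both energies (the stage, not the optics, drifts).
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer seed for noise and shifts.
#' @param independent_shifts If `TRUE`, draw separate shifts per energy (to
#'   stress registration); default `FALSE`.
#' @return An `acquisition_spec` list.
#' @export
acquisition_spec <- function(energies = c(1186, 1189), angles,
                             pixel_size_nm = 50, incident_counts = 1e4,
                             shift_jitter_px = 0, noise = c("none", "poisson"),
                             seed = 1, independent_shifts = FALSE) {
  noise <- match.arg(noise)
  stopifnot(length(energies) == 2, energies[2] > energies[1],
            incident_counts > 0, inherits(angles, "pp_angles"))
  structure(list(energies = energies, angles = angles,
                 pixel_size_nm = pixel_size_nm,
                 incident_counts = incident_counts,
                 shift_jitter_px = shift_jitter_px, noise = noise,
                 seed = seed, independent_shifts = independent_shifts),
            class = "acquisition_spec")
}

new_tilt_series <- function(data, angles, energy_ev, pixel_size_nm,
                            kind = c("intensity", "od"),
                            incident_counts = NA_real_,
                            true_shifts = NULL) {
  kind <- match.arg(kind)
  structure(list(data = data, angles = angles, energy_ev = energy_ev,
                 pixel_size_nm = pixel_size_nm, kind = kind,
                 incident_counts = incident_counts,
                 true_shifts = true_shifts),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Tilt series: %d x %d px, %d angles, %g eV, %s\n",
              d[1], d[2], d[3], x$energy_ev, x$kind))
  invisible(x)
}

#' Simulate a dual-energy STXM tilt series
#'
#' For every measured equally sloped angle and both energies: project the
#' ground-truth absorption volume (ray model, or the pseudo-polar-consistent
#' model for oracle runs), convert optical density to transmitted intensity
#' `I = I0 exp(-OD)`, optionally apply a common per-angle subpixel
#' misalignment (Fourier shift of the OD field), and optionally draw Poisson
#' counts. Both energies share one geometry; shifts are recorded.
#'
#' @param gt A `ground_truth` from [render_phantom()].
#' @param acq An [acquisition_spec()].
#' @param model `"ray"` (default) or `"pp"` (pseudo-polar-consistent; exact
#'   under the reconstruction operator).
#' @return List with `below` and `above` [tilt_series] (intensity
#'   representation) and `true_shifts` (n_angles x 2 matrix of (dx, dy) px).
#' @export
simulate_tilt_series <- function(gt, acq, model = c("ray", "pp")) {
  model <- match.arg(model)
  stopifnot(inherits(gt, "ground_truth"), inherits(acq, "acquisition_spec"))
  ang <- acq$angles
  m <- ang[ang$measured, ]
  if (any(m$angle_deg <= -90 | m$angle_deg > 90)) {
    stop("tilt angles must lie in (-90, 90]", call. = FALSE)
  }
  N <- dim(gt$mu_below)[1]
  set.seed(acq$seed)
  shifts <- matrix(stats::runif(2 * nrow(m), -1, 1) * acq$shift_jitter_px,
                   ncol = 2, dimnames = list(NULL, c("dx", "dy")))
  shifts2 <- if (acq$independent_shifts) {
    matrix(stats::runif(2 * nrow(m), -1, 1) * acq$shift_jitter_px, ncol = 2)
  } else shifts
  one_energy <- function(vol, sh) {
    od <- if (model == "ray") {
      project_volume(vol, m$angle_deg, gt$voxel_size_nm)
    } else {
      pp_sino_volume(vol, ang, gt$voxel_size_nm)
    }
    for (i in seq_len(nrow(m))) {
      if (any(sh[i, ] != 0)) {
        od[, , i] <- fourier_shift2(od[, , i], sh[i, 1], sh[i, 2])
      }
    }
    inten <- acq$incident_counts * exp(-od)
    if (acq$noise == "poisson") {
      inten[] <- stats::rpois(length(inten), lambda = pmax(inten, 0))
    }
    inten
  }
  below <- one_energy(gt$mu_below, shifts)
  above <- one_energy(gt$mu_above, shifts2)
  mk <- function(dat, e, sh) {
    new_tilt_series(dat, ang, e, acq$pixel_size_nm, "intensity",
                    incident_counts = acq$incident_counts, true_shifts = sh)
  }
  list(below = mk(below, acq$energies[1], shifts),
       above = mk(above, acq$energies[2], shifts2),
       true_shifts = shifts)
}

# Subpixel translation by Fourier phase ramps (periodic).
fourier_shift2 <- function(img, dx, dy) {
  n1 <- nrow(img); n2 <- ncol(img)
  f1 <- c(0:(n1 %/% 2), -((n1 - n1 %/% 2 - 1):1)) / n1
  f2 <- c(0:(n2 %/% 2), -((n2 - n2 %/% 2 - 1):1)) / n2
  if (n1 %% 2 == 0) f1[n1 %/% 2 + 1] <- abs(f1[n1 %/% 2 + 1])
  if (n2 %% 2 == 0) f2[n2 %/% 2 + 1] <- abs(f2[n2 %/% 2 + 1])
  ph <- exp(-2i * pi * (outer(f1 * dx, f2 * dy, "+")))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (n1 * n2)
}
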