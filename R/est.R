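#' 3D volume container
#'
#' @param data 3D numeric array `[x, y, z]` (linear absorption, 1/um).
#' @param voxel_size_nm Cubic voxel edge in nm.
#' @param energy_ev Photon energy tag (optional).
#' @return A `volume3d` list.
#' @export
volume3d <- function(data, voxel_size_nm, energy_ev = NA_real_) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  structure(list(data = data, voxel_size_nm = voxel_size_nm,
                 energy_ev = energy_ev),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Volume: %d x %d x %d @ %g nm/voxel%s\n", d[1], d[2], d[3],
              x$voxel_size_nm,
              if (is.finite(x$energy_ev)) sprintf(", %g eV", x$energy_ev) else ""))
  invisible(x)
}

#' EST reconstruction settings
#'
#' @param n_iter Number of constraint iterations (default 300; the error
#'   metric typically stabilizes well before that).
#' @param positivity Push negative absorption to zero each iteration.
#' @param support Optional logical mask (per slice `N` x `N`, or an
#'   `N` x `N` x `n_slices` array); density outside it is pushed to zero.
#' @param inverse_tol,inverse_max_iter Conjugate-gradient settings for the
#'   standalone inverse PPFFT used when a slice is reconstructed in one shot.
#' @param inner_cg_iter Warm-started CG steps per EST iteration (the inverse
#'   PPFFT inside the loop); 2 balances accuracy and cost.
#' @param first_cg_iter CG steps for the first EST iteration (cold start).
#' @param record_error_every Record the per-slice error metric every this many
#'   iterations (the first and last iterations are always recorded).
#' @return An `est_config` list.
#' @export
est_config <- function(n_iter = 300, positivity = TRUE, support = NULL,
                       inverse_tol = 1e-8, inverse_max_iter = 200,
                       inner_cg_iter = 2, first_cg_iter = 12,
                       record_error_every = 25) {
  stopifnot(n_iter >= 1, inner_cg_iter >= 1, first_cg_iter >= 1)
  structure(list(n_iter = as.integer(n_iter), positivity = positivity,
                 support = support, inverse_tol = inverse_tol,
                 inverse_max_iter = as.integer(inverse_max_iter),
                 inner_cg_iter = as.integer(inner_cg_iter),
                 first_cg_iter = as.integer(first_cg_iter),
                 record_error_every = as.integer(record_error_every)),
            class = "est_config")
}

# Assemble measured pseudo-polar spectra from sinograms.
# sino: array [N, n_measured, S]; angles: pp_angles. The two 45 degree lines
# are duplicated into both sectors (the BV copy of the -45 line is k-reversed)
# so Fourier replacement acts on every stored copy; the error masks keep each
# physical line once.
assemble_measured <- function(sino, angles) {
  N <- dim(sino)[1]
  S <- dim(sino)[3]
  m <- angles[angles$measured, ]
  stopifnot(dim(sino)[2] == nrow(m))
  mBH <- array(0i, c(2 * N, N + 1, S))
  mBV <- array(0i, c(2 * N, N + 1, S))
  kBH <- integer(N + 1); kBV <- integer(N + 1)
  eBH <- integer(N + 1); eBV <- integer(N + 1)
  for (i in seq_len(nrow(m))) {
    p <- matrix(sino[, i, ], nrow = N)
    L <- projection_to_pp_line(p, m$sector[i], m$slope[i], N)
    col <- pp_line_col(m$slope[i], N)
    if (m$sector[i] == "BH") {
      mBH[, col, ] <- L; kBH[col] <- 1L; eBH[col] <- 1L
      if (m$slope[i] == -N / 2) {       # shared -45 deg line, k-reversed copy
        mBV[, col, ] <- rbind(Conj(L[1, , drop = FALSE]),
                              L[(2 * N):2, , drop = FALSE])
        kBV[col] <- 1L
      }
    } else {
      mBV[, col, ] <- L; kBV[col] <- 1L; eBV[col] <- 1L
      if (m$slope[i] == N / 2) {        # shared +45 deg line, direct copy
        mBH[, col, ] <- L; kBH[col] <- 1L
      }
    }
  }
  list(mBH = mBH, mBV = mBV, kBH = kBH, kBV = kBV, eBH = eBH, eBV = eBV)
}

#' Reconstruct one slice by iterative equally sloped tomography
#'
#' Measured projections are mapped onto their pseudo-polar Fourier lines (the
#' fractional transform of [projection_to_pp_line()]); unmeasured lines start
#' at zero. Each iteration computes the least-squares inverse PPFFT of the
#' current spectrum (warm-started conjugate gradients), pushes negative
#' density and density outside the support to zero in real space, transforms
#' back, and overwrites the measured Fourier coefficients - magnitude and
#' phase - with the measured values, leaving the others free. The normalized
#' L1 error metric between calculated and measured coefficients is recorded.
#'
#' @param sinogram `N` x `n_measured` matrix of optical-density projections,
#'   columns ordered as the measured rows of `angles`.
#' @param angles A `pp_angles` set.
#' @param cfg An [est_config()].
#' @return List: `slice` (`N` x `N`, in sinogram units per voxel length;
#'   [reconstruct_volume()] rescales to 1/um), `error` (data frame
#'   `iteration`, `error`).
#' @export
est_slice <- function(sinogram, angles, cfg = est_config()) {
  N <- attr(angles, "grid_size_N")
  if (nrow(sinogram) != N) {
    stop("sinogram rows must match the angle-set grid size", call. = FALSE)
  }
  if (sum(angles$measured) == 0 || ncol(sinogram) != sum(angles$measured)) {
    stop("sinogram columns must match the measured angle count", call. = FALSE)
  }
  a <- assemble_measured(array(sinogram, c(N, ncol(sinogram), 1)), angles)
  supp <- prepare_support(cfg$support, N, 1)
  r <- cpp_est(a$mBH, a$mBV, a$kBH, a$kBV, a$eBH, a$eBV,
               cfg$n_iter, cfg$inner_cg_iter, cfg$first_cg_iter,
               cfg$positivity, supp, cfg$record_error_every)
  list(slice = r$x[, , 1, drop = TRUE],
       error = data.frame(iteration = r$error_iters,
                          error = r$error_history[, 1]))
}

prepare_support <- function(support, N, S) {
  if (is.null(support)) return(array(0, c(0, 0, 0)))
  if (is.matrix(support)) support <- array(rep(support, S), c(N, N, S))
  stopifnot(all(dim(support) == c(N, N, S)))
  array(as.double(support != 0), dim(support))
}

#' Normalized L1 error between calculated and measured Fourier coefficients
#'
#' `R_F = sum |F_calc - F_meas| / sum |F_meas|` over the measured pseudo-polar
#' lines (moduli of complex differences). Defined as 0 when both sides are
#' identically zero.
#'
#' @param calc,meas `pp_spectrum` objects sharing grid size and measured
#'   masks (the masks of `meas` are used).
#' @return Scalar.
#' @export
error_metric <- function(calc, meas) {
  calc <- check_spectrum(calc); meas <- check_spectrum(meas)
  stopifnot(calc$grid_size_N == meas$grid_size_N)
  mb <- meas$measured
  num <- sum(abs(calc$BH[, mb$BH] - meas$BH[, mb$BH])) +
    sum(abs(calc$BV[, mb$BV] - meas$BV[, mb$BV]))
  den <- sum(abs(meas$BH[, mb$BH])) + sum(abs(meas$BV[, mb$BV]))
  if (den == 0) {
    if (num == 0) return(0)
    stop("error metric undefined: measured coefficients are all zero",
         call. = FALSE)
  }
  num / den
}

#' Reconstruct a 3D volume from an aligned tilt series
#'
#' Slices perpendicular to the y tilt axis are independent in single-axis
#' geometry; each row of the (OD-converted) series is a sinogram reconstructed
#' with [est_slice()] machinery, all rows batched through one compiled call.
#'
#' @param series An aligned `tilt_series` (intensity input is converted to OD
#'   using its `incident_counts`; an error is raised if absent).
#' @param cfg An [est_config()].
#' @param rows Optional integer vector of y rows to reconstruct (defaults to
#'   all rows with any signal; rows without signal come back as zeros).
#' @return An `est_recon`: `volume` ([volume3d], 1/um), `error_history`
#'   (iterations x slices matrix), `error_iters`, `rows`, `config`, `angles`.
#' @export
reconstruct_volume <- function(series, cfg = est_config(), rows = NULL) {
  series <- as_od(series)
  dat <- series$data
  N <- dim(dat)[1]
  NY <- dim(dat)[2]
  ang <- series$angles
  stopifnot(attr(ang, "grid_size_N") == N)
  if (is.null(rows)) {
    rows <- which(apply(dat != 0, 2, any))
    if (length(rows) == 0) rows <- seq_len(NY)
  }
  sino <- aperm(dat[, rows, , drop = FALSE], c(1, 3, 2))  # [N, n_ang, S]
  a <- assemble_measured(sino, ang)
  supp <- prepare_support(cfg$support, N, length(rows))
  r <- cpp_est(a$mBH, a$mBV, a$kBH, a$kBV, a$eBH, a$eBV,
               cfg$n_iter, cfg$inner_cg_iter, cfg$first_cg_iter,
               cfg$positivity, supp, cfg$record_error_every)
  vox_um <- series$pixel_size_nm * 1e-3
  vol <- array(0, c(N, NY, N))
  for (s in seq_along(rows)) vol[, rows[s], ] <- r$x[, , s] / vox_um
  structure(list(volume = volume3d(vol, series$pixel_size_nm, series$energy_ev),
                 error_history = r$error_history,
                 error_iters = r$error_iters,
                 rows = rows, config = cfg, angles = ang),
            class = "est_recon")
}

#' @export
print.est_recon <- function(x, ...) {
  cat(sprintf("EST reconstruction: %d slices, %d iterations\n",
              length(x$rows), x$config$n_iter))
  cat(sprintf("Final error metric: mean %.4g (max %.4g) over slices\n",
              mean(x$error_history[nrow(x$error_history), ]),
              max(x$error_history[nrow(x$error_history), ])))
  print(x$volume)
  invisible(x)
}

#' Per-angle R-factor between measured and calculated projections
#'
#' Projects the reconstructed volume with the ray model at every measured
#' angle and compares with the measured optical densities:
#' `R = sum|calc - meas| / sum|meas|` per angle.
#'
#' @param recon An `est_recon` (or `volume3d`).
#' @param series The measured `tilt_series` (converted to OD as needed).
#' @return Data frame `angle_deg`, `rfactor`.
#' @export
rfactor_projections <- function(recon, series) {
  vol <- if (inherits(recon, "est_recon")) recon$volume else recon
  series <- as_od(series)
  m <- series$angles[series$angles$measured, ]
  calc <- project_volume(vol, m$angle_deg, vol$voxel_size_nm)
  if (length(m$angle_deg) == 1L) calc <- array(calc, c(dim(calc), 1))
  r <- vapply(seq_len(nrow(m)), function(i) {
    den <- sum(abs(series$data[, , i]))
    if (den == 0) return(NA_real_)
    sum(abs(calc[, , i] - series$data[, , i])) / den
  }, numeric(1))
  data.frame(angle_deg = m$angle_deg, rfactor = r)
}

#' Fourier shell correlation and resolution estimate
#'
#' Correlates two volumes shell by shell in Fourier space; the resolution is
#' reported at the first crossing of `criterion` (default 0.5), converted to a
#' real-space length via the voxel size. Identical volumes have FSC 1
#' everywhere and report the Nyquist length (two voxels). Typically applied to
#' reconstructions from even/odd angle subsets.
#'
#' @param vol_a,vol_b `volume3d` or arrays on the same grid.
#' @param criterion FSC threshold defining the resolution.
#' @param voxel_size_nm Required if inputs are bare arrays.
#' @return List: `curve` (data frame `shell`, `freq_per_nm`, `fsc`, `n`),
#'   `resolution_nm`, `criterion`.
#' @export
fsc_resolution <- function(vol_a, vol_b, criterion = 0.5,
                           voxel_size_nm = NULL) {
  a <- as_volume_array(vol_a); b <- as_volume_array(vol_b)
  if (!all(dim(a) == dim(b))) stop("volumes must share a grid", call. = FALSE)
  if (is.null(voxel_size_nm)) voxel_size_nm <- attr_or(vol_a, "voxel_size_nm", 1)
  d <- dim(a)
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  idx <- function(n) c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fr <- sqrt(outer(outer(idx(d[1])^2, idx(d[2])^2, "+"), idx(d[3])^2, "+"))
  nshell <- floor(min(d) / 2)
  shell <- pmin(floor(fr * min(d) + 0.5), nshell)
  num <- Re(tapply(Fa * Conj(Fb), shell, sum))
  den <- sqrt(tapply(abs(Fa)^2, shell, sum) * tapply(abs(Fb)^2, shell, sum))
  n <- as.integer(table(shell))
  fsc <- ifelse(den > 0, num / den, 1)
  sh <- as.integer(names(num))
  keep <- sh <= nshell
  curve <- data.frame(shell = sh[keep],
                      freq_per_nm = sh[keep] / (min(d) * voxel_size_nm),
                      fsc = as.numeric(fsc)[keep], n = n[keep])
  res <- 2 * voxel_size_nm
  below <- which(curve$fsc < criterion & curve$shell > 0)
  if (length(below) > 0) {
    j <- below[1]
    f1 <- curve$freq_per_nm[j - 1]; f2 <- curve$freq_per_nm[j]
    c1 <- curve$fsc[j - 1]; c2 <- curve$fsc[j]
    fx <- f1 + (criterion - c1) * (f2 - f1) / (c2 - c1)
    res <- 1 / fx
  }
  list(curve = curve, resolution_nm = res, criterion = criterion)
}
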