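#' Plot the EST error-metric history
#'
#' One line per reconstructed slice (normalized L1 distance between
#' calculated and measured Fourier coefficients), on a log scale.
#'
#' @param x An `est_recon`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.est_recon <- function(x, ...) {
  graphics::matplot(x$error_iters, x$error_history, type = "l", log = "y",
                    lty = 1, col = grDevices::grey(0.2, alpha = 0.25),
                    xlab = "iteration", ylab = "error metric R_F", ...)
  graphics::lines(x$error_iters, rowMeans(x$error_history), lwd = 2)
  invisible(x)
}

#' Display an absorption slice
#'
#' @param volume `volume3d` or 3D array.
#' @param y Row (slice index along the tilt axis) to display; defaults to the
#'   middle.
#' @param ... Passed to [graphics::image()].
#' @export
plot_slice <- function(volume, y = NULL, ...) {
  v <- as_volume_array(volume)
  if (is.null(y)) y <- dim(v)[2] %/% 2
  sl <- v[, y, ]
  graphics::image(seq_len(nrow(sl)), seq_len(ncol(sl)), sl, asp = 1,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "x (voxel)", ylab = "z (voxel)", ...)
  invisible(volume)
}

#' Plot a Fourier shell correlation curve
#'
#' @param fsc Result of [fsc_resolution()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_fsc <- function(fsc, ...) {
  graphics::plot(fsc$curve$freq_per_nm, fsc$curve$fsc, type = "l",
                 ylim = c(min(0, min(fsc$curve$fsc)), 1),
                 xlab = "spatial frequency (1/nm)", ylab = "FSC", ...)
  graphics::abline(h = fsc$criterion, lty = 2)
  graphics::mtext(sprintf("resolution %.1f nm", fsc$resolution_nm), line = 0.2)
  invisible(fsc)
}
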