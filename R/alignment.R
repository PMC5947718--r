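#' Convert a tilt series to optical density
#'
#' `OD = -log(I / I0)` with `I0` the incident counts from the series metadata.
#' Non-positive counts (possible under Poisson noise) are clamped to the
#' smallest positive count, 1, with a message.
#'
#' @param series A `tilt_series`.
#' @return The series with `kind = "od"`.
#' @export
as_od <- function(series) {
  stopifnot(inherits(series, "tilt_series"))
  if (series$kind == "od") return(series)
  if (!is.finite(series$incident_counts)) {
    stop("intensity series has no incident_counts metadata; cannot form OD",
         call. = FALSE)
  }
  dat <- series$data
  nbad <- sum(dat <= 0)
  if (nbad > 0) {
    message(sprintf("as_od: clamped %d non-positive counts to 1", nbad))
    dat[dat <= 0] <- 1
  }
  series$data <- -log(dat / series$incident_counts)
  series$kind <- "od"
  series
}

#' Centre-of-mass tilt-series alignment
#'
#' Projections of the same object at different tilts share one consistency
#' rule: the centre of mass along the tilt axis (y) is tilt-invariant, and the
#' centre of mass across it (x) of the rotating object follows
#' `x_com(theta) = cx cos(theta) + cz sin(theta)`. Each projection is shifted
#' (subpixel, Fourier phase ramps) so its y centre of mass equals the series
#' mean and its x centre of mass lands on the rotation axis, i.e. the fitted
#' sinusoid re-centred at `cx = cz = 0`. The component of per-projection
#' jitter that itself forms a `cos/sin` sinusoid is indistinguishable from a
#' global object offset and is absorbed into `(cx, cz)`; recovered shifts are
#' therefore defined up to that two-parameter family (plus a common y offset).
#'
#' Masses are computed on optical density with negative values floored at
#' zero. A free margin of at least the jitter magnitude must exist at the
#' projection edges (Fourier shifts are periodic).
#'
#' @param series A `tilt_series` in OD representation (intensity input is
#'   converted via [as_od()]).
#' @return List with `aligned` (the shifted series) and `result`, an
#'   `alignment_result` holding per-projection `shifts` (dx, dy), the fitted
#'   trajectory parameters `cx`, `cz`, and per-angle sinusoid `residuals`.
#' @export
com_align <- function(series) {
  series <- as_od(series)
  dat <- series$data
  na <- dim(dat)[3]
  if (na < 3) stop("need at least 3 projections to align", call. = FALSE)
  n1 <- dim(dat)[1]; n2 <- dim(dat)[2]
  xs <- seq_len(n1) - 1 - n1 / 2
  ys <- seq_len(n2) - 1 - n2 / 2
  com_of <- function(d) {
    com <- matrix(0, na, 2)
    for (i in seq_len(na)) {
      w <- pmax(d[, , i], 0)
      m <- sum(w)
      if (m <= 0) {
        stop(sprintf("projection %d has non-positive total mass", i),
             call. = FALSE)
      }
      com[i, 1] <- sum(xs * rowSums(w)) / m
      com[i, 2] <- sum(ys * colSums(w)) / m
    }
    com
  }
  th <- series$angles$angle_deg[series$angles$measured] * pi / 180
  stopifnot(length(th) == na)
  com <- com_of(dat)
  fit <- stats::lm.fit(cbind(cos(th), sin(th)), com[, 1])
  cxz <- fit$coefficients
  ybar <- mean(com[, 2])
  # the shift is a fixed-point target (COM on the axis); interpolation of the
  # shifted images perturbs the mass slightly, so iterate the correction,
  # always shifting the original data once by the accumulated amount
  dx <- -com[, 1]
  dy <- ybar - com[, 2]
  out <- dat
  for (pass in 1:6) {
    for (i in seq_len(na)) {
      out[, , i] <- fourier_shift2(dat[, , i], dx[i], dy[i])
    }
    cnew <- com_of(out)
    corr <- cbind(-cnew[, 1], ybar - cnew[, 2])
    if (max(abs(corr)) < 1e-8) break
    dx <- dx + corr[, 1]
    dy <- dy + corr[, 2]
  }
  aligned <- series
  aligned$data <- out
  res <- structure(list(shifts = cbind(dx = dx, dy = dy),
                        cx = unname(cxz[1]), cz = unname(cxz[2]),
                        residuals = unname(fit$residuals),
                        angles_deg = th * 180 / pi),
                   class = "alignment_result")
  list(aligned = aligned, result = res)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("COM alignment: %d projections, |shift| max %.3f px, cx %.3f, cz %.3f\n",
              nrow(x$shifts), max(abs(x$shifts)), x$cx, x$cz))
  invisible(x)
}

#' Radiation-damage check between two projections
#'
#' R-factor between projections taken at the same angle before and after the
#' full acquisition: `R = sum|a - b| / sum|(a + b)/2|`, after registering `b`
#' to `a` by their centre-of-mass offset. Identical projections give 0; values
#' rising with dose indicate structural change.
#'
#' @param proj_before,proj_after Matrices of identical shape (OD).
#' @return Scalar R-factor (attribute `shift` carries the registration shift).
#' @export
damage_check <- function(proj_before, proj_after) {
  if (!all(dim(proj_before) == dim(proj_after))) {
    stop("projections must have the same shape", call. = FALSE)
  }
  com2 <- function(w) {
    w <- pmax(w, 0)
    m <- sum(w)
    if (m <= 0) return(c(0, 0))
    n1 <- nrow(w); n2 <- ncol(w)
    c(sum((seq_len(n1) - 1 - n1 / 2) * rowSums(w)),
      sum((seq_len(n2) - 1 - n2 / 2) * colSums(w))) / m
  }
  d <- com2(proj_before) - com2(proj_after)
  b <- if (any(d != 0)) fourier_shift2(proj_after, d[1], d[2]) else proj_after
  denom <- sum(abs((proj_before + b) / 2))
  r <- if (denom == 0) 0 else sum(abs(proj_before - b)) / denom
  structure(r, shift = d)
}
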