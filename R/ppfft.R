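#' Pseudo-polar fast Fourier transform of a 2D slice
#'
#' Evaluates the discrete Fourier transform of an `N` x `N` real slice exactly
#' (to floating tolerance) on the pseudo-polar grid: two sectors of `N + 1`
#' lines each, with `2N` radial samples per line (radial oversampling x2).
#' The BH sector holds samples `F(k, l) = sum x(u, v) exp(-2i pi k (u + s v) /
#' (2N))` with slope `s = 2l/N`; the BV sector exchanges the roles of `u`
#' (first array index, the x axis) and `v` (second index, the beam axis at
#' 0 degrees). Row `r` of each matrix is radial index `k = r - 1 - N`
#' (`k = -N..N-1`); column `c` is slope index `l = c - 1 - N/2`
#' (`l = -N/2..N/2`). The image centre sits at 0-based index `N/2`.
#'
#' Computation follows the fractional-FFT factorization: a zero-padded column
#' FFT followed by a slope-dependent chirp-z resampling along rows, batched so
#' cost is `O(N^2 log N)`.
#'
#' The two 45 degree lines appear in both sectors (`l = N/2` of BH equals
#' `l = N/2` of BV; `l = -N/2` of BH equals the k-reversed `l = -N/2` of BV);
#' angle bookkeeping treats them as single measured lines.
#'
#' @param slice Real `N` x `N` matrix, `N` even (linear absorption
#'   coefficient per micrometre, or any linear quantity).
#' @return A `pp_spectrum`: list with complex matrices `BH` and `BV`
#'   (`2N` x `N+1`), `grid_size_N`, and per-line logical `measured` masks
#'   (all `TRUE` for a spectrum computed from a full slice).
#' @seealso [ppfft2_adjoint()], [ppfft2_inverse()], [projection_to_pp_line()]
#' @export
ppfft2 <- function(slice) {
  slice <- check_slice(slice)
  N <- nrow(slice)
  f <- cpp_ppfft_forward(array(slice, c(N, N, 1)))
  new_pp_spectrum(f$BH[, , 1, drop = TRUE], f$BV[, , 1, drop = TRUE], N)
}

new_pp_spectrum <- function(BH, BV, N, measured = NULL) {
  if (is.null(measured)) {
    measured <- list(BH = rep(TRUE, N + 1), BV = rep(TRUE, N + 1))
  }
  structure(list(BH = BH, BV = BV, grid_size_N = N, measured = measured),
            class = "pp_spectrum")
}

#' @export
print.pp_spectrum <- function(x, ...) {
  cat(sprintf("Pseudo-polar spectrum: N = %d, 2 x %d lines x %d radial samples\n",
              x$grid_size_N, x$grid_size_N + 1, 2 * x$grid_size_N))
  cat(sprintf("Measured lines: BH %d/%d, BV %d/%d\n",
              sum(x$measured$BH), length(x$measured$BH),
              sum(x$measured$BV), length(x$measured$BV)))
  invisible(x)
}

check_slice <- function(slice) {
  if (!is.matrix(slice) || nrow(slice) != ncol(slice)) {
    stop("slice must be a square matrix", call. = FALSE)
  }
  if (nrow(slice) %% 2 != 0) stop("slice size N must be even", call. = FALSE)
  if (!all(is.finite(slice))) stop("slice must be finite", call. = FALSE)
  storage.mode(slice) <- "double"
  slice
}

check_spectrum <- function(spec) {
  if (!inherits(spec, "pp_spectrum")) stop("expected a pp_spectrum", call. = FALSE)
  N <- spec$grid_size_N
  if (!all(dim(spec$BH) == c(2 * N, N + 1)) ||
      !all(dim(spec$BV) == c(2 * N, N + 1))) {
    stop("pp_spectrum sector dimensions do not match grid_size_N", call. = FALSE)
  }
  spec
}

#' Adjoint of the pseudo-polar FFT
#'
#' The exact complex adjoint of [ppfft2()] viewed as a linear map from real
#' `N` x `N` slices to the pseudo-polar samples: for a real slice `u` and any
#' spectrum `v`, `sum(ppfft2(u) * Conj(v)) == sum(u * Conj(ppfft2_adjoint(v)))`.
#' Returned complex; the real-constrained solver uses its real part.
#'
#' @param spectrum A `pp_spectrum`.
#' @return Complex `N` x `N` matrix.
#' @export
ppfft2_adjoint <- function(spectrum) {
  spectrum <- check_spectrum(spectrum)
  N <- spectrum$grid_size_N
  out <- cpp_ppfft_adjoint(array(spectrum$BH, c(2 * N, N + 1, 1)),
                           array(spectrum$BV, c(2 * N, N + 1, 1)))
  out[, , 1, drop = TRUE]
}

#' Least-squares inverse of the pseudo-polar FFT
#'
#' Recovers the real slice whose pseudo-polar transform best matches a fully
#' sampled spectrum, by conjugate gradients on the normal equations with a
#' radial density weighting (weight `|k|`, DC weight 1/2, i.e. `|k|/N` with DC
#' `1/(2N)` after normalization) as preconditioner. For spectra that are exact
#' transforms of real slices the recovery is exact to solver tolerance.
#'
#' @param spectrum A fully sampled `pp_spectrum`.
#' @param tol Relative residual (in the preconditioned normal-equation norm)
#'   at which to stop.
#' @param max_iter Iteration cap; if reached before `tol`, the result carries
#'   attribute `converged = FALSE` and a warning is raised.
#' @param x0 Optional warm-start slice.
#' @return Real `N` x `N` matrix with attributes `iterations`, `residual`,
#'   `converged`.
#' @export
ppfft2_inverse <- function(spectrum, tol = 1e-8, max_iter = 200, x0 = NULL) {
  spectrum <- check_spectrum(spectrum)
  N <- spectrum$grid_size_N
  x0a <- if (is.null(x0)) array(0, c(0, 0, 0)) else array(check_slice(x0), c(N, N, 1))
  r <- cpp_pp_inverse(array(spectrum$BH, c(2 * N, N + 1, 1)),
                      array(spectrum$BV, c(2 * N, N + 1, 1)),
                      tol, as.integer(max_iter), x0a)
  out <- r$x[, , 1, drop = TRUE]
  conv <- r$rel[1] <= tol
  if (!conv) {
    warning(sprintf("inverse PPFFT stopped at max_iter = %d with residual %.3g",
                    max_iter, r$rel[1]))
  }
  structure(out, iterations = r$iters[1], residual = r$rel[1], converged = conv)
}

# Generic chirp-z transform: G(k) = sum_t g(t) exp(-2i pi alpha k t) for
# centred integer index sets t_idx, k_idx. g may be a matrix (columns =
# independent signals indexed by t_idx).
chirpz <- function(g, alpha, t_idx, k_idx) {
  g <- as.matrix(g)
  stopifnot(nrow(g) == length(t_idx))
  a <- g * exp(-1i * pi * alpha * t_idx^2)
  m_min <- min(k_idx) - max(t_idx)
  m <- m_min:(max(k_idx) - min(t_idx))
  b <- exp(1i * pi * alpha * m^2)
  M <- stats::nextn(length(t_idx) + length(m) - 1, c(2, 3, 5))
  A <- rbind(a, matrix(0i, M - nrow(a), ncol(a)))
  Bf <- stats::fft(c(b, rep(0i, M - length(b))))
  conv <- stats::mvfft(stats::mvfft(A) * Bf, inverse = TRUE) / M
  out <- conv[k_idx - t_idx[1] - m_min + 1, , drop = FALSE]
  out * exp(-1i * pi * alpha * k_idx^2)
}

#' Map a 1D projection onto a pseudo-polar Fourier line
#'
#' By the Fourier slice theorem, the 1D Fourier transform of a projection at
#' tilt `theta` samples the slice's 2D transform along the line at `theta`.
#' For an equally sloped angle the line is a pseudo-polar line; its `2N`
#' radial samples are spaced `sqrt(1 + s^2) / (2N)` cycles per pixel apart
#' (`s = 2l/N` the line slope), so a fractional (chirp-z) transform of the
#' zero-padded projection lands exactly on the pseudo-polar samples.
#'
#' BV lines with negative slope correspond to tilt angles wrapped from
#' `(90, 135)` into `(-90, -45)` degrees; their physical detector axis points
#' opposite to the line's stored parameterization, so the radial samples are
#' taken at `-k` for those lines (handled internally from `sector`/`slope`).
#'
#' @param projection Real (or complex) vector of length `N` (zero-padded
#'   internally) or `2N`; matrices are handled column-wise.
#' @param sector `"BH"` or `"BV"`.
#' @param slope Integer line index `l` with `|l| <= N/2`.
#' @param grid_size_N Grid size `N`; defaults to the projection length.
#' @return Complex vector (or matrix) of `2N` radial samples, row `r` being
#'   `k = r - 1 - N`.
#' @export
projection_to_pp_line <- function(projection, sector, slope, grid_size_N = NULL) {
  p <- if (is.matrix(projection)) projection else matrix(projection, ncol = 1)
  N <- if (is.null(grid_size_N)) {
    if (nrow(p) %% 2 != 0) stop("projection length must be even", call. = FALSE)
    nrow(p)
  } else grid_size_N
  if (nrow(p) == N) {
    t_idx <- seq_len(N) - 1 - N / 2
  } else if (nrow(p) == 2 * N) {
    t_idx <- seq_len(2 * N) - 1 - N
  } else {
    stop(sprintf("projection length %d does not match grid size N = %d",
                 nrow(p), N), call. = FALSE)
  }
  if (abs(slope) > N / 2 || slope != round(slope)) {
    stop("slope must be an integer with |l| <= N/2", call. = FALSE)
  }
  s <- 2 * slope / N
  alpha <- sqrt(1 + s^2) / (2 * N)
  k_idx <- seq(-N, N - 1)
  if (pp_line_flipped(sector, slope)) k_idx <- -k_idx
  out <- chirpz(p, alpha, t_idx, k_idx)
  if (!is.matrix(projection)) out <- out[, 1]
  out
}

# TRUE for lines whose canonical parameterization runs opposite to the
# detector axis of the tilt angle they represent.
pp_line_flipped <- function(sector, slope) sector == "BV" & slope < 0
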