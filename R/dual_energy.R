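#' Register the above-edge volume onto the below-edge volume
#'
#' Whole-volume cross-correlation (FFT-based) with subvoxel refinement by a
#' separable quadratic fit around the correlation peak; the above-edge volume
#' is shifted (Fourier phase ramps) onto the below-edge frame.
#'
#' @param vol_above,vol_below `volume3d` objects (or arrays) on one grid.
#' @return List: `above` (registered `volume3d`), `below`, `shift` (length-3,
#'   voxels, the shift applied to `vol_above`).
#' @export
register_volumes <- function(vol_above, vol_below) {
  a <- as_volume_array(vol_above); b <- as_volume_array(vol_below)
  if (!all(dim(a) == dim(b))) stop("volumes must share a grid", call. = FALSE)
  if (all(a == 0) || all(b == 0)) {
    stop("cannot register an all-zero volume", call. = FALSE)
  }
  d <- dim(a)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE)) /
    prod(d)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sh <- numeric(3)
  for (ax in 1:3) {
    i0 <- pk[ax]
    ip <- i0 %% d[ax] + 1
    im <- (i0 - 2) %% d[ax] + 1
    sel <- function(i) {
      j <- pk; j[ax] <- i
      cc[j[1], j[2], j[3]]
    }
    y0 <- sel(i0); yp <- sel(ip); ym <- sel(im)
    denom <- ym - 2 * y0 + yp
    frac <- if (denom != 0) 0.5 * (ym - yp) / denom else 0
    ctr <- i0 - 1 + frac
    if (ctr > d[ax] / 2) ctr <- ctr - d[ax]
    sh[ax] <- ctr
  }
  areg <- fourier_shift3(a, sh)
  above <- if (inherits(vol_above, "volume3d")) vol_above else volume3d(a, 1)
  above$data <- areg
  list(above = above,
       below = if (inherits(vol_below, "volume3d")) vol_below else volume3d(b, 1),
       shift = sh)
}

fourier_shift3 <- function(vol, shift) {
  d <- dim(vol)
  idx <- function(n) {
    f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
    if (n %% 2 == 0) f[n %/% 2 + 1] <- abs(f[n %/% 2 + 1])
    f
  }
  ph <- exp(-2i * pi * (outer(outer(idx(d[1]) * shift[1],
                                    idx(d[2]) * shift[2], "+"),
                              idx(d[3]) * shift[3], "+")))
  Re(stats::fft(stats::fft(vol) * ph, inverse = TRUE)) / prod(d)
}

#' Above-minus-below absorption difference map
#'
#' Because the photon-energy step across the edge is small, all elements but
#' the target contribute equally to both volumes and cancel in the
#' difference; what remains is the target element's absorption jump (plus
#' noise). Negative values are retained - they carry the noise floor that
#' histogram thresholding needs.
#'
#' @param registered A list from [register_volumes()] (fields `above`,
#'   `below`, `shift`), or two volumes passed as `above` and `below`.
#' @param edge [edge_constants()] describing the element and edge.
#' @return An `element_map`: `delta_mu` (1/um), `voxel_size_nm`, `edge`,
#'   `shift`; mask/density/threshold fields are filled by
#'   [threshold_from_histogram()].
#' @export
diff_map <- function(registered, edge = edge_constants()) {
  a <- as_volume_array(registered$above)
  b <- as_volume_array(registered$below)
  structure(list(delta_mu = a - b,
                 voxel_size_nm = attr_or(registered$below, "voxel_size_nm", 1),
                 edge = edge,
                 shift = registered$shift %||% c(0, 0, 0),
                 threshold = NA_real_, mask = NULL, density = NULL),
            class = "element_map")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Share of mask voxels with at least half of their face neighbours in the
# mask (2D or 3D); 0 for an empty mask.
interior_fraction <- function(m) {
  n <- sum(m)
  if (n == 0) return(0)
  dm <- dim(m)
  nb <- array(0L, dm)
  for (ax in seq_along(dm)) {
    for (by in c(-1, 1)) {
      idx <- lapply(dm, seq_len)
      src <- idx
      src[[ax]] <- idx[[ax]] + by
      keep <- src[[ax]] >= 1 & src[[ax]] <= dm[ax]
      dst <- idx; dst[[ax]] <- idx[[ax]][keep]
      src[[ax]] <- src[[ax]][keep]
      if (length(dm) == 2) {
        nb[dst[[1]], dst[[2]]] <- nb[dst[[1]], dst[[2]]] +
          m[src[[1]], src[[2]]]
      } else {
        nb[dst[[1]], dst[[2]], dst[[3]]] <- nb[dst[[1]], dst[[2]], dst[[3]]] +
          m[src[[1]], src[[2]], src[[3]]]
      }
    }
  }
  sum(m & nb >= length(dm)) / n
}

#' @export
print.element_map <- function(x, ...) {
  cat(sprintf("Element map (%s): delta-mu range [%.4g, %.4g] 1/um\n",
              x$edge$element, min(x$delta_mu), max(x$delta_mu)))
  if (!is.na(x$threshold)) {
    cat(sprintf("Threshold %.4g; %d voxels in mask\n", x$threshold,
                sum(x$mask)))
  }
  invisible(x)
}

#' Histogram threshold for the element mask
#'
#' Separates the element signal from the noise background of the difference
#' volume using its intensity histogram: Otsu's criterion on 256 bins over the
#' observed range (default; a reproducible stand-in for reading the histogram
#' by eye), or a plain percentile. Voxels with `delta_mu >= threshold` form
#' the element mask; the mask's density field is the clipped difference
#' converted through the edge constants.
#'
#' A specimen without the element still shows above-threshold voxels - the
#' upper tail of (spatially correlated) reconstruction noise - but they are
#' scattered, whereas a real element distribution is compact. Presence is
#' therefore decided by the interior fraction of the thresholded set: the
#' share of mask voxels having at least half of their face neighbours in the
#' mask. Noise alone stays under ~0.1 (0.09 measured on a null specimen at
#' 1e4 incident counts); vesicle-scale signal gives 0.3-1.0. Below
#' `presence_interior` the element is declared absent and the mask comes
#' back empty.
#'
#' @param map An `element_map` from [diff_map()] (or a bare array with
#'   `edge`).
#' @param method `"otsu"` or `"percentile"`.
#' @param percentile Percentile (0..100) used by the percentile method.
#' @param bins Histogram bin count for Otsu.
#' @param presence_interior Interior fraction below which the automatic
#'   method declares the element absent; an explicitly requested percentile
#'   is never screened.
#' @return The `element_map` with `threshold`, `mask` (logical array),
#'   `density` (g/cm^3, zero outside the mask) and `no_element` filled in.
#' @export
threshold_from_histogram <- function(map, method = c("otsu", "percentile"),
                                     percentile = 99, bins = 256,
                                     presence_interior = 0.2) {
  method <- match.arg(method)
  dm <- if (inherits(map, "element_map")) map$delta_mu else map
  if (!all(is.finite(dm))) stop("difference volume must be finite", call. = FALSE)
  rng <- range(dm)
  if (diff(rng) == 0) {
    stop("constant difference volume: no threshold exists", call. = FALSE)
  }
  med <- stats::median(dm)
  mad <- stats::mad(dm)
  thr <- if (method == "otsu") {
    # one histogram for the whole volume (EBImage computes per-frame otherwise)
    scaled <- matrix((as.numeric(dm) - rng[1]) / diff(rng), ncol = 1)
    t01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = bins)
    # when noise dominates the histogram, Otsu can dip into the noise bulk;
    # the threshold never goes below the noise floor
    max(rng[1] + t01 * diff(rng), med + 4 * mad)
  } else {
    stats::quantile(dm, percentile / 100, names = FALSE)
  }
  # a user-requested percentile is taken at face value; only the automatic
  # histogram split is screened by the compactness test
  mask0 <- dm >= thr
  no_element <- method == "otsu" && interior_fraction(mask0) < presence_interior
  mask <- if (no_element) array(FALSE, dim(dm)) else mask0
  if (!inherits(map, "element_map")) {
    return(list(threshold = thr, mask = mask, no_element = no_element))
  }
  map$threshold <- thr
  map$mask <- mask
  map$no_element <- no_element
  dens <- density_from_delta_mu(pmax(dm, 0), map$edge$delta_mass_attenuation)
  dens[!map$mask] <- 0
  map$density <- dens
  map
}

#' Verify the 3D element mask against a 2D projected difference
#'
#' Projects the thresholded 3D mask along the beam axis (z) and measures the
#' Dice overlap with a thresholded 2D dual-energy difference image - the
#' projection-level evidence for the element that needs no reconstruction.
#' By default the 2D threshold is chosen so that the 2D footprint has the
#' same area as the projected mask (`method = "match"`); the Dice score then
#' asks purely whether the two footprints sit in the same place. Otsu or an
#' explicit percentile can be requested instead. Two empty masks have Dice 1
#' by convention.
#'
#' @param map An `element_map` with its `mask` filled in.
#' @param delta_od_2d 2D difference of optical densities `[x, y]` (above -
#'   below) at 0 degrees, or an already-thresholded logical matrix.
#' @param method `"match"`, `"otsu"` or `"percentile"` for the 2D image.
#' @param percentile Used when `method = "percentile"`.
#' @return Dice coefficient in [0, 1].
#' @export
verify_threshold_projection <- function(map, delta_od_2d,
                                        method = c("match", "otsu",
                                                   "percentile"),
                                        percentile = 99) {
  method <- match.arg(method)
  stopifnot(inherits(map, "element_map"), !is.null(map$mask))
  proj <- apply(map$mask, c(1, 2), any)
  m2 <- if (is.logical(delta_od_2d)) delta_od_2d else {
    if (diff(range(delta_od_2d)) == 0) {
      delta_od_2d > 0
    } else if (method == "match") {
      q <- 1 - sum(proj) / length(delta_od_2d)
      delta_od_2d >= stats::quantile(delta_od_2d, q, names = FALSE)
    } else {
      threshold_from_histogram(delta_od_2d, method, percentile)$mask
    }
  }
  stopifnot(all(dim(proj) == dim(m2)))
  inter <- sum(proj & m2)
  tot <- sum(proj) + sum(m2)
  if (tot == 0) return(1)
  2 * inter / tot
}

#' Quantify element mass and volume fraction
#'
#' `mass = sum(density) * voxel volume` over the element mask, in grams;
#' `volume_fraction = |mask| / |cell mask|`. When a component (vesicle) mask
#' is supplied, the fraction of whole-vesicle volume to cell volume is also
#' reported, since a rim-distributed element occupies less volume than the
#' vesicles that carry it.
#'
#' At finite resolution a threshold that localizes the element well clips the
#' smooth skirts that carry part of its mass; the mass integral therefore runs
#' over the mask grown by `grow_mask_voxels` (about twice the expected
#' point-spread sigma), while the volume fraction keeps the raw mask. The
#' integral uses the signed difference, which is unbiased under zero-mean
#' reconstruction noise (clipping negatives first would inflate the mass by
#' the folded noise mean); the stored `density` field stays clipped at zero.
#'
#' @param map An `element_map` with `mask` and `density` filled in.
#' @param cell_mask Logical array: the cell support.
#' @param vesicle_mask Optional logical array of whole-vesicle volumes.
#' @param grow_mask_voxels Dilation (voxels) applied to the mask for the mass
#'   integral only.
#' @return A `gd_quant` list: `mass_g`, `volume_fraction`,
#'   `vesicle_volume_fraction` (NA without `vesicle_mask`), `threshold`,
#'   `n_mask_voxels`.
#' @export
quantify <- function(map, cell_mask, vesicle_mask = NULL,
                     grow_mask_voxels = 3) {
  stopifnot(inherits(map, "element_map"), !is.null(map$mask))
  if (!all(dim(cell_mask) == dim(map$delta_mu))) {
    stop("cell mask grid does not match the map", call. = FALSE)
  }
  ncell <- sum(cell_mask)
  if (ncell == 0) stop("cell mask is empty", call. = FALSE)
  vv <- voxel_cm3(map$voxel_size_nm)
  mmask <- map$mask
  if (any(mmask) && grow_mask_voxels > 0) {
    for (i in seq_len(grow_mask_voxels)) mmask <- dilate_mask(mmask)
  }
  signed <- density_from_delta_mu(map$delta_mu,
                                  map$edge$delta_mass_attenuation)
  mass <- sum(signed[mmask]) * vv
  structure(list(mass_g = mass,
                 volume_fraction = sum(map$mask) / ncell,
                 vesicle_volume_fraction =
                   if (is.null(vesicle_mask)) NA_real_
                   else sum(vesicle_mask) / ncell,
                 threshold = map$threshold,
                 n_mask_voxels = sum(map$mask)),
            class = "gd_quant")
}

#' @export
print.gd_quant <- function(x, ...) {
  cat(sprintf("Element quantification: mass %.4g g, volume fraction %.2f%%\n",
              x$mass_g, 100 * x$volume_fraction))
  invisible(x)
}
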