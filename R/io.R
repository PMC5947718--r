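#' Read and write MRC volumes and stacks
#'
#' Minimal MRC2014 reader/writer (no R package on the stack reads MRC):
#' mode 2 (float32) for absorption volumes and tilt stacks, modes 0/1 (int8 /
#' int16) for label volumes; voxel size carried in the cell dimensions;
#' little-endian.
#'
#' @param x 3D array, `volume3d`, or matrix (written as a single section).
#' @param path File path.
#' @param voxel_size_nm Voxel edge (nm); taken from `volume3d` input.
#' @param mode MRC mode: 2 float32 (default), 1 int16, 0 int8.
#' @return `read_mrc` returns a `volume3d` (data integer for modes 0/1).
#' @export
write_mrc <- function(x, path, voxel_size_nm = NULL, mode = 2) {
  if (inherits(x, "volume3d")) {
    if (is.null(voxel_size_nm)) voxel_size_nm <- x$voxel_size_nm
    x <- x$data
  }
  if (is.null(voxel_size_nm)) voxel_size_nm <- 1
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  stopifnot(length(dim(x)) == 3, mode %in% c(0, 1, 2))
  d <- dim(x)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.double(v), con, size = 4, endian = "little")
  wi(d); wi(mode); wi(c(0, 0, 0)); wi(d)
  wf(d * voxel_size_nm * 10); wf(c(90, 90, 90))   # cell (Angstrom), angles
  wi(c(1, 2, 3))
  wf(c(min(x), max(x), mean(x)))
  wi(0); wi(0)                                     # ISPG, NSYMBT
  wi(rep(0, 25))                                   # EXTRA
  wi(c(0, 0))                                      # ORIGIN (words 50-52 start)
  wf(0)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)       # little-endian stamp
  wf(stats::sd(as.numeric(x)))
  wi(1)
  lab <- sprintf("%-80s", "esttomo")
  writeChar(c(lab, rep(sprintf("%-80s", ""), 9)), con, nchars = rep(80, 10),
            eos = NULL)
  if (mode == 2) {
    wf(as.numeric(x))
  } else {
    writeBin(as.integer(x), con, size = if (mode == 0) 1 else 2,
             endian = "little")
  }
  invisible(path)
}

#' @rdname write_mrc
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "double", n, size = 4, endian = "little")
  d <- ri(3); mode <- ri(1); ri(3); mxyz <- ri(3)
  cella <- rf(3); rf(3); ri(3); rf(3); ri(2)
  seek(con, 1024)
  n <- prod(d)
  dat <- if (mode == 2) {
    rf(n)
  } else if (mode == 1) {
    readBin(con, "integer", n, size = 2, endian = "little")
  } else if (mode == 0) {
    readBin(con, "integer", n, size = 1, endian = "little")
  } else {
    stop(sprintf("unsupported MRC mode %d in '%s'", mode, path), call. = FALSE)
  }
  vox <- if (mxyz[1] > 0) cella[1] / mxyz[1] / 10 else 1
  volume3d(array(dat, d), voxel_size_nm = vox)
}

#' Read and write float TIFF stacks with sidecar metadata
#'
#' Multi-page 32-bit TIFF plus a JSON sidecar (`<path>.json`). TIFF float
#' storage is confined to [0, 1], so values are affinely mapped onto that
#' range; the mapping (`offset`, `scale`) and any extra metadata ride in the
#' sidecar and are undone on read. Round trips are exact to float32
#' precision of the scaled representation.
#'
#' @param x 3D array `[x, y, page]` or list of matrices.
#' @param path TIFF path.
#' @param metadata Named list stored in the sidecar.
#' @return `read_tiff_stack` returns a list: `data` (3D array), `metadata`.
#' @export
write_tiff_stack <- function(x, path, metadata = list()) {
  if (is.list(x)) x <- simplify2array(x)
  stopifnot(length(dim(x)) == 3)
  lo <- min(x); hi <- max(x)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(x)[3]), function(i) (x[, , i] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- c(list(offset = lo, scale = scale, dim = dim(x)), metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tiff_stack
#' @export
read_tiff_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  x <- simplify2array(pages) * meta$scale + meta$offset
  list(data = x, metadata = meta[setdiff(names(meta), c("offset", "scale", "dim"))])
}

#' Write a simulated tilt series to disk
#'
#' MRC stack (pages = angles) + plain-text angle list + JSON metadata
#' (energy, incident counts, pixel size, true shifts if known).
#'
#' @param series A `tilt_series`.
#' @param prefix Output path prefix; writes `<prefix>.mrc`,
#'   `<prefix>_angles.txt`, `<prefix>.json`.
#' @return `read_tilt_series` returns the `tilt_series`.
#' @export
write_tilt_series <- function(series, prefix) {
  stopifnot(inherits(series, "tilt_series"))
  write_mrc(series$data, paste0(prefix, ".mrc"), series$pixel_size_nm)
  write_angle_file(series$angles, paste0(prefix, "_angles.txt"))
  meta <- list(energy_ev = series$energy_ev,
               pixel_size_nm = series$pixel_size_nm,
               kind = series$kind,
               incident_counts = series$incident_counts,
               grid_size_N = attr(series$angles, "grid_size_N"),
               tilt_range_deg = attr(series$angles, "tilt_range_deg"),
               true_shifts = series$true_shifts)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_tilt_series
#' @export
read_tilt_series <- function(prefix) {
  vol <- read_mrc(paste0(prefix, ".mrc"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  ang <- equally_sloped_angles(meta$grid_size_N, meta$tilt_range_deg)
  file_angles <- read_angle_file(paste0(prefix, "_angles.txt"))
  match_angles(file_angles, ang)   # validates the list
  ts <- new_tilt_series(vol$data, ang, meta$energy_ev, meta$pixel_size_nm,
                        meta$kind, meta$incident_counts,
                        true_shifts = if (!is.null(meta$true_shifts))
                          as.matrix(meta$true_shifts))
  ts
}

#' Pipeline configuration files
#'
#' Structured YAML with four blocks (`acquisition`, `reconstruction`,
#' `dual_energy`, `segmentation`) plus `paths` and a single `seed` that every
#' stage derives its randomness from. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("acquisition", "reconstruction", "dual_energy", "segmentation",
             "paths", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    stop(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  block_keys <- list(
    acquisition = c("energies", "grid_size_N", "tilt_range_deg",
                    "incident_counts", "pixel_size_nm", "shift_jitter_px",
                    "noise"),
    reconstruction = c("n_iter", "positivity", "inner_cg_iter",
                       "first_cg_iter", "record_error_every"),
    dual_energy = c("delta_mass_attenuation", "element", "threshold_method",
                    "percentile"),
    segmentation = c("intervals", "min_voxels"))
  for (b in names(block_keys)) {
    extra <- setdiff(names(cfg[[b]]), block_keys[[b]])
    if (length(extra) > 0) {
      stop(sprintf("unknown keys in config block '%s': %s", b,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
  }
  cfg
}
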