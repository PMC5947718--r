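#' Equally sloped tilt angle sets
#'
#' Builds the full pseudo-polar angle set for an `N` x `N` slice and flags
#' which lines fall inside an achievable tilt range. The pseudo-polar grid has
#' `2N` distinct line orientations split into two sectors: basically horizontal
#' (BH) lines with `tan(theta) = 2l/N` and basically vertical (BV) lines with
#' `cot(theta) = 2l/N`. Tilt angles whose tangents are equally spaced coincide
#' exactly with these Fourier lines, which is what makes an interpolation-free
#' iterative reconstruction possible. Lines outside `tilt_range_deg` (the
#' missing wedge left by the rotation stage) are kept in the set but flagged
#' unmeasured so the wedge is represented explicitly.
#'
#' @param grid_size_N Even, positive slice size `N`.
#' @param tilt_range_deg Length-2 numeric, achievable tilt interval in degrees,
#'   a subset of (-90, 90].
#' @return An object of class `pp_angles`: a data frame with one row per
#'   pseudo-polar line, columns `angle_deg` (strictly increasing), `sector`
#'   (`"BH"` or `"BV"`), `slope` (integer line index `l`), `measured`
#'   (logical), and attributes `grid_size_N` and `tilt_range_deg`.
#' @examples
#' ang <- equally_sloped_angles(4)
#' ang$angle_deg   # -63.435, -45, -26.565, 0, 26.565, 45, 63.435, 90
#' @export
equally_sloped_angles <- function(grid_size_N, tilt_range_deg = c(-90, 90)) {
  N <- grid_size_N
  if (length(N) != 1L || N != round(N) || N < 2 || N %% 2 != 0) {
    stop("grid_size_N must be an even integer >= 2", call. = FALSE)
  }
  if (length(tilt_range_deg) != 2L || diff(tilt_range_deg) <= 0) {
    stop("tilt_range_deg must be an increasing interval", call. = FALSE)
  }
  bh <- data.frame(sector = "BH", slope = seq(-N / 2, N / 2 - 1))
  bh$angle_deg <- atan(2 * bh$slope / N) * 180 / pi
  bv <- data.frame(sector = "BV", slope = seq(-N / 2 + 1, N / 2))
  bv$angle_deg <- 90 - atan(2 * bv$slope / N) * 180 / pi
  bv$angle_deg[bv$angle_deg > 90] <- bv$angle_deg[bv$angle_deg > 90] - 180
  tab <- rbind(bh, bv)
  tab <- tab[order(tab$angle_deg), c("angle_deg", "sector", "slope")]
  rownames(tab) <- NULL
  tab$measured <- tab$angle_deg >= tilt_range_deg[1] - 1e-9 &
    tab$angle_deg <= tilt_range_deg[2] + 1e-9
  if (!any(tab$measured)) {
    stop(sprintf("no equally sloped angle falls inside [%g, %g] degrees",
                 tilt_range_deg[1], tilt_range_deg[2]), call. = FALSE)
  }
  structure(tab,
            grid_size_N = N,
            tilt_range_deg = as.numeric(tilt_range_deg),
            class = c("pp_angles", "data.frame"))
}

#' @export
print.pp_angles <- function(x, ...) {
  N <- attr(x, "grid_size_N")
  rng <- attr(x, "tilt_range_deg")
  cat(sprintf("Equally sloped angle set: N = %d, %d lines (%d measured)\n",
              N, nrow(x), sum(x$measured)))
  wedge <- if (all(x$measured)) 0 else 180 - diff(range(x$angle_deg[x$measured]))
  cat(sprintf("Tilt range [%g, %g] deg; unmeasured wedge ~%.1f deg\n",
              rng[1], rng[2], wedge))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# Column index of a line in the per-sector spectrum matrices (l = -N/2..N/2).
pp_line_col <- function(slope, N) as.integer(slope + N / 2 + 1)

#' Write and read plain-text angle lists
#'
#' One angle in degrees per line; `#` starts a comment. The writer records the
#' grid size, tilt range and each line's sector/slope index as comments, and
#' only emits measured angles.
#'
#' @param angles A `pp_angles` object.
#' @param path File path.
#' @return `read_angle_file` returns a numeric vector of angles in degrees
#'   (attribute `lines` carries any sector/slope annotations found).
#' @export
write_angle_file <- function(angles, path) {
  stopifnot(inherits(angles, "pp_angles"))
  rng <- attr(angles, "tilt_range_deg")
  hdr <- c(
    sprintf("# equally sloped angles, N = %d", attr(angles, "grid_size_N")),
    sprintf("# tilt range [%g, %g] deg", rng[1], rng[2])
  )
  m <- angles[angles$measured, ]
  body <- sprintf("%.10g  # %s %+d", m$angle_deg, m$sector, m$slope)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_angle_file
#' @export
read_angle_file <- function(path) {
  ln <- readLines(path)
  ann <- sub("^[^#]*", "", ln)
  ln <- sub("#.*$", "", ln)
  keep <- nzchar(trimws(ln))
  vals <- suppressWarnings(as.numeric(trimws(ln[keep])))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1]]
    stop(sprintf("angle file '%s': line %d is not a number", path, bad),
         call. = FALSE)
  }
  attr(vals, "lines") <- trimws(sub("^#", "", ann[keep]))
  vals
}

# Match a vector of angles (degrees) against a pp_angles set; errors if an
# angle is not an equally sloped angle of this grid.
match_angles <- function(angle_deg, angles, tol = 1e-6) {
  idx <- vapply(angle_deg, function(a) {
    j <- which(abs(angles$angle_deg - a) < tol)
    if (length(j) != 1L) {
      stop(sprintf("angle %.6g deg is not in the equally sloped set (N = %d)",
                   a, attr(angles, "grid_size_N")), call. = FALSE)
    }
    j
  }, integer(1))
  idx
}
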