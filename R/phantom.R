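#' Edge constants for dual-energy differencing
#'
#' Bundles the two photon energies bracketing an element's absorption edge and
#' the jump `delta_mass_attenuation` of the element's mass attenuation
#' coefficient across it, which converts an absorption difference (1/um) into
#' an element mass density (g/cm^3). No numeric jump is baked in; it is a
#' required user input tied to the element and edge in use.
#'
#' @param e_below,e_above Photon energies in eV, `e_above > e_below`.
#' @param delta_mass_attenuation Jump of mu/rho across the edge, cm^2/g (> 0).
#' @param element Element label (metadata only).
#' @return An `edge_constants` list.
#' @export
edge_constants <- function(e_below = 1186, e_above = 1189,
                           delta_mass_attenuation = 2000, element = "Gd") {
  stopifnot(e_above > e_below, delta_mass_attenuation > 0)
  structure(list(e_below = e_below, e_above = e_above,
                 delta_mass_attenuation = delta_mass_attenuation,
                 element = element),
            class = "edge_constants")
}

# density (g/cm^3) from an absorption difference (1/um):
# delta_mu [1/um] = 1e4 * delta_mu [1/cm]; rho = delta_mu[1/cm] / (mu/rho)[cm^2/g]
density_from_delta_mu <- function(delta_mu_per_um, delta_mass_attenuation) {
  1e4 * delta_mu_per_um / delta_mass_attenuation
}

delta_mu_from_density <- function(rho_g_cm3, delta_mass_attenuation) {
  rho_g_cm3 * delta_mass_attenuation * 1e-4
}

# voxel volume in cm^3 from its edge length in nm
voxel_cm3 <- function(voxel_size_nm) (voxel_size_nm * 1e-7)^3

phantom_classes <- c("background", "cytoplasm", "nucleus", "vacuole",
                     "lysosome", "gd_vesicle_core", "gd_vesicle_rim")

new_primitive <- function(shape, centre, size, mu_below, class_label,
                          gd_density = 0) {
  stopifnot(shape %in% c("ellipsoid", "sphere", "box", "spherical-shell"),
            class_label %in% phantom_classes,
            mu_below >= 0, gd_density >= 0)
  list(shape = shape, centre = centre, size = size, mu_below = mu_below,
       class_label = class_label, gd_density = gd_density)
}

#' Macrophage-like dual-energy phantom
#'
#' Generates a reproducible specification of a flat ellipsoidal cell holding a
#' nucleus, a few low-absorption vacuoles, many small dense lysosomes and a
#' handful of element-laden vesicles, mimicking an active macrophage that has
#' taken up metallofullerene nanoparticle aggregates: some vesicles are
#' uniformly filled, others carry the element only in a shell at the vesicle
#' periphery (ring-shaped rims). Below-edge absorption values are fixed per
#' class; above-edge absorption is derived from the element density and the
#' edge constants, so that dual-energy quantification closes exactly on the
#' ground truth. Geometry scales with the grid: lysosome diameters are drawn
#' from `lysosome_diameter_nm` and converted to voxels.
#'
#' @param grid_shape Cubic grid size (single integer or length-3, all equal),
#'   at least 32.
#' @param voxel_size_nm Voxel edge, nm (50 by default, the acquisition step).
#' @param seed Integer; all geometry is reproducible from it.
#' @param n_vacuoles,n_lysosomes,n_gd_vesicles Component counts (vacuoles
#'   3..6; at least 20 lysosomes; vesicles 2..5, alternating rim-only and
#'   filled).
#' @param lysosome_diameter_nm Range the lysosome diameters are drawn from.
#' @param gd_density_g_cm3 Element mass density assigned to filled vesicle
#'   interiors and to vesicle rims, g/cm^3.
#' @param band_limit_sigma_px In-plane (x-z) Gaussian band-limiting applied at
#'   render time, in pixels; see [render_phantom()].
#' @param edge [edge_constants()] used to derive above-edge absorption.
#' @return A `phantom_spec` list (primitives, grid, voxel size, seed, edge,
#'   band limit).
#' @export
default_cell_phantom <- function(grid_shape = 64, voxel_size_nm = 50, seed = 1,
                                 n_vacuoles = 4, n_lysosomes = 20,
                                 n_gd_vesicles = 4,
                                 lysosome_diameter_nm = c(200, 400),
                                 gd_density_g_cm3 = 1.0,
                                 band_limit_sigma_px = 1.2,
                                 edge = edge_constants()) {
  N <- unique(as.integer(grid_shape))
  if (length(N) != 1L) stop("grid must be cubic", call. = FALSE)
  if (N < 32) stop("grid must be at least 32^3 to host the phantom", call. = FALSE)
  stopifnot(n_vacuoles >= 3, n_vacuoles <= 6,
            n_lysosomes >= 20, n_gd_vesicles >= 2, n_gd_vesicles <= 5)
  rs <- N / 64  # reference geometry is laid out on a 64-grid
  set.seed(seed)

  cell_ax <- c(0.37, 0.34, 0.20) * N
  nuc_ctr <- c(-0.10, 0.06, 0) * N
  nuc_ax <- c(0.13, 0.11, 0.08) * N
  prims <- list(
    new_primitive("ellipsoid", c(0, 0, 0), cell_ax, 0.35, "cytoplasm"),
    new_primitive("ellipsoid", nuc_ctr, nuc_ax, 0.45, "nucleus")
  )
  # rejection placement in the cytoplasm: inside the cell ellipsoid (shrunk by
  # the primitive radius), outside the nucleus dilated by it, clear of
  # previously placed spheres
  placed <- list()
  placed_r <- numeric()
  draw_centre <- function(radius, tries = 2000) {
    for (i in seq_len(tries)) {
      p <- stats::runif(3, -1, 1) * (cell_ax - radius - 2 * rs)
      if (sum((p / pmax(cell_ax - radius - rs, 1))^2) > 1) next
      if (sum(((p - nuc_ctr) / (nuc_ax + radius))^2) < 1) next
      ok <- TRUE
      for (j in seq_along(placed)) {
        if (sqrt(sum((p - placed[[j]])^2)) < 0.75 * (placed_r[j] + radius)) {
          ok <- FALSE; break
        }
      }
      if (ok) return(p)
    }
    NULL
  }
  # shrink a primitive slightly (up to 3 times) when the cytoplasm is crowded
  draw_sized <- function(radius) {
    for (f in c(1, 0.85, 0.85^2, 0.85^3)) {
      p <- draw_centre(radius * f)
      if (!is.null(p)) return(list(p = p, r = radius * f))
    }
    stop("grid too small to place phantom primitives without overlap",
         call. = FALSE)
  }
  add_placed <- function(p, r) {
    placed[[length(placed) + 1]] <<- p
    placed_r[length(placed_r) + 1] <<- r
  }

  # large primitives are placed first so the small lysosomes fill the gaps
  for (i in seq_len(n_gd_vesicles)) {
    rim_only <- i %% 2 == 1
    d <- draw_sized(stats::runif(1, 4.5, 6.5) * rs)
    p <- d$p; r <- d$r
    if (rim_only) {
      prims[[length(prims) + 1]] <-
        new_primitive("sphere", p, r, 0.20, "vacuole")
      prims[[length(prims) + 1]] <-
        new_primitive("spherical-shell", p, c(r - 2 * rs, r), 0.30,
                      "gd_vesicle_rim", gd_density = gd_density_g_cm3)
    } else {
      prims[[length(prims) + 1]] <-
        new_primitive("sphere", p, r * 0.85, 0.25, "gd_vesicle_core",
                      gd_density = gd_density_g_cm3)
    }
    add_placed(p, r)
  }
  for (i in seq_len(n_vacuoles)) {
    d <- draw_sized(stats::runif(1, 3.5, 6) * rs)
    p <- d$p; r <- d$r
    prims[[length(prims) + 1]] <- new_primitive("sphere", p, r, 0.10, "vacuole")
    add_placed(p, r)
  }
  lys_r_px <- lysosome_diameter_nm / 2 / voxel_size_nm * rs
  for (i in seq_len(n_lysosomes)) {
    d <- draw_sized(stats::runif(1, lys_r_px[1], lys_r_px[2]))
    p <- d$p; r <- d$r
    prims[[length(prims) + 1]] <- new_primitive("sphere", p, r, 1.2, "lysosome")
    add_placed(p, r)
  }

  structure(list(primitives = prims, grid_shape = rep(N, 3),
                 voxel_size_nm = voxel_size_nm, seed = seed, edge = edge,
                 band_limit_sigma_px = band_limit_sigma_px),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cls <- vapply(x$primitives, `[[`, "", "class_label")
  cat(sprintf("Phantom: %d^3 voxels @ %g nm, seed %d\n",
              x$grid_shape[1], x$voxel_size_nm, x$seed))
  print(table(factor(cls, levels = phantom_classes)))
  invisible(x)
}

# In-plane (x-z) Gaussian band limit, applied independently per y row.
# Circular convolution with a normalized discrete Gaussian kernel: the output
# of a nonnegative volume stays nonnegative and the total is conserved
# exactly (the kernel sums to one). vol is [x, y, z].
bandlimit_xz <- function(vol, sigma_px) {
  if (sigma_px <= 0) return(vol)
  N <- dim(vol)[1]
  d <- pmin(0:(N - 1), N:1)             # periodic distance to the origin
  g <- exp(-d^2 / (2 * sigma_px^2))
  g <- g / sum(g)
  H <- stats::fft(outer(g, g))
  out <- vol
  for (y in seq_len(dim(vol)[2])) {
    out[, y, ] <- Re(stats::fft(stats::fft(vol[, y, ]) * H, inverse = TRUE)) / N^2
  }
  out
}

#' Rasterize a phantom into ground-truth volumes
#'
#' Voxelizes the primitives in order (later primitives overwrite earlier ones)
#' into below- and above-edge absorption volumes, an integer class-label
#' volume and an element density volume, then applies the in-plane Gaussian
#' band limit of the specification to the continuous fields (labels stay
#' crisp). The
#' band limit models the finite probe size and keeps slices representable by
#' their equally sloped projections; it conserves total absorption and element
#' mass exactly.
#'
#' @param spec A `phantom_spec`.
#' @return A `ground_truth` list: `mu_below`, `mu_above` (1/um), `labels`
#'   (integer codes along `phantom_classes`), `gd_density` (g/cm^3),
#'   `voxel_size_nm`, `edge`, `spec`.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  N <- spec$grid_shape[1]
  cc <- seq_len(N) - 1 - N / 2        # centred voxel coordinates
  mu <- array(0, dim = spec$grid_shape)
  gd <- array(0, dim = spec$grid_shape)
  lab <- array(0L, dim = spec$grid_shape)
  for (p in spec$primitives) {
    m <- primitive_mask(p, cc)
    mu[m] <- p$mu_below
    gd[m] <- p$gd_density
    lab[m] <- match(p$class_label, phantom_classes) - 1L
  }
  mu_above <- mu + delta_mu_from_density(gd, spec$edge$delta_mass_attenuation)
  sg <- spec$band_limit_sigma_px
  structure(list(mu_below = bandlimit_xz(mu, sg),
                 mu_above = bandlimit_xz(mu_above, sg),
                 labels = lab,
                 gd_density = bandlimit_xz(gd, sg),
                 voxel_size_nm = spec$voxel_size_nm,
                 edge = spec$edge,
                 spec = spec),
            class = "ground_truth")
}

primitive_mask <- function(p, cc) {
  ctr <- p$centre
  switch(p$shape,
    sphere = {
      r2 <- outer(outer((cc - ctr[1])^2, (cc - ctr[2])^2, "+"),
                  (cc - ctr[3])^2, "+")
      r2 <= p$size[1]^2
    },
    ellipsoid = {
      q <- outer(outer(((cc - ctr[1]) / p$size[1])^2,
                       ((cc - ctr[2]) / p$size[2])^2, "+"),
                 ((cc - ctr[3]) / p$size[3])^2, "+")
      q <= 1
    },
    box = {
      outer(outer(abs(cc - ctr[1]) <= p$size[1],
                  abs(cc - ctr[2]) <= p$size[2], "&"),
            abs(cc - ctr[3]) <= p$size[3], "&")
    },
    `spherical-shell` = {
      r2 <- outer(outer((cc - ctr[1])^2, (cc - ctr[2])^2, "+"),
                  (cc - ctr[3])^2, "+")
      r2 <= p$size[2]^2 & r2 >= p$size[1]^2
    })
}

# Total element mass (g) in a ground-truth object.
ground_truth_gd_mass <- function(gt) {
  sum(gt$gd_density) * voxel_cm3(gt$voxel_size_nm)
}
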