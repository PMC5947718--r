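#' Segment a reconstructed volume by linear absorption coefficient
#'
#' Organelles have characteristic linear absorption coefficients, so a
#' reconstructed absorption volume can be partitioned by disjoint, ordered mu
#' intervals; each voxel gets the class whose interval contains its value.
#' The cell mask is the union of all non-background classes.
#'
#' @param volume `volume3d` or array (1/um).
#' @param intervals Data frame with columns `name`, `mu_min`, `mu_max`
#'   (half-open `[mu_min, mu_max)` bins; they must not overlap). A helper
#'   building candidate intervals from the histogram is
#'   [propose_mu_intervals()].
#' @return A `label_map`: `labels` (integer array, 0 = background), `classes`
#'   (the interval table with `label` codes), `voxel_size_nm`.
#' @export
segment_by_mu <- function(volume, intervals) {
  v <- as_volume_array(volume)
  stopifnot(is.data.frame(intervals),
            all(c("name", "mu_min", "mu_max") %in% names(intervals)))
  iv <- intervals[order(intervals$mu_min), ]
  if (any(iv$mu_max <= iv$mu_min)) {
    stop("each interval needs mu_max > mu_min", call. = FALSE)
  }
  if (nrow(iv) > 1 && any(iv$mu_min[-1] < iv$mu_max[-nrow(iv)] - 1e-12)) {
    stop("mu intervals overlap", call. = FALSE)
  }
  iv$label <- seq_len(nrow(iv))
  lab <- array(0L, dim(v))
  for (i in seq_len(nrow(iv))) {
    lab[v >= iv$mu_min[i] & v < iv$mu_max[i]] <- iv$label[i]
  }
  structure(list(labels = lab, classes = iv,
                 voxel_size_nm = attr_or(volume, "voxel_size_nm", 1)),
            class = "label_map")
}

#' Propose mu intervals from the volume histogram
#'
#' Convenience only: finds modes of the smoothed absorption histogram and cuts
#' at the minima between them. Segmentation itself always uses explicit
#' intervals.
#'
#' @param volume `volume3d` or array.
#' @param k Number of classes to aim for.
#' @return Interval data frame usable with [segment_by_mu()].
#' @export
propose_mu_intervals <- function(volume, k = 4) {
  v <- as.numeric(as_volume_array(volume))
  d <- stats::density(v[v > 0], n = 512)
  mins <- which(diff(sign(diff(d$y))) == 2) + 1
  cuts <- d$x[mins]
  if (length(cuts) > k - 1) {
    cuts <- cuts[order(d$y[mins])][seq_len(k - 1)]
    cuts <- sort(cuts)
  }
  lo <- c(min(v[v > 0]), cuts)
  hi <- c(cuts, max(v) + 1e-9)
  data.frame(name = paste0("class", seq_along(lo)), mu_min = lo, mu_max = hi)
}

# 26-connected component labelling of a logical 3D mask via igraph.
label_components_26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  comp <- array(0L, d)
  if (length(idx) == 0) return(comp)
  pos <- arrayInd(idx, d)
  key <- function(p) (p[, 3] - 1) * d[1] * d[2] + (p[, 2] - 1) * d[1] + p[, 1]
  id_of <- integer(prod(d))
  id_of[idx] <- seq_along(idx)
  edges <- vector("list", 13)
  e <- 0L
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dx != 0 | offs$dy != 0 | offs$dz != 0, ]
  offs <- offs[1:(nrow(offs) / 2), ]          # half the neighbourhood suffices
  for (o in seq_len(nrow(offs))) {
    q <- pos
    q[, 1] <- q[, 1] + offs$dx[o]
    q[, 2] <- q[, 2] + offs$dy[o]
    q[, 3] <- q[, 3] + offs$dz[o]
    ok <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2] &
      q[, 3] >= 1 & q[, 3] <= d[3]
    if (!any(ok)) next
    nb <- id_of[key(q[ok, , drop = FALSE])]
    src <- which(ok)
    hit <- nb > 0
    if (!any(hit)) next
    e <- e + 1L
    edges[[e]] <- rbind(src[hit], nb[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (e > 0) {
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges[seq_len(e)])))
  }
  comp[idx] <- igraph::components(g)$membership
  comp
}

#' Per-component organelle statistics
#'
#' 26-connected components are extracted per class; components smaller than
#' `min_voxels` are discarded as noise. For each component: voxel count,
#' volume (um^3), equivalent spherical diameter (nm), centroid, and - when an
#' element map is supplied - the mean absorption difference and the rim
#' fraction, the share of the component's element voxels lying in its
#' 2-voxel outer shell. Ring-shaped (membrane-bound) element distributions
#' give rim fractions near 1, uniformly filled components near the shell's
#' own volume share.
#'
#' @param labels A `label_map`.
#' @param element Optional `element_map` with `mask` filled in.
#' @param min_voxels Minimum component size kept.
#' @param classes Restrict to these class names (default: all).
#' @return Data frame, one row per component: `class`, `component`,
#'   `n_voxels`, `volume_um3`, `diameter_nm`, `centroid_x/y/z`,
#'   `mean_delta_mu`, `rim_fraction`.
#' @export
component_stats <- function(labels, element = NULL, min_voxels = 3,
                            classes = NULL) {
  stopifnot(inherits(labels, "label_map"))
  vox_nm <- labels$voxel_size_nm
  vox_um3 <- (vox_nm * 1e-3)^3
  cls <- labels$classes
  if (!is.null(classes)) cls <- cls[cls$name %in% classes, ]
  out <- list()
  for (i in seq_len(nrow(cls))) {
    mask <- labels$labels == cls$label[i]
    if (!any(mask)) next
    comp <- label_components_26(mask)
    for (cid in setdiff(unique(as.integer(comp)), 0L)) {
      sel <- comp == cid
      n <- sum(sel)
      if (n < min_voxels) next
      pos <- arrayInd(which(sel), dim(sel))
      vol <- n * vox_um3
      row <- data.frame(
        class = cls$name[i], component = cid, n_voxels = n,
        volume_um3 = vol,
        diameter_nm = (6 * vol / pi)^(1 / 3) * 1e3,
        centroid_x = mean(pos[, 1]), centroid_y = mean(pos[, 2]),
        centroid_z = mean(pos[, 3]),
        mean_delta_mu = NA_real_, rim_fraction = NA_real_)
      if (!is.null(element)) {
        row$mean_delta_mu <- mean(element$delta_mu[sel])
        gd_in <- element$mask & sel
        if (any(gd_in)) {
          core <- erode_mask(erode_mask(sel))
          shell <- sel & !core
          row$rim_fraction <- sum(gd_in & shell) / sum(gd_in)
        }
      }
      out[[length(out) + 1]] <- row
    }
  }
  if (length(out) == 0) {
    return(data.frame(class = character(), component = integer(),
                      n_voxels = integer(), volume_um3 = numeric(),
                      diameter_nm = numeric(), centroid_x = numeric(),
                      centroid_y = numeric(), centroid_z = numeric(),
                      mean_delta_mu = numeric(), rim_fraction = numeric()))
  }
  do.call(rbind, out)
}

# 6-connected binary dilation by one voxel (outside the grid stays empty).
dilate_mask <- function(m) {
  d <- dim(m)
  out <- m
  for (ax in 1:3) {
    for (by in c(-1, 1)) {
      idx <- lapply(d, seq_len)
      src <- idx
      src[[ax]] <- idx[[ax]] + by
      keep <- src[[ax]] >= 1 & src[[ax]] <= d[ax]
      dst <- idx; dst[[ax]] <- idx[[ax]][keep]
      src[[ax]] <- src[[ax]][keep]
      out[dst[[1]], dst[[2]], dst[[3]]] <-
        out[dst[[1]], dst[[2]], dst[[3]]] | m[src[[1]], src[[2]], src[[3]]]
    }
  }
  out
}

# 6-connected binary erosion by one voxel.
erode_mask <- function(m) {
  d <- dim(m)
  out <- m
  shift_and <- function(ax, by) {
    idx <- vector("list", 3)
    for (a in 1:3) idx[[a]] <- seq_len(d[a])
    src <- idx; src[[ax]] <- pmin(pmax(idx[[ax]] + by, 1), d[ax])
    pad <- m[src[[1]], src[[2]], src[[3]], drop = FALSE]
    # voxels at the border erode against the outside (treated as FALSE)
    edge <- if (by > 0) d[ax] else 1
    sl <- idx; sl[[ax]] <- edge
    pad[sl[[1]], sl[[2]], sl[[3]]] <- FALSE
    pad
  }
  for (ax in 1:3) {
    out <- out & shift_and(ax, 1) & shift_and(ax, -1)
  }
  out
}

#' Type vesicles by size, density and element distribution
#'
#' Rule-based typing of element-carrying components reflecting the observed
#' progression as vesicles grow: type A, small with high element density
#' (uniformly filled); type C, large with low density and the element
#' concentrated at the periphery (rim fraction above `rim_cut`); type B,
#' intermediate. Cutpoints are configurable; assignment is independent of
#' component order.
#'
#' @param stats Data frame from [component_stats()] with `mean_delta_mu` and
#'   `rim_fraction` available.
#' @param volume_cut_um3 Volume separating "small" from "large".
#' @param rim_cut Rim fraction above which the distribution counts as
#'   rim-like.
#' @return The data frame with a `type` column (`"A"`, `"B"`, `"C"`).
#' @export
classify_vesicles <- function(stats, volume_cut_um3 = 0.01, rim_cut = 0.8) {
  stopifnot(is.data.frame(stats))
  type <- rep("B", nrow(stats))
  rim <- ifelse(is.na(stats$rim_fraction), 0, stats$rim_fraction)
  type[rim >= rim_cut & stats$volume_um3 >= volume_cut_um3] <- "C"
  type[rim < 0.5 & stats$volume_um3 < volume_cut_um3] <- "A"
  stats$type <- type
  stats
}

#' Assemble a machine-readable pipeline report
#'
#' One JSON-serializable document carrying the acquisition echo, alignment
#' shifts, reconstruction error metrics, resolution estimate, element
#' threshold and quantification, and the component table. Parsing the written
#' file back reproduces all numeric fields exactly (JSON written at full
#' precision).
#'
#' @param acquisition,alignment,reconstruction,element,quant,components
#'   Pipeline stage results (any may be NULL).
#' @param resolution Optional [fsc_resolution()] result.
#' @param path Optional path; if given the report is written as JSON.
#' @return The report list, invisibly if written.
#' @export
pipeline_report <- function(acquisition = NULL, alignment = NULL,
                            reconstruction = NULL, element = NULL,
                            quant = NULL, components = NULL,
                            resolution = NULL, path = NULL) {
  rep <- list(
    schema = "esttomo-report/1",
    acquisition = acquisition,
    alignment = if (!is.null(alignment)) {
      list(shifts = unclass(alignment$shifts), cx = alignment$cx,
           cz = alignment$cz)
    },
    reconstruction = if (!is.null(reconstruction)) {
      list(n_iter = reconstruction$config$n_iter,
           rows = reconstruction$rows,
           final_error = as.numeric(
             reconstruction$error_history[nrow(reconstruction$error_history), ]))
    },
    element = if (!is.null(element)) {
      list(threshold = element$threshold,
           n_mask_voxels = if (!is.null(element$mask)) sum(element$mask),
           registration_shift = element$shift)
    },
    quant = if (!is.null(quant)) unclass(quant),
    resolution = if (!is.null(resolution)) {
      list(resolution_nm = resolution$resolution_nm,
           criterion = resolution$criterion)
    },
    components = components
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = I(17),
                         dataframe = "columns", null = "null")
    return(invisible(rep))
  }
  rep
}

#' @rdname pipeline_report
#' @param path Path of a written report.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
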