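#' Closed-form ellipsoid volume
#'
#' Volume of an ellipsoid from its three full axes: `(pi/6) * a * b * c`.
#' Axes in nm give volume in nm^3.
#'
#' @param a,b,c full (not semi-) axes.
#' @return volume.
#' @export
ellipsoid_volume <- function(a, b, c) pi / 6 * a * b * c

#' Voxelize an atomic model
#'
#' Builds an occupancy lattice over the model's bounding box with at least
#' `2 * probe_radius` of empty padding on every face. A voxel is occupied
#' when its center lies within `atom_radius` of any atom; the dilated
#' lattice uses `atom_radius + probe_radius`, so an empty dilated voxel is a
#' position the center of a spherical probe can occupy.
#'
#' @param model an [atomic_model()]; all-atom coordinates are used when
#'   present, otherwise the per-residue points.
#' @param voxel_size lattice spacing in Angstrom, in (0.5, 5]; default 2.
#' @param atom_radius atom radius class in Angstrom; default the model's
#'   `radius_class` (2 for pseudo-atom shells).
#' @param probe_radius probe radius in Angstrom; default 5. The probe must
#'   exceed the pseudo-atom lattice spacing of synthetic shells yet stay
#'   below nm-scale openings, so enclosure is not broken by inter-atom gaps.
#' @return list of class `voxel_grid`: `origin`, `voxel_size`, `dims`,
#'   logical arrays `occupancy` and `dilated_occupancy`, and the radii.
#' @export
voxelize <- function(model, voxel_size = 2, atom_radius = NULL, probe_radius = 5) {
  if (!(voxel_size > 0.5 && voxel_size <= 5)) stop("voxel_size must be in (0.5, 5]")
  atom_radius <- atom_radius %||% model$radius_class
  stopifnot(atom_radius > 0, probe_radius > 0)
  pts <- model_points(model)
  if (nrow(pts) == 0) stop("empty model")
  pad <- atom_radius + 2 * probe_radius + 2 * voxel_size
  lo <- apply(pts, 2, min) - pad
  hi <- apply(pts, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / voxel_size))
  occ <- stamp_spheres_cpp(pts, atom_radius, lo, voxel_size, dims)
  dil <- stamp_spheres_cpp(pts, atom_radius + probe_radius, lo, voxel_size, dims)
  structure(list(origin = as.numeric(lo), voxel_size = voxel_size,
                 dims = dims,
                 occupancy = array(occ, dims),
                 dilated_occupancy = array(dil, dims),
                 atom_radius = atom_radius, probe_radius = probe_radius,
                 points = pts),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels at %g A (%.1f%% occupied)\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size,
              100 * mean(x$occupancy)))
  invisible(x)
}

#' Detect the enclosed cavity of a voxelized model
#'
#' Cavity and exterior are the probe-accessible empty spaces of the model.
#' The set of positions the center of a spherical probe can occupy is the
#' complement of the dilated lattice; flood-filling it 6-connected from
#' the grid boundary separates outside probe positions from enclosed ones
#' (the probe cannot pass openings narrower than its own diameter, so
#' enclosure survives sub-probe slits). Re-dilating each side by the probe
#' radius recovers the space the probe body sweeps: the exterior mask is
#' the swept outside, the cavity mask the swept volume of the largest
#' enclosed component. Enclosed pockets too small to host the probe are
#' not counted as cavity; additional probe-sized enclosed components are
#' reported as minor voids.
#'
#' @param grid a [voxelize()] result.
#' @return list of class `cavity_masks`: logical arrays `cavity` (largest
#'   enclosed probe-swept component), `exterior` (probe-swept outside),
#'   `minor_voids`, plus `n_minor_voids`.
#' @export
find_cavity <- function(grid) {
  dims <- grid$dims
  r_vox <- grid$probe_radius / grid$voxel_size
  ext_reach <- flood_exterior_cpp(grid$dilated_occupancy, dims)
  ext_closed <- array(dilate_mask_cpp(ext_reach, dims, r_vox), dims)
  empty <- !grid$occupancy
  exterior <- empty & ext_closed
  seed <- !grid$dilated_occupancy & !array(ext_reach, dims)
  if (!any(seed)) {
    warning("no cavity found (no enclosed space can host the probe)")
    return(structure(list(cavity = array(FALSE, dims), exterior = exterior,
                          minor_voids = array(FALSE, dims), n_minor_voids = 0L),
                     class = "cavity_masks"))
  }
  lab <- array(label_components_cpp(seed, dims, 6L), dims)
  sizes <- tabulate(lab[lab > 0])
  main <- which.max(sizes)
  cavity <- array(dilate_mask_cpp(lab == main, dims, r_vox), dims) & empty
  minor <- if (length(sizes) > 1) {
    array(dilate_mask_cpp(lab > 0 & lab != main, dims, r_vox), dims) &
      empty & !cavity
  } else {
    array(FALSE, dims)
  }
  structure(list(cavity = cavity,
                 exterior = exterior & !cavity,
                 minor_voids = minor,
                 n_minor_voids = as.integer(length(sizes) - 1L)),
            class = "cavity_masks")
}

#' Cavity volume and ellipsoid metrics
#'
#' Volume is the voxel count times the voxel volume, reported in nm^3
#' (1 nm^3 = 1000 A^3). Principal axes come from the eigendecomposition of
#' the covariance of cavity voxel centers; the full axis along eigenvector
#' k is `2 * sqrt(5 * lambda_k)`, the moment relation of a uniform solid
#' ellipsoid. Axes are returned in descending order.
#'
#' @param cavity logical array (a cavity mask).
#' @param grid the [voxelize()] grid the mask lives on.
#' @return list of class `cavity_report`: `cavity_volume` (nm^3),
#'   `cavity_axes` (full axes, nm, descending), `ellipsoid_volume`
#'   (closed-form `(pi/6) a b c`, nm^3), `n_voxels`, and `reliable`
#'   (`FALSE` for cavities under 10 voxels).
#' @export
cavity_metrics <- function(cavity, grid) {
  n_vox <- sum(cavity)
  if (n_vox == 0) stop("empty cavity mask")
  v <- grid$voxel_size
  vol_nm3 <- n_vox * v^3 / 1000
  idx <- which(cavity, arr.ind = TRUE)
  centers <- sweep((idx - 0.5) * v, 2, grid$origin, "+")
  if (n_vox > 1) {
    ev <- eigen(stats::cov(centers), symmetric = TRUE)
    axes_A <- 2 * sqrt(5 * pmax(ev$values, 0))
  } else {
    axes_A <- rep(v, 3)
  }
  axes_nm <- sort(axes_A, decreasing = TRUE) / 10
  structure(list(cavity_volume = vol_nm3,
                 cavity_axes = axes_nm,
                 ellipsoid_volume = ellipsoid_volume(axes_nm[1], axes_nm[2], axes_nm[3]),
                 n_voxels = n_vox,
                 reliable = n_vox >= 10),
            class = "cavity_report")
}

#' Enumerate openings between cavity and exterior
#'
#' An opening is a passage through the wall that is wider than the atomic
#' packing but narrower than the probe (which is what keeps the cavity
#' enclosed). Channel space is recovered by eroding the empty space by
#' `clearance` (voxels within `atom_radius + clearance` of an atom are
#' discarded, which removes atomic-scale packing gaps inside walls); its
#' 26-connected components outside the cavity and exterior masks that
#' touch both are the openings. Area is the channel voxel count times
#' `voxel_size^2`, in nm^2.
#'
#' @param grid a [voxelize()] grid.
#' @param cavity,exterior masks from [find_cavity()].
#' @param clearance minimum half-width of a passage, Angstrom; default 2.
#' @return data.frame with one row per opening: `opening`, `n_voxels`,
#'   `area_nm2`.
#' @export
detect_openings <- function(grid, cavity, exterior, clearance = 2) {
  dims <- grid$dims
  no_open <- data.frame(opening = integer(), n_voxels = integer(),
                        area_nm2 = numeric())
  wide <- !array(stamp_spheres_cpp(grid$points, grid$atom_radius + clearance,
                                   grid$origin, grid$voxel_size, dims), dims)
  cand <- wide & !cavity & !exterior
  if (!any(cand)) return(no_open)
  lab <- array(label_components_cpp(cand, dims, 26L), dims)
  near_cav <- adjacent6(adjacent6(cavity, dims) | cavity, dims)
  near_ext <- adjacent6(adjacent6(exterior, dims) | exterior, dims)
  ids <- seq_len(max(lab))
  keep <- vapply(ids, function(i) {
    v <- lab == i
    any(v & near_cav) && any(v & near_ext)
  }, logical(1))
  ids <- ids[keep]
  if (!length(ids)) return(no_open)
  sizes <- vapply(ids, function(i) sum(lab == i), integer(1))
  data.frame(opening = seq_along(ids), n_voxels = sizes,
             area_nm2 = sizes * grid$voxel_size^2 / 100)
}

# voxels with at least one TRUE 6-neighbor in `mask`
adjacent6 <- function(mask, dims) {
  out <- array(FALSE, dims)
  n <- dims
  out[-1, , ] <- out[-1, , ] | mask[-n[1], , ]
  out[-n[1], , ] <- out[-n[1], , ] | mask[-1, , ]
  out[, -1, ] <- out[, -1, ] | mask[, -n[2], ]
  out[, -n[2], ] <- out[, -n[2], ] | mask[, -1, ]
  out[, , -1] <- out[, , -1] | mask[, , -n[3]]
  out[, , -n[3]] <- out[, , -n[3]] | mask[, , -1]
  out
}

#' Classify surface residues as interior- or exterior-facing
#'
#' For each residue's C-alpha, the nearest empty voxel within
#' `reach_radius` decides the label: `interior` when it belongs to the
#' cavity, `exterior` when it belongs to the outside. Residues whose
#' nearest cavity and exterior voxels are within `tie_margin` of each
#' other, or that reach neither, are `buried`. Residues without a C-alpha
#' are excluded.
#'
#' @param model the [atomic_model()] that was voxelized.
#' @param cavity,exterior masks from [find_cavity()].
#' @param grid the [voxelize()] grid.
#' @param reach_radius search radius in Angstrom (default 8).
#' @param tie_margin tie distance in Angstrom (default 2).
#' @return data.frame of class `surface_classification`: `chain`, `resno`,
#'   `label` in {interior, exterior, buried}.
#' @export
classify_surface_residues <- function(model, cavity, exterior, grid,
                                      reach_radius = 8, tie_margin = 2) {
  r <- model$residues[!is.na(model$residues$x), ]
  pts <- as.matrix(r[, c("x", "y", "z")])
  code <- classify_points_cpp(pts, as.logical(cavity), as.logical(exterior),
                              grid$dims, grid$origin, grid$voxel_size,
                              reach_radius, tie_margin)
  out <- data.frame(chain = r$chain, resno = r$resno,
                    label = c("interior", "exterior", "buried")[code],
                    stringsAsFactors = FALSE)
  class(out) <- c("surface_classification", "data.frame")
  out
}

#' Full cavity analysis of a model
#'
#' Convenience pipeline: [voxelize()], [find_cavity()], [cavity_metrics()],
#' [detect_openings()], [classify_surface_residues()], plus the outer
#' extent of the assembly (axis-aligned bounding box of the atoms inflated
#' by the atom radius, nm, descending).
#'
#' @inheritParams voxelize
#' @inheritParams classify_surface_residues
#' @return list of class `cavity_analysis` combining the pieces.
#' @export
analyze_cavity <- function(model, voxel_size = 2, atom_radius = NULL,
                           probe_radius = 5, reach_radius = 8, tie_margin = 2) {
  grid <- voxelize(model, voxel_size, atom_radius, probe_radius)
  masks <- find_cavity(grid)
  has_cavity <- any(masks$cavity)
  metrics <- if (has_cavity) cavity_metrics(masks$cavity, grid) else NULL
  openings <- if (has_cavity) detect_openings(grid, masks$cavity, masks$exterior)
    else data.frame(opening = integer(), n_voxels = integer(), area_nm2 = numeric())
  surface <- classify_surface_residues(model, masks$cavity, masks$exterior,
                                       grid, reach_radius, tie_margin)
  pts <- model_points(model)
  extent <- unname(sort((apply(pts, 2, max) - apply(pts, 2, min) + 2 * grid$atom_radius) / 10,
                        decreasing = TRUE))
  structure(list(grid = grid, masks = masks, metrics = metrics,
                 openings = openings, surface = surface,
                 outer_extent = extent),
            class = "cavity_analysis")
}

#' @export
print.cavity_analysis <- function(x, ...) {
  cat(sprintf("<cavity_analysis> outer extent %.1f x %.1f x %.1f nm\n",
              x$outer_extent[1], x$outer_extent[2], x$outer_extent[3]))
  if (is.null(x$metrics)) {
    cat("  no enclosed cavity\n")
  } else {
    m <- x$metrics
    cat(sprintf("  cavity: %.1f nm^3 (approximately %d nm^3), full axes %.1f x %.1f x %.1f nm\n",
                m$cavity_volume, round(m$cavity_volume / 100) * 100,
                m$cavity_axes[1], m$cavity_axes[2], m$cavity_axes[3]))
    cat(sprintf("  ellipsoid (pi/6)abc volume: %.1f nm^3%s\n", m$ellipsoid_volume,
                if (m$reliable) "" else "  [unreliable: <10 voxels]"))
    cat(sprintf("  openings: %d\n", nrow(x$openings)))
  }
  cnt <- function(lab) sum(x$surface$label == lab)
  cat(sprintf("  surface residues: %d interior, %d exterior, %d buried\n",
              cnt("interior"), cnt("exterior"), cnt("buried")))
  invisible(x)
}
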