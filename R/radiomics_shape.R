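# 3D morphology features (33). Volume is voxel count x voxel volume; the
# surface comes from the smoothed marching-tetrahedra mesh (see R/mesh.R).
# All lengths are physical (mm); anisotropic spacing is honored.

# axis-aligned caliper extents of mask voxels projected along `axis`,
# measured over voxel footprints (centers +/- half a voxel)
projected_extents <- function(coords, spacing, axes) {
  vapply(axes, function(a) {
    diff(range(coords[, a])) + spacing[a]
  }, numeric(1))
}

#' Bidimensional diameter product on the largest axial slice
#'
#' On the axial (third-axis) slice with the largest lesion cross-section,
#' the product of the two in-plane axis-aligned caliper diameters (voxel
#' footprints included), in mm^2 — the volumetric stand-in for the
#' planimetric diameter product of the clinical RANO criteria, read off the
#' orthogonal image axes.
#'
#' @param mask 3D array, nonzero = lesion.
#' @param spacing Physical voxel size per axis (mm).
#' @return Area in mm^2.
#' @export
bidimensional_product <- function(mask, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(mask)) == 3, length(spacing) == 3, all(spacing > 0))
  if (sum(mask != 0) == 0) stop("empty lesion mask", call. = FALSE)
  counts <- apply(mask != 0, 3, sum)
  z <- which.max(counts)
  sl <- which(mask[, , z] != 0, arr.ind = TRUE)
  d1 <- (diff(range(sl[, 1])) + 1) * spacing[1]
  d2 <- (diff(range(sl[, 2])) + 1) * spacing[2]
  d1 * d2
}

# voxels with at least one exposed face (6-neighborhood)
boundary_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 3) return(mask)
    lo <- slice_shift(mask, ax, -1)
    hi <- slice_shift(mask, ax, 1)
    interior <- interior & lo & hi
  }
  mask & !interior
}

# shift a 3D logical array by one voxel along `ax`, padding with FALSE
slice_shift <- function(mask, ax, by) {
  d <- dim(mask)
  out <- array(FALSE, d)
  src <- lapply(d, seq_len)
  dst <- src
  if (by > 0) {
    src[[ax]] <- 1:(d[ax] - 1); dst[[ax]] <- 2:d[ax]
  } else {
    src[[ax]] <- 2:d[ax]; dst[[ax]] <- 1:(d[ax] - 1)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

max_pairwise_distance <- function(points) {
  if (nrow(points) == 1) return(0)
  if (nrow(points) > 250) { # convex-hull-free reduction: extreme points only
    keep <- unique(unlist(lapply(seq_len(ncol(points)), function(a) {
      c(which.min(points[, a]), which.max(points[, a]))
    })))
    # refine with the farthest-from-centroid shell
    ctr <- colMeans(points)
    d2 <- rowSums(sweep(points, 2, ctr)^2)
    keep <- unique(c(keep, order(d2, decreasing = TRUE)[seq_len(min(250, nrow(points)))]))
    points <- points[keep, , drop = FALSE]
  }
  max(dist(points))
}

#' Shape radiomic features (33)
#'
#' Volume and surface descriptors: voxel and mesh volume, mesh surface area,
#' surface/volume ratios, sphericity and compactness, principal-axis
#' lengths with elongation/flatness, bounding-box statistics, the
#' bidimensional diameter product, and radial boundary-distance statistics.
#' Shape features ignore the intensities entirely.
#'
#' @param lv A [labeled_volume()].
#' @param mesh Optional precomputed [mask_mesh()] of `lv$mask` (reused by
#'   [extract_features()] to avoid meshing twice).
#' @return One-row tibble with 33 columns prefixed `shape.`.
#' @export
extract_shape <- function(lv, mesh = NULL) {
  check_nonempty(lv)
  mask <- crop_to_mask(lv$mask) # all shape features are translation-invariant
  spacing <- lv$spacing
  voxvol <- prod(spacing)
  idx <- which(mask, arr.ind = TRUE)
  coords <- sweep(idx - 1, 2, spacing, `*`) # physical voxel centers
  n <- nrow(idx)
  v_voxel <- n * voxvol

  if (is.null(mesh)) mesh <- mask_mesh(mask, spacing)
  area <- mesh_area(mesh)
  v_mesh <- mesh_volume(mesh)

  r_eq <- (3 * v_voxel / (4 * pi))^(1 / 3)
  sphericity <- pi^(1 / 3) * (6 * v_voxel)^(2 / 3) / area
  bbox <- projected_extents(coords, spacing, 1:3)
  bbox_vol <- prod(bbox)

  # principal axes from the voxel-center covariance (physical units)
  if (n > 1) {
    ev <- eigen(stats::cov(coords), symmetric = TRUE)$values
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }
  axis_len <- 4 * sqrt(ev) # full axis lengths, ellipsoid convention
  elongation <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flatness <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0

  # maximal 3D diameter over voxel corner extremes (footprints included);
  # only boundary voxels (those with an exposed face) can be extremal
  bcoords <- coords[boundary_voxels(mask)[mask], , drop = FALSE]
  corners <- rbind(sweep(bcoords, 2, spacing / 2, `-`),
                   sweep(bcoords, 2, spacing / 2, `+`))
  max3d <- max_pairwise_distance(corners)

  max2d <- vapply(1:3, function(drop_axis) {
    keep <- setdiff(1:3, drop_axis)
    pts <- corners[, keep, drop = FALSE]
    pts <- pts[!duplicated(pts), , drop = FALSE]
    max_pairwise_distance(pts)
  }, numeric(1))
  # axial slice = fixed third axis, coronal = second, sagittal = first
  names(max2d) <- c("sagittal", "coronal", "axial")

  radial <- sqrt(rowSums(sweep(mesh$vertices, 2, colMeans(mesh$vertices))^2))

  out <- c(
    volume_voxel = v_voxel,
    volume_mesh = v_mesh,
    surface_area = area,
    surface_to_volume_ratio = area / v_voxel,
    volume_to_surface_ratio = v_voxel / area,
    sphericity = sphericity,
    compactness1 = v_voxel / (sqrt(pi) * area^(3 / 2)),
    compactness2 = 36 * pi * v_voxel^2 / area^3,
    spherical_disproportion = area / (4 * pi * r_eq^2),
    equivalent_sphere_radius = r_eq,
    equivalent_sphere_diameter = 2 * r_eq,
    max_3d_diameter = max3d,
    max_2d_diameter_axial = max2d[["axial"]],
    max_2d_diameter_coronal = max2d[["coronal"]],
    max_2d_diameter_sagittal = max2d[["sagittal"]],
    pca_major_axis = axis_len[1],
    pca_minor_axis = axis_len[2],
    pca_least_axis = axis_len[3],
    elongation = elongation,
    flatness = flatness,
    bbox_extent_x = bbox[1],
    bbox_extent_y = bbox[2],
    bbox_extent_z = bbox[3],
    bbox_volume = bbox_vol,
    extent_fraction = v_voxel / bbox_vol,
    bidimensional_product = bidimensional_product(mask, spacing),
    radial_mean = mean(radial),
    radial_sd = if (length(radial) > 1) sd(radial) else 0,
    radial_max = max(radial),
    radial_min = min(radial),
    radial_cv = if (length(radial) > 1 && mean(radial) > 0)
      sd(radial) / mean(radial) else 0,
    mesh_voxel_volume_ratio = v_mesh / v_voxel,
    least_major_ratio = if (axis_len[1] > 0) axis_len[3] / axis_len[1] else 0
  )
  names(out) <- paste0("shape.", names(out))
  stopifnot(length(out) == 33, all(is.finite(out)))
  row_tibble(out)
}
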