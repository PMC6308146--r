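# Meshed surface area of a binary mask: the 0.5-level set of the lightly
# Gaussian-smoothed indicator (sigma in voxels), triangulated by marching
# tetrahedra with interpolated crossings. Smoothing suppresses the
# staircase bias of meshing a raw binary field.
mask_surface_area <- function(m, spacing, sigma_vox = 0.7) {
  f <- gaussian_smooth(array(as.numeric(m), dim(m)), rep(sigma_vox, 3))
  cpp_surface_area(f, dim(m), spacing, 0.5)
}

#' Morphological (shape and size) features of an ROI
#'
#' Thirteen descriptors of the mask geometry: volume (voxel count times
#' voxel volume), meshed surface area (marching-tetrahedra surface of the
#' binary mask), surface-to-volume ratio, sphericity, maximum 3D diameter,
#' three maximum in-plane 2D diameters, the three principal-axis lengths
#' (4 sqrt(lambda) of the voxel-coordinate covariance eigenvalues),
#' elongation and flatness. Shape is geometry only: intensity outliers
#' excluded during quantization stay in the mask here.
#'
#' @param mask a [roi_mask()] (nonempty), usually on the isotropic grid.
#' @param spacing optional per-axis voxel size override in mm.
#' @return Named numeric vector of 13 features (`shape_*`).
#' @export
shape_features <- function(mask, spacing = mask$spacing) {
  if (mask_is_empty(mask)) stop("mask is empty")
  m <- mask$values
  dims <- dim(m)
  nvox <- sum(m)
  vol <- nvox * prod(spacing)
  area <- mask_surface_area(m, spacing)

  # surface voxels: mask voxels with an exposed face
  surf <- m & !erode6(m)
  sw <- which(surf, arr.ind = TRUE)
  smm <- sweep(sw - 1, 2, spacing, `*`)
  max3d <- if (nrow(smm) > 1) cpp_max_pairwise_dist(smm) else 0

  max2d <- function(drop_axis) {
    planes <- unique(sw[, drop_axis])
    best <- 0
    keep <- setdiff(1:3, drop_axis)
    for (p in planes) {
      pts <- smm[sw[, drop_axis] == p, keep, drop = FALSE]
      if (nrow(pts) > 1) best <- max(best, cpp_max_pairwise_dist(pts))
    }
    best
  }

  w <- which(m, arr.ind = TRUE)
  mm <- sweep(w - 1, 2, spacing, `*`)
  if (nvox < 2) {
    warning("single-voxel mask: principal axes degenerate, reported as 0")
    lam <- c(0, 0, 0)
  } else {
    lam <- sort(eigen(stats::cov(mm), symmetric = TRUE,
                      only.values = TRUE)$values, decreasing = TRUE)
    lam[lam < 0] <- 0
  }
  axes <- 4 * sqrt(lam)
  elong <- if (lam[1] > 0) sqrt(lam[2] / lam[1]) else 0
  flat <- if (lam[1] > 0) sqrt(lam[3] / lam[1]) else 0

  c(shape_Volume = vol,
    shape_SurfaceArea = area,
    shape_SurfaceVolumeRatio = area / vol,
    shape_Sphericity = (pi^(1 / 3)) * (6 * vol)^(2 / 3) / area,
    shape_Max3DDiameter = max3d,
    shape_Max2DSlice = max2d(3),    # in-plane (axis 1-2) diameter
    shape_Max2DColumn = max2d(2),   # axis 1-3 plane
    shape_Max2DRow = max2d(1),      # axis 2-3 plane
    shape_MajorAxis = axes[1],
    shape_MinorAxis = axes[2],
    shape_LeastAxis = axes[3],
    shape_Elongation = elong,
    shape_Flatness = flat)
}
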