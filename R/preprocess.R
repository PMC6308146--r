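#' Resample a volume and its ROI mask to isotropic voxels
#'
#' Resamples the image with tricubic (Keys) interpolation and the mask with
#' trilinear interpolation thresholded at 0.5, onto an isotropic grid of
#' `target_mm` voxels sharing the input origin. The output grid covers the
#' input physical extent (output sample points never extrapolate).
#'
#' @param vol an [image_volume()].
#' @param mask a [roi_mask()] congruent with `vol`.
#' @param target_mm isotropic target voxel size in mm (default 1).
#' @return List with resampled `image` and `mask`; both carry the exact
#'   spacing `c(target, target, target)`.
#' @export
resample_isotropic <- function(vol, mask, target_mm = 1) {
  check_congruent(vol, mask)
  out_dim <- out_grid_dim(dim(vol$values), vol$spacing, target_mm)
  out_sp <- rep(target_mm, 3)
  img <- cpp_resample(vol$values, dim(vol$values), vol$spacing,
                      out_dim, out_sp, 3L)
  mk <- resample_mask(mask, target_mm)
  if (mask_is_empty(mk)) stop("resampled mask is empty")
  list(image = image_volume(array(img, out_dim), out_sp, vol$origin),
       mask = mk)
}

out_grid_dim <- function(dims, spacing, target) {
  as.integer(floor((dims - 1) * spacing / target) + 1)
}

resample_mask <- function(mask, target_mm = 1) {
  out_dim <- out_grid_dim(dim(mask$values), mask$spacing, target_mm)
  out_sp <- rep(target_mm, 3)
  mk <- cpp_resample(array(as.numeric(mask$values), dim(mask$values)),
                     dim(mask$values), mask$spacing, out_dim, out_sp, 1L)
  roi_mask(array(mk >= 0.5, out_dim), out_sp, mask$origin, label = mask$label)
}

#' Normalize ROI gray levels and quantize to discrete levels
#'
#' Computes the ROI mean `m` and standard deviation `s`, excludes voxels
#' with intensities outside `[m - 3s, m + 3s]`, and maps the remaining
#' intensities by equal-width binning of that range onto integer levels
#' `1..n_levels` (default 64, i.e. 6-bit). The mapping is monotone and
#' invariant under positive affine intensity transforms. A constant ROI
#' (`s = 0`) maps every voxel to level 1 with a warning, so entropy-type
#' features take their analytic limit of zero.
#'
#' @param vol an [image_volume()] (typically the resampled original or a
#'   filtered derivative).
#' @param mask a [roi_mask()] congruent with `vol`, nonempty.
#' @param n_levels number of gray levels (>= 2).
#' @return A `quantized_roi`: integer `levels` array (0 outside the ROI and
#'   for excluded voxels), logical `include` array, the included raw
#'   intensities, `m`, `s`, `n_excluded`, `n_levels` and the voxel spacing.
#' @export
normalize_and_quantize <- function(vol, mask, n_levels = 64) {
  check_congruent(vol, mask)
  if (mask_is_empty(mask)) stop("mask is empty")
  stopifnot(n_levels >= 2)
  x <- vol$values[mask$values]
  m <- mean(x)
  s <- sd(x)
  dims <- dim(vol$values)
  levels <- array(0L, dims)
  if (!is.finite(s) || s == 0) {
    warning("constant ROI (s = 0): all voxels assigned level 1")
    levels[mask$values] <- 1L
    return(structure(
      list(levels = levels, include = mask$values,
           raw_values = x, m = m, s = 0, n_excluded = 0L,
           n_levels = as.integer(n_levels), spacing = vol$spacing),
      class = "quantized_roi"))
  }
  lo <- m - 3 * s
  hi <- m + 3 * s
  inside <- x >= lo & x <= hi
  lev <- floor((x[inside] - lo) / (hi - lo) * n_levels) + 1
  lev[lev > n_levels] <- n_levels   # right-closed top bin
  include <- mask$values
  include[mask$values] <- inside
  levels[include] <- as.integer(lev)
  structure(
    list(levels = levels, include = include, raw_values = x[inside],
         m = m, s = s, n_excluded = sum(!inside),
         n_levels = as.integer(n_levels), spacing = vol$spacing),
    class = "quantized_roi"
  )
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat("<quantized_roi> ", length(x$raw_values), " voxels in 1..",
      x$n_levels, " (", x$n_excluded, " excluded; m = ", signif(x$m, 5),
      ", s = ", signif(x$s, 5), ")\n", sep = "")
  invisible(x)
}
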