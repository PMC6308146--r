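#' 3D image volume
#'
#' A scalar 3D grid (MRI intensities in arbitrary units, or dose in Gy) with
#' per-axis voxel spacing and a physical origin. Voxel `(i, j, k)` (1-based)
#' sits at `origin + (i-1, j-1, k-1) * spacing` mm.
#'
#' @param values 3D numeric array.
#' @param spacing numeric length-3, voxel size per axis in mm (positive).
#' @param origin numeric length-3, physical position of voxel (1,1,1) in mm.
#' @return An `image_volume` object.
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3L, length(spacing) == 3L)
  if (any(spacing <= 0)) stop("`spacing` must be strictly positive")
  if (!all(is.finite(values))) stop("`values` must be finite")
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "image_volume"
  )
}

#' Binary region-of-interest mask
#'
#' A binary 3D mask congruent with its parent [image_volume()]: the manually
#' delineated gross tumor volume (GTV), a recurrence volume, or a
#' second-observer contour.
#'
#' @param values 3D logical (or 0/1) array.
#' @param spacing,origin geometry, as in [image_volume()].
#' @param label one of `"GTV"`, `"V_recur"`, `"observer2"`.
#' @return A `roi_mask` object.
#' @export
roi_mask <- function(values, spacing, origin = c(0, 0, 0), label = "GTV") {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3L)
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask values must be 0/1 with no NA")
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin), label = label),
    class = "roi_mask"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask:", x$label, "> ", sum(x$values), " voxels of ",
      length(x$values), "\n", sep = "")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' @export
dim.roi_mask <- function(x) dim(x$values)

check_congruent <- function(vol, mask) {
  if (!identical(dim(vol$values), dim(mask$values)))
    stop("mask and volume shapes differ")
  if (max(abs(vol$spacing - mask$spacing)) > 1e-8)
    stop("mask and volume spacings differ")
  invisible(TRUE)
}

mask_is_empty <- function(mask) !any(mask$values)

#' Physical voxel coordinates of mask voxels
#' @noRd
mask_coords_mm <- function(mask) {
  w <- which(mask$values, arr.ind = TRUE)
  sweep((w - 1) %*% diag(mask$spacing), 2, -mask$origin)
}

#' Check that a mask is a single connected component
#'
#' @param mask a [roi_mask()].
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return Logical scalar.
#' @export
is_single_component <- function(mask, connectivity = 6) {
  lab <- cpp_label_components(array(as.integer(mask$values), dim(mask$values)),
                              dim(mask$values), as.integer(connectivity))
  attr(lab, "n_components") == 1L
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' carry the spacing into the package's containers. The origin is kept at
#' zero: all geometry in this package is relative to the grid itself.
#'
#' @param path file path of a NIfTI image (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns an [image_volume()]; `read_mask()` a
#'   [roi_mask()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim(img)[1:3]),
               spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @param label mask label, see [roi_mask()].
#' @export
read_mask <- function(path, label = "GTV") {
  img <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(img) > 0.5, dim(img)[1:3]),
           spacing = RNifti::pixdim(img)[1:3], label = label)
}

#' @rdname read_volume
#' @param x an [image_volume()] or [roi_mask()].
#' @export
write_volume <- function(x, path) {
  vals <- if (inherits(x, "roi_mask")) array(as.numeric(x$values), dim(x$values))
          else x$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
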