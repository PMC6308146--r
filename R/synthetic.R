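#' Specify a synthetic two-phenotype tumor cohort
#'
#' Defines the study conditions for the synthetic stand-in cohort: textured
#' tumor volumes of two phenotype classes ("IFR", tumors that later recur
#' in-field, and "NPD", non-progressing tumors) on an SPAIR-T2W-like
#' acquisition grid. Each tumor is a Gaussian random field — white noise
#' convolved with an isotropic Gaussian kernel whose correlation length (in
#' mm) differs between the classes — plus a constant offset and additive
#' noise. The intensity scale is arbitrary: downstream gray-level
#' normalization removes scale and offset.
#'
#' Defaults mirror the clinical cohort the package targets: 11 IFR and 16
#' NPD cases on a 0.65 x 0.65 x 4 mm grid. IFR tumors get the shorter
#' correlation length (finer, more heterogeneous texture).
#'
#' @param n_ifr,n_npd cases per class.
#' @param grid_shape voxels per axis.
#' @param spacing_mm voxel size per axis in mm.
#' @param texture_scale_ifr,texture_scale_npd Gaussian correlation length in
#'   mm for each class.
#' @param noise_sd additive white-noise standard deviation (intensity units).
#' @param roi_radius_mm ellipsoid semi-axes of the tumor ROI in mm; each
#'   case's radii are jittered by +/-10 percent.
#' @param intensity_offset,intensity_amplitude offset and scale applied to
#'   the unit random field (arbitrary units).
#' @param observer2_magnitude_mm boundary displacement bound for the
#'   simulated second-observer contour (see [perturb_contour()]).
#' @param seed integer RNG seed; the whole cohort is a pure function of the
#'   spec including this seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_ifr = 11, n_npd = 16,
                        grid_shape = c(48, 48, 12),
                        spacing_mm = c(0.65, 0.65, 4),
                        texture_scale_ifr = 1.5,
                        texture_scale_npd = 4,
                        noise_sd = 0.2,
                        roi_radius_mm = c(9, 9, 9),
                        intensity_offset = 100,
                        intensity_amplitude = 20,
                        observer2_magnitude_mm = 1,
                        seed = 1L) {
  stopifnot(n_ifr >= 0, n_npd >= 0, length(grid_shape) == 3,
            length(spacing_mm) == 3, length(roi_radius_mm) == 3)
  if (any(spacing_mm <= 0)) stop("`spacing_mm` must be strictly positive")
  if (texture_scale_ifr == texture_scale_npd)
    stop("texture scales must differ between classes for a separable cohort")
  structure(
    list(n_ifr = as.integer(n_ifr), n_npd = as.integer(n_npd),
         grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
         texture_scale_ifr = texture_scale_ifr,
         texture_scale_npd = texture_scale_npd,
         noise_sd = noise_sd, roi_radius_mm = roi_radius_mm,
         intensity_offset = intensity_offset,
         intensity_amplitude = intensity_amplitude,
         observer2_magnitude_mm = observer2_magnitude_mm,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# One RNG stream per case, keyed by (seed, class, index), so changing the
# cohort size does not reshuffle existing cases.
case_seed <- function(seed, class_label, index, stream = 0L) {
  code <- if (class_label == "IFR") 1L else 2L
  as.integer((as.double(seed) * 7919 + code * 104729 + index * 13 +
                stream * 7907) %% 2147483647)
}

#' Generate one synthetic tumor case
#'
#' Produces the MRI-like volume and its tumor mask for one case of a
#' [cohort_spec()] cohort. The volume is a smoothed-white-noise Gaussian
#' random field with the class's correlation length; the mask is an
#' ellipsoid (radii jittered per case) fully inside the grid. Bit-identical
#' for repeated calls with the same `(seed, class_label, index)`.
#'
#' @param spec a [cohort_spec()].
#' @param class_label `"IFR"` or `"NPD"`.
#' @param index 1-based case index within the class.
#' @return List with elements `image` ([image_volume()]) and `mask`
#'   ([roi_mask()]).
#' @export
generate_tumor_case <- function(spec, class_label = c("IFR", "NPD"), index = 1) {
  class_label <- match.arg(class_label)
  n_class <- if (class_label == "IFR") spec$n_ifr else spec$n_npd
  if (index < 1 || index > n_class)
    stop("`index` out of range for class ", class_label)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(case_seed(spec$seed, class_label, index))

  dims <- spec$grid_shape
  scale_mm <- if (class_label == "IFR") spec$texture_scale_ifr
              else spec$texture_scale_npd
  white <- array(rnorm(prod(dims)), dims)
  field <- gaussian_smooth(white, sigma_vox = scale_mm / spec$spacing_mm)
  vals <- spec$intensity_offset + spec$intensity_amplitude * field
  if (spec$noise_sd > 0)
    vals <- vals + array(rnorm(prod(dims), sd = spec$noise_sd), dims)

  radii <- spec$roi_radius_mm * runif(3, 0.9, 1.1)
  extent <- (dims - 1) * spec$spacing_mm
  center <- extent / 2 + runif(3, -1, 1)
  mask_arr <- ellipsoid_mask(dims, spec$spacing_mm, center, radii)
  touching <- mask_touches_boundary(mask_arr)
  if (any(touching))
    stop("ROI touches the grid boundary on axis ",
         paste(which(touching), collapse = ", "),
         "; enlarge grid_shape or shrink roi_radius_mm")
  list(image = image_volume(vals, spec$spacing_mm),
       mask = roi_mask(mask_arr, spec$spacing_mm, label = "GTV"))
}

ellipsoid_mask <- function(dims, spacing, center_mm, radii_mm) {
  ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - 1) * spacing[a] -
                                   center_mm[a]) / radii_mm[a])
  x2 <- array(ax[[1]]^2, dims)
  y2 <- aperm(array(ax[[2]]^2, dims[c(2, 1, 3)]), c(2, 1, 3))
  z2 <- aperm(array(ax[[3]]^2, dims[c(3, 1, 2)]), c(2, 3, 1))
  x2 + y2 + z2 <= 1
}

mask_touches_boundary <- function(m) {
  d <- dim(m)
  c(any(m[c(1, d[1]), , ]), any(m[, c(1, d[2]), ]), any(m[, , c(1, d[3])]))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Simulate a perturbed second-observer contour
#'
#' Stands in for repeated manual delineation: the mask boundary is displaced
#' by a smooth random signed-distance offset bounded by `magnitude_mm`,
#' emulating inter-observer contouring variability. Deterministic given
#' `seed`. If the displacement disconnects the region, the largest
#' 6-connected component is kept, so the result remains a single contour.
#'
#' @param mask a [roi_mask()] (nonempty).
#' @param magnitude_mm maximum radial boundary displacement in mm;
#'   `0` returns the input mask unchanged.
#' @param seed integer RNG seed.
#' @return A [roi_mask()] labelled `"observer2"`.
#' @export
perturb_contour <- function(mask, magnitude_mm = 1, seed = 1L) {
  if (mask_is_empty(mask)) stop("mask is empty")
  if (magnitude_mm == 0) {
    out <- mask; out$label <- "observer2"
    return(out)
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  dims <- dim(mask$values)
  sp <- mask$spacing
  # signed distance between voxel centers across the boundary: for mask
  # voxels, minus the distance to the nearest outside voxel; for outside
  # voxels, the distance to the nearest mask voxel. Nearest opposite-side
  # voxels always lie in the one-voxel boundary layers, so the search sets
  # stay small.
  inner <- mask$values & !erode6(mask$values)
  outer <- dilate6(mask$values) & !mask$values
  vox_mm <- function(w) sweep(w - 1, 2, sp, `*`)
  all_mm <- vox_mm(which(array(TRUE, dims), arr.ind = TRUE))
  din <- array(cpp_min_dist_to_set(
    all_mm, vox_mm(which(inner, arr.ind = TRUE))), dims)
  dout <- array(cpp_min_dist_to_set(
    all_mm, vox_mm(which(outer, arr.ind = TRUE))), dims)
  sdf <- din
  sdf[mask$values] <- -dout[mask$values]
  # the interface runs midway between the two boundary voxel layers, so the
  # layers themselves sit at half their center-to-center distance
  sdf[inner] <- -dout[inner] / 2
  sdf[outer] <- din[outer] / 2

  disp <- gaussian_smooth(array(rnorm(prod(dims)), dims), sigma_vox = 5 / sp)
  disp <- disp / max(abs(disp)) * magnitude_mm
  new_mask <- sdf <= disp
  # the surface proxy sits one voxel inside; voxels at sdf = 0 stay unless
  # pushed out, outside voxels join when the displacement reaches them
  if (!any(new_mask)) stop("perturbation emptied the mask")
  lab <- cpp_label_components(array(as.integer(new_mask), dims), dims, 6L)
  if (attr(lab, "n_components") > 1L) {
    keep <- which.max(tabulate(lab[lab > 0]))
    new_mask <- array(lab == keep, dims)
  }
  roi_mask(new_mask, sp, mask$origin, label = "observer2")
}

# shift an array along one axis, padding with FALSE (out-of-grid = outside)
shift_arr <- function(a, ax, by) {
  d <- dim(a)
  out <- array(FALSE, d)
  n <- d[ax]
  if (abs(by) >= n) return(out)
  if (ax == 1) {
    if (by > 0) out[1:(n - by), , ] <- a[(1 + by):n, , ]
    else out[(1 - by):n, , ] <- a[1:(n + by), , ]
  } else if (ax == 2) {
    if (by > 0) out[, 1:(n - by), ] <- a[, (1 + by):n, ]
    else out[, (1 - by):n, ] <- a[, 1:(n + by), ]
  } else {
    if (by > 0) out[, , 1:(n - by)] <- a[, , (1 + by):n]
    else out[, , (1 - by):n] <- a[, , 1:(n + by)]
  }
  out
}

erode6 <- function(m) {
  out <- m
  for (ax in 1:3) out <- out & shift_arr(m, ax, 1) & shift_arr(m, ax, -1)
  out
}

dilate6 <- function(m) {
  out <- m
  for (ax in 1:3) out <- out | shift_arr(m, ax, 1) | shift_arr(m, ax, -1)
  out
}

#' Dice overlap of two masks
#'
#' @param a,b [roi_mask()] objects on the same grid.
#' @return Dice similarity coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a$values), dim(b$values)))
  2 * sum(a$values & b$values) / (sum(a$values) + sum(b$values))
}

#' Specify a synthetic dosimetric recurrence case
#'
#' Ground-truth control for the isodose-coverage recurrence rule: a smooth
#' radially decreasing dose field is scaled so that a known fraction of the
#' recurrence-volume voxels receives at least 95 percent of the
#' prescription dose.
#'
#' @param prescription_gy prescribed dose in Gy (> 0).
#' @param target_fraction_in intended fraction of recurrence voxels at or
#'   above the 95 percent isodose, in \[0, 1\].
#' @param recur_radius_mm radius of the spherical recurrence volume in mm.
#' @param center_offset_mm offset of the recurrence sphere from the dose
#'   focal point, in mm.
#' @param seed integer RNG seed (reserved; generation is deterministic).
#' @return A `dose_case_spec` object.
#' @export
dose_case_spec <- function(prescription_gy = 70, target_fraction_in = 0.95,
                           recur_radius_mm = 6,
                           center_offset_mm = c(2.3, 1.2, 0.6), seed = 1L) {
  stopifnot(prescription_gy > 0,
            target_fraction_in >= 0, target_fraction_in <= 1)
  structure(
    list(prescription_gy = prescription_gy,
         target_fraction_in = target_fraction_in,
         recur_radius_mm = recur_radius_mm,
         center_offset_mm = center_offset_mm, seed = as.integer(seed)),
    class = "dose_case_spec"
  )
}

#' Generate a dose grid and recurrence mask with known isodose coverage
#'
#' Builds a [recurrence_case()] on the given grid geometry. The dose is a
#' smooth Gaussian-shaped field centered on the grid, scaled so that the
#' achieved fraction of recurrence-mask voxels with dose at or above
#' `0.95 * prescription_gy` matches the spec's `target_fraction_in` to
#' within the voxel-count granularity (and always within +/- 0.02). The
#' achieved fraction is stored as ground truth.
#'
#' @param spec a [dose_case_spec()].
#' @param grid_dim,grid_spacing dose-grid geometry (voxels, mm).
#' @param site,time_to_failure_months optional clinical annotations.
#' @return A [recurrence_case()] with extra field `achieved_fraction_in`.
#' @export
generate_dose_case <- function(spec, grid_dim = c(64, 64, 48),
                               grid_spacing = c(1, 1, 1),
                               site = "local", time_to_failure_months = NA) {
  dims <- as.integer(grid_dim)
  sp <- grid_spacing
  extent <- (dims - 1) * sp
  focal <- extent / 2
  rec_center <- focal + spec$center_offset_mm

  mask_arr <- ellipsoid_mask(dims, sp, rec_center, rep(spec$recur_radius_mm, 3))
  if (!any(mask_arr)) stop("recurrence sphere lies outside the grid")

  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * sp[a] - focal[a])
  r2 <- array(ax[[1]]^2, dims) +
    aperm(array(ax[[2]]^2, dims[c(2, 1, 3)]), c(2, 1, 3)) +
    aperm(array(ax[[3]]^2, dims[c(3, 1, 2)]), c(2, 3, 1))
  # tiny strictly-monotone lattice perturbation so every voxel has a unique
  # effective radius (lattice shells otherwise tie, making fine fraction
  # targets unreachable); the dose stays smooth and radially decreasing
  eps <- array(0, dims)
  eps <- eps + array(seq_len(dims[1]) * 1e-4, dims) +
    aperm(array(seq_len(dims[2]) * 1e-6, dims[c(2, 1, 3)]), c(2, 1, 3)) +
    aperm(array(seq_len(dims[3]) * 1e-8, dims[c(3, 1, 2)]), c(2, 3, 1))
  r2 <- r2 + eps
  r <- sqrt(r2)
  rmask <- sort(r[mask_arr])
  n <- length(rmask)

  if (spec$target_fraction_in <= 0) {
    R <- rmask[1] - 1e-6
  } else if (spec$target_fraction_in >= 1) {
    R <- rmask[n] + 1e-6
  } else {
    # choose the threshold radius between distinct radii whose cumulative
    # voxel fraction is closest to the target (radius ties are common on a
    # lattice, so quantiles alone can overshoot)
    ru <- unique(rmask)
    cum <- cumsum(tabulate(match(rmask, ru))) / n
    j <- which.min(abs(cum - spec$target_fraction_in))
    R <- if (j < length(ru)) (ru[j] + ru[j + 1]) / 2 else ru[j] + 1e-6
  }
  achieved <- mean(rmask <= R)
  if (abs(achieved - spec$target_fraction_in) > 0.02)
    stop("target fraction ", spec$target_fraction_in,
         " unreachable on this geometry (achievable: ", round(achieved, 4), ")")

  a <- max(extent) / 2          # dose fall-off scale
  level <- 0.95 * spec$prescription_gy
  dose <- level * exp((R^2 - r2) / (2 * a^2))
  dose <- pmin(dose, 1.05 * spec$prescription_gy)
  case <- recurrence_case(
    dose = image_volume(dose, sp),
    prescription_gy = spec$prescription_gy,
    recur_mask = roi_mask(mask_arr, sp, label = "V_recur"),
    site = site, time_to_failure_months = time_to_failure_months
  )
  case$achieved_fraction_in <- achieved
  case
}

#' Simulate the full synthetic cohort
#'
#' Generates every case of a [cohort_spec()]: image, tumor mask, and the
#' perturbed second-observer mask used for reproducibility (ICC) analysis.
#'
#' @param spec a [cohort_spec()].
#' @return A `synthetic_cohort`: list with `cases` (list of per-case lists
#'   `id`, `label`, `image`, `mask`, `mask_obs2`) and `manifest` (tibble:
#'   case id, class, per-case seed, texture scale).
#' @export
simulate_cohort <- function(spec) {
  gen_class <- function(label, n) {
    lapply(seq_len(n), function(i) {
      tc <- generate_tumor_case(spec, label, i)
      obs2 <- perturb_contour(tc$mask, spec$observer2_magnitude_mm,
                              seed = case_seed(spec$seed, label, i, stream = 1L))
      list(id = sprintf("%s_%02d", label, i), label = label,
           image = tc$image, mask = tc$mask, mask_obs2 = obs2)
    })
  }
  cases <- c(gen_class("IFR", spec$n_ifr), gen_class("NPD", spec$n_npd))
  manifest <- tibble::tibble(
    case_id = vapply(cases, `[[`, "", "id"),
    label = vapply(cases, `[[`, "", "label"),
    case_seed = vapply(cases, function(cs)
      case_seed(spec$seed, cs$label, as.integer(sub(".*_", "", cs$id))), 0L),
    texture_scale_mm = ifelse(vapply(cases, `[[`, "", "label") == "IFR",
                              spec$texture_scale_ifr, spec$texture_scale_npd)
  )
  structure(list(cases = cases, manifest = manifest, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$cases), " cases (",
      x$spec$n_ifr, " IFR, ", x$spec$n_npd, " NPD)\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes each case as a NIfTI pair (image, mask) plus the second-observer
#' mask, and the cohort manifest as CSV.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (cs in cohort$cases) {
    write_volume(cs$image, file.path(dir, paste0(cs$id, "_image.nii.gz")))
    write_volume(cs$mask, file.path(dir, paste0(cs$id, "_mask.nii.gz")))
    write_volume(cs$mask_obs2, file.path(dir, paste0(cs$id, "_mask_obs2.nii.gz")))
  }
  write.csv(cohort$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
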