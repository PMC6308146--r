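derivation_tags <- function() {
  c("LoG_0.5", "LoG_1.5", "LoG_2.5",
    "W_LLL", "W_LLH", "W_LHL", "W_LHH",
    "W_HLL", "W_HLH", "W_HHL", "W_HHH")
}

feature_family <- function(key) sub("_.*$", "", sub("^.*__", "", key))

#' The default 1117-feature manifest
#'
#' Enumerates every feature key the default extraction produces: 13 shape +
#' 18 first-order + 74 texture features on the original image (105), plus
#' 18 + 74 = 92 per derived image for the 3 LoG and 8 wavelet derivations
#' (11 x 92), totalling 1117. Derived keys follow the grammar
#' `<tag>__<family>_<name>`, e.g. `W_HLL__gldm_DE`.
#'
#' @return A tibble with columns `key`, `derivation`, `family`, `name`.
#' @export
feature_manifest <- function() {
  shape <- names(shape_feature_template())
  fo <- names(first_order_template())
  tex <- names(texture_template())
  orig <- c(shape, fo, tex)
  derived <- unlist(lapply(derivation_tags(), function(tag)
    paste0(tag, "__", c(fo, tex))))
  keys <- c(orig, derived)
  tibble::tibble(
    key = keys,
    derivation = c(rep("original", length(orig)),
                   rep(derivation_tags(), each = length(fo) + length(tex))),
    family = feature_family(keys),
    name = sub("^[^_]*_", "", sub("^.*__", "", keys))
  )
}

shape_feature_template <- function() {
  setNames(rep(NA_real_, 13),
           c("shape_Volume", "shape_SurfaceArea", "shape_SurfaceVolumeRatio",
             "shape_Sphericity", "shape_Max3DDiameter", "shape_Max2DSlice",
             "shape_Max2DColumn", "shape_Max2DRow", "shape_MajorAxis",
             "shape_MinorAxis", "shape_LeastAxis", "shape_Elongation",
             "shape_Flatness"))
}

first_order_template <- function() {
  setNames(rep(NA_real_, 18),
           c("F_Energy", "F_Entropy", "F_Min", "F_P10", "F_P90", "F_Max",
             "F_Mean", "F_Median", "F_IQR", "F_Range", "F_MAD", "F_rMAD",
             "F_RMS", "F_Skewness", "F_Kurtosis", "F_Variance",
             "F_Uniformity", "F_SD"))
}

texture_template <- function() {
  glcm <- c("Autocorrelation", "CP", "CS", "CT", "Contrast", "Correlation",
            "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
            "JointEnergy", "JointEntropy", "JointAverage", "IMC", "IMC2",
            "IDM", "IDMN", "ID", "IDN", "InverseVariance",
            "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares")
  gldm <- c("SDE", "LDE", "GLN", "DN", "DNN", "GLV", "DV", "DE", "LGLE",
            "HGLE", "SDLGLE", "SDHGLE", "LDLGLE", "LDHGLE")
  ngtdm <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  setNames(rep(NA_real_, 74),
           c(paste0("glcm_", glcm), paste0("glrlm_", glrlm_names),
             paste0("glszm_", glszm_names), paste0("gldm_", gldm),
             paste0("ngtdm_", ngtdm)))
}

#' Abbreviation map for feature keys
#'
#' Machine-readable expansion of the abbreviated feature names used in the
#' manifest (e.g. `glcm_CT` = cluster tendency, `gldm_DE` = dependence
#' entropy, `F_RMS` = first-order root mean squared, `glcm_IMC` =
#' informational measure of correlation 1).
#'
#' @return A tibble with columns `abbrev` and `full_name`.
#' @export
feature_abbreviations <- function() {
  path <- system.file("extdata", "feature_abbreviations.json",
                      package = "radrecur")
  m <- jsonlite::fromJSON(path)
  tibble::tibble(abbrev = names(m), full_name = unname(unlist(m)))
}

# features for one quantized ROI of a derived image (no shape)
intensity_features <- function(qroi) {
  c(first_order_features(qroi), texture_features(qroi))
}

#' Extract the full radiomic feature vector of one case
#'
#' Runs the whole per-case chain: isotropic resampling, gray-level
#' normalization and 64-level quantization, the 11 derived images, and all
#' feature families, yielding the 1117-key vector of [feature_manifest()].
#' Filtered images are re-normalized and re-quantized within the ROI before
#' texture computation, since LoG and wavelet outputs live on their own
#' intensity scales. Any non-finite feature flags the case (attribute
#' `flagged`) rather than being dropped.
#'
#' @param vol an [image_volume()] (native grid).
#' @param mask a [roi_mask()] congruent with `vol`.
#' @param target_mm isotropic resampling target in mm.
#' @param n_levels gray levels for quantization.
#' @return Named numeric vector of 1117 features with attribute `flagged`.
#' @export
extract_features <- function(vol, mask, target_mm = 1, n_levels = 64) {
  rs <- resample_isotropic(vol, mask, target_mm)
  derived <- derive_images(rs$image)
  extract_from_derived(rs$image, derived, rs$mask, n_levels)
}

# core extraction on precomputed resampled image + derived images; the mask
# must already live on the same isotropic grid
extract_from_derived <- function(image_rs, derived, mask_rs, n_levels = 64) {
  out <- c(
    shape_features(mask_rs),
    intensity_features(normalize_and_quantize(image_rs, mask_rs, n_levels))
  )
  for (tag in names(derived)) {
    q <- normalize_and_quantize(derived[[tag]], mask_rs, n_levels)
    f <- intensity_features(q)
    names(f) <- paste0(tag, "__", names(f))
    out <- c(out, f)
  }
  flagged <- !all(is.finite(out))
  if (flagged)
    warning("case flagged: non-finite features ",
            paste(head(names(out)[!is.finite(out)], 5), collapse = ", "))
  attr(out, "flagged") <- flagged
  out
}

#' Extract features for every case of a cohort
#'
#' Applies [extract_features()] to each case of a [simulate_cohort()]
#' result (or any list of cases with `id`, `label`, `image`, `mask`, and
#' optionally `mask_obs2` elements). When `observer = "obs2"` the
#' second-observer mask is used with the same derived images, mirroring
#' repeated delineation of the same scan.
#'
#' @param cohort a `synthetic_cohort` or compatible list of cases.
#' @param observer `"obs1"` (primary contour) or `"obs2"`.
#' @param target_mm,n_levels see [extract_features()].
#' @return A tibble: `case_id`, `label`, then one column per feature key.
#' @export
extract_cohort_features <- function(cohort, observer = c("obs1", "obs2"),
                                    target_mm = 1, n_levels = 64) {
  observer <- match.arg(observer)
  cases <- if (inherits(cohort, "synthetic_cohort")) cohort$cases else cohort
  rows <- lapply(cases, function(cs) {
    mask <- if (observer == "obs2") {
      if (is.null(cs$mask_obs2)) stop("case ", cs$id, " has no obs2 mask")
      cs$mask_obs2
    } else cs$mask
    f <- extract_features(cs$image, mask, target_mm, n_levels)
    tibble::as_tibble(c(list(case_id = cs$id, label = cs$label),
                        as.list(f)))
  })
  dplyr::bind_rows(rows)
}

#' Extract features for both observers sharing the filtered images
#'
#' Computes the derived images once per case and quantizes them under both
#' the primary and the second-observer contour, returning the two feature
#' tables used by the reproducibility (ICC) filter.
#'
#' @inheritParams extract_cohort_features
#' @return List of two tibbles, `obs1` and `obs2`, shaped as in
#'   [extract_cohort_features()].
#' @export
extract_observer_pair <- function(cohort, target_mm = 1, n_levels = 64) {
  cases <- if (inherits(cohort, "synthetic_cohort")) cohort$cases else cohort
  r1 <- list(); r2 <- list()
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    rs <- resample_isotropic(cs$image, cs$mask, target_mm)
    derived <- derive_images(rs$image)
    m2 <- resample_mask(cs$mask_obs2, target_mm)
    f1 <- extract_from_derived(rs$image, derived, rs$mask, n_levels)
    f2 <- extract_from_derived(rs$image, derived, m2, n_levels)
    r1[[k]] <- tibble::as_tibble(c(list(case_id = cs$id, label = cs$label),
                                   as.list(f1)))
    r2[[k]] <- tibble::as_tibble(c(list(case_id = cs$id, label = cs$label),
                                   as.list(f2)))
  }
  list(obs1 = dplyr::bind_rows(r1), obs2 = dplyr::bind_rows(r2))
}

#' Write a feature table to CSV
#'
#' @param features tibble from [extract_cohort_features()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

# numeric feature matrix from a feature tibble (case_id/label columns kept
# aside); rows named by case id
feature_matrix <- function(features) {
  keys <- setdiff(names(features), c("case_id", "label"))
  m <- as.matrix(features[, keys])
  rownames(m) <- features$case_id
  m
}
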