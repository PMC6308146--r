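# Small fixtures built in code.

# digital ball mask of radius r (voxels/mm), isotropic 1 mm grid
make_ball <- function(r, n = 2 * r + 11) {
  dims <- rep(n, 3)
  cmid <- (n - 1) / 2
  ax <- (seq_len(n) - 1) - cmid
  r2 <- array(ax^2, dims) +
    aperm(array(ax^2, dims), c(2, 1, 3)) +
    aperm(array(ax^2, dims), c(3, 2, 1))
  roi_mask(r2 <= r^2, c(1, 1, 1))
}

# quantized ROI object built directly from a level array (0 = outside);
# raw values default to the levels themselves
make_qroi <- function(levels, n_levels = max(levels), raw = NULL) {
  levels <- array(as.integer(levels), dim(levels))
  include <- levels > 0
  structure(
    list(levels = levels, include = include,
         raw_values = if (is.null(raw)) as.numeric(levels[include]) else raw,
         m = 0, s = 1, n_excluded = 0L,
         n_levels = as.integer(n_levels), spacing = c(1, 1, 1)),
    class = "quantized_roi")
}

# random small quantized ROI: dims^3 grid, a random subset of voxels in the
# ROI, levels uniform on 1..n_levels
rand_qroi <- function(seed, dims = c(8, 8, 8), n_levels = 6, p_roi = 0.7) {
  set.seed(seed)
  lev <- array(0L, dims)
  roi <- array(runif(prod(dims)) < p_roi, dims)
  lev[roi] <- sample.int(n_levels, sum(roi), replace = TRUE)
  make_qroi(lev, n_levels)
}

# small synthetic cohort spec used in integration tests (coarser grid than
# the default to keep the suite fast)
small_spec <- function(n_ifr = 5, n_npd = 5, seed = 1) {
  cohort_spec(n_ifr = n_ifr, n_npd = n_npd,
              grid_shape = c(32, 32, 10), roi_radius_mm = c(7, 7, 7),
              seed = seed)
}

table2_path <- function() {
  system.file("extdata", "table2_clinical.csv", package = "radrecur")
}
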