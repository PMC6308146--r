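# Resampling and gray-level normalization / quantization.

test_that("resampling an already-isotropic 1 mm grid is the identity", {
  set.seed(1)
  vals <- array(rnorm(20 * 20 * 20), c(20, 20, 20))
  vol <- image_volume(vals, c(1, 1, 1))
  mask <- make_ball(6, 20)
  rs <- resample_isotropic(vol, mask, 1)
  expect_equal(rs$image$values, vals, tolerance = 1e-12)
  expect_identical(rs$mask$values, mask$values)
})

test_that("a constant image stays constant under resampling", {
  vol <- image_volume(array(5, c(16, 16, 8)), c(0.65, 0.65, 4))
  mask <- roi_mask(with(expand.grid(x = 1:16, y = 1:16, z = 1:8), {
    array((x - 8)^2 + (y - 8)^2 + (z - 4)^2 <= 9, c(16, 16, 8))
  }), c(0.65, 0.65, 4))
  rs <- resample_isotropic(vol, mask, 1)
  expect_equal(max(abs(rs$image$values - 5)), 0, tolerance = 1e-10)
  expect_equal(rs$image$spacing, c(1, 1, 1))
})

test_that("anisotropic grid: extent preserved and linear ramp reproduced", {
  dims <- c(64, 64, 16)
  sp <- c(0.65, 0.65, 4)
  # ramp in physical coordinates: f(x,y,z) = 2x + 0.5y - z + 3
  coords <- function(d, s) (seq_len(d) - 1) * s
  X <- array(coords(64, 0.65), dims)
  Y <- aperm(array(coords(64, 0.65), dims[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(coords(16, 4), dims[c(3, 1, 2)]), c(2, 3, 1))
  vol <- image_volume(2 * X + 0.5 * Y - Z + 3, sp)
  mask <- roi_mask(array(TRUE, dims), sp)
  rs <- resample_isotropic(vol, mask, 1)

  in_extent <- (dims - 1) * sp
  out_extent <- (dim(rs$image$values) - 1) * rs$image$spacing
  expect_true(all(abs(in_extent - out_extent) <= 1))

  od <- dim(rs$image$values)
  Xo <- array(coords(od[1], 1), od)
  Yo <- aperm(array(coords(od[2], 1), od[c(2, 1, 3)]), c(2, 1, 3))
  Zo <- aperm(array(coords(od[3], 1), od[c(3, 1, 2)]), c(2, 3, 1))
  expected <- 2 * Xo + 0.5 * Yo - Zo + 3
  # drop the boundary ring where the clamped cubic support is truncated
  # (two input voxels; the 4 mm slices span eight output voxels)
  core <- rs$image$values[10:(od[1] - 9), 10:(od[2] - 9), 10:(od[3] - 9)]
  exp_core <- expected[10:(od[1] - 9), 10:(od[2] - 9), 10:(od[3] - 9)]
  expect_lt(max(abs(core - exp_core)), 1e-6)
})

test_that("mask resampling keeps the ROI centroid within one voxel", {
  spec <- small_spec()
  tc <- generate_tumor_case(spec, "IFR", 1)
  rs <- resample_isotropic(tc$image, tc$mask, 1)
  cen_in <- colMeans(sweep(which(tc$mask$values, arr.ind = TRUE) - 1, 2,
                           tc$mask$spacing, `*`))
  cen_out <- colMeans(which(rs$mask$values, arr.ind = TRUE) - 1)
  expect_true(all(abs(cen_in - cen_out) < 1))
})

test_that("constant ROI quantizes to level 1 everywhere with a warning", {
  vol <- image_volume(array(7, c(8, 8, 8)), c(1, 1, 1))
  mask <- make_ball(3, 8)
  expect_warning(q <- normalize_and_quantize(vol, mask), "constant ROI")
  expect_true(all(q$levels[mask$values] == 1))
  expect_equal(q$n_excluded, 0L)
})

test_that("uniform intensities fill the 64 levels approximately evenly", {
  set.seed(42)
  n <- 1e5
  dims <- c(50, 50, 40)
  vals <- array(0, dims)
  mask_arr <- array(FALSE, dims)
  mask_arr[seq_len(n)] <- TRUE
  # draw uniform over exactly [m - 3s, m + 3s] of its own distribution:
  # uniform(0,1) has m = 0.5, s = sqrt(1/12); 3s > 0.5 so no exclusion
  x <- runif(n)
  vals[seq_len(n)] <- x
  q <- normalize_and_quantize(image_volume(vals, c(1, 1, 1)),
                              roi_mask(mask_arr, c(1, 1, 1)))
  lev <- q$levels[q$include]
  # direct-binning oracle on the sampled values
  m <- mean(x); s <- sd(x)
  lev_oracle <- pmin(floor((x - (m - 3 * s)) / (6 * s) * 64) + 1, 64)
  expect_identical(as.integer(lev), as.integer(lev_oracle))
  # only the central ~37% of the [m-3s, m+3s] range is populated, but the
  # fully covered levels should be uniform: chi-squared on interior occupied
  # bins (the two edge bins are only partially covered by the data range)
  occ <- table(lev)
  interior <- occ[-c(1, length(occ))]
  chi <- chisq.test(interior)
  expect_gt(chi$p.value, 0.001)
})

test_that("levels stay inside 1..64 and the map is monotone", {
  set.seed(7)
  dims <- c(20, 20, 20)
  vol <- image_volume(array(rnorm(prod(dims), 100, 25), dims), c(1, 1, 1))
  mask <- make_ball(8, 20)
  q <- normalize_and_quantize(vol, mask)
  lev <- q$levels[q$include]
  expect_gte(min(lev), 1L)
  expect_lte(max(lev), 64L)
  x <- vol$values[q$include]
  ord <- order(x)
  expect_true(all(diff(lev[ord]) >= 0))
})

test_that("quantization is invariant to positive affine intensity maps", {
  set.seed(8)
  dims <- c(20, 20, 20)
  vals <- array(rnorm(prod(dims), 50, 10), dims)
  mask <- make_ball(8, 20)
  q1 <- normalize_and_quantize(image_volume(vals, c(1, 1, 1)), mask)
  q2 <- normalize_and_quantize(image_volume(3.7 * vals + 11, c(1, 1, 1)), mask)
  expect_identical(q1$levels, q2$levels)
  expect_identical(q1$n_excluded, q2$n_excluded)
})

test_that("Gaussian ROI excludes about 0.27% of voxels at 3 sigma", {
  set.seed(9)
  n <- 1e5
  dims <- c(50, 50, 40)
  vals <- array(0, dims)
  mask_arr <- array(FALSE, dims)
  mask_arr[seq_len(n)] <- TRUE
  vals[seq_len(n)] <- rnorm(n)
  q <- normalize_and_quantize(image_volume(vals, c(1, 1, 1)),
                              roi_mask(mask_arr, c(1, 1, 1)))
  frac <- q$n_excluded / n
  expect_lt(abs(frac - 0.0027), 0.0015)
})
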