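# LoG and wavelet image filters.

test_that("LoG of a constant image is zero", {
  vol <- image_volume(array(4.2, c(16, 16, 16)), c(1, 1, 1))
  r <- log_response(vol, 1.5)
  expect_lt(max(abs(r$values)), 1e-10)
})

test_that("LoG impulse response equals the sampled analytic kernel", {
  dims <- c(33, 33, 33)
  vol_arr <- array(0, dims)
  vol_arr[17, 17, 17] <- 1
  r <- log_response(image_volume(vol_arr, c(1, 1, 1)), 1.5)
  s <- 1.5
  x <- (1:33) - 17
  g <- function(t) exp(-t^2 / (2 * s^2)) / (sqrt(2 * pi) * s)
  g2 <- function(t) (t^2 - s^2) / s^4 * g(t)
  G <- g(x) / sum(g(x))           # normalized as in the implementation
  G2 <- g2(x) - mean(g2(x))       # zero-sum correction
  expected <- array(0, dims)
  for (ax in 1:3) {
    k1 <- if (ax == 1) G2 else G
    k2 <- if (ax == 2) G2 else G
    k3 <- if (ax == 3) G2 else G
    expected <- expected + outer(outer(k1, k2), k3)
  }
  # away from the reflected boundary (kernel half-width 6) the sampled
  # analytic LoG matches
  core <- 8:26
  err <- max(abs(r$values[core, core, core] - expected[core, core, core]))
  expect_lt(err, 1e-4 * max(abs(expected)))
  # and the zero-sum-corrected sampled kernel is itself within 1e-4 of the
  # exact analytic LoG samples
  analytic <- array(0, dims)
  for (ax in 1:3) {
    k1 <- if (ax == 1) g2(x) else g(x)
    k2 <- if (ax == 2) g2(x) else g(x)
    k3 <- if (ax == 3) g2(x) else g(x)
    analytic <- analytic + outer(outer(k1, k2), k3)
  }
  expect_lt(max(abs(expected - analytic)), 1e-4 * max(abs(analytic)))
})

test_that("LoG annihilates affine ramps in the interior", {
  dims <- c(24, 24, 24)
  X <- array((1:24), dims)
  vol <- image_volume(3 * X + 7, c(1, 1, 1))
  r <- log_response(vol, 1.5)
  span <- diff(range(vol$values))
  core <- r$values[9:16, 9:16, 9:16]
  expect_lt(max(abs(core)), 1e-6 * span)
})

test_that("LoG is linear in the input", {
  set.seed(3)
  dims <- c(16, 16, 16)
  a <- array(rnorm(prod(dims)), dims)
  r1 <- log_response(image_volume(a, c(1, 1, 1)), 1.5)$values
  r2 <- log_response(image_volume(2.5 * a, c(1, 1, 1)), 1.5)$values
  expect_equal(r2, 2.5 * r1, tolerance = 1e-12)
})

test_that("LoG warns for under-resolved sigma", {
  vol <- image_volume(array(0, c(8, 8, 8)), c(1, 1, 1))
  expect_warning(log_response(vol, 0.3), "under-resolved")
  expect_silent(log_response(vol, 0.5))
})

test_that("wavelet sub-bands: constant image has zero H bands", {
  vol <- image_volume(array(3, c(12, 12, 12)), c(1, 1, 1))
  wb <- wavelet_subbands(vol)
  expect_named(wb, paste0("W_", c("LLL", "LLH", "LHL", "LHH",
                                  "HLL", "HLH", "HHL", "HHH")))
  for (tag in names(wb)) {
    if (grepl("H", tag)) {
      expect_lt(max(abs(wb[[tag]]$values)), 1e-10)
    } else {
      # LLL is the constant scaled by the cubed filter sum
      expect_lt(diff(range(wb[[tag]]$values)), 1e-10)
    }
  }
})

test_that("wavelet impulse response matches direct separable convolution", {
  dims <- c(12, 12, 12)
  arr <- array(0, dims)
  arr[6, 6, 6] <- 1
  wb <- wavelet_subbands(image_volume(arr, c(1, 1, 1)))
  lo <- c(-0.015655728135792, -0.072732619512526, 0.384864846864858,
          0.852572020211600, 0.337897662457482, -0.072732619512526)
  hi <- c(0.072732619512526, 0.337897662457482, -0.852572020211600,
          0.384864846864858, 0.072732619512526, -0.015655728135792)
  offs <- -2:3
  pick <- function(l) if (l == "L") lo else hi
  for (tag in c("HLL", "LHH", "LLL")) {
    ltrs <- strsplit(tag, "")[[1]]
    expected <- oracle_conv3(arr, pick(ltrs[1]), pick(ltrs[2]),
                             pick(ltrs[3]), offs, "periodic")
    expect_lt(max(abs(wb[[paste0("W_", tag)]]$values - expected)), 1e-10)
  }
})

test_that("wavelet energy matches the direct-convolution oracle", {
  set.seed(5)
  dims <- c(10, 10, 10)
  arr <- array(rnorm(prod(dims)), dims)
  wb <- wavelet_subbands(image_volume(arr, c(1, 1, 1)))
  lo <- c(-0.015655728135792, -0.072732619512526, 0.384864846864858,
          0.852572020211600, 0.337897662457482, -0.072732619512526)
  hi <- c(0.072732619512526, 0.337897662457482, -0.852572020211600,
          0.384864846864858, 0.072732619512526, -0.015655728135792)
  offs <- -2:3
  pick <- function(l) if (l == "L") lo else hi
  tags <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  e_pkg <- 0
  e_oracle <- 0
  for (tag in tags) {
    ltrs <- strsplit(tag, "")[[1]]
    e_pkg <- e_pkg + sum(wb[[paste0("W_", tag)]]$values^2)
    e_oracle <- e_oracle +
      sum(oracle_conv3(arr, pick(ltrs[1]), pick(ltrs[2]), pick(ltrs[3]),
                       offs, "periodic")^2)
  }
  expect_lt(abs(e_pkg - e_oracle) / e_oracle, 0.01)
})

test_that("derived images preserve geometry and carry the 11 tags", {
  set.seed(6)
  vol <- image_volume(array(rnorm(12^3), c(12, 12, 12)), c(1, 1, 1))
  d <- derive_images(vol)
  expect_length(d, 11)
  expect_named(d, c("LoG_0.5", "LoG_1.5", "LoG_2.5",
                    "W_LLL", "W_LLH", "W_LHL", "W_LHH",
                    "W_HLL", "W_HLH", "W_HHL", "W_HHH"))
  for (tag in names(d)) {
    expect_identical(dim(d[[tag]]$values), dim(vol$values))
    expect_identical(d[[tag]]$spacing, vol$spacing)
    expect_identical(attr(d[[tag]], "derivation"), tag)
  }
})

test_that("grids smaller than the wavelet filter are rejected", {
  vol <- image_volume(array(0, c(4, 12, 12)), c(1, 1, 1))
  expect_error(wavelet_subbands(vol), "filter length")
})
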