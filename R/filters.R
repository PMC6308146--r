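# Separable axis convolutions via banded matrices. For a kernel w with
# integer offsets off, out[i] = sum_k w[k] * in[i + off[k]] with the chosen
# boundary rule, implemented as an n x n matrix applied along one axis.
conv_matrix <- function(n, weights, offsets, boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  K <- matrix(0, n, n)
  for (k in seq_along(weights)) {
    j <- seq_len(n) + offsets[k]
    if (boundary == "periodic") {
      j <- ((j - 1) %% n) + 1
    } else {
      # symmetric reflection with edge repeat: ... 2 1 | 1 2 ... n | n n-1 ...
      repeat {
        bad_lo <- j < 1
        bad_hi <- j > n
        if (!any(bad_lo | bad_hi)) break
        j[bad_lo] <- 1 - j[bad_lo]
        j[bad_hi] <- 2 * n + 1 - j[bad_hi]
      }
    }
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + weights[k]
  }
  K
}

apply_axis <- function(arr, K, axis) {
  d <- dim(arr)
  if (axis == 1) {
    array(K %*% matrix(arr, d[1], d[2] * d[3]), d)
  } else if (axis == 2) {
    p <- aperm(arr, c(2, 1, 3))
    out <- array(K %*% matrix(p, d[2], d[1] * d[3]), d[c(2, 1, 3)])
    aperm(out, c(2, 1, 3))
  } else {
    p <- aperm(arr, c(3, 1, 2))
    out <- array(K %*% matrix(p, d[3], d[1] * d[2]), d[c(3, 1, 2)])
    aperm(out, c(2, 3, 1))
  }
}

separable_conv <- function(arr, kernels, offsets, boundary = "reflect") {
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    K <- conv_matrix(d[ax], kernels[[ax]], offsets[[ax]], boundary)
    out <- apply_axis(out, K, ax)
  }
  out
}

gaussian_kernel <- function(sigma_vox) {
  h <- max(1L, ceiling(5 * sigma_vox))
  x <- (-h):h
  w <- exp(-x^2 / (2 * sigma_vox^2))
  list(weights = w / sum(w), offsets = x)
}

# second-derivative-of-Gaussian samples; zero-sum enforced so affine inputs
# are annihilated exactly
gaussian_d2_kernel <- function(sigma_vox) {
  h <- max(2L, ceiling(5 * sigma_vox))
  x <- (-h):h
  g <- exp(-x^2 / (2 * sigma_vox^2)) / (sqrt(2 * pi) * sigma_vox)
  w <- (x^2 - sigma_vox^2) / sigma_vox^4 * g
  w <- w - mean(w)
  list(weights = w, offsets = x)
}

# smooth an array with an isotropic (in mm) Gaussian; sigma_vox may differ
# per axis to account for anisotropic spacing
gaussian_smooth <- function(arr, sigma_vox) {
  sigma_vox <- rep(sigma_vox, length.out = 3)
  ker <- lapply(sigma_vox, gaussian_kernel)
  separable_conv(arr,
                 kernels = lapply(ker, `[[`, "weights"),
                 offsets = lapply(ker, `[[`, "offsets"))
}

#' Laplacian-of-Gaussian response of a volume
#'
#' Band-pass filters the image with the Laplacian of a Gaussian of physical
#' width `sigma_mm`, enhancing texture at that scale (fine 0.5 mm, medium
#' 1.5 mm, coarse 2.5 mm). The operator is evaluated as the sum over axes of
#' a sampled second-derivative-of-Gaussian kernel along that axis times
#' Gaussian smoothing along the others, with reflective boundaries; the
#' impulse response is the analytic LoG kernel sampled at voxel centers.
#'
#' @param vol an [image_volume()] on an isotropic grid.
#' @param sigma_mm Gaussian width in mm.
#' @return An [image_volume()] with a `derivation` attribute
#'   `"LoG_<sigma>"`.
#' @export
log_response <- function(vol, sigma_mm) {
  sp <- vol$spacing
  if (max(abs(sp - sp[1])) > 1e-8)
    stop("LoG filtering expects an isotropic grid; resample first")
  sigma_vox <- sigma_mm / sp[1]
  if (sigma_vox < 0.5)
    warning("sigma = ", sigma_mm, " mm is under-resolved at ", sp[1],
            " mm voxels")
  g <- gaussian_kernel(sigma_vox)
  g2 <- gaussian_d2_kernel(sigma_vox)
  out <- array(0, dim(vol$values))
  for (ax in 1:3) {
    kernels <- list(g$weights, g$weights, g$weights)
    offsets <- list(g$offsets, g$offsets, g$offsets)
    kernels[[ax]] <- g2$weights
    offsets[[ax]] <- g2$offsets
    out <- out + separable_conv(vol$values, kernels, offsets)
  }
  res <- image_volume(out, vol$spacing, vol$origin)
  attr(res, "derivation") <- paste0("LoG_", format(sigma_mm))
  res
}

# Coiflet-1 analysis filter bank (low / high pass), 6 taps
coif1_filters <- function() {
  lo <- c(-0.015655728135792, -0.072732619512526, 0.384864846864858,
          0.852572020211600, 0.337897662457482, -0.072732619512526)
  hi <- c(0.072732619512526, 0.337897662457482, -0.852572020211600,
          0.384864846864858, 0.072732619512526, -0.015655728135792)
  list(L = lo, H = hi, offsets = -2:3)
}

#' One-level undecimated 3D wavelet sub-bands
#'
#' Applies a one-level stationary (undecimated) 3D wavelet transform with
#' the Coiflet-1 filter bank and periodic boundaries. The per-axis low/high
#' choice yields 8 sub-bands named first-axis-first: `HLL` is high-pass
#' along axis 1 and low-pass along axes 2 and 3. Being undecimated, every
#' sub-band is congruent with the input grid, so the ROI mask applies
#' without resampling.
#'
#' @param vol an [image_volume()] on an isotropic grid.
#' @return Named list of 8 [image_volume()] objects (`W_LLL` .. `W_HHH`),
#'   each with a matching `derivation` attribute.
#' @export
wavelet_subbands <- function(vol) {
  fb <- coif1_filters()
  d <- dim(vol$values)
  if (any(d < length(fb$L)))
    stop("grid dimension smaller than the wavelet filter length (",
         length(fb$L), ")")
  combos <- expand.grid(a1 = c("L", "H"), a2 = c("L", "H"), a3 = c("L", "H"),
                        stringsAsFactors = FALSE)
  # order: LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH (first letter = axis 1)
  tags <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  out <- lapply(tags, function(tag) {
    letters3 <- strsplit(tag, "")[[1]]
    kernels <- lapply(letters3, function(l) fb[[l]])
    offsets <- list(fb$offsets, fb$offsets, fb$offsets)
    band <- separable_conv(vol$values, kernels, offsets, boundary = "periodic")
    res <- image_volume(band, vol$spacing, vol$origin)
    attr(res, "derivation") <- paste0("W_", tag)
    res
  })
  names(out) <- paste0("W_", tags)
  out
}

#' All derived images of a resampled volume
#'
#' Produces the 11 filtered derivatives used by the feature manifest: LoG
#' responses at sigma 0.5 / 1.5 / 2.5 mm and the 8 one-level undecimated
#' wavelet sub-bands, keyed by their derivation tag.
#'
#' @param vol an [image_volume()] on an isotropic grid (see
#'   [resample_isotropic()]).
#' @param log_sigmas_mm LoG widths in mm.
#' @return Named list of 11 [image_volume()] objects.
#' @export
derive_images <- function(vol, log_sigmas_mm = c(0.5, 1.5, 2.5)) {
  logs <- lapply(log_sigmas_mm, function(s) log_response(vol, s))
  names(logs) <- paste0("LoG_", format(log_sigmas_mm))
  c(logs, wavelet_subbands(vol))
}
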