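# Texture-matrix feature families. Matrices are built in C++ over the
# quantized ROI (level 0 = outside/excluded); features are evaluated here.
# The gray-level axis always spans 1..n_levels so features are comparable
# across cases. Directional families (GLCM, GLRLM) evaluate each of the 13
# unique 26-connectivity directions at distance 1 separately and report the
# mean feature value over directions.

#' Gray-level co-occurrence (GLCM) features
#'
#' Builds the symmetric, per-direction-normalized co-occurrence matrix for
#' each of the 13 unique 3D directions at distance 1 voxel, evaluates 23
#' Haralick-style features on each, and averages each feature over
#' directions.
#'
#' @param qroi a [normalize_and_quantize()] result.
#' @return Named numeric vector of 23 features (`glcm_*`).
#' @export
glcm_features <- function(qroi) {
  arr <- cpp_glcm(qroi$levels, dim(qroi$levels), qroi$n_levels)
  vals <- NULL
  nd <- 0
  for (d in 1:13) {
    P <- arr[, , d]
    tot <- sum(P)
    if (tot == 0) next
    f <- glcm_feature_values(P / tot, qroi$n_levels)
    vals <- if (is.null(vals)) f else vals + f
    nd <- nd + 1
  }
  if (nd == 0) stop("no valid voxel pair in any direction")
  vals / nd
}

# static index/weight vectors per gray-level count, cached across calls
glcm_statics_cache <- new.env(parent = emptyenv())
glcm_statics <- function(ng) {
  key <- as.character(ng)
  st <- glcm_statics_cache[[key]]
  if (!is.null(st)) return(st)
  i <- rep(seq_len(ng), times = ng)
  j <- rep(seq_len(ng), each = ng)
  dg <- abs(i - j) + 1L            # group 1..ng for |i-j| = 0..ng-1
  sg <- i + j - 1L                 # group 1..2ng-1 for i+j = 2..2ng
  st <- list(
    i = i, j = j, ij = i * j, ipj = i + j, dg = dg, sg = sg,
    d2 = (i - j)^2,
    w_idm = 1 / (1 + (i - j)^2),
    w_idmn = 1 / (1 + ((i - j) / ng)^2),
    w_id = 1 / (1 + abs(i - j)),
    w_idn = 1 / (1 + abs(i - j) / ng),
    inv_d2 = ifelse(i == j, 0, 1 / pmax((i - j)^2, 1)),
    diff_idx = split(seq_along(dg), dg),
    sum_idx = split(seq_along(sg), sg),
    k_diff = 0:(ng - 1), k_sum = 2:(2 * ng)
  )
  glcm_statics_cache[[key]] <- st
  st
}

glcm_feature_values <- function(P, ng) {
  st <- glcm_statics(ng)
  Pv <- as.vector(P)
  px <- .rowSums(P, ng, ng)
  py <- .colSums(P, ng, ng)     # equals px for a symmetric matrix
  lev <- seq_len(ng)
  mux <- sum(lev * px)
  muy <- sum(lev * py)
  sigx <- sqrt(sum((lev - mux)^2 * px))
  sigy <- sqrt(sum((lev - muy)^2 * py))

  # diagonal (difference) and cross-diagonal (sum) distributions
  p_diff <- vapply(st$diff_idx, function(ix) sum(Pv[ix]), 0)
  p_sum <- vapply(st$sum_idx, function(ix) sum(Pv[ix]), 0)

  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  HXY <- ent(Pv)
  pxpy <- as.vector(outer(px, py))
  nz <- Pv > 0 & pxpy > 0
  HXY1 <- -sum(Pv[nz] * log2(pxpy[nz]))
  HXY2 <- ent(pxpy)
  HX <- ent(px)
  HY <- ent(py)

  da <- sum(st$k_diff * p_diff)
  corr <- if (sigx > 0 && sigy > 0)
    (sum(st$ij * Pv) - mux * muy) / (sigx * sigy) else 1
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- if (HXY2 >= HXY) sqrt(1 - exp(-2 * (HXY2 - HXY))) else 0
  cdev <- st$ipj - mux - muy
  cdev2 <- cdev^2

  c(glcm_Autocorrelation = sum(st$ij * Pv),
    glcm_CP = sum(cdev2^2 * Pv),
    glcm_CS = sum(cdev2 * cdev * Pv),
    glcm_CT = sum(cdev2 * Pv),
    glcm_Contrast = sum(st$d2 * Pv),
    glcm_Correlation = corr,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = ent(p_diff),
    glcm_DifferenceVariance = sum((st$k_diff - da)^2 * p_diff),
    glcm_JointEnergy = sum(Pv^2),
    glcm_JointEntropy = HXY,
    glcm_JointAverage = mux,
    glcm_IMC = imc1,
    glcm_IMC2 = imc2,
    glcm_IDM = sum(st$w_idm * Pv),
    glcm_IDMN = sum(st$w_idmn * Pv),
    glcm_ID = sum(st$w_id * Pv),
    glcm_IDN = sum(st$w_idn * Pv),
    glcm_InverseVariance = sum(st$inv_d2 * Pv),
    glcm_MaximumProbability = max(Pv),
    glcm_SumAverage = sum(st$k_sum * p_sum),
    glcm_SumEntropy = ent(p_sum),
    glcm_SumSquares = sum((st$i - mux)^2 * Pv))
}

# Shared formulas for the three (level x size) count-matrix families.
# P: counts with rows = gray level, cols = run length / zone size /
# dependence size; np = number of ROI voxels. `prefix` and `size_word`
# select the family naming.
size_matrix_features <- function(P, np, prefix, size_names) {
  ns <- sum(P)
  g <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  s <- matrix(seq_len(ncol(P)), nrow(P), ncol(P), byrow = TRUE)
  p <- P / ns
  mu_g <- sum(g * p)
  mu_s <- sum(s * p)
  pnz <- p[p > 0]
  out <- c(
    sum(P / s^2) / ns,                 # small emphasis
    sum(P * s^2) / ns,                 # large emphasis
    sum(rowSums(P)^2) / ns,            # gray-level non-uniformity
    sum(rowSums(P)^2) / ns^2,          # ... normalized
    sum(p * (g - mu_g)^2),             # gray-level variance
    sum(P * g^2) / ns,                 # high gray-level emphasis
    sum(P * s^2 * g^2) / ns,           # large + high
    sum(P * s^2 / g^2) / ns,           # large + low
    sum(P / g^2) / ns,                 # low gray-level emphasis
    -sum(pnz * log2(pnz)),             # entropy
    sum(colSums(P)^2) / ns,            # size non-uniformity
    sum(colSums(P)^2) / ns^2,          # ... normalized
    ns / np,                           # percentage
    sum(p * (s - mu_s)^2),             # size variance
    sum(P * g^2 / s^2) / ns,           # small + high
    sum(P / (g^2 * s^2)) / ns          # small + low
  )
  names(out) <- paste0(prefix, "_", size_names)
  out
}

glrlm_names <- c("SRE", "LRE", "GLN", "GLNN", "GLV", "HGLRE", "LRHGLE",
                 "LRLGLE", "LGLRE", "RE", "RLN", "RLNN", "RP", "RV",
                 "SRHGLE", "SRLGLE")
glszm_names <- c("SAE", "LAE", "GLN", "GLNN", "GLV", "HGLZE", "LAHGLE",
                 "LALGLE", "LGLZE", "ZE", "SZN", "SZNN", "ZP", "ZV",
                 "SAHGLE", "SALGLE")

#' Gray-level run-length (GLRLM) features
#'
#' Run-length matrices for the 13 unique 3D directions, 16 features each,
#' averaged over directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features (`glrlm_*`).
#' @export
glrlm_features <- function(qroi) {
  arr <- cpp_glrlm(qroi$levels, dim(qroi$levels), qroi$n_levels)
  np <- sum(qroi$include)
  if (np == 0) stop("empty quantized ROI")
  vals <- NULL
  nd <- 0
  for (d in 1:13) {
    P <- arr[, , d]
    if (sum(P) == 0) next
    f <- size_matrix_features(P, np, "glrlm", glrlm_names)
    vals <- if (is.null(vals)) f else vals + f
    nd <- nd + 1
  }
  if (nd == 0) stop("no runs in any direction")
  vals / nd
}

#' Gray-level size-zone (GLSZM) features
#'
#' A single rotation-invariant matrix of 26-connected equal-level zones
#' (size-zone matrices have no directional parameter), 16 features.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features (`glszm_*`).
#' @export
glszm_features <- function(qroi) {
  zones <- cpp_glszm(qroi$levels, dim(qroi$levels))
  np <- sum(qroi$include)
  if (nrow(zones) == 0) stop("empty quantized ROI")
  P <- matrix(0, qroi$n_levels, max(zones[, 2]))
  for (r in seq_len(nrow(zones)))
    P[zones[r, 1], zones[r, 2]] <- P[zones[r, 1], zones[r, 2]] + 1
  size_matrix_features(P, np, "glszm", glszm_names)
}

#' Gray-level dependence (GLDM) features
#'
#' Dependence counts over the 26-neighborhood at Chebyshev distance 1 with
#' zero gray-level tolerance; dependence size j = 1 + number of neighbors
#' equal in level to the center. 14 features.
#'
#' @inheritParams glcm_features
#' @param alpha gray-level tolerance for dependence (default 0).
#' @return Named numeric vector of 14 features (`gldm_*`).
#' @export
gldm_features <- function(qroi, alpha = 0) {
  P <- cpp_gldm(qroi$levels, dim(qroi$levels), qroi$n_levels,
                as.integer(alpha))
  nz <- sum(P)
  if (nz == 0) stop("empty quantized ROI")
  g <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  dmat <- matrix(seq_len(ncol(P)), nrow(P), ncol(P), byrow = TRUE)
  p <- P / nz
  mu_g <- sum(g * p)
  mu_d <- sum(dmat * p)
  pnz <- p[p > 0]
  c(gldm_SDE = sum(P / dmat^2) / nz,
    gldm_LDE = sum(P * dmat^2) / nz,
    gldm_GLN = sum(rowSums(P)^2) / nz,
    gldm_DN = sum(colSums(P)^2) / nz,
    gldm_DNN = sum(colSums(P)^2) / nz^2,
    gldm_GLV = sum(p * (g - mu_g)^2),
    gldm_DV = sum(p * (dmat - mu_d)^2),
    gldm_DE = -sum(pnz * log2(pnz)),
    gldm_LGLE = sum(P / g^2) / nz,
    gldm_HGLE = sum(P * g^2) / nz,
    gldm_SDLGLE = sum(P / (g^2 * dmat^2)) / nz,
    gldm_SDHGLE = sum(P * g^2 / dmat^2) / nz,
    gldm_LDLGLE = sum(P * dmat^2 / g^2) / nz,
    gldm_LDHGLE = sum(P * dmat^2 * g^2) / nz)
}

#' Neighboring gray-tone difference (NGTDM) features
#'
#' Level-wise absolute deviation from the 26-neighborhood (3 x 3 x 3) mean:
#' coarseness, contrast, busyness, complexity and strength.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 features (`ngtdm_*`).
#' @export
ngtdm_features <- function(qroi) {
  M <- cpp_ngtdm(qroi$levels, dim(qroi$levels), qroi$n_levels)
  n_i <- M[, 1]
  s_i <- M[, 2]
  nvp <- sum(n_i)
  if (nvp == 0) stop("empty quantized ROI")
  p_i <- n_i / nvp
  act <- which(p_i > 0)
  ngp <- length(act)
  ii <- matrix(act, ngp, ngp)
  jj <- t(ii)
  pi_ <- p_i[act]
  si_ <- s_i[act]
  pmat_i <- matrix(pi_, ngp, ngp)
  pmat_j <- t(pmat_i)
  smat_i <- matrix(si_, ngp, ngp)
  smat_j <- t(smat_i)

  coars_den <- sum(pi_ * si_)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  contrast <- if (ngp > 1)
    sum(pmat_i * pmat_j * (ii - jj)^2) / (ngp * (ngp - 1)) * sum(si_) / nvp
  else 0
  busy_den <- sum(abs(ii * pmat_i - jj * pmat_j))
  busyness <- if (busy_den > 0) sum(pi_ * si_) / busy_den else 0
  complexity <- sum(abs(ii - jj) * (pmat_i * smat_i + pmat_j * smat_j) /
                      (pmat_i + pmat_j)) / nvp
  str_den <- sum(si_)
  strength <- if (str_den > 0)
    sum((pmat_i + pmat_j) * (ii - jj)^2) / str_den else 0

  c(ngtdm_Coarseness = coarseness,
    ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness,
    ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}

#' All texture features of a quantized ROI
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 74 features across the five families.
#' @export
texture_features <- function(qroi) {
  c(glcm_features(qroi), glrlm_features(qroi), glszm_features(qroi),
    gldm_features(qroi), ngtdm_features(qroi))
}
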