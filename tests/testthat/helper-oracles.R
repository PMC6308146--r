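# Brute-force, loop-style oracles written independently of the package
# implementation (no shared code): explicit voxel-pair enumeration, flood
# fill, and direct formula evaluation.

oracle_offsets13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

oracle_offsets26 <- rbind(oracle_offsets13, -oracle_offsets13)

o_in <- function(v, d) all(v >= 1) && all(v <= d)

# ---- GLCM ---------------------------------------------------------------
oracle_glcm_matrix <- function(lev, off, ng) {
  d <- dim(lev)
  P <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    q <- c(x, y, z) + off
    if (!o_in(q, d)) next
    b <- lev[q[1], q[2], q[3]]
    if (b == 0) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P
}

oracle_glcm_feats <- function(P, ng) {
  P <- P / sum(P)
  px <- py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + P[i, j]
    py[j] <- py[j] + P[i, j]
  }
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sigx <- sqrt(sum(((1:ng) - mux)^2 * px))
  sigy <- sqrt(sum(((1:ng) - muy)^2 * py))
  pd <- numeric(ng)            # |i-j| = 0..ng-1
  ps <- numeric(2 * ng - 1)    # i+j = 2..2ng
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  H <- function(p) { s <- 0; for (v in p) if (v > 0) s <- s - v * log2(v); s }
  hxy <- H(as.vector(P)); hx <- H(px); hy <- H(py)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    if (px[i] * py[j] > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(px[i] * py[j])
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
    }
  }
  acc <- cp <- cs <- ct <- con <- idm <- idmn <- id <- idn <- iv <- ss <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    acc <- acc + i * j * p
    cp <- cp + (i + j - mux - muy)^4 * p
    cs <- cs + (i + j - mux - muy)^3 * p
    ct <- ct + (i + j - mux - muy)^2 * p
    con <- con + (i - j)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + ((i - j) / ng)^2)
    id <- id + p / (1 + abs(i - j))
    idn <- idn + p / (1 + abs(i - j) / ng)
    if (i != j) iv <- iv + p / (i - j)^2
    ss <- ss + (i - mux)^2 * p
  }
  da <- sum((0:(ng - 1)) * pd)
  dv <- sum(((0:(ng - 1)) - da)^2 * pd)
  c(glcm_Autocorrelation = acc, glcm_CP = cp, glcm_CS = cs, glcm_CT = ct,
    glcm_Contrast = con,
    glcm_Correlation = if (sigx > 0 && sigy > 0)
      (acc - mux * muy) / (sigx * sigy) else 1,
    glcm_DifferenceAverage = da, glcm_DifferenceEntropy = H(pd),
    glcm_DifferenceVariance = dv,
    glcm_JointEnergy = sum(P^2), glcm_JointEntropy = hxy,
    glcm_JointAverage = mux,
    glcm_IMC = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    glcm_IMC2 = if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0,
    glcm_IDM = idm, glcm_IDMN = idmn, glcm_ID = id, glcm_IDN = idn,
    glcm_InverseVariance = iv, glcm_MaximumProbability = max(P),
    glcm_SumAverage = sum((2:(2 * ng)) * ps), glcm_SumEntropy = H(ps),
    glcm_SumSquares = ss)
}

oracle_glcm <- function(lev, ng) {
  acc <- NULL
  nd <- 0
  for (k in 1:13) {
    P <- oracle_glcm_matrix(lev, oracle_offsets13[k, ], ng)
    if (sum(P) == 0) next
    f <- oracle_glcm_feats(P, ng)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  acc / nd
}

# ---- shared level x size feature formulas (runs / zones) ----------------
oracle_size_feats <- function(P, np, prefix, nms) {
  ng <- nrow(P); ms <- ncol(P); ns <- sum(P)
  p <- P / ns
  mug <- 0; mus <- 0
  for (g in 1:ng) for (s in 1:ms) { mug <- mug + g * p[g, s]; mus <- mus + s * p[g, s] }
  acc <- setNames(numeric(16), nms)
  rsum <- numeric(ng); csum <- numeric(ms)
  ent <- 0
  for (g in 1:ng) for (s in 1:ms) {
    v <- P[g, s]
    rsum[g] <- rsum[g] + v; csum[s] <- csum[s] + v
    acc[1] <- acc[1] + v / s^2
    acc[2] <- acc[2] + v * s^2
    acc[5] <- acc[5] + p[g, s] * (g - mug)^2
    acc[6] <- acc[6] + v * g^2
    acc[7] <- acc[7] + v * s^2 * g^2
    acc[8] <- acc[8] + v * s^2 / g^2
    acc[9] <- acc[9] + v / g^2
    if (p[g, s] > 0) ent <- ent - p[g, s] * log2(p[g, s])
    acc[14] <- acc[14] + p[g, s] * (s - mus)^2
    acc[15] <- acc[15] + v * g^2 / s^2
    acc[16] <- acc[16] + v / (g^2 * s^2)
  }
  acc[c(1, 2, 6, 7, 8, 9, 15, 16)] <- acc[c(1, 2, 6, 7, 8, 9, 15, 16)] / ns
  acc[3] <- sum(rsum^2) / ns
  acc[4] <- sum(rsum^2) / ns^2
  acc[10] <- ent
  acc[11] <- sum(csum^2) / ns
  acc[12] <- sum(csum^2) / ns^2
  acc[13] <- ns / np
  names(acc) <- paste0(prefix, "_", nms)
  acc
}

# ---- GLRLM --------------------------------------------------------------
oracle_glrlm_matrix <- function(lev, off, ng) {
  d <- dim(lev)
  maxrun <- max(d)
  P <- matrix(0, ng, maxrun)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    prev <- c(x, y, z) - off
    if (o_in(prev, d) && lev[prev[1], prev[2], prev[3]] == a) next
    len <- 1
    nxt <- c(x, y, z) + off
    while (o_in(nxt, d) && lev[nxt[1], nxt[2], nxt[3]] == a) {
      len <- len + 1
      nxt <- nxt + off
    }
    P[a, len] <- P[a, len] + 1
  }
  P
}

oracle_glrlm <- function(lev, ng) {
  np <- sum(lev > 0)
  nms <- c("SRE", "LRE", "GLN", "GLNN", "GLV", "HGLRE", "LRHGLE", "LRLGLE",
           "LGLRE", "RE", "RLN", "RLNN", "RP", "RV", "SRHGLE", "SRLGLE")
  acc <- NULL; nd <- 0
  for (k in 1:13) {
    P <- oracle_glrlm_matrix(lev, oracle_offsets13[k, ], ng)
    if (sum(P) == 0) next
    f <- oracle_size_feats(P, np, "glrlm", nms)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  acc / nd
}

# ---- GLSZM (explicit flood fill) ----------------------------------------
oracle_zones <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (lev[x, y, z] == 0 || seen[x, y, z]) next
    g <- lev[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (k in 1:26) {
        q <- v + oracle_offsets26[k, ]
        if (o_in(q, d) && !seen[q[1], q[2], q[3]] &&
            lev[q[1], q[2], q[3]] == g) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  do.call(rbind, zones)
}

oracle_glszm <- function(lev, ng) {
  z <- oracle_zones(lev)
  P <- matrix(0, ng, max(z[, 2]))
  for (r in seq_len(nrow(z))) P[z[r, 1], z[r, 2]] <- P[z[r, 1], z[r, 2]] + 1
  nms <- c("SAE", "LAE", "GLN", "GLNN", "GLV", "HGLZE", "LAHGLE", "LALGLE",
           "LGLZE", "ZE", "SZN", "SZNN", "ZP", "ZV", "SAHGLE", "SALGLE")
  f <- oracle_size_feats(P, sum(lev > 0), "glszm", nms)
  # package order differs: entropy/percentage positions are family-specific
  f[c("glszm_SAE", "glszm_LAE", "glszm_GLN", "glszm_GLNN", "glszm_GLV",
      "glszm_HGLZE", "glszm_LAHGLE", "glszm_LALGLE", "glszm_LGLZE",
      "glszm_ZE", "glszm_SZN", "glszm_SZNN", "glszm_ZP", "glszm_ZV",
      "glszm_SAHGLE", "glszm_SALGLE")]
}

# ---- GLDM ---------------------------------------------------------------
oracle_gldm <- function(lev, ng, alpha = 0) {
  d <- dim(lev)
  P <- matrix(0, ng, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    dep <- 0
    for (k in 1:26) {
      q <- c(x, y, z) + oracle_offsets26[k, ]
      if (!o_in(q, d)) next
      b <- lev[q[1], q[2], q[3]]
      if (b != 0 && abs(b - a) <= alpha) dep <- dep + 1
    }
    P[a, dep + 1] <- P[a, dep + 1] + 1
  }
  nz <- sum(P)
  p <- P / nz
  mug <- 0; mud <- 0
  for (g in 1:ng) for (j in 1:27) { mug <- mug + g * p[g, j]; mud <- mud + j * p[g, j] }
  sde <- lde <- glv <- dv <- de <- lgle <- hgle <- 0
  sdl <- sdh <- ldl <- ldh <- 0
  for (g in 1:ng) for (j in 1:27) {
    v <- P[g, j]
    sde <- sde + v / j^2; lde <- lde + v * j^2
    glv <- glv + p[g, j] * (g - mug)^2
    dv <- dv + p[g, j] * (j - mud)^2
    if (p[g, j] > 0) de <- de - p[g, j] * log2(p[g, j])
    lgle <- lgle + v / g^2; hgle <- hgle + v * g^2
    sdl <- sdl + v / (g^2 * j^2); sdh <- sdh + v * g^2 / j^2
    ldl <- ldl + v * j^2 / g^2; ldh <- ldh + v * j^2 * g^2
  }
  c(gldm_SDE = sde / nz, gldm_LDE = lde / nz,
    gldm_GLN = sum(rowSums(P)^2) / nz, gldm_DN = sum(colSums(P)^2) / nz,
    gldm_DNN = sum(colSums(P)^2) / nz^2, gldm_GLV = glv, gldm_DV = dv,
    gldm_DE = de, gldm_LGLE = lgle / nz, gldm_HGLE = hgle / nz,
    gldm_SDLGLE = sdl / nz, gldm_SDHGLE = sdh / nz,
    gldm_LDLGLE = ldl / nz, gldm_LDHGLE = ldh / nz)
}

# ---- NGTDM --------------------------------------------------------------
oracle_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    vals <- c()
    for (k in 1:26) {
      q <- c(x, y, z) + oracle_offsets26[k, ]
      if (o_in(q, d) && lev[q[1], q[2], q[3]] != 0)
        vals <- c(vals, lev[q[1], q[2], q[3]])
    }
    if (!length(vals)) next
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(vals))
  }
  nvp <- sum(n_i)
  p_i <- n_i / nvp
  act <- which(p_i > 0)
  ngp <- length(act)
  coars <- if (sum(p_i * s_i) > 0) 1 / sum(p_i * s_i) else 1e6
  contr <- 0; busy_den <- 0; compl <- 0; str_num <- 0
  for (i in act) for (j in act) {
    contr <- contr + p_i[i] * p_i[j] * (i - j)^2
    busy_den <- busy_den + abs(i * p_i[i] - j * p_i[j])
    compl <- compl + abs(i - j) * (p_i[i] * s_i[i] + p_i[j] * s_i[j]) /
      (p_i[i] + p_i[j])
    str_num <- str_num + (p_i[i] + p_i[j]) * (i - j)^2
  }
  contr <- if (ngp > 1) contr / (ngp * (ngp - 1)) * sum(s_i) / nvp else 0
  c(ngtdm_Coarseness = coars,
    ngtdm_Contrast = contr,
    ngtdm_Busyness = if (busy_den > 0) sum(p_i * s_i) / busy_den else 0,
    ngtdm_Complexity = compl / nvp,
    ngtdm_Strength = if (sum(s_i) > 0) str_num / sum(s_i) else 0)
}

# ---- first order --------------------------------------------------------
oracle_first_order <- function(x, lev_included, ng) {
  h <- numeric(ng)
  for (l in lev_included) h[l] <- h[l] + 1
  p <- h / length(lev_included)
  ent <- 0
  for (v in p) if (v > 0) ent <- ent - v * log2(v)
  mu <- sum(x) / length(x)
  m2 <- sum((x - mu)^2) / length(x)
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  rx <- x[x >= q[1] & x <= q[5]]
  c(F_Energy = sum(x^2), F_Entropy = ent, F_Min = min(x), F_P10 = q[1],
    F_P90 = q[5], F_Max = max(x), F_Mean = mu, F_Median = q[3],
    F_IQR = q[4] - q[2], F_Range = max(x) - min(x),
    F_MAD = sum(abs(x - mu)) / length(x),
    F_rMAD = sum(abs(rx - mean(rx))) / length(rx),
    F_RMS = sqrt(sum(x^2) / length(x)),
    F_Skewness = if (m2 > 0) (sum((x - mu)^3) / length(x)) / m2^1.5 else 0,
    F_Kurtosis = if (m2 > 0) (sum((x - mu)^4) / length(x)) / m2^2 else 0,
    F_Variance = m2, F_Uniformity = sum(p^2), F_SD = sqrt(m2))
}

# ---- statistics ---------------------------------------------------------
# Benjamini-Hochberg step-up, evaluated directly from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (r in seq_len(m)) adj[o[r]] <- p[o[r]] * m / r
  # enforce monotonicity from the largest rank down
  for (r in (m - 1):1) adj[o[r]] <- min(adj[o[r]], adj[o[r + 1]])
  pmin(adj, 1)
}

# AUC by exhaustive pair counting with half credit for ties
oracle_auc <- function(pos, neg) {
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

# ICC(2,1) evaluated spreadsheet-style from sums of squares
oracle_icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  msr <- sum((rowMeans(m) - gm)^2) * k / (n - 1)
  msc <- sum((colMeans(m) - gm)^2) * n / (k - 1)
  res <- 0
  for (i in 1:n) for (j in 1:k)
    res <- res + (m[i, j] - rowMeans(m)[i] - colMeans(m)[j] + gm)^2
  mse <- res / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# independent re-implementation of the greedy |PCC| pruning rule
oracle_pcc_prune <- function(m, threshold = 0.8) {
  keys <- colnames(m)
  repeat {
    if (length(keys) < 2) break
    r <- abs(cor(m[, keys, drop = FALSE]))
    diag(r) <- 0
    if (max(r) < threshold) break
    top <- which(r == max(r), arr.ind = TRUE)
    cand <- cbind(rownames(r)[top[, 1]], rownames(r)[top[, 2]])
    cand <- t(apply(cand, 1, sort))
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    a <- cand[1, 1]; b <- cand[1, 2]
    ma <- mean(r[a, colnames(r) != a])
    mb <- mean(r[b, colnames(r) != b])
    drop <- if (ma > mb) a else if (mb > ma) b else max(a, b)
    keys <- setdiff(keys, drop)
  }
  keys
}

# ROI-restricted empirical autocorrelation length via brute-force FFT
# autocorrelation of the masked, demeaned voxels: the in-plane integral
# scale (half-voxel plus the positive part of the normalized ACF summed
# over lags, averaged across both in-plane axes), in mm. Zero-padded so
# cyclic shifts never alias mask voxels onto each other.
oracle_acf_length <- function(image, mask, max_lag = 12) {
  v <- image$values
  m <- mask$values * 1
  v[mask$values] <- v[mask$values] - mean(v[mask$values])
  v[!mask$values] <- 0
  d <- dim(v) + max_lag + 1
  vp <- array(0, d); vp[seq_len(dim(v)[1]), seq_len(dim(v)[2]),
                        seq_len(dim(v)[3])] <- v
  mp <- array(0, d); mp[seq_len(dim(m)[1]), seq_len(dim(m)[2]),
                        seq_len(dim(m)[3])] <- m
  f <- fft(vp)
  fm <- fft(mp)
  num <- Re(fft(Conj(f) * f, inverse = TRUE))
  den <- Re(fft(Conj(fm) * fm, inverse = TRUE))
  c0 <- num[1, 1, 1] / den[1, 1, 1]
  cx <- vapply(seq_len(max_lag), function(k)
    (num[k + 1, 1, 1] / den[k + 1, 1, 1]) / c0, 0)
  cy <- vapply(seq_len(max_lag), function(k)
    (num[1, k + 1, 1] / den[1, k + 1, 1]) / c0, 0)
  image$spacing[1] * (0.5 + sum(pmax((cx + cy) / 2, 0)))
}

# direct (non-FFT, non-matrix) separable convolution for filter oracles
oracle_conv3 <- function(arr, kx, ky, kz, offs, boundary = "periodic") {
  d <- dim(arr)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  map <- if (boundary == "periodic") wrap else refl
  out <- array(0, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    s <- 0
    for (a in seq_along(kx)) for (b in seq_along(ky)) for (cc in seq_along(kz)) {
      s <- s + kx[a] * ky[b] * kz[cc] *
        arr[map(x + offs[a], d[1]), map(y + offs[b], d[2]),
            map(z + offs[cc], d[3])]
    }
    out[x, y, z] <- s
  }
  out
}
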