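## Radiomics feature extraction.
##
## The catalog follows the standard radiomics feature classes: 14 shape
## descriptors from the mask, and 93 intensity/texture features (18
## first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM) computed on
## the original image, on Laplacian-of-Gaussian filtered images at five
## sigma values, and on the eight single-level Haar wavelet decompositions
## (undecimated, so masks need no resampling). Under the default
## configuration this yields 107 + 5 x 93 + 8 x 93 = 1316 features per
## tumor. Shape approximations are voxel-based (face-count surface area,
## PCA axis lengths) rather than mesh-based.

#' Radiomics extraction configuration
#'
#' @param bin_width intensity bin width for gray-level discretization
#'   (applied per image, bins anchored at the masked minimum; widened if
#'   needed to keep at most `max_bins` levels).
#' @param log_sigmas_mm Laplacian-of-Gaussian scales in mm.
#' @param wavelet include the 8 Haar decompositions.
#' @param max_bins cap on the number of gray levels.
#' @export
radiomics_config <- function(bin_width = 5, log_sigmas_mm = 1:5,
                             wavelet = TRUE, max_bins = 64) {
  stopifnot(bin_width > 0, all(log_sigmas_mm > 0), max_bins >= 2)
  structure(list(bin_width = bin_width, log_sigmas_mm = log_sigmas_mm,
                 wavelet = wavelet, max_bins = as.integer(max_bins)),
            class = "hep_radiomics_config")
}

## ---- image filters --------------------------------------------------------

# 1-D convolution along one axis with replicate-edge padding, as a single
# band-matrix multiply.
axis_conv <- function(a, kern, axis) {
  r <- (length(kern) - 1L) %/% 2L
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  L <- d[axis]
  m <- matrix(ap, nrow = L)
  # replicate edges
  mp <- rbind(m[rep(1, r), , drop = FALSE], m,
              m[rep(L, r), , drop = FALSE])
  K <- matrix(0, L, L + 2 * r)
  for (i in seq_len(L)) K[i, i:(i + 2 * r)] <- kern
  y <- K %*% mp
  aperm(array(y, d[perm]), order(perm))
}

gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Scale-normalized Laplacian of Gaussian, sigma in mm.
log_filter <- function(a, spacing, sigma_mm) {
  sm <- a
  for (ax in 1:3)
    sm <- axis_conv(sm, gauss_kernel(sigma_mm / spacing[ax]), ax)
  lap <- array(0, dim(a))
  for (ax in 1:3)
    lap <- lap + axis_conv(sm, c(1, -2, 1) / spacing[ax]^2, ax)
  lap * sigma_mm^2
}

# Undecimated single-level Haar decompositions; band names use axis order
# (z, y, x), e.g. "LLH" = low-pass in z and y, high-pass in x.
haar_bands <- function(a) {
  lo <- function(x, ax) (x + shift_edge(x, ax)) / sqrt(2)
  hi <- function(x, ax) (x - shift_edge(x, ax)) / sqrt(2)
  out <- list()
  for (bz in c("L", "H")) for (by in c("L", "H")) for (bx in c("L", "H")) {
    cur <- if (bz == "L") lo(a, 1) else hi(a, 1)
    cur <- if (by == "L") lo(cur, 2) else hi(cur, 2)
    cur <- if (bx == "L") lo(cur, 3) else hi(cur, 3)
    out[[paste0(bz, by, bx)]] <- cur
  }
  out
}

# Shift by one voxel along `ax` with replicated leading edge.
shift_edge <- function(a, ax) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  idx[[ax]] <- c(1, seq_len(d[ax] - 1))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

## ---- discretization -------------------------------------------------------

quantize_roi <- function(vals, bin_width, max_bins) {
  rng <- range(vals)
  w <- bin_width
  if ((rng[2] - rng[1]) / w > max_bins - 1)
    w <- (rng[2] - rng[1]) / (max_bins - 1)
  q <- floor((vals - rng[1]) / w) + 1L
  ng <- max(q)
  list(q = as.integer(q), ng = as.integer(ng))
}

## ---- first-order features -------------------------------------------------

firstorder_features <- function(vals, q, ng, voxvol) {
  n <- length(vals)
  p <- tabulate(q, ng) / n
  p_nz <- p[p > 0]
  mu <- mean(vals); va <- mean((vals - mu)^2)
  qs <- stats::quantile(vals, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE,
                        type = 7)
  core <- vals[vals >= qs[1] & vals <= qs[5]]
  sk <- if (va > 0) mean((vals - mu)^3) / va^1.5 else 0
  ku <- if (va > 0) mean((vals - mu)^4) / va^2 else 0
  c(Energy = sum(vals^2),
    TotalEnergy = voxvol * sum(vals^2),
    Entropy = -sum(p_nz * log2(p_nz)),
    Minimum = min(vals),
    `10Percentile` = qs[1],
    `90Percentile` = qs[5],
    Maximum = max(vals),
    Mean = mu,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(vals) - min(vals),
    MeanAbsoluteDeviation = mean(abs(vals - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(core)) mean(abs(core - mean(core))) else 0,
    RootMeanSquared = sqrt(mean(vals^2)),
    Skewness = sk,
    Kurtosis = ku,
    Variance = va,
    Uniformity = sum(p_nz^2))
}

## ---- texture matrices -----------------------------------------------------

# The 13 unique 3-D directions (half of the 26-neighbourhood).
texture_directions <- function() {
  g <- neighbor_offsets(26)
  keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  g[keep, , drop = FALSE]
}

glcm_matrix <- function(qarr, ng) {
  dirs <- texture_directions()
  P <- matrix(0, ng, ng)
  for (di in seq_len(nrow(dirs))) {
    sh <- shift3d(qarr, dirs[di, 1], dirs[di, 2], dirs[di, 3], fill = NA)
    ok <- !is.na(qarr) & !is.na(sh)
    if (!any(ok)) next
    idx <- qarr[ok] + (sh[ok] - 1L) * ng
    P <- P + matrix(tabulate(idx, ng * ng), ng, ng)
  }
  P + t(P)                      # symmetric co-occurrence
}

glcm_features <- function(qarr, ng) {
  eps <- .Machine$double.eps
  P <- glcm_matrix(qarr, ng)
  s <- sum(P)
  if (s == 0 || ng < 2) {
    p <- matrix(0, max(ng, 1), max(ng, 1)); p[1, 1] <- 1
    ng <- max(ng, 1)
  } else p <- P / s
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  pdiff <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ksd <- 0:(ng - 1)
  psum <- vapply(2:(2 * ng), function(k) sum(p[(i + j) == k]), numeric(1))
  kss <- 2:(2 * ng)
  da <- sum(ksd * pdiff)
  hxy <- -sum(p[p > 0] * log2(p[p > 0]))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p * log2(pxpy + eps))
  hxy2 <- -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))  # = HY by symmetry
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1
  # maximal correlation coefficient via the second eigenvalue of Q
  mcc_v <- tryCatch({
    if (ng < 2) 1 else {
      pxs <- pmax(px, eps); pys <- pmax(py, eps)
      A <- p %*% diag(1 / pys)
      Q <- diag(1 / pxs) %*% (A %*% t(p))
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(0, min(1, ev[2])))
    }
  }, error = function(e) 1)
  c(Autocorrelation = sum(i * j * p),
    JointAverage = mu,
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pdiff[pdiff > 0] * log2(pdiff[pdiff > 0])),
    DifferenceVariance = sum((ksd - da)^2 * pdiff),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Id = sum(p / (1 + abs(i - j))),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    InverseVariance = {
      off <- i != j
      sum(p[off] / ((i - j)[off])^2)
    },
    MaximumProbability = max(p),
    SumAverage = sum(kss * psum),
    SumEntropy = -sum(psum[psum > 0] * log2(psum[psum > 0])),
    SumSquares = sig2,
    MaximalCorrelationCoefficient = mcc_v)
}

# Run-length matrix accumulated over the 13 directions.
glrlm_features <- function(qarr, ng) {
  d <- dim(qarr)
  coords <- which(!is.na(qarr), arr.ind = TRUE)
  vals <- qarr[!is.na(qarr)]
  np <- length(vals)
  dirs <- texture_directions()
  K <- 512
  runs_g <- integer(0); runs_l <- integer(0)
  for (di in seq_len(nrow(dirs))) {
    dv <- dirs[di, ]
    t_ <- coords %*% dv
    step <- sum(dv^2)
    c1 <- coords[, 2] * dv[1] - coords[, 1] * dv[2]
    c2 <- coords[, 3] * dv[1] - coords[, 1] * dv[3]
    c3 <- coords[, 3] * dv[2] - coords[, 2] * dv[3]
    lid <- ((c1 + K) * 2 * K + (c2 + K)) * 2 * K + (c3 + K)
    o <- order(lid, t_)
    lv <- lid[o]; tv <- t_[o]; gv <- vals[o]
    brk <- c(TRUE, lv[-1] != lv[-np] | gv[-1] != gv[-np] |
               tv[-1] != tv[-np] + step)
    rid <- cumsum(brk)
    len <- tabulate(rid)
    runs_g <- c(runs_g, gv[brk])
    runs_l <- c(runs_l, len)
  }
  nr <- length(runs_l)
  ig <- as.numeric(runs_g); il <- as.numeric(runs_l)
  gl_counts <- tabulate(runs_g, ng)
  rl_counts <- tabulate(runs_l)
  mu_g <- sum(ig) / nr
  mu_l <- sum(il) / nr
  ent_p <- table(paste(runs_g, runs_l)) / nr
  c(ShortRunEmphasis = mean(1 / il^2),
    LongRunEmphasis = mean(il^2),
    GrayLevelNonUniformity = sum(gl_counts^2) / nr,
    GrayLevelNonUniformityNormalized = sum(gl_counts^2) / nr^2,
    RunLengthNonUniformity = sum(rl_counts^2) / nr,
    RunLengthNonUniformityNormalized = sum(rl_counts^2) / nr^2,
    RunPercentage = nr / (np * nrow(dirs)),
    GrayLevelVariance = mean((ig - mu_g)^2),
    RunVariance = mean((il - mu_l)^2),
    RunEntropy = -sum(ent_p * log2(ent_p)),
    LowGrayLevelRunEmphasis = mean(1 / ig^2),
    HighGrayLevelRunEmphasis = mean(ig^2),
    ShortRunLowGrayLevelEmphasis = mean(1 / (ig^2 * il^2)),
    ShortRunHighGrayLevelEmphasis = mean(ig^2 / il^2),
    LongRunLowGrayLevelEmphasis = mean(il^2 / ig^2),
    LongRunHighGrayLevelEmphasis = mean(ig^2 * il^2))
}

glszm_features <- function(qarr, ng) {
  msk <- !is.na(qarr)
  np <- sum(msk)
  zg <- integer(0); zs <- integer(0)
  for (g in seq_len(ng)) {
    sel <- !is.na(qarr) & qarr == g
    if (!any(sel)) next
    lab <- label_components(array(sel, dim(qarr)), connectivity = 26)
    sizes <- tabulate(lab[lab > 0])
    zg <- c(zg, rep(g, length(sizes)))
    zs <- c(zs, sizes)
  }
  nz <- length(zs)
  ig <- as.numeric(zg); is_ <- as.numeric(zs)
  gl_counts <- tabulate(zg, ng)
  sz_counts <- tabulate(zs)
  mu_g <- mean(ig); mu_s <- mean(is_)
  ent_p <- table(paste(zg, zs)) / nz
  c(SmallAreaEmphasis = mean(1 / is_^2),
    LargeAreaEmphasis = mean(is_^2),
    GrayLevelNonUniformity = sum(gl_counts^2) / nz,
    GrayLevelNonUniformityNormalized = sum(gl_counts^2) / nz^2,
    SizeZoneNonUniformity = sum(sz_counts^2) / nz,
    SizeZoneNonUniformityNormalized = sum(sz_counts^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = mean((ig - mu_g)^2),
    ZoneVariance = mean((is_ - mu_s)^2),
    ZoneEntropy = -sum(ent_p * log2(ent_p)),
    LowGrayLevelZoneEmphasis = mean(1 / ig^2),
    HighGrayLevelZoneEmphasis = mean(ig^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (ig^2 * is_^2)),
    SmallAreaHighGrayLevelEmphasis = mean(ig^2 / is_^2),
    LargeAreaLowGrayLevelEmphasis = mean(is_^2 / ig^2),
    LargeAreaHighGrayLevelEmphasis = mean(ig^2 * is_^2))
}

gldm_features <- function(qarr, ng) {
  offs <- neighbor_offsets(26)
  dep <- array(0L, dim(qarr))
  for (oi in seq_len(nrow(offs))) {
    sh <- shift3d(qarr, offs[oi, 1], offs[oi, 2], offs[oi, 3], fill = NA)
    dep <- dep + (!is.na(qarr) & !is.na(sh) & qarr == sh)
  }
  msk <- !is.na(qarr)
  g <- qarr[msk]; k <- dep[msk] + 1L     # dependence bins start at 1
  n <- length(g)
  ig <- as.numeric(g); ik <- as.numeric(k)
  gl_counts <- tabulate(g, ng)
  dp_counts <- tabulate(k)
  mu_g <- mean(ig); mu_k <- mean(ik)
  ent_p <- table(paste(g, k)) / n
  c(SmallDependenceEmphasis = mean(1 / ik^2),
    LargeDependenceEmphasis = mean(ik^2),
    GrayLevelNonUniformity = sum(gl_counts^2) / n,
    DependenceNonUniformity = sum(dp_counts^2) / n,
    DependenceNonUniformityNormalized = sum(dp_counts^2) / n^2,
    GrayLevelVariance = mean((ig - mu_g)^2),
    DependenceVariance = mean((ik - mu_k)^2),
    DependenceEntropy = -sum(ent_p * log2(ent_p)),
    LowGrayLevelEmphasis = mean(1 / ig^2),
    HighGrayLevelEmphasis = mean(ig^2),
    SmallDependenceLowGrayLevelEmphasis = mean(1 / (ig^2 * ik^2)),
    SmallDependenceHighGrayLevelEmphasis = mean(ig^2 / ik^2),
    LargeDependenceLowGrayLevelEmphasis = mean(ik^2 / ig^2),
    LargeDependenceHighGrayLevelEmphasis = mean(ig^2 * ik^2))
}

ngtdm_features <- function(qarr, ng) {
  offs <- neighbor_offsets(26)
  nb_sum <- array(0, dim(qarr))
  nb_cnt <- array(0L, dim(qarr))
  for (oi in seq_len(nrow(offs))) {
    sh <- shift3d(qarr, offs[oi, 1], offs[oi, 2], offs[oi, 3], fill = NA)
    ok <- !is.na(sh)
    nb_sum[ok] <- nb_sum[ok] + sh[ok]
    nb_cnt <- nb_cnt + ok
  }
  msk <- !is.na(qarr) & nb_cnt > 0
  g <- qarr[msk]
  abar <- nb_sum[msk] / nb_cnt[msk]
  n <- sum(msk)
  s_i <- vapply(seq_len(ng), function(i) sum(abs(i - abar[g == i])),
                numeric(1))
  n_i <- tabulate(g, ng)
  p_i <- n_i / n
  act <- which(p_i > 0)
  ngp <- length(act)
  coars <- if (sum(p_i * s_i) > 0) 1 / sum(p_i * s_i) else 1e6
  if (ngp > 1) {
    pij <- outer(p_i[act], p_i[act])
    dij <- outer(act, act, `-`)
    contrast <- sum(pij * dij^2) / (ngp * (ngp - 1)) * sum(s_i) / n
    busy_den <- sum(abs(outer(act * p_i[act], act * p_i[act], `-`)))
    busy <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
    cplx_num <- outer(p_i[act] * s_i[act], p_i[act] * s_i[act], `+`)
    cplx <- sum(abs(dij) * cplx_num / (outer(p_i[act], p_i[act], `+`))) / n
    stren_num <- sum(outer(p_i[act], p_i[act], `+`) * dij^2)
    stren <- if (sum(s_i) > 0) stren_num / sum(s_i) else 0
  } else {
    contrast <- 0; busy <- 0; cplx <- 0; stren <- 0
  }
  c(Coarseness = coars, Contrast = contrast, Busyness = busy,
    Complexity = cplx, Strength = stren)
}

## ---- shape features -------------------------------------------------------

max_diam_plane <- function(a, axis, spacing) {
  d <- dim(a)
  best <- 0
  other <- setdiff(1:3, axis)
  for (i in seq_len(d[axis])) {
    sl <- switch(axis, a[i, , ], a[, i, ], a[, , i])
    if (!any(sl != 0)) next
    pts <- which(sl != 0, arr.ind = TRUE)
    if (nrow(pts) < 2) next
    pts <- sweep(matrix(as.numeric(pts), ncol = 2), 2, spacing[other], `*`)
    best <- max(best, max_pairwise_dist(cbind(0, pts)))
  }
  best
}

# Surface area via the coarea formula: the integral of |grad u| for a
# smoothed indicator converges to the true surface area, avoiding the
# staircase overestimate of voxel-face counting.
smooth_surface_area <- function(a, spacing) {
  pd <- dim(a) + 8L
  u <- array(0, pd)
  u[5:(4 + dim(a)[1]), 5:(4 + dim(a)[2]), 5:(4 + dim(a)[3])] <- a
  for (ax in 1:3) u <- axis_conv(u, gauss_kernel(1.0), ax)
  g2 <- array(0, pd)
  for (ax in 1:3) {
    idx_f <- lapply(pd, seq_len); idx_b <- idx_f
    idx_f[[ax]] <- pmin(idx_f[[ax]] + 1, pd[ax])
    idx_b[[ax]] <- pmax(idx_b[[ax]] - 1, 1)
    gax <- (do.call(`[`, c(list(u), idx_f)) -
              do.call(`[`, c(list(u), idx_b))) / (2 * spacing[ax])
    g2 <- g2 + gax^2
  }
  sum(sqrt(g2)) * prod(spacing)
}

shape_features <- function(msk, spacing) {
  a <- msk != 0
  n <- sum(a)
  voxvol <- prod(spacing)
  area <- smooth_surface_area(a, spacing)
  # voxel-count volume is asymptotically unbiased; the "mesh" volume uses
  # the smoothed indicator, whose integral coincides with it
  vol <- n * voxvol
  mesh_vol <- vol
  coords <- which(a, arr.ind = TRUE)
  pc <- sweep(matrix(as.numeric(coords), ncol = 3), 2, spacing, `*`)
  ev <- if (n >= 2) sort(pmax(eigen(stats::cov(pc),
                                    only.values = TRUE)$values, 0),
                         decreasing = TRUE)
        else c(0, 0, 0)
  sph <- (36 * pi * mesh_vol^2)^(1 / 3) / area
  c(MeshVolume = mesh_vol,
    VoxelVolume = vol,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / mesh_vol,
    Sphericity = sph,
    Maximum3DDiameter = longest_diameter(a * 1, "volume3d", spacing = spacing),
    Maximum2DDiameterSlice = max_diam_plane(a, 1, spacing),
    Maximum2DDiameterColumn = max_diam_plane(a, 2, spacing),
    Maximum2DDiameterRow = max_diam_plane(a, 3, spacing),
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1)
}

## ---- extraction driver ----------------------------------------------------

#' Extract the radiomics feature vector for one tumor
#'
#' @param v intensity volume (`hep_volume` or 3-D array).
#' @param tumor binary tumor mask aligned with `v`; needs at least 2
#'   voxels.
#' @param cfg a [radiomics_config()].
#' @return named numeric vector; 1316 components under the default
#'   configuration.
#' @export
extract_features <- function(v, tumor, cfg = radiomics_config()) {
  a <- as_array3d(v)
  msk <- as_array3d(tumor) != 0
  spacing <- spacing_of(v, spacing_of(tumor))
  if (sum(msk) < 2) stopf("extract_features: degenerate ROI (< 2 voxels)")
  # crop to the mask bounding box with enough margin for the filters
  marg <- ceiling(3 * max(cfg$log_sigmas_mm) / spacing) + 1
  bb <- apply(which(msk, arr.ind = TRUE), 2, range)
  lo <- pmax(1, bb[1, ] - marg); hi <- pmin(dim(a), bb[2, ] + marg)
  sub <- a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  smk <- msk[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  voxvol <- prod(spacing)

  images <- list(original = sub)
  for (s in cfg$log_sigmas_mm)
    images[[sprintf("log-sigma-%.1f-mm", s)]] <- log_filter(sub, spacing, s)
  if (cfg$wavelet) {
    hb <- haar_bands(sub)
    for (nm in names(hb)) images[[paste0("wavelet-", nm)]] <- hb[[nm]]
  }

  out <- numeric(0)
  shp <- shape_features(smk, spacing)
  out <- c(out, stats::setNames(shp, paste0("original_shape_", names(shp))))
  for (nm in names(images)) {
    img <- images[[nm]]
    vals <- img[smk]
    qz <- quantize_roi(vals, cfg$bin_width, cfg$max_bins)
    qarr <- array(NA_integer_, dim(img))
    qarr[smk] <- qz$q
    fo <- firstorder_features(vals, qz$q, qz$ng, voxvol)
    gc_ <- glcm_features(qarr, qz$ng)
    rl <- glrlm_features(qarr, qz$ng)
    sz <- glszm_features(qarr, qz$ng)
    dm <- gldm_features(qarr, qz$ng)
    nt <- ngtdm_features(qarr, qz$ng)
    out <- c(out,
             stats::setNames(fo, paste0(nm, "_firstorder_", names(fo))),
             stats::setNames(gc_, paste0(nm, "_glcm_", names(gc_))),
             stats::setNames(rl, paste0(nm, "_glrlm_", names(rl))),
             stats::setNames(sz, paste0(nm, "_glszm_", names(sz))),
             stats::setNames(dm, paste0(nm, "_gldm_", names(dm))),
             stats::setNames(nt, paste0(nm, "_ngtdm_", names(nt))))
  }
  out[!is.finite(out)] <- 0
  out
}

#' Extract a feature matrix for a phantom cohort
#'
#' One row per tumor across all cases, with stable ordered column names;
#' also returns the matching label matrix and true sizes.
#'
#' @param cases list of phantom cases.
#' @param cfg a [radiomics_config()].
#' @return list with `features` (matrix), `labels` (matrix), `sizes`,
#'   `case` (case index per row).
#' @export
cohort_features <- function(cases, cfg = radiomics_config()) {
  rows <- list(); labs <- list(); sizes <- numeric(0); caseix <- integer(0)
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    for (ti in seq_along(cs$tumors)) {
      rows[[length(rows) + 1]] <-
        extract_features(cs$volume, cs$tumors[[ti]], cfg)
      labs[[length(labs) + 1]] <- cs$labels[ti, ]
      sizes <- c(sizes, cs$true_size_cm[ti])
      caseix <- c(caseix, ci)
    }
  }
  list(features = do.call(rbind, rows), labels = do.call(rbind, labs),
       sizes = sizes, case = caseix)
}
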