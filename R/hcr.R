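# Handcrafted radiomic features: 14 shape + 18 first-order + 73 texture
# (22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM) = 105 per ROI.
# Texture matrices are built in 3-D: GLCM/GLRLM over the 13 unique distance-1
# direction offsets with per-direction features averaged; GLSZM zones use
# 26-connectivity; GLDM/NGTDM use the 26-voxel neighbourhood.
# Degenerate denominators (constant ROI, single gray level) return 0 rather
# than NaN; NGTDM coarseness on a flat region returns 1e6 by convention.

#' Handcrafted-extraction parameters
#'
#' @param bin_width fixed bin width in HU for gray-level discretisation
#'   (default 25 HU).
#' @return A list of class `hcr_params`.
#' @export
hcr_params <- function(bin_width = 25) {
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  structure(list(bin_width = bin_width), class = "hcr_params")
}

#' Fixed-bin-width gray-level discretisation
#'
#' level(v) = floor((I(v) - min over mask) / bin_width) + 1, so the darkest
#' in-mask voxel is level 1 and a constant region yields a single level.
#'
#' @param image 3-D numeric array or [image_grid()].
#' @param mask logical array or [structure_mask()], non-empty.
#' @param params an [hcr_params()].
#' @return List with `levels` (array, NA outside mask) and `n_levels`.
#' @export
discretize <- function(image, mask, params = hcr_params()) {
  img <- if (is_image_grid(image)) image$values else image
  m <- mask_array(mask)
  if (!any(m)) stop("empty ROI")
  lv <- array(NA_integer_, dim(img))
  vals <- img[m]
  lv[m] <- as.integer(floor((vals - min(vals)) / params$bin_width)) + 1L
  list(levels = lv, n_levels = max(lv[m]))
}

# 13 unique direction offsets at Chebyshev distance 1
hcr_directions <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), ]
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
          (offs[, 2] == 0 & offs[, 1] > 0)))
  offs[keep, , drop = FALSE]
}

xlog2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# --- first order ---------------------------------------------------------------

firstorder_features <- function(vals, voxel_mm3, levels_in_mask) {
  n <- length(vals)
  mu <- mean(vals)
  vr <- sum((vals - mu)^2) / n
  q <- stats::quantile(vals, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE,
                       type = 7)
  sub <- vals[vals >= q[1] & vals <= q[5]]
  p_hist <- tabulate(levels_in_mask) / n
  m3 <- sum((vals - mu)^3) / n
  m4 <- sum((vals - mu)^4) / n
  c(
    Energy = sum(vals^2),
    TotalEnergy = voxel_mm3 * sum(vals^2),
    Entropy = xlog2(p_hist),
    Minimum = min(vals),
    P10 = q[1],
    P90 = q[5],
    Maximum = max(vals),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(vals) - min(vals),
    MeanAbsoluteDeviation = mean(abs(vals - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(sub)) mean(abs(sub - mean(sub))) else 0,
    RootMeanSquared = sqrt(mean(vals^2)),
    Skewness = if (vr > 0) m3 / vr^1.5 else 0,
    Kurtosis = if (vr > 0) m4 / vr^2 else 0,
    Variance = vr,
    Uniformity = sum(p_hist^2)
  )
}

# --- GLCM ----------------------------------------------------------------------

glcm_from_direction <- function(lv, ng, off) {
  b <- shift_array(lv, -off[1], -off[2], -off[3], fill = NA_integer_)
  ok <- !is.na(lv) & !is.na(b)
  if (!any(ok)) return(NULL)
  cnt <- tabulate((lv[ok] - 1L) * ng + b[ok], nbins = ng * ng)
  P <- matrix(cnt, ng, ng, byrow = TRUE)
  P + t(P)  # symmetric co-occurrence
}

glcm_features_one <- function(P) {
  ng <- nrow(P)
  p <- P / sum(P)
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  pxy_sum <- vapply(2:(2 * ng), function(k) sum(p[(i + j) == k]), 0)
  kd <- 0:(ng - 1)
  pxy_diff <- vapply(kd, function(k) sum(p[abs(i - j) == k]), 0)
  hxy <- xlog2(p)
  hx <- xlog2(px)
  # information measures of correlation
  pipj <- outer(px, px)
  ok <- p > 0 & pipj > 0
  hxy1 <- -sum(p[ok] * log2(pipj[ok]))
  ok2 <- pipj > 0
  hxy2 <- -sum(pipj[ok2] * log2(pipj[ok2]))
  da <- sum(kd * pxy_diff)
  c(
    Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 0,
    DifferenceAverage = da,
    DifferenceEntropy = xlog2(pxy_diff),
    DifferenceVariance = sum((kd - da)^2 * pxy_diff),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    InverseVariance = sum(p[i != j] / (i - j)[i != j]^2),
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MaximumProbability = max(p),
    SumEntropy = xlog2(pxy_sum),
    SumSquares = sig2
  )
}

glcm_features <- function(lv, ng) {
  offs <- hcr_directions()
  res <- NULL
  for (k in seq_len(nrow(offs))) {
    P <- glcm_from_direction(lv, ng, offs[k, ])
    if (is.null(P) || sum(P) == 0) next
    f <- glcm_features_one(P)
    res <- if (is.null(res)) rbind(f) else rbind(res, f)
  }
  if (is.null(res)) {
    f <- rep(0, 22)
    names(f) <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
                  "ClusterTendency", "Contrast", "Correlation",
                  "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
                  "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
                  "JointAverage", "JointEnergy", "JointEntropy",
                  "MaximumProbability", "SumEntropy", "SumSquares")
    return(f)
  }
  colMeans(res)
}

# --- GLRLM ---------------------------------------------------------------------

# Run lengths along one direction via dynamic programming over projection
# groups: L(v) = 1 + L(v + d) when the next voxel continues the run.
# Neighbour lookups use linear-index arithmetic on the in-mask voxels only.
glrlm_from_direction <- function(lv, ng, off, dims) {
  mask_idx <- which(!is.na(lv))
  if (!length(mask_idx)) return(NULL)
  ijk <- arrayInd(mask_idx, dims)
  step <- off[1] + off[2] * dims[1] + off[3] * dims[1] * dims[2]
  inb <- function(sgn) {
    ijk[, 1] + sgn * off[1] >= 1 & ijk[, 1] + sgn * off[1] <= dims[1] &
    ijk[, 2] + sgn * off[2] >= 1 & ijk[, 2] + sgn * off[2] <= dims[2] &
    ijk[, 3] + sgn * off[3] >= 1 & ijk[, 3] + sgn * off[3] <= dims[3]
  }
  nxt_ok <- inb(1L)
  cont <- nxt_ok
  cont[nxt_ok] <- {
    nv <- lv[mask_idx[nxt_ok] + step]
    !is.na(nv) & nv == lv[mask_idx[nxt_ok]]
  }
  proj <- ijk %*% off
  L <- array(NA_integer_, dims)
  L[mask_idx] <- 1L
  ord <- order(proj, decreasing = TRUE)
  grp <- split(ord, proj[ord])
  for (g in rev(grp)) {
    cc <- g[cont[g]]
    if (length(cc)) L[mask_idx[cc]] <- 1L + L[mask_idx[cc] + step]
  }
  prev_ok <- inb(-1L)
  same_prev <- prev_ok
  same_prev[prev_ok] <- {
    pv <- lv[mask_idx[prev_ok] - step]
    !is.na(pv) & pv == lv[mask_idx[prev_ok]]
  }
  st <- mask_idx[!same_prev]
  lev <- lv[st]; len <- L[st]
  maxlen <- max(len)
  cnt <- tabulate((lev - 1L) * maxlen + len, nbins = ng * maxlen)
  matrix(cnt, ng, maxlen, byrow = TRUE)
}

rl_features <- function(P, np, prefix_short, prefix_long, what) {
  # shared formula family for GLRLM (what = run) and GLSZM (what = zone)
  nr <- sum(P)
  ng <- nrow(P); nl <- ncol(P)
  i <- row(P); l <- col(P)
  p <- P / nr
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  v <- c(
    sum(P / l^2) / nr,                 # short emphasis
    sum(P * l^2) / nr,                 # long emphasis
    sum(rowSums(P)^2) / nr,            # gray level non-uniformity
    sum(rowSums(P)^2) / nr^2,          # ... normalized
    sum(colSums(P)^2) / nr,            # run/zone length non-uniformity
    sum(colSums(P)^2) / nr^2,          # ... normalized
    nr / np,                           # percentage
    sum(p * (i - mu_i)^2),             # gray level variance
    sum(p * (l - mu_l)^2),             # length variance
    xlog2(p),                          # entropy
    sum(P / i^2) / nr,                 # low gray level
    sum(P * i^2) / nr,                 # high gray level
    sum(P / (i^2 * l^2)) / nr,
    sum(P * i^2 / l^2) / nr,
    sum(P * l^2 / i^2) / nr,
    sum(P * i^2 * l^2) / nr
  )
  names(v) <- c(paste0(prefix_short, "Emphasis"), paste0(prefix_long, "Emphasis"),
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    paste0(what, "NonUniformity"), paste0(what, "NonUniformityNormalized"),
    paste0(what, "Percentage"), "GrayLevelVariance", paste0(what, "Variance"),
    paste0(what, "Entropy"), "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
    paste0(prefix_short, "LowGrayLevelEmphasis"),
    paste0(prefix_short, "HighGrayLevelEmphasis"),
    paste0(prefix_long, "LowGrayLevelEmphasis"),
    paste0(prefix_long, "HighGrayLevelEmphasis"))
  v
}

glrlm_features <- function(lv, ng, dims) {
  np <- sum(!is.na(lv))
  offs <- hcr_directions()
  res <- NULL
  for (k in seq_len(nrow(offs))) {
    P <- glrlm_from_direction(lv, ng, offs[k, ], dims)
    if (is.null(P)) next
    f <- rl_features(P, np, "ShortRun", "LongRun", "RunLength")
    names(f)[names(f) == "RunLengthPercentage"] <- "RunPercentage"
    names(f)[names(f) == "RunLengthVariance"] <- "RunVariance"
    names(f)[names(f) == "RunLengthEntropy"] <- "RunEntropy"
    res <- if (is.null(res)) rbind(f) else rbind(res, f)
  }
  colMeans(res)
}

# --- GLSZM ---------------------------------------------------------------------

shift2 <- function(m, di, dj, fill) {
  d <- dim(m)
  out <- matrix(fill, d[1], d[2])
  if (abs(di) >= d[1] || abs(dj) >= d[2]) return(out)
  si <- max(1, 1 + di):min(d[1], d[1] + di)
  sj <- max(1, 1 + dj):min(d[2], d[2] + dj)
  out[si, sj] <- m[si - di, sj - dj]
  out
}

# zones = 26-connected components of constant gray level, labelled by
# minimum-label propagation with Gauss-Seidel raster sweeps along each axis
# (sequential along the sweep axis, so labels travel the full axis per pass;
# the nine cross-slice neighbour offsets cover 26-connectivity across the
# three axes)
glszm_zones <- function(lv, dims) {
  lab <- array(0, dims)
  mask_idx <- which(!is.na(lv))
  lab[mask_idx] <- mask_idx
  sweep_axis <- function(lab, axis, forward) {
    n <- dims[axis]
    if (n < 2) return(lab)
    idx <- if (forward) 2:n else (n - 1):1
    for (i in idx) {
      j <- if (forward) i - 1 else i + 1
      cur <- slice_get(lab, axis, i); prv <- slice_get(lab, axis, j)
      lcur <- slice_get(lv, axis, i); lprv <- slice_get(lv, axis, j)
      for (da in -1:1) for (db in -1:1) {
        nl <- shift2(prv, da, db, fill = 0)
        nv <- shift2(lprv, da, db, fill = NA_integer_)
        upd <- !is.na(lcur) & !is.na(nv) & nv == lcur & nl > 0 & nl < cur
        if (any(upd)) cur[upd] <- nl[upd]
      }
      lab <- slice_set(lab, axis, i, cur)
    }
    lab
  }
  repeat {
    old <- lab
    for (axis in 1:3) {
      lab <- sweep_axis(lab, axis, TRUE)
      lab <- sweep_axis(lab, axis, FALSE)
    }
    if (identical(old, lab)) break
  }
  labs <- lab[mask_idx]
  sizes <- table(labs)
  lev <- lv[as.integer(names(sizes))]
  data.frame(level = lev, size = as.integer(sizes))
}

glszm_features <- function(lv, ng, dims) {
  np <- sum(!is.na(lv))
  z <- glszm_zones(lv, dims)
  maxs <- max(z$size)
  cnt <- tabulate((z$level - 1L) * maxs + z$size, nbins = ng * maxs)
  P <- matrix(cnt, ng, maxs, byrow = TRUE)
  f <- rl_features(P, np, "SmallArea", "LargeArea", "SizeZone")
  names(f)[names(f) == "SizeZonePercentage"] <- "ZonePercentage"
  names(f)[names(f) == "SizeZoneVariance"] <- "ZoneVariance"
  names(f)[names(f) == "SizeZoneEntropy"] <- "ZoneEntropy"
  f
}

# --- GLDM ----------------------------------------------------------------------

neighbor_stats <- function(lv) {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  eqn <- array(0L, dim(lv)); cnt <- array(0L, dim(lv)); s <- array(0, dim(lv))
  for (k in seq_len(nrow(offs))) {
    nv <- shift_array(lv, offs[k, 1], offs[k, 2], offs[k, 3],
                      fill = NA_integer_)
    has <- !is.na(lv) & !is.na(nv)
    eqn <- eqn + (has & nv == lv)
    cnt <- cnt + has
    s[has] <- s[has] + nv[has]
  }
  list(equal = eqn, count = cnt, sum = s)
}

gldm_features <- function(lv, ng) {
  ns <- neighbor_stats(lv)
  inm <- which(!is.na(lv))
  dep <- ns$equal[inm] + 1L          # dependence size includes the centre
  lev <- lv[inm]
  maxd <- max(dep)
  cnt <- tabulate((lev - 1L) * maxd + dep, nbins = ng * maxd)
  P <- matrix(cnt, ng, maxd, byrow = TRUE)
  nz <- sum(P)
  i <- row(P); j <- col(P)
  p <- P / nz
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(
    SmallDependenceEmphasis = sum(P / j^2) / nz,
    LargeDependenceEmphasis = sum(P * j^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    DependenceNonUniformity = sum(colSums(P)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    DependenceVariance = sum(p * (j - mu_j)^2),
    DependenceEntropy = xlog2(p),
    LowGrayLevelEmphasis = sum(P / i^2) / nz,
    HighGrayLevelEmphasis = sum(P * i^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz
  )
}

# --- NGTDM ---------------------------------------------------------------------

ngtdm_features <- function(lv, ng) {
  ns <- neighbor_stats(lv)
  valid <- !is.na(lv) & ns$count > 0
  A <- ns$sum[valid] / ns$count[valid]
  lev <- lv[valid]
  nvp <- length(lev)
  n_i <- tabulate(lev, nbins = ng)
  s_i <- vapply(seq_len(ng), function(i) sum(abs(i - A[lev == i])), 0)
  p_i <- n_i / nvp
  act <- which(p_i > 0)
  ngp <- length(act)
  coarse_den <- sum(p_i * s_i)
  contrast <- if (ngp > 1) {
    (sum(outer(p_i[act], p_i[act]) *
         outer(act, act, function(a, b) (a - b)^2)) / (ngp * (ngp - 1))) *
      (sum(s_i) / nvp)
  } else 0
  busy_den <- sum(abs(outer(act * p_i[act], act * p_i[act], "-")))
  complexity <- if (nvp > 0) {
    num <- outer(act, act, function(a, b) abs(a - b)) *
      (outer(p_i[act] * s_i[act], p_i[act] * s_i[act], "+") /
         outer(p_i[act], p_i[act], "+"))
    sum(num) / nvp
  } else 0
  strength_num <- sum(outer(p_i[act], p_i[act], "+") *
                        outer(act, act, function(a, b) (a - b)^2))
  c(
    Coarseness = if (coarse_den > 0) 1 / coarse_den else 1e6,
    Contrast = contrast,
    Busyness = if (busy_den > 0) coarse_den / busy_den else 0,
    Complexity = complexity,
    Strength = if (sum(s_i) > 0) strength_num / sum(s_i) else 0
  )
}

# --- shape ---------------------------------------------------------------------

max_pairwise_mm <- function(pts) {
  if (nrow(pts) < 2) return(0)
  if (nrow(pts) > 600) {
    # candidate extremes along a deterministic set of directions; the maximal
    # chord is attained at convex-hull vertices, which projections locate
    gold <- pi * (3 - sqrt(5))
    k <- seq_len(192)
    zc <- 1 - 2 * (k - 0.5) / 192
    r <- sqrt(pmax(0, 1 - zc^2))
    dirs <- cbind(r * cos(gold * k), r * sin(gold * k), zc)
    proj <- pts %*% t(dirs)
    cand <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
    pts <- pts[cand, , drop = FALSE]
  }
  sqrt(max(stats::dist(pts)^2))
}

max_2d_diameter <- function(pts2, groups) {
  best <- 0
  for (g in unique(groups)) {
    q <- pts2[groups == g, , drop = FALSE]
    if (nrow(q) < 2) next
    if (nrow(q) > 3) q <- q[grDevices::chull(q), , drop = FALSE]
    best <- max(best, max(stats::dist(q)))
  }
  best
}

shape_features <- function(mask, spacing) {
  d <- dim(mask)
  n <- sum(mask)
  vox_mm3 <- prod(spacing)
  vol <- n * vox_mm3
  # surface area: exposed voxel faces
  area <- 0
  face_mm2 <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                spacing[1] * spacing[2])
  for (axis in 1:3) {
    for (sgn in c(-1, 1)) {
      sh <- c(0, 0, 0); sh[axis] <- sgn
      nb <- shift_array(mask, sh[1], sh[2], sh[3], fill = FALSE)
      area <- area + sum(mask & !nb) * face_mm2[axis]
    }
  }
  idx <- which(mask)
  ijk <- arrayInd(idx, d)
  pts <- sweep(ijk - 1, 2, spacing, "*")
  # surface voxels only, for diameters
  interior <- array(TRUE, d)
  for (axis in 1:3) for (sgn in c(-1, 1)) {
    sh <- c(0, 0, 0); sh[axis] <- sgn
    interior <- interior & shift_array(mask, sh[1], sh[2], sh[3], fill = FALSE)
  }
  surf <- mask & !interior
  sijk <- arrayInd(which(surf), d)
  spts <- sweep(sijk - 1, 2, spacing, "*")
  cen <- colMeans(pts)
  cpts <- sweep(pts, 2, cen)
  ev <- if (n > 1) {
    eigen(crossprod(cpts) / n, symmetric = TRUE, only.values = TRUE)$values
  } else c(0, 0, 0)
  ev <- pmax(ev, 0)
  axlen <- 4 * sqrt(ev)
  c(
    MeshVolume = vol,
    VoxelVolume = vol,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / vol,
    Sphericity = (36 * pi * vol^2)^(1 / 3) / area,
    Maximum3DDiameter = max_pairwise_mm(spts),
    Maximum2DDiameterSlice = max_2d_diameter(spts[, 1:2, drop = FALSE], sijk[, 3]),
    Maximum2DDiameterColumn = max_2d_diameter(spts[, c(2, 3), drop = FALSE], sijk[, 1]),
    Maximum2DDiameterRow = max_2d_diameter(spts[, c(1, 3), drop = FALSE], sijk[, 2]),
    MajorAxisLength = axlen[1],
    MinorAxisLength = axlen[2],
    LeastAxisLength = axlen[3],
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  )
}

# --- manifest and driver -------------------------------------------------------

#' The frozen 105-feature name manifest
#'
#' @return Character vector of the 105 feature names in extraction order,
#'   prefixed `hcr_<family>_<name>`.
#' @export
hcr_feature_names <- function() {
  shape <- c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
             "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
             "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
             "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
             "Elongation", "Flatness")
  fo <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "P10", "P90",
          "Maximum", "Mean", "Median", "InterquartileRange", "Range",
          "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
          "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")
  glcm <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
            "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
            "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
            "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
            "JointEnergy", "JointEntropy", "MaximumProbability", "SumEntropy",
            "SumSquares")
  glrlm <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
             "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
             "RunLengthNonUniformityNormalized", "RunPercentage",
             "GrayLevelVariance", "RunVariance", "RunEntropy",
             "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
             "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
             "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  glszm <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
             "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
             "SizeZoneNonUniformityNormalized", "ZonePercentage",
             "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
             "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
             "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
             "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  gldm <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
            "GrayLevelNonUniformity", "DependenceNonUniformity",
            "DependenceNonUniformityNormalized", "GrayLevelVariance",
            "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
            "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
            "SmallDependenceHighGrayLevelEmphasis",
            "LargeDependenceLowGrayLevelEmphasis",
            "LargeDependenceHighGrayLevelEmphasis")
  ngtdm <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  c(paste0("hcr_shape_", shape), paste0("hcr_firstorder_", fo),
    paste0("hcr_glcm_", glcm), paste0("hcr_glrlm_", glrlm),
    paste0("hcr_glszm_", glszm), paste0("hcr_gldm_", gldm),
    paste0("hcr_ngtdm_", ngtdm))
}

#' Extract the 105 handcrafted radiomic features from one ROI
#'
#' @param image 3-D numeric array or [image_grid()] (CT in HU).
#' @param mask logical array or [structure_mask()] with at least 8 voxels.
#' @param params an [hcr_params()].
#' @param spacing voxel spacing in mm (taken from `image` if it is a grid).
#' @return Named numeric vector of length 105 (see [hcr_feature_names()]).
#' @export
extract_hcr <- function(image, mask, params = hcr_params(), spacing = NULL) {
  if (is_image_grid(image)) {
    spacing <- image$spacing
    img <- image$values
  } else img <- image
  if (is.null(spacing)) stop("spacing required when image is a bare array")
  m <- mask_array(mask)
  if (sum(m) < 8) stop("roi too small: need >= 8 voxels")
  dsc <- discretize(img, m, params)
  lv <- dsc$levels; ng <- dsc$n_levels
  dims <- dim(img)
  out <- c(
    shape_features(m, spacing),
    firstorder_features(img[m], prod(spacing), lv[m]),
    glcm_features(lv, ng),
    glrlm_features(lv, ng, dims),
    glszm_features(lv, ng, dims),
    gldm_features(lv, ng),
    ngtdm_features(lv, ng)
  )
  names(out) <- hcr_feature_names()
  if (any(!is.finite(out))) stop("non-finite handcrafted feature produced")
  out
}
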