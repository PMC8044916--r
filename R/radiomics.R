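#' Radiomic feature extraction parameters
#'
#' @param bin_mode gray-level discretization mode: `"width"` (fixed bin
#'   width in intensity units, the default for contrast-enhanced intensity
#'   images — absolute enhancement carries the treatment effect, so the
#'   gray-level axis must not be renormalized per image) or `"count"`
#'   (fixed number of bins inside the ROI; appropriate for unitless maps
#'   such as the Jacobian determinant).
#' @param bin_value bin width (mode `"width"`, default 25 intensity units)
#'   or number of bins (mode `"count"`).
#' @param gldm_alpha dependence tolerance: a neighbour is dependent when
#'   its gray level differs from the centre by at most `gldm_alpha`.
#' @param energy_shift optional intensity shift c added before the energy /
#'   RMS computations (default 0; subtraction images may be negative,
#'   which is deliberate and documented).
#' @return A `feature_params` list.
#' @export
feature_params <- function(bin_mode = c("width", "count"), bin_value = NULL,
                           gldm_alpha = 0, energy_shift = 0) {
  bin_mode <- match.arg(bin_mode)
  if (is.null(bin_value)) bin_value <- if (bin_mode == "width") 25 else 32
  if (bin_mode == "count" && bin_value < 2) stop("bin count must be >= 2")
  if (bin_mode == "width" && bin_value <= 0) stop("bin width must be > 0")
  structure(list(bin_mode = bin_mode, bin_value = bin_value,
                 gldm_alpha = gldm_alpha, energy_shift = energy_shift),
            class = "feature_params")
}

#' The frozen 102-feature name registry
#'
#' Family sizes: shape 14, first-order 18, GLCM 24, GLRLM 16, GLSZM 16,
#' GLDM 14. Names are stable across runs and releases.
#'
#' @return Character vector of 102 feature names.
#' @export
feature_names <- function() {
  c(paste0("shape_", c(
      "MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
      "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
      "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "MajorAxisLength",
      "MinorAxisLength", "LeastAxisLength", "Elongation", "Flatness")),
    paste0("firstorder_", c(
      "Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10",
      "Percentile90", "Maximum", "Mean", "Median", "InterquartileRange",
      "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
      "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")),
    paste0("glcm_", c(
      "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
      "InverseVariance", "JointEnergy", "JointEntropy", "Imc1", "Imc2",
      "MCC", "MaximumProbability", "SumAverage", "SumEntropy",
      "SumSquares")),
    paste0("glrlm_", c(
      "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")),
    paste0("glszm_", c(
      "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")),
    paste0("gldm_", c(
      "SmallDependenceEmphasis", "LargeDependenceEmphasis",
      "GrayLevelNonUniformity", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "GrayLevelVariance",
      "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
      "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
      "SmallDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis",
      "LargeDependenceHighGrayLevelEmphasis")))
}

#' Discretize in-mask intensities into gray levels
#'
#' Fixed-bin-count mode maps the in-mask minimum to level 1 and the maximum
#' to level G; fixed-bin-width mode uses levels
#' `floor((x - min) / width) + 1`. The mapping is monotone. Constant
#' in-mask regions collapse to a single level and are flagged.
#'
#' @param volume an `image_volume`.
#' @param mask a `binary_mask` on the same lattice.
#' @param params a [feature_params()].
#' @return A list with `levels` (integer array, 0 outside the mask),
#'   `n_levels` (G) and `degenerate` (TRUE when the region is constant).
#' @export
discretize <- function(volume, mask, params = feature_params()) {
  stopifnot(is_image_volume(volume), inherits(mask, "binary_mask"))
  stopifnot_same_lattice(volume, mask)
  sel <- mask_logical(mask)
  if (!any(sel)) stop("empty mask")
  x <- volume$values[sel]
  rng <- range(x)
  degenerate <- (rng[2] - rng[1]) < 1e-12
  lev <- array(0L, dim = dim(volume$values))
  if (degenerate) {
    lev[sel] <- 1L
    G <- 1L
  } else if (params$bin_mode == "count") {
    G <- as.integer(params$bin_value)
    width <- (rng[2] - rng[1]) / G
    lev[sel] <- pmin(G, as.integer(floor((x - rng[1]) / width)) + 1L)
  } else {
    l <- as.integer(floor((x - rng[1]) / params$bin_value)) + 1L
    G <- max(l)
    lev[sel] <- l
  }
  list(levels = lev, n_levels = G, degenerate = degenerate)
}

#' Shape features (14) of a binary mask
#'
#' Mesh volume and surface area come from a marching-tetrahedra surface of
#' the lightly smoothed mask (iso-level 0.5); axis lengths derive from the
#' principal components of the foreground voxel coordinates. Shape features
#' depend only on the mask and spacing, never on intensities.
#'
#' @param mask a `binary_mask`.
#' @param spacing optional spacing override (mm), default the mask's.
#' @return Named numeric vector of 14 features (volumes in mm^3, areas in
#'   mm^2, lengths in mm).
#' @export
shape_features <- function(mask, spacing = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (is.null(spacing)) spacing <- mask$spacing
  sel <- mask_logical(mask)
  if (!any(sel)) stop("empty mask")
  d <- dim(mask$values)
  n_vox <- sum(sel)
  vv <- prod(spacing)
  # Crop to the mask's bounding box (meshing cost scales with the box, and
  # volume/area are unaffected), pad by one voxel so surfaces close, then
  # smooth lightly so the mesh is not voxel-jagged.
  idx0 <- which(sel, arr.ind = TRUE)
  lo <- apply(idx0, 2, min)
  hi <- apply(idx0, 2, max)
  cropped <- sel[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  cd <- dim(cropped)
  pd <- cd + 6L  # 3-voxel pad fully contains the smoothing kernel support
  padded <- array(0, dim = pd)
  padded[4:(cd[1] + 3), 4:(cd[2] + 3), 4:(cd[3] + 3)] <- as.double(cropped)
  sm <- array(cpp_gaussian_smooth3(as.numeric(padded), pd, rep(0.6, 3)),
              dim = pd)
  if (max(sm) < 0.5) sm <- padded  # tiny masks: march the binary lattice
  va <- cpp_mesh_volume_area(as.numeric(sm), pd, spacing, 0.5)
  mesh_vol <- va[1]
  area <- va[2]
  if (area <= 0) {  # degenerate fallback: voxel-face surface
    mesh_vol <- n_vox * vv
    area <- 6 * vv^(2 / 3) * n_vox
  }
  diam <- cpp_max_diameters(sel, d, spacing)
  idx <- which(sel, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, spacing, "*")
  if (nrow(pts) > 1) {
    cv <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  c(shape_MeshVolume = mesh_vol,
    shape_VoxelVolume = n_vox * vv,
    shape_SurfaceArea = area,
    shape_SurfaceVolumeRatio = area / mesh_vol,
    shape_Sphericity = (36 * pi * mesh_vol^2)^(1 / 3) / area,
    shape_Maximum3DDiameter = diam[1],
    shape_Maximum2DDiameterSlice = diam[2],
    shape_Maximum2DDiameterColumn = diam[3],
    shape_Maximum2DDiameterRow = diam[4],
    shape_MajorAxisLength = axes[1],
    shape_MinorAxisLength = axes[2],
    shape_LeastAxisLength = axes[3],
    shape_Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    shape_Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}

#' First-order statistical features (18)
#'
#' Computed on the raw in-mask intensities; entropy and uniformity use the
#' discretized histogram. Skewness and kurtosis use population moments
#' (kurtosis is not excess-corrected); both are defined as 0 for constant
#' regions.
#'
#' @inheritParams discretize
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(volume, mask, params = feature_params()) {
  sel <- mask_logical(mask)
  if (!any(sel)) stop("empty mask")
  x <- volume$values[sel]
  n <- length(x)
  vv <- prod(volume$spacing)
  cshift <- params$energy_shift
  disc <- discretize(volume, mask, params)
  p <- tabulate(disc$levels[sel], nbins = disc$n_levels) / n
  p_pos <- p[p > 0]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  robust <- x[x >= q[1] & x <= q[5]]
  c(firstorder_Energy = sum((x + cshift)^2),
    firstorder_TotalEnergy = vv * sum((x + cshift)^2),
    firstorder_Entropy = -sum(p_pos * log2(p_pos)),
    firstorder_Minimum = min(x),
    firstorder_Percentile10 = q[1],
    firstorder_Percentile90 = q[5],
    firstorder_Maximum = max(x),
    firstorder_Mean = mu,
    firstorder_Median = q[3],
    firstorder_InterquartileRange = q[4] - q[2],
    firstorder_Range = max(x) - min(x),
    firstorder_MeanAbsoluteDeviation = mean(abs(x - mu)),
    firstorder_RobustMeanAbsoluteDeviation =
      mean(abs(robust - mean(robust))),
    firstorder_RootMeanSquared = sqrt(mean((x + cshift)^2)),
    firstorder_Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    firstorder_Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2))
}

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' GLCM texture features (24)
#'
#' Built from the symmetric gray-level co-occurrence matrix aggregated
#' (summed, then normalized) over the 13 unique 3D directions at distance
#' 1. For a single-level region the correlation-type features take their
#' documented degenerate values (Correlation = 1, Imc1 = 0, Imc2 = 0,
#' MCC = 1) and the result carries attribute `degenerate = TRUE`.
#'
#' @param levels integer level array from [discretize()] (0 outside mask).
#' @param mask a `binary_mask`.
#' @param n_levels number of gray levels G.
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(levels, mask, n_levels) {
  sel <- mask_logical(mask)
  G <- n_levels
  P <- cpp_glcm(as.integer(levels), sel, dim(mask$values), G)
  tot <- sum(P)
  if (tot == 0) stop("no co-occurring voxel pairs inside the mask")
  p <- P / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p)  # == colSums by symmetry
  ux <- sum(seq_len(G) * px)
  sx2 <- sum((seq_len(G) - ux)^2 * px)
  # Difference distribution over k = |i-j| in 0..G-1.
  kdiff <- abs(i - j)
  pdiff <- vapply(0:(G - 1), function(k) sum(p[kdiff == k]), numeric(1))
  ksum <- i + j
  psum <- vapply(2:(2 * G), function(k) sum(p[ksum == k]), numeric(1))
  da <- sum((0:(G - 1)) * pdiff)
  hxy <- entropy2(p)
  pxy_prod <- outer(px, px)
  hxy1 <- -sum(p[pxy_prod > 0] * log2(pxy_prod[pxy_prod > 0]))
  hxy2 <- entropy2(pxy_prod)
  hx <- entropy2(px)
  degenerate <- G == 1 || sx2 <= 0
  corr <- if (degenerate) 1 else
    (sum(p * i * j) - ux^2) / sx2
  imc1 <- if (degenerate || hx == 0) 0 else (hxy - hxy1) / hx
  imc2 <- if (degenerate) 0 else sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  mcc <- if (degenerate) 1 else {
    Q <- matrix(0, G, G)
    pos <- px > 0
    pk <- p
    # Q(a,b) = sum_k p(a,k) p(b,k) / (px(a) px(k))
    W <- sweep(pk, 2, ifelse(pos, px, 1), "/")  # p(b,k)/px(k) in cols
    Q <- sweep(pk %*% t(W), 1, ifelse(pos, px, 1), "/")
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) > 1 && ev[2] > 0) sqrt(ev[2]) else 0
  }
  out <- c(
    glcm_Autocorrelation = sum(p * i * j),
    glcm_JointAverage = ux,
    glcm_ClusterProminence = sum((i + j - 2 * ux)^4 * p),
    glcm_ClusterShade = sum((i + j - 2 * ux)^3 * p),
    glcm_ClusterTendency = sum((i + j - 2 * ux)^2 * p),
    glcm_Contrast = sum((i - j)^2 * p),
    glcm_Correlation = corr,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = entropy2(pdiff),
    glcm_DifferenceVariance = sum(((0:(G - 1)) - da)^2 * pdiff),
    glcm_Id = sum(p / (1 + kdiff)),
    glcm_Idm = sum(p / (1 + kdiff^2)),
    glcm_Idmn = sum(p / (1 + kdiff^2 / G^2)),
    glcm_Idn = sum(p / (1 + kdiff / G)),
    glcm_InverseVariance = sum(p[kdiff > 0] / kdiff[kdiff > 0]^2),
    glcm_JointEnergy = sum(p^2),
    glcm_JointEntropy = hxy,
    glcm_Imc1 = imc1,
    glcm_Imc2 = imc2,
    glcm_MCC = mcc,
    glcm_MaximumProbability = max(p),
    glcm_SumAverage = sum((2:(2 * G)) * psum),
    glcm_SumEntropy = entropy2(psum),
    glcm_SumSquares = sum((i - ux)^2 * p))
  attr(out, "degenerate") <- degenerate
  out
}

#' GLRLM run-length features (16)
#'
#' Run counting over the 13 unique 3D directions on the direction-summed
#' run-length matrix. Run percentage is normalized by the number of voxels
#' times the 13 directions, so it lies in (0, 1].
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(levels, mask, n_levels) {
  sel <- mask_logical(mask)
  if (!any(sel)) stop("empty mask")
  G <- n_levels
  R <- cpp_glrlm(as.integer(levels), sel, dim(mask$values), G)
  maxr <- max(which(colSums(R) > 0), 1L)
  R <- R[, seq_len(maxr), drop = FALSE]
  nr <- sum(R)
  p <- R / nr
  g <- row(p); r <- col(p)
  pg <- rowSums(p)
  pr <- colSums(p)
  mug <- sum(seq_len(G) * pg)
  mur <- sum(seq_len(maxr) * pr)
  np <- sum(sel)
  c(glrlm_ShortRunEmphasis = sum(p / r^2),
    glrlm_LongRunEmphasis = sum(p * r^2),
    glrlm_GrayLevelNonUniformity = sum(rowSums(R)^2) / nr,
    glrlm_GrayLevelNonUniformityNormalized = sum(pg^2),
    glrlm_RunLengthNonUniformity = sum(colSums(R)^2) / nr,
    glrlm_RunLengthNonUniformityNormalized = sum(pr^2),
    glrlm_RunPercentage = nr / (np * 13),
    glrlm_GrayLevelVariance = sum((seq_len(G) - mug)^2 * pg),
    glrlm_RunVariance = sum((seq_len(maxr) - mur)^2 * pr),
    glrlm_RunEntropy = entropy2(p),
    glrlm_LowGrayLevelRunEmphasis = sum(pg / seq_len(G)^2),
    glrlm_HighGrayLevelRunEmphasis = sum(pg * seq_len(G)^2),
    glrlm_ShortRunLowGrayLevelEmphasis = sum(p / (g^2 * r^2)),
    glrlm_ShortRunHighGrayLevelEmphasis = sum(p * g^2 / r^2),
    glrlm_LongRunLowGrayLevelEmphasis = sum(p * r^2 / g^2),
    glrlm_LongRunHighGrayLevelEmphasis = sum(p * g^2 * r^2))
}

#' GLSZM size-zone features (16)
#'
#' Zones are 26-connected components of equal gray level inside the mask;
#' zone sizes partition the mask.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(levels, mask, n_levels) {
  sel <- mask_logical(mask)
  if (!any(sel)) stop("empty mask")
  zones <- cpp_glszm_zones(as.integer(levels), sel, dim(mask$values))
  G <- n_levels
  sizes <- zones[, 2]
  levs <- zones[, 1]
  maxs <- max(sizes)
  Z <- matrix(0, G, maxs)
  for (k in seq_along(sizes)) Z[levs[k], sizes[k]] <- Z[levs[k], sizes[k]] + 1
  nz <- sum(Z)
  p <- Z / nz
  g <- row(p); s <- col(p)
  pg <- rowSums(p)
  ps <- colSums(p)
  mug <- sum(seq_len(G) * pg)
  mus <- sum(seq_len(maxs) * ps)
  np <- sum(sel)
  c(glszm_SmallAreaEmphasis = sum(p / s^2),
    glszm_LargeAreaEmphasis = sum(p * s^2),
    glszm_GrayLevelNonUniformity = sum(rowSums(Z)^2) / nz,
    glszm_GrayLevelNonUniformityNormalized = sum(pg^2),
    glszm_SizeZoneNonUniformity = sum(colSums(Z)^2) / nz,
    glszm_SizeZoneNonUniformityNormalized = sum(ps^2),
    glszm_ZonePercentage = nz / np,
    glszm_GrayLevelVariance = sum((seq_len(G) - mug)^2 * pg),
    glszm_ZoneVariance = sum((seq_len(maxs) - mus)^2 * ps),
    glszm_ZoneEntropy = entropy2(p),
    glszm_LowGrayLevelZoneEmphasis = sum(pg / seq_len(G)^2),
    glszm_HighGrayLevelZoneEmphasis = sum(pg * seq_len(G)^2),
    glszm_SmallAreaLowGrayLevelEmphasis = sum(p / (g^2 * s^2)),
    glszm_SmallAreaHighGrayLevelEmphasis = sum(p * g^2 / s^2),
    glszm_LargeAreaLowGrayLevelEmphasis = sum(p * s^2 / g^2),
    glszm_LargeAreaHighGrayLevelEmphasis = sum(p * g^2 * s^2))
}

#' GLDM dependence features (14)
#'
#' A 26-neighbour is "dependent" when its gray level differs from the
#' centre by at most `alpha`. The dependence size used in the feature
#' formulas is the dependent-neighbour count plus one (the centre), so it
#' is always at least 1.
#'
#' @inheritParams glcm_features
#' @param alpha dependence tolerance (gray levels).
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(levels, mask, n_levels, alpha = 0) {
  sel <- mask_logical(mask)
  if (!any(sel)) stop("empty mask")
  G <- n_levels
  P <- cpp_gldm(as.integer(levels), sel, dim(mask$values), G, alpha)
  # Column d+1 holds dependence count d; formulas use size j = d + 1.
  maxd <- max(which(colSums(P) > 0))
  P <- P[, seq_len(maxd), drop = FALSE]
  nz <- sum(P)
  p <- P / nz
  g <- row(p)
  jj <- col(p)  # dependence size (count + 1)
  pg <- rowSums(p)
  pj <- colSums(p)
  mug <- sum(seq_len(G) * pg)
  muj <- sum(seq_len(maxd) * pj)
  c(gldm_SmallDependenceEmphasis = sum(p / jj^2),
    gldm_LargeDependenceEmphasis = sum(p * jj^2),
    gldm_GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    gldm_DependenceNonUniformity = sum(colSums(P)^2) / nz,
    gldm_DependenceNonUniformityNormalized = sum(pj^2),
    gldm_GrayLevelVariance = sum((seq_len(G) - mug)^2 * pg),
    gldm_DependenceVariance = sum((seq_len(maxd) - muj)^2 * pj),
    gldm_DependenceEntropy = entropy2(p),
    gldm_LowGrayLevelEmphasis = sum(pg / seq_len(G)^2),
    gldm_HighGrayLevelEmphasis = sum(pg * seq_len(G)^2),
    gldm_SmallDependenceLowGrayLevelEmphasis = sum(p / (g^2 * jj^2)),
    gldm_SmallDependenceHighGrayLevelEmphasis = sum(p * g^2 / jj^2),
    gldm_LargeDependenceLowGrayLevelEmphasis = sum(p * jj^2 / g^2),
    gldm_LargeDependenceHighGrayLevelEmphasis = sum(p * g^2 * jj^2))
}

#' Extract the full 102-feature vector for one ROI
#'
#' Runs all six families (shape, first-order, GLCM, GLRLM, GLSZM, GLDM) on
#' a volume/mask pair and returns the named 102-vector in registry order.
#' Deterministic: the same input always yields the bit-identical vector.
#'
#' @inheritParams discretize
#' @return Named numeric vector of exactly 102 finite values.
#' @export
extract_all_features <- function(volume, mask, params = feature_params()) {
  stopifnot(is_image_volume(volume), inherits(mask, "binary_mask"))
  stopifnot_same_lattice(volume, mask)
  run <- function(fam, expr) {
    tryCatch(expr, error = function(e)
      stop("feature family '", fam, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  disc <- run("discretize", discretize(volume, mask, params))
  out <- c(
    run("shape", shape_features(mask)),
    run("firstorder", first_order_features(volume, mask, params)),
    run("glcm", glcm_features(disc$levels, mask, disc$n_levels)),
    run("glrlm", glrlm_features(disc$levels, mask, disc$n_levels)),
    run("glszm", glszm_features(disc$levels, mask, disc$n_levels)),
    run("gldm", gldm_features(disc$levels, mask, disc$n_levels,
                              params$gldm_alpha)))
  stopifnot(identical(names(out), feature_names()))
  if (any(!is.finite(out)))
    stop("non-finite feature value(s): ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}
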