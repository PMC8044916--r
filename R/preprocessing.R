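#' Simplified multiplicative bias-field correction
#'
#' Estimates a smooth multiplicative intensity inhomogeneity field as a
#' low-order polynomial in the log domain: the log image is regressed on a
#' tensor polynomial basis over the foreground and the fitted surface,
#' exponentiated and normalized to unit mean over the foreground, is
#' divided out. Because the fit is a linear projection, the correction is
#' idempotent: a second pass finds an essentially flat field. This is a
#' deliberately simple smooth-field estimator for the slowly varying
#' coil-profile artifact; it is not a histogram-sharpening N4
#' implementation, and it will absorb genuine anatomy whose scale reaches
#' the polynomial's (see the methods vignette).
#'
#' @param volume an `image_volume`. Non-positive intensities are shifted
#'   up before the log transform and the shift is undone afterwards.
#' @param smoothness spatial scale of the field in mm (default 15); the
#'   polynomial degree is chosen as roughly half the volume extent divided
#'   by this scale (capped at 4), so coarser scales give lower degrees.
#' @param foreground optional `binary_mask`; default: voxels above 5% of
#'   the maximum intensity.
#' @return A list with `corrected` (`image_volume`), `bias_field`
#'   (`image_volume`, unit mean over foreground) and `degree` (the
#'   polynomial degree used).
#' @export
correct_bias <- function(volume, smoothness = 15, foreground = NULL) {
  stopifnot(is_image_volume(volume))
  v <- volume$values
  if (all(v == 0)) stop("all-zero volume")
  d <- dim(v)
  shift <- 0
  mn <- min(v)
  if (mn <= 0) shift <- -mn + 1e-3 * max(abs(v))
  if (is.null(foreground)) {
    fg <- as.numeric(v) > 0.05 * max(v)
  } else {
    fg <- as.numeric(mask_logical(foreground))
    fg <- fg > 0
  }
  if (!any(fg)) fg <- rep(TRUE, length(v))
  extent <- max(d * volume$spacing)
  degree <- max(1L, min(4L, as.integer(round(extent / (2 * smoothness)))))
  # Normalized coordinates in [-1, 1] per axis.
  nc <- function(n) if (n > 1) (2 * (seq_len(n) - 1) / (n - 1) - 1) else 0
  cx <- rep(nc(d[1]), times = d[2] * d[3])
  cy <- rep(rep(nc(d[2]), each = d[1]), times = d[3])
  cz <- rep(nc(d[3]), each = d[1] * d[2])
  basis <- list(rep(1, length(cx)))
  for (i in 0:degree) for (j in 0:(degree - i)) for (k in 0:(degree - i - j))
    if (i + j + k > 0)
      basis[[length(basis) + 1]] <- cx^i * cy^j * cz^k
  B <- do.call(cbind, basis)
  lv <- log(as.numeric(v) + shift)
  fit <- stats::lm.fit(B[fg, , drop = FALSE], lv[fg])
  pred <- as.numeric(B %*% ifelse(is.na(fit$coefficients), 0,
                                  fit$coefficients))
  field <- exp(pred - mean(pred[fg]))
  field <- field / mean(field[fg])
  field <- array(field, dim = d)
  corrected <- (v + shift) / field - shift
  list(corrected = image_volume(corrected, volume$spacing, volume$origin),
       bias_field = image_volume(field, volume$spacing, volume$origin),
       degree = degree)
}

#' Select the peak-enhancement frame and build the subtraction image
#'
#' Finds the postcontrast frame with maximal mean intensity over the
#' evaluation region (typically around the third postcontrast series, where
#' enhancement usually peaks) and subtracts the precontrast frame from it.
#' Ties are broken toward the earliest such frame.
#'
#' @param series a `dce_series` (frame 1 = precontrast S0).
#' @param region optional `binary_mask` restricting the mean-intensity
#'   evaluation; default: whole volume.
#' @return A list with `frame_index` (index into the series, >= 2) and
#'   `subtraction` (`image_volume`, selected frame minus S0).
#' @export
select_enhancement_frame <- function(series, region = NULL) {
  stopifnot(inherits(series, "dce_series"))
  nf <- length(series$frames)
  if (nf < 2) stop("series must contain at least one postcontrast frame")
  sel <- if (is.null(region)) NULL else mask_logical(region)
  means <- vapply(2:nf, function(i) {
    v <- series$frames[[i]]$values
    if (is.null(sel)) mean(v) else mean(v[sel])
  }, numeric(1))
  idx <- which.max(means) + 1L   # which.max takes the first maximum
  s0 <- series$frames[[1L]]
  frame <- series$frames[[idx]]
  sub <- image_volume(frame$values - s0$values, s0$spacing, s0$origin)
  list(frame_index = idx, subtraction = sub)
}

#' Spatial fuzzy C-means configuration
#'
#' @param n_clusters number of intensity clusters (default 3: tumor,
#'   parenchyma, background).
#' @param fuzzifier fuzziness exponent m > 1 (default 2).
#' @param spatial_weight exponent q of the neighbourhood membership term;
#'   0 reduces to plain FCM.
#' @param neighborhood_radius radius (voxels) of the cubic spatial window
#'   (1 = 3x3x3).
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the maximum membership change
#'   (1e-3 is ample for a 0.5-threshold mask).
#' @param seed reserved for stochastic center initialization; the default
#'   initializer (intensity quantiles) is deterministic.
#' @return An `fcm_config` list.
#' @export
fcm_config <- function(n_clusters = 3L, fuzzifier = 2, spatial_weight = 1,
                       neighborhood_radius = 1L, max_iter = 100L,
                       tol = 1e-3, seed = 1L) {
  stopifnot(n_clusters >= 2, fuzzifier > 1, tol > 0,
            neighborhood_radius >= 1)
  structure(list(n_clusters = as.integer(n_clusters), fuzzifier = fuzzifier,
                 spatial_weight = spatial_weight,
                 neighborhood_radius = as.integer(neighborhood_radius),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "fcm_config")
}

# Plain FCM membership update for given centers; x is the intensity vector.
fcm_memberships <- function(x, centers, m) {
  w <- matrix(0, length(x), length(centers))
  p <- -1 / (m - 1)
  for (k in seq_along(centers))
    w[, k] <- pmax((x - centers[k])^2, 1e-300)^p
  w / rowSums(w)
}

#' Tumor segmentation by spatial fuzzy C-means
#'
#' Clusters voxel intensities with fuzzy C-means whose memberships are
#' spatially regularized: at each iteration the membership of a voxel is
#' multiplied by the q-th power of the mean membership in its cubic
#' neighbourhood and renormalized (q = `spatial_weight`; q = 0 gives plain
#' FCM). The tumor cluster is the one with the highest center; the mask is
#' the set of voxels whose tumor membership exceeds 0.5, restricted to the
#' 26-connected component containing `seed_point`.
#'
#' @param volume an `image_volume` (typically the subtraction image).
#' @param config an [fcm_config()].
#' @param seed_point integer length-3 voxel index (1-based) inside the
#'   tumor; default: the brightest voxel after light smoothing.
#' @param bbox optional region of interest: either a 3 x 2 matrix of
#'   1-based voxel index ranges (rows = axes, columns = lo/hi) restricting
#'   the clustering, or `"auto"` to take a margin around the brightest
#'   region. The region must still contain both tumor and background.
#' @return A `binary_mask`; attributes `memberships` (n x c matrix),
#'   `centers`, `iterations`, `objective_trace`.
#' @export
segment_tumor_fcm <- function(volume, config = fcm_config(),
                              seed_point = NULL, bbox = NULL) {
  stopifnot(is_image_volume(volume))
  if (!is.null(bbox)) {
    full_dims <- dim(volume$values)
    if (identical(bbox, "auto")) {
      # locate the enhancing region on a 2x-decimated copy (4x cheaper)
      dec <- volume$values[seq(1, full_dims[1], 2), seq(1, full_dims[2], 2),
                           seq(1, full_dims[3], 2), drop = FALSE]
      sm0 <- smooth_array(dec, mean(volume$spacing), 2 * volume$spacing)
      hot <- which(sm0 >= min(sm0) + 0.5 * (max(sm0) - min(sm0)),
                   arr.ind = TRUE)
      bbox <- 2L * t(apply(hot, 2, range)) - 1L
      bbox[, 1] <- pmax(1L, bbox[, 1] - 8L)
      bbox[, 2] <- pmin(full_dims, bbox[, 2] + 9L)
    }
    bbox <- matrix(as.integer(bbox), 3, 2)
    sub <- volume$values[bbox[1, 1]:bbox[1, 2], bbox[2, 1]:bbox[2, 2],
                         bbox[3, 1]:bbox[3, 2], drop = FALSE]
    seed_sub <- if (is.null(seed_point)) NULL else
      as.integer(seed_point - bbox[, 1] + 1L)
    inner <- segment_tumor_fcm(image_volume(sub, volume$spacing,
                                            volume$origin),
                               config, seed_sub, bbox = NULL)
    out_arr <- array(0, dim = full_dims)
    out_arr[bbox[1, 1]:bbox[1, 2], bbox[2, 1]:bbox[2, 2],
            bbox[3, 1]:bbox[3, 2]] <- inner$values
    out <- binary_mask(out_arr, volume$spacing, volume$origin,
                       require_foreground = FALSE)
    for (a in c("memberships", "centers", "iterations", "objective_trace"))
      attr(out, a) <- attr(inner, a)
    return(out)
  }
  dims <- dim(volume$values)
  x <- as.numeric(volume$values)
  if (max(x) - min(x) < 1e-12)
    stop("degenerate (constant) input: nothing to cluster")
  c_ <- config$n_clusters
  m <- config$fuzzifier
  # Deterministic initialization: evenly spaced intensity quantiles.
  centers <- as.numeric(quantile(x, probs = seq(0.05, 0.95,
                                                length.out = c_)))
  if (any(duplicated(centers)))
    centers <- centers + seq_len(c_) * 1e-6 * max(abs(centers) + 1)
  u <- fcm_memberships(x, centers, m)
  obj_trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    um <- u^m
    centers <- colSums(um * x) / colSums(um)
    u_new <- fcm_memberships(x, centers, m)
    if (config$spatial_weight > 0) {
      h <- u_new
      for (k in seq_len(c_))
        h[, k] <- cpp_box_mean3(u_new[, k], dims,
                                config$neighborhood_radius)
      u_new <- u_new * h^config$spatial_weight
      u_new <- u_new / rowSums(u_new)
    }
    d2 <- outer(x, centers, function(a, b) (a - b)^2)
    obj_trace <- c(obj_trace, sum(u_new^m * d2))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < config$tol) break
    if (iter >= config$max_iter) {
      stop("FCM did not converge after ", config$max_iter,
           " iterations (last membership change ", signif(delta, 3),
           "); objective trace: ",
           paste(signif(tail(obj_trace, 5), 4), collapse = ", "))
    }
  }
  tumor_k <- which.max(centers)
  raw <- u[, tumor_k] > 0.5
  if (!any(raw)) stop("no voxel reached tumor membership > 0.5")
  if (is.null(seed_point)) {
    sm <- smooth_array(volume$values, 2 * mean(volume$spacing),
                       volume$spacing)
    seed_idx <- which.max(as.numeric(sm) * raw)
  } else {
    seed_idx <- seed_point[1] + dims[1] * (seed_point[2] - 1) +
      dims[1] * dims[2] * (seed_point[3] - 1)
  }
  comp <- cpp_connected_component(raw, dims, as.integer(seed_idx - 1L))
  mask <- binary_mask(array(as.double(comp), dim = dims), volume$spacing,
                      volume$origin, require_foreground = FALSE)
  if (sum(mask$values) == 0)
    stop("seed point does not lie in a tumor-membership component")
  attr(mask, "memberships") <- u
  attr(mask, "centers") <- centers
  attr(mask, "iterations") <- iter
  attr(mask, "objective_trace") <- obj_trace
  mask
}
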