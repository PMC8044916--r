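#' Registration configuration
#'
#' Settings for the multi-resolution Gaussian-regularized demons algorithm.
#' The update field is smoothed with `sigma_update` (fluid-like
#' regularization) and the accumulated field with `sigma_total`
#' (diffusion-like regularization), both in mm.
#'
#' @param shrink_factors integer vector, coarse-to-fine downsampling factors
#'   (one pyramid level per entry). The default stops at half resolution —
#'   with presmoothed noisy inputs the native-resolution level adds cost
#'   but no accuracy — and the field is upsampled back to the native
#'   lattice.
#' @param iterations iterations per level, same length as `shrink_factors`.
#' @param sigma_update Gaussian smoothing of each demons update, mm.
#' @param sigma_total Gaussian smoothing of the accumulated field, mm.
#' @param step_scale maximum update magnitude per iteration, in voxels.
#' @param tol relative improvement of mean squared difference below which a
#'   level stops early.
#' @param intensity_match `"gain"` (default) linearly rescales the
#'   follow-up intensities so its 50th-99.5th percentile range matches the
#'   baseline's before the demons iterations; `"none"` disables this.
#'   Longitudinal DCE series violate intensity constancy — enhancement
#'   drops after treatment — and the demons force assumes it.
#' @param presmooth Gaussian presmoothing (mm) of both images before
#'   registration; suppresses voxel noise that otherwise drives spurious
#'   forces. 0 disables.
#' @return A `registration_config` list.
#' @export
registration_config <- function(shrink_factors = c(4L, 2L),
                                iterations = c(50L, 30L),
                                sigma_update = 1.5, sigma_total = 1.5,
                                step_scale = 1.0, tol = 1e-4,
                                intensity_match = c("gain", "none"),
                                presmooth = 2.0) {
  intensity_match <- match.arg(intensity_match)
  if (length(shrink_factors) < 1L) stop("need at least one pyramid level")
  if (length(iterations) != length(shrink_factors))
    stop("`iterations` must match `shrink_factors`")
  if (sigma_update < 0 || sigma_total < 0)
    stop("smoothing scales must be >= 0")
  structure(list(shrink_factors = as.integer(shrink_factors),
                 iterations = as.integer(iterations),
                 sigma_update = sigma_update, sigma_total = sigma_total,
                 step_scale = step_scale, tol = tol,
                 intensity_match = intensity_match, presmooth = presmooth),
            class = "registration_config")
}

# Pull-back sample of `arr` (3D) at voxel coords displaced by the field
# (field in mm on the same lattice), returning a 3D array.
warp_array <- function(arr, field_comp, spacing, order = 1L) {
  d <- dim(arr)
  n <- prod(d)
  base <- cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
                rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
                rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  u <- matrix(field_comp, nrow = n, ncol = 3)
  coords <- base + sweep(u, 2, spacing, "/")
  array(cpp_interp3(as.numeric(arr), d, coords, as.integer(order)), dim = d)
}

#' Warp a volume through a displacement field
#'
#' Pull-back interpolation: the output at baseline voxel x samples the input
#' at x + u(x). Warping a follow-up image through the field estimated by
#' [register_deformable()] aligns it onto the baseline lattice.
#'
#' @param volume an `image_volume` (or `binary_mask`, warped with nearest
#'   neighbour).
#' @param field a `displacement_field` on the same lattice.
#' @param order interpolation order, 0 or 1.
#' @return The warped `image_volume`.
#' @export
warp_volume <- function(volume, field, order = 1L) {
  stopifnot(is_image_volume(volume), inherits(field, "displacement_field"))
  if (!identical(dim(volume$values), dim(field$components)[1:3]))
    stop("volume and field must share a lattice")
  is_mask <- inherits(volume, "binary_mask")
  if (is_mask) order <- 0L
  arr <- warp_array(volume$values, field$components, volume$spacing, order)
  if (is_mask) {
    binary_mask(arr, volume$spacing, volume$origin, require_foreground = FALSE)
  } else {
    image_volume(arr, volume$spacing, volume$origin)
  }
}

smooth_field_components <- function(comp, sigma_mm, spacing) {
  if (sigma_mm <= 0) return(comp)
  d <- dim(comp)[1:3]
  for (k in 1:3)
    comp[, , , k] <- array(
      cpp_gaussian_smooth3(as.numeric(comp[, , , k]), d, sigma_mm / spacing),
      dim = d)
  comp
}

# One pyramid level of Gaussian-regularized demons with symmetric forces
# (mean of fixed- and warped-image gradients) and an additive update scheme.
# The best field seen (lowest mean squared difference) is returned, with a
# patience-based stop once the metric no longer improves.
demons_level <- function(fixed, moving, spacing, field, iters, sigma_update,
                         sigma_total, step_scale, tol, patience = 4L) {
  d <- dim(fixed)
  fixed_v <- as.numeric(fixed)
  grad_f <- cpp_gradient3(fixed_v, d, spacing)  # n x 3, mm^-1
  # Thirion's intensity normalization scale: mean squared spacing.
  kappa <- mean(spacing)^2
  mse_trace <- numeric(0)
  best_mse <- Inf
  best_field <- field
  stall <- 0L
  for (it in seq_len(iters)) {
    warped <- warp_array(moving, field, spacing)
    diffv <- as.numeric(warped) - fixed_v
    mse <- mean(diffv^2)
    mse_trace <- c(mse_trace, mse)
    if (mse < best_mse * (1 - tol)) {
      best_mse <- mse
      best_field <- field
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
    grad <- 0.5 * (grad_f + cpp_gradient3(as.numeric(warped), d, spacing))
    denom <- rowSums(grad^2) + diffv^2 / kappa
    fac <- ifelse(denom > 1e-12, -diffv / denom, 0)
    upd <- grad * fac                       # n x 3, mm
    # Cap each voxel's update at step_scale voxels.
    mag <- sqrt(rowSums(sweep(upd, 2, spacing, "/")^2))
    over <- mag > step_scale
    if (any(over)) upd[over, ] <- upd[over, ] * (step_scale / mag[over])
    upd <- array(upd, dim = c(d, 3))
    upd <- smooth_field_components(upd, sigma_update, spacing)
    field <- field + upd
    field <- smooth_field_components(field, sigma_total, spacing)
  }
  list(field = best_field, mse_trace = mse_trace, best_mse = best_mse)
}

#' Deformable registration of a follow-up image to a baseline image
#'
#' Multi-resolution Gaussian-regularized demons. The returned displacement
#' field lives on the baseline lattice and maps baseline coordinates to
#' follow-up coordinates, so warping the follow-up image through it
#' reproduces the baseline anatomy and the Jacobian determinant is below 1
#' where tissue contracted.
#'
#' @param baseline,followup `image_volume`s on the same lattice and spacing.
#' @param config a [registration_config()].
#' @return A list with `field` (`displacement_field`), `warped`
#'   (`image_volume`, the follow-up aligned to baseline), and `report`
#'   (per-level mean-squared-difference traces, final metric, iteration
#'   counts, and an `improved` flag per level).
#' @export
register_deformable <- function(baseline, followup,
                                config = registration_config()) {
  stopifnot(is_image_volume(baseline), is_image_volume(followup))
  stopifnot_same_lattice(baseline, followup)
  spacing <- baseline$spacing
  base_vals <- baseline$values
  fup_vals <- followup$values
  if (config$intensity_match == "gain") {
    # Gain from the bright (enhancing) foreground of each image, so the
    # estimate is insensitive to how much of the volume the tumor occupies
    # at each time point; offset from the overall (background) median.
    bg_b <- median(base_vals)
    bg_f <- median(fup_vals)
    ref_b <- quantile(base_vals, 0.999, names = FALSE)
    ref_f <- quantile(fup_vals, 0.999, names = FALSE)
    fg_b <- base_vals > bg_b + 0.5 * (ref_b - bg_b)
    fg_f <- fup_vals > bg_f + 0.5 * (ref_f - bg_f)
    if (any(fg_b) && any(fg_f)) {
      gain <- (median(base_vals[fg_b]) - bg_b) /
        max(median(fup_vals[fg_f]) - bg_f, 1e-12)
      fup_vals <- (fup_vals - bg_f) * gain + bg_b
    }
  }
  if (config$presmooth > 0) {
    base_vals <- smooth_array(base_vals, config$presmooth, spacing)
    fup_vals <- smooth_array(fup_vals, config$presmooth, spacing)
  }
  # The demons force balances image gradients against intensity residuals,
  # so both images are scaled to a common unit intensity range internally.
  iscale <- diff(range(base_vals))
  if (iscale <= 0) iscale <- 1
  baseline_n <- image_volume((base_vals - min(base_vals)) / iscale,
                             spacing, baseline$origin)
  followup_n <- image_volume((fup_vals - min(base_vals)) / iscale,
                             spacing, followup$origin)
  levels <- length(config$shrink_factors)
  field <- NULL
  report <- list(levels = list())
  for (l in seq_len(levels)) {
    s <- config$shrink_factors[l]
    if (s > 1) {
      fx <- resample_volume(baseline_n, spacing * s)
      mv <- resample_volume(followup_n, spacing * s)
    } else {
      fx <- baseline_n
      mv <- followup_n
    }
    d <- dim(fx$values)
    if (is.null(field)) {
      field <- array(0, dim = c(d, 3))
    } else {
      # Upsample the previous level's field (mm values interpolate directly).
      prev <- field
      field <- array(0, dim = c(d, 3))
      pd <- dim(prev)[1:3]
      gx <- (seq_len(d[1]) - 1) * fx$spacing[1] / (spacing[1] * config$shrink_factors[l - 1])
      gy <- (seq_len(d[2]) - 1) * fx$spacing[2] / (spacing[2] * config$shrink_factors[l - 1])
      gz <- (seq_len(d[3]) - 1) * fx$spacing[3] / (spacing[3] * config$shrink_factors[l - 1])
      coords <- cbind(rep(gx, times = d[2] * d[3]),
                      rep(rep(gy, each = d[1]), times = d[3]),
                      rep(gz, each = d[1] * d[2]))
      for (k in 1:3)
        field[, , , k] <- array(
          cpp_interp3(as.numeric(prev[, , , k]), pd, coords, 1L), dim = d)
    }
    res <- demons_level(fx$values, mv$values, fx$spacing, field,
                        config$iterations[l], config$sigma_update,
                        config$sigma_total, config$step_scale, config$tol)
    field <- res$field
    tr <- res$mse_trace
    report$levels[[l]] <- list(shrink = s, iterations = length(tr),
                               mse_first = tr[1], mse_last = res$best_mse,
                               improved = res$best_mse <= tr[1],
                               mse_trace = tr)
  }
  # If the last level was coarser than the native lattice, upsample the
  # field back to it so the returned field always lives on the baseline grid.
  d_full <- dim(baseline$values)
  if (!identical(dim(field)[1:3], d_full)) {
    prev <- field
    pd <- dim(prev)[1:3]
    s_last <- config$shrink_factors[levels]
    gx <- (seq_len(d_full[1]) - 1) / s_last
    gy <- (seq_len(d_full[2]) - 1) / s_last
    gz <- (seq_len(d_full[3]) - 1) / s_last
    coords <- cbind(rep(gx, times = d_full[2] * d_full[3]),
                    rep(rep(gy, each = d_full[1]), times = d_full[3]),
                    rep(gz, each = d_full[1] * d_full[2]))
    field <- array(0, dim = c(d_full, 3))
    for (k in 1:3)
      field[, , , k] <- array(
        cpp_interp3(as.numeric(prev[, , , k]), pd, coords, 1L), dim = d_full)
  }
  report$final_metric <- report$levels[[levels]]$mse_last
  report$converged_all_levels <-
    all(vapply(report$levels, function(x) x$improved, logical(1)))
  if (!report$converged_all_levels)
    warning("similarity metric failed to improve at one or more levels; ",
            "inputs may not overlap")
  fld <- displacement_field(field, spacing, baseline$origin)
  warped <- warp_volume(followup, fld)
  list(field = fld, warped = warped, report = report)
}

#' Jacobian determinant map of a displacement field
#'
#' Per voxel, the determinant of (I + grad u), with spatial gradients of the
#' mm-valued displacement taken by central differences scaled by the voxel
#' spacing. A value of 1 means local volume preservation, below 1 local
#' shrinkage and above 1 local expansion. Non-positive determinants indicate
#' a folded field; they are counted, reported via the `n_nonpositive`
#' attribute and a warning, and (optionally) clamped.
#'
#' @param field a `displacement_field`.
#' @param clamp_epsilon if not `NULL`, non-positive values are clamped to
#'   this small positive number so that downstream texture discretization
#'   stays defined. Default 1e-6.
#' @return An `image_volume` (unitless determinants) with attribute
#'   `n_nonpositive`.
#' @export
compute_jacobian_map <- function(field, clamp_epsilon = 1e-6) {
  stopifnot(inherits(field, "displacement_field"))
  comp <- field$components
  d <- dim(comp)[1:3]
  spacing <- field$spacing
  J <- vector("list", 9)  # d u_i / d x_j
  for (i in 1:3) {
    g <- cpp_gradient3(as.numeric(comp[, , , i]), d, spacing)
    for (j in 1:3) J[[(i - 1) * 3 + j]] <- g[, j]
  }
  a11 <- J[[1]] + 1; a12 <- J[[2]];     a13 <- J[[3]]
  a21 <- J[[4]];     a22 <- J[[5]] + 1; a23 <- J[[6]]
  a31 <- J[[7]];     a32 <- J[[8]];     a33 <- J[[9]] + 1
  det <- a11 * (a22 * a33 - a23 * a32) -
         a12 * (a21 * a33 - a23 * a31) +
         a13 * (a21 * a32 - a22 * a31)
  n_nonpos <- sum(det <= 0)
  if (n_nonpos > 0) {
    warning(n_nonpos, " voxel(s) with non-positive Jacobian (folded field)")
    if (!is.null(clamp_epsilon)) det[det <= 0] <- clamp_epsilon
  }
  out <- image_volume(array(det, dim = d), spacing, field$origin)
  attr(out, "n_nonpositive") <- n_nonpos
  out
}

#' Summarize a Jacobian map over a region of interest
#'
#' @param jacobian an `image_volume` from [compute_jacobian_map()].
#' @param roi a `binary_mask` on the same lattice.
#' @return A list with `mean`, `median`, `sd`, `n_voxels`, and
#'   `volume_ratio` (the ROI integral of the map divided by the ROI volume
#'   times the ROI volume ratio interpretation: the predicted
#'   follow-up/baseline volume ratio of the region).
#' @export
summarize_jacobian <- function(jacobian, roi) {
  stopifnot(is_image_volume(jacobian), inherits(roi, "binary_mask"))
  stopifnot_same_lattice(jacobian, roi)
  sel <- mask_logical(roi)
  if (!any(sel)) stop("empty ROI")
  v <- jacobian$values[sel]
  list(mean = mean(v), median = median(v), sd = sd(v),
       n_voxels = sum(sel), volume_ratio = mean(v))
}
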