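# Textured blob image used across the registration tests.
reg_blob <- function(n = 40, radius = 10, seed = 1) {
  withr::with_seed(seed, {
    cen <- rep((n - 1) / 2, 3)
    co <- as.matrix(expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1)))
    r2 <- rowSums(sweep(co, 2, cen, "-")^2)
    tex <- nactrad:::smooth_array(array(rnorm(n^3), c(n, n, n)), 3, c(1, 1, 1))
    tex <- tex / sd(tex) * 30
    vals <- array(ifelse(r2 <= radius^2, 150, 0), c(n, n, n)) +
      array(ifelse(r2 <= radius^2, tex, 0), c(n, n, n))
    list(volume = image_volume(vals), inside = array(r2 <= radius^2, c(n, n, n)),
         center = cen, coords = co)
  })
}

test_that("self-registration returns an essentially zero field", {
  b <- reg_blob(n = 32, radius = 9)
  reg <- register_deformable(b$volume, b$volume)
  mags <- sqrt(rowSums(matrix(reg$field$components, ncol = 3)^2))
  expect_lt(mean(mags), 0.1)
  expect_true(reg$report$converged_all_levels)
})

test_that("a known affine contraction is recovered within half a voxel", {
  b <- reg_blob(n = 48, radius = 12, seed = 2)
  s <- 0.8
  inv <- sweep(sweep(b$coords, 2, b$center, "-") / s, 2, b$center, "+")
  fup <- array(nactrad:::cpp_interp3(as.numeric(b$volume$values),
                                     dim(b$volume$values), inv, 1L),
               dim(b$volume$values))
  # noise-free phantom: full-resolution pyramid without presmoothing
  rc <- registration_config(shrink_factors = c(4L, 2L, 1L),
                            iterations = c(100L, 60L, 40L),
                            presmooth = 0, intensity_match = "none",
                            sigma_total = 0.5)
  reg <- register_deformable(b$volume, image_volume(fup), rc)
  tru <- sweep(b$coords, 2, b$center, "-") * (s - 1)
  est <- matrix(reg$field$components, ncol = 3)
  epe <- sqrt(rowSums((est - tru)^2))[b$inside]
  expect_lt(mean(epe), 0.5)
  jac <- suppressWarnings(compute_jacobian_map(reg$field))
  mean_jac <- mean(jac$values[b$inside])
  expect_lt(abs(mean_jac - s^3) / s^3, 0.15)
})

test_that("a known smooth residual field is recovered to r > 0.98", {
  cfg <- sim_config(dims = c(48L, 48L, 48L), radius_range = c(9, 11),
                    contraction_responder = c(mean = 1, sd = 0),
                    contraction_axis_sd = 0, residual_amplitude = 1,
                    residual_scale = 12, noise_sd = 0, bias_amplitude = 0,
                    het_reduction_responder = 0, enh_reduction_responder = 0)
  p <- generate_tumor_pair(cfg, responder = TRUE, seed = 15)
  sb <- select_enhancement_frame(p$baseline)$subtraction
  sf <- select_enhancement_frame(p$followup)$subtraction
  rc <- registration_config(shrink_factors = c(4L, 2L, 1L),
                            iterations = c(100L, 60L, 40L),
                            presmooth = 0, intensity_match = "none",
                            sigma_total = 0.5)
  reg <- register_deformable(sb, sf, rc)
  # correlation on the tumor interior: the sharp rim is excluded because
  # interpolating a step edge twice smears it regardless of the field
  er <- nactrad:::ellipsoid_mask(dim(sb$values), c(1, 1, 1),
                                 p$meta$center_mm, p$meta$radii_mm * 0.8)
  sel <- as.logical(er)
  expect_gt(cor(reg$warped$values[sel], sb$values[sel]), 0.98)
})

test_that("registration is deterministic given its configuration", {
  b <- reg_blob(n = 32, radius = 8, seed = 3)
  fup <- image_volume(b$volume$values[c(2:32, 32), , ])  # 1-voxel shift
  r1 <- register_deformable(b$volume, fup)
  r2 <- register_deformable(b$volume, fup)
  expect_identical(r1$field$components, r2$field$components)
})

test_that("the Jacobian map is exact on identity and affine fields", {
  d <- c(12, 12, 12)
  idf <- displacement_field(array(0, c(d, 3)))
  expect_equal(range(compute_jacobian_map(idf)$values), c(1, 1))
  cen <- (d - 1) / 2
  co <- as.matrix(expand.grid(x = 0:11, y = 0:11, z = 0:11))
  u <- sweep(co, 2, cen, "-") %*% diag(c(0.5, 0.5, 0.5) - 1)
  aff <- displacement_field(array(u, c(d, 3)))
  jac <- compute_jacobian_map(aff)
  expect_equal(max(abs(jac$values - 0.125)), 0, tolerance = 1e-12)
})

test_that("the Jacobian map matches a mapped-coordinate oracle", {
  withr::with_seed(44, {
    d <- c(14, 14, 14)
    comp <- array(0, c(d, 3))
    for (k in 1:3)
      comp[, , , k] <- nactrad:::smooth_array(array(rnorm(prod(d)), d), 2,
                                              c(1, 1, 1)) * 3
    fld <- displacement_field(comp)
    jac <- suppressWarnings(compute_jacobian_map(fld, clamp_epsilon = NULL))
    # oracle: differentiate the mapped coordinates phi(x) = x + u(x)
    phi <- comp
    for (k in 1:3) {
      ax <- array(0, d)
      idx <- slice.index(ax, k)
      phi[, , , k] <- comp[, , , k] + (idx - 1)
    }
    oracle <- array(NA_real_, d)
    for (x in 2:(d[1] - 1)) for (y in 2:(d[2] - 1)) for (z in 2:(d[3] - 1)) {
      J <- matrix(0, 3, 3)
      J[, 1] <- (phi[x + 1, y, z, ] - phi[x - 1, y, z, ]) / 2
      J[, 2] <- (phi[x, y + 1, z, ] - phi[x, y - 1, z, ]) / 2
      J[, 3] <- (phi[x, y, z + 1, ] - phi[x, y, z - 1, ]) / 2
      oracle[x, y, z] <- det(J)
    }
    sel <- !is.na(oracle)
    expect_lt(max(abs(jac$values[sel] - oracle[sel])), 1e-6)
  })
})

test_that("Jacobian of composed affine maps multiplies determinants", {
  d <- c(16, 16, 16)
  cen <- (d - 1) / 2
  co <- as.matrix(expand.grid(x = 0:15, y = 0:15, z = 0:15))
  sa <- c(0.9, 0.8, 0.85)
  sb <- c(0.95, 0.9, 1.05)
  phi1 <- sweep(sweep(co, 2, cen, "-") %*% diag(sa), 2, cen, "+")
  phi2 <- function(p) sweep(sweep(p, 2, cen, "-") %*% diag(sb), 2, cen, "+")
  ucomp <- phi2(phi1) - co
  jac <- compute_jacobian_map(displacement_field(array(ucomp, c(d, 3))))
  interior <- jac$values[5:12, 5:12, 5:12]
  expect_equal(max(abs(interior - prod(sa) * prod(sb))), 0, tolerance = 1e-10)
})

test_that("warping follows the field exactly on ramps and identity", {
  n <- 16
  ramp <- image_volume(array(rep(0:(n - 1), n * n), c(n, n, n)))
  zero <- displacement_field(array(0, c(n, n, n, 3)))
  expect_equal(warp_volume(ramp, zero)$values, ramp$values)
  tr <- displacement_field(array(rep(c(1, 0, 0), each = n^3), c(n, n, n, 3)))
  w <- warp_volume(ramp, tr)
  expect_lt(max(abs(w$values[1:(n - 2), , ] - ramp$values[2:(n - 1), , ])),
            1e-6)
})

test_that("warping a mask through an affine contraction scales its volume", {
  n <- 48
  m <- sphere_mask(n, 12)
  cen <- rep((n - 1) / 2, 3)
  co <- as.matrix(expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1)))
  s <- 0.8
  # pull-back through u(x) = (1/s - 1)(x - c) samples the mask at x/s:
  # the warped mask is the original scaled by s about the centre.
  u <- sweep(co, 2, cen, "-") * (1 / s - 1)
  fld <- displacement_field(array(u, c(n, n, n, 3)))
  w <- warp_volume(m, fld)
  ratio <- mask_volume_mm3(w) / mask_volume_mm3(m)
  expect_lt(abs(ratio - s^3) / s^3, 0.05)
})

test_that("the ROI integral of the Jacobian predicts the volume ratio", {
  cfg <- sim_config(dims = c(48L, 48L, 48L), radius_range = c(10, 12),
                    contraction_responder = c(mean = 0.85, sd = 0),
                    contraction_axis_sd = 0, residual_amplitude = 1,
                    residual_scale = 10, noise_sd = 0, bias_amplitude = 0)
  p <- generate_tumor_pair(cfg, responder = TRUE, seed = 23)
  jac <- compute_jacobian_map(p$true_field)
  pred <- summarize_jacobian(jac, p$baseline_mask)$volume_ratio
  obs <- mask_volume_mm3(p$followup_mask) / mask_volume_mm3(p$baseline_mask)
  expect_lt(abs(pred - obs) / obs, 0.10)
})

test_that("Jacobian summaries require a matching non-empty ROI", {
  d <- c(8, 8, 8)
  jac <- compute_jacobian_map(displacement_field(array(0, c(d, 3))))
  m <- binary_mask(array(rep(c(1, 0), each = 256), d))
  s <- summarize_jacobian(jac, m)
  expect_equal(s$mean, 1)
  expect_equal(s$sd, 0)
  expect_error(summarize_jacobian(jac,
    binary_mask(array(0, d), require_foreground = FALSE)), "empty")
})
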