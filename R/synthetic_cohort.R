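#' Simulation configuration for the synthetic NACT cohort
#'
#' Defines the study conditions the generator emulates: paired
#' baseline/early-follow-up DCE series of a single enhancing breast tumor
#' per patient, a ground-truth deformation (responders contract more
#' strongly), a class-dependent reduction of intensity heterogeneity and
#' enhancement after treatment, and clinical covariates with the observed
#' cohort proportions (114 patients, 38.6% responders, 61/114 in the
#' development arm, subtype mix 10/51/18/21%).
#'
#' @param n number of patients.
#' @param responder_fraction probability that a patient is a responder
#'   (Miller-Payne 4-5).
#' @param dev_fraction probability of assignment to the development arm.
#' @param dims lattice size of each frame.
#' @param spacing voxel spacing in mm.
#' @param radius_range tumor mean-radius range in mm (per-axis radii get a
#'   further 0.85-1.15 anisotropy factor).
#' @param contraction_responder,contraction_nonresponder mean and SD of the
#'   per-axis contraction factor for each class (responders shrink more).
#' @param contraction_axis_sd per-axis jitter of the contraction factor.
#' @param residual_amplitude amplitude (mm) of the smooth non-affine
#'   component of the ground-truth deformation; 0 disables it.
#' @param residual_scale length-scale (mm) of the residual field.
#' @param texture_sd standard deviation of the correlated Gaussian random
#'   field that models intra-tumor enhancement heterogeneity.
#' @param texture_scale length-scale (mm) of the texture field.
#' @param het_reduction_responder,het_reduction_nonresponder fraction by
#'   which the tumor texture deviations from the tumor mean are shrunk at
#'   follow-up (responders reduce heterogeneity more).
#' @param enh_reduction_responder,enh_reduction_nonresponder fractional
#'   reduction of the enhancement amplitude at follow-up.
#' @param background_level,background_sd,background_scale mean, SD and
#'   length-scale (mm) of the smooth parenchyma background.
#' @param tumor_precontrast tumor intensity in the precontrast frame.
#' @param enhancement_amplitude peak postcontrast enhancement above the
#'   precontrast tumor intensity.
#' @param enhancement_curve per-postcontrast-frame multipliers of the
#'   enhancement amplitude (peak at the third frame, as typically observed).
#' @param frame_times_s acquisition times (s) of S0 and the postcontrast
#'   frames.
#' @param noise_sd additive Gaussian noise SD.
#' @param bias_amplitude relative amplitude of the smooth multiplicative
#'   bias field (0.1 = +/-10%).
#' @param bias_scale length-scale (mm) of the bias field.
#' @param subtype_props probabilities of (luminal A, luminal B, basal-like,
#'   HER2-enriched).
#' @param menopause_post_prob,family_history_prob,age_mean,age_sd,age_range
#'   clinical covariate distributions.
#' @param p_missing_imaging,p_missing_mp,p_missing_clinical exclusion-flag
#'   rates (0 = clean cohort).
#' @param seed master seed; a fixed seed reproduces the cohort bit-exactly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = 114,
                       responder_fraction = 44 / 114,
                       dev_fraction = 61 / 114,
                       dims = c(64L, 64L, 64L),
                       spacing = c(1, 1, 1),
                       radius_range = c(8, 16),
                       contraction_responder = c(mean = 0.75, sd = 0.08),
                       contraction_nonresponder = c(mean = 0.95, sd = 0.05),
                       contraction_axis_sd = 0.03,
                       residual_amplitude = 0.5,
                       residual_scale = 10,
                       texture_sd = 25,
                       texture_scale = 3,
                       het_reduction_responder = 0.5,
                       het_reduction_nonresponder = 0.15,
                       enh_reduction_responder = 0.35,
                       enh_reduction_nonresponder = 0.10,
                       background_level = 60,
                       background_sd = 8,
                       background_scale = 20,
                       tumor_precontrast = 75,
                       enhancement_amplitude = 150,
                       enhancement_curve = c(0.55, 0.85, 1.0, 0.92, 0.80),
                       frame_times_s = c(0, 90, 133, 177, 220, 264),
                       noise_sd = 6,
                       bias_amplitude = 0.1,
                       bias_scale = 40,
                       subtype_props = c(luminal_A = 12, luminal_B = 58,
                                         basal_like = 20, HER2_enriched = 24) / 114,
                       menopause_post_prob = 68 / 114,
                       family_history_prob = 27 / 114,
                       age_mean = 48, age_sd = 10, age_range = c(27, 79),
                       p_missing_imaging = 0, p_missing_mp = 0,
                       p_missing_clinical = 0,
                       seed = 1L) {
  stopifnot(n >= 2, responder_fraction >= 0, responder_fraction <= 1,
            dev_fraction >= 0, dev_fraction <= 1,
            all(spacing > 0), radius_range[1] > 0,
            contraction_responder[["mean"]] > 0,
            contraction_responder[["mean"]] <= 1,
            contraction_nonresponder[["mean"]] > 0,
            contraction_nonresponder[["mean"]] <= 1,
            abs(sum(subtype_props) - 1) < 1e-8)
  cfg <- as.list(environment())
  cfg$dims <- as.integer(dims)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# Correlated Gaussian random field: smoothed white noise rescaled to unit
# SD. Fields with a length-scale much coarser than the voxel size are
# simulated on a decimated grid and trilinearly upsampled, which preserves
# the covariance structure at a fraction of the smoothing cost.
gaussian_random_field <- function(dims, spacing, scale_mm) {
  f <- max(1L, floor(scale_mm / (2 * min(spacing))))
  if (f > 1L) {
    cd <- pmax(2L, as.integer(ceiling(dims / f)) + 1L)
    w <- array(rnorm(prod(cd)), dim = cd)
    g <- smooth_array(w, scale_mm / f, spacing)
    co <- cbind(rep((seq_len(dims[1]) - 1) / f, times = dims[2] * dims[3]),
                rep(rep((seq_len(dims[2]) - 1) / f, each = dims[1]),
                    times = dims[3]),
                rep((seq_len(dims[3]) - 1) / f, each = dims[1] * dims[2]))
    g <- array(cpp_interp3(as.numeric(g), cd, co, 1L), dim = dims)
  } else {
    w <- array(rnorm(prod(dims)), dim = dims)
    g <- smooth_array(w, scale_mm, spacing)
  }
  g / max(sd(g), 1e-12)
}

ellipsoid_mask <- function(dims, spacing, center_mm, radii_mm) {
  cx <- (seq_len(dims[1]) - 1) * spacing[1]
  cy <- (seq_len(dims[2]) - 1) * spacing[2]
  cz <- (seq_len(dims[3]) - 1) * spacing[3]
  dx2 <- ((cx - center_mm[1]) / radii_mm[1])^2
  dy2 <- ((cy - center_mm[2]) / radii_mm[2])^2
  dz2 <- ((cz - center_mm[3]) / radii_mm[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  array(r2 <= 1, dim = dims)
}

# Clean (noise- and bias-free) DCE scene. `texture_factor` scales the tumor
# texture deviations; `enh_factor` scales the enhancement amplitude.
build_scene_frames <- function(cfg, bg, texture, tumor_in, texture_factor = 1,
                               enh_factor = 1) {
  frames <- vector("list", 1L + length(cfg$enhancement_curve))
  t_in <- as.numeric(tumor_in)
  # Precontrast: tumor iso-intense-ish, mild intrinsic texture.
  s0 <- bg + t_in * (cfg$tumor_precontrast - bg +
                       0.15 * texture_factor * cfg$texture_sd * texture)
  frames[[1L]] <- s0
  for (k in seq_along(cfg$enhancement_curve)) {
    cv <- cfg$enhancement_curve[k]
    frames[[k + 1L]] <- bg + t_in *
      (cfg$tumor_precontrast - bg +
         enh_factor * cv * cfg$enhancement_amplitude +
         cv * texture_factor * cfg$texture_sd * texture)
  }
  frames
}

apply_noise_bias <- function(frames, cfg) {
  dims <- dim(frames[[1]])
  if (cfg$bias_amplitude > 0) {
    b <- gaussian_random_field(dims, cfg$spacing, cfg$bias_scale)
    bias <- 1 + cfg$bias_amplitude * b / max(abs(b))
  } else bias <- 1
  lapply(frames, function(f) {
    out <- f * bias
    if (cfg$noise_sd > 0)
      out <- out + array(rnorm(prod(dims), sd = cfg$noise_sd), dim = dims)
    out
  })
}

#' Generate one synthetic baseline/follow-up tumor image pair
#'
#' The follow-up series equals the (heterogeneity- and enhancement-reduced)
#' baseline scene warped through the ground-truth deformation: an affine
#' contraction about the tumor centroid (responders contract more) composed
#' with a small smooth residual field. Noise and a multiplicative bias field
#' are added independently at each time point.
#'
#' @param config a [sim_config()].
#' @param responder logical, patient class.
#' @param seed integer seed for this patient.
#' @return A list with `baseline`/`followup` (`dce_series`),
#'   `baseline_mask`/`followup_mask` (`binary_mask`, ground truth),
#'   `true_field` (`displacement_field`, baseline -> follow-up), and
#'   `meta` (true contraction per axis, Jacobian determinant of the affine
#'   part, heterogeneity/enhancement reduction, radii, centroid).
#' @export
generate_tumor_pair <- function(config, responder, seed) {
  cfg <- config
  withr::with_seed(as.integer(seed), {
    dims <- cfg$dims
    spacing <- cfg$spacing
    extent <- dims * spacing
    r0 <- runif(1, cfg$radius_range[1], cfg$radius_range[2])
    radii <- r0 * runif(3, 0.85, 1.15)
    if (any(2 * radii > 0.8 * extent))
      stop("tumor radius exceeds the volume extent")
    center <- extent / 2 + runif(3, -2, 2)
    cpars <- if (responder) cfg$contraction_responder else
      cfg$contraction_nonresponder
    s_base <- min(1, max(0.5, rnorm(1, cpars[["mean"]], cpars[["sd"]])))
    s_axis <- pmin(1, pmax(0.5, s_base + rnorm(3, 0, cfg$contraction_axis_sd)))
    rho <- if (responder) cfg$het_reduction_responder else
      cfg$het_reduction_nonresponder
    enh_red <- if (responder) cfg$enh_reduction_responder else
      cfg$enh_reduction_nonresponder

    bg <- cfg$background_level +
      cfg$background_sd * gaussian_random_field(dims, spacing, cfg$background_scale)
    texture <- gaussian_random_field(dims, spacing, cfg$texture_scale)
    tumor_base <- ellipsoid_mask(dims, spacing, center, radii)

    base_clean <- build_scene_frames(cfg, bg, texture, tumor_base)

    # Ground-truth forward displacement: an affine contraction about the
    # tumor centroid, tapered smoothly to zero away from the tumor (distant
    # breast tissue does not move when the tumor shrinks), plus a small
    # smooth residual field. Inside the tumor the map is exactly affine, so
    # the interior Jacobian determinant is analytically prod(s_axis).
    n <- prod(dims)
    wx <- (seq_len(dims[1]) - 1) * spacing[1]
    wy <- (seq_len(dims[2]) - 1) * spacing[2]
    wz <- (seq_len(dims[3]) - 1) * spacing[3]
    coord <- cbind(rep(wx, times = dims[2] * dims[3]),
                   rep(rep(wy, each = dims[1]), times = dims[3]),
                   rep(wz, each = dims[1] * dims[2]))
    centered <- sweep(coord, 2, center, "-")
    u <- centered %*% diag(s_axis - 1)
    rad <- sqrt(rowSums(sweep(centered, 2, radii, "/")^2))
    rbar <- mean(radii)
    # Taper width keeps the tapered map's Jacobian strictly positive even
    # at the strongest admissible contraction.
    delta <- max(4, 1.5 * (1 - min(s_axis)) * rbar)
    taper <- ifelse(rad <= 1, 1, exp(-((rad - 1) * rbar / delta)^2))
    u <- u * taper
    if (cfg$residual_amplitude > 0) {
      for (k in 1:3) {
        rf <- gaussian_random_field(dims, spacing, cfg$residual_scale)
        u[, k] <- u[, k] + cfg$residual_amplitude * as.numeric(rf)
      }
    }
    ufield <- array(u, dim = c(dims, 3))

    # Inverse map by fixed-point iteration: x = y - u(x).
    inv <- coord  # start at x = y
    for (it in 1:4) {
      ux <- vapply(1:3, function(k)
        cpp_interp3(as.numeric(ufield[, , , k]), dims,
                    sweep(inv, 2, spacing, "/"), 1L), numeric(n))
      inv <- coord - ux
    }
    inv_disp <- inv - coord  # mm, on the follow-up lattice

    mod_clean <- build_scene_frames(cfg, bg, texture, tumor_base,
                                    texture_factor = 1 - rho,
                                    enh_factor = 1 - enh_red)
    fup_clean <- lapply(mod_clean, function(f)
      warp_array(f, inv_disp, spacing))

    base_frames <- apply_noise_bias(base_clean, cfg)
    fup_frames <- apply_noise_bias(fup_clean, cfg)

    to_vol <- function(a) image_volume(a, spacing)
    baseline <- dce_series(lapply(base_frames, to_vol), cfg$frame_times_s)
    followup <- dce_series(lapply(fup_frames, to_vol), cfg$frame_times_s)
    fup_mask_arr <- ellipsoid_mask(dims, spacing, center, radii * s_axis)
    list(
      baseline = baseline,
      followup = followup,
      baseline_mask = binary_mask(tumor_base, spacing),
      followup_mask = binary_mask(fup_mask_arr, spacing),
      true_field = displacement_field(ufield, spacing),
      meta = list(contraction = s_axis, jacobian_det = prod(s_axis),
                  het_reduction = rho, enh_reduction = enh_red,
                  radii_mm = radii, center_mm = center,
                  responder = responder, seed = as.integer(seed))
    )
  })
}

mp_probs_responder <- c(`4` = 10 / 44, `5` = 34 / 44)
mp_probs_nonresponder <- c(`1` = 9 / 70, `2` = 21 / 70, `3` = 40 / 70)

#' Derive the molecular subtype from receptor status
#'
#' Luminal A: HR+/HER2- with Ki-67 at or below 14%; luminal B: HR+/HER2+
#' or HR+/HER2- with Ki-67 above 14%; HER2-enriched: HR-/HER2+;
#' basal-like (triple-negative): HR-/HER2-.
#'
#' @param hr_positive,her2_positive logical vectors.
#' @param ki67 Ki-67 expression level in percent.
#' @return Character vector of subtypes.
#' @export
derive_subtype <- function(hr_positive, her2_positive, ki67) {
  ifelse(hr_positive & !her2_positive & ki67 <= 14, "luminal_A",
  ifelse(hr_positive, "luminal_B",
  ifelse(her2_positive, "HER2_enriched", "basal_like")))
}

draw_receptors <- function(subtype) {
  n <- length(subtype)
  hr <- subtype %in% c("luminal_A", "luminal_B")
  her2 <- logical(n)
  ki67 <- numeric(n)
  for (i in seq_len(n)) {
    switch(subtype[i],
      luminal_A = { her2[i] <- FALSE; ki67[i] <- runif(1, 2, 14) },
      luminal_B = {
        her2[i] <- runif(1) < 0.5
        ki67[i] <- if (her2[i]) runif(1, 5, 80) else runif(1, 15, 80)
      },
      HER2_enriched = { her2[i] <- TRUE; ki67[i] <- runif(1, 5, 80) },
      basal_like = { her2[i] <- FALSE; ki67[i] <- runif(1, 5, 80) })
  }
  data.frame(hr_positive = hr, her2_positive = her2, ki67 = round(ki67, 1))
}

#' Generate a synthetic patient cohort
#'
#' Draws the clinical table (age, menopausal status, family history,
#' receptor status and derived molecular subtype, Miller-Payne grade,
#' development/testing arm, exclusion flags) for `config$n` patients, plus a
#' per-patient image seed from which [patient_images()] deterministically
#' regenerates the paired baseline/follow-up series. Images are not held in
#' memory for the whole cohort.
#'
#' @param config a [sim_config()].
#' @return A `data.frame` with one row per patient (class
#'   `cohort_records`).
#' @export
generate_cohort <- function(config) {
  cfg <- config
  withr::with_seed(cfg$seed, {
    n <- cfg$n
    id <- sprintf("P%03d", seq_len(n))
    responder <- runif(n) < cfg$responder_fraction
    if (sum(responder) < 2 || sum(!responder) < 2)
      stop("need at least 2 patients per class for modeling use")
    mp <- integer(n)
    mp[responder] <- as.integer(sample(names(mp_probs_responder),
                                       sum(responder), TRUE,
                                       mp_probs_responder))
    mp[!responder] <- as.integer(sample(names(mp_probs_nonresponder),
                                        sum(!responder), TRUE,
                                        mp_probs_nonresponder))
    age <- round(pmin(cfg$age_range[2], pmax(cfg$age_range[1],
                 rnorm(n, cfg$age_mean, cfg$age_sd))))
    menopause <- ifelse(runif(n) < cfg$menopause_post_prob, "post", "pre")
    family_history <- ifelse(runif(n) < cfg$family_history_prob, "yes", "no")
    subtype <- sample(names(cfg$subtype_props), n, TRUE, cfg$subtype_props)
    rec <- draw_receptors(subtype)
    arm <- ifelse(runif(n) < cfg$dev_fraction, "development", "testing")
    missing_imaging <- runif(n) < cfg$p_missing_imaging
    missing_mp <- runif(n) < cfg$p_missing_mp
    missing_clinical <- runif(n) < cfg$p_missing_clinical
    image_seed <- (cfg$seed + seq_len(n) * 10007L) %% .Machine$integer.max
    out <- data.frame(
      id = id, age = age, menopause = menopause,
      family_history = family_history,
      subtype = subtype, hr_positive = rec$hr_positive,
      her2_positive = rec$her2_positive, ki67 = rec$ki67,
      mp_grade = mp, responder = responder, arm = arm,
      missing_imaging = missing_imaging, missing_mp = missing_mp,
      missing_clinical = missing_clinical,
      image_seed = as.integer(image_seed),
      stringsAsFactors = FALSE)
    class(out) <- c("cohort_records", class(out))
    out
  })
}

#' Regenerate the image pair of one cohort patient
#'
#' @param config the [sim_config()] used for the cohort.
#' @param record one row of the [generate_cohort()] table.
#' @return The [generate_tumor_pair()] result for that patient.
#' @export
patient_images <- function(config, record) {
  generate_tumor_pair(config, responder = record$responder[1],
                      seed = record$image_seed[1])
}

#' Write cohort records as CSV
#'
#' @param records a `cohort_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Read cohort records from CSV
#'
#' @param path CSV written by [write_cohort_csv()].
#' @return A `cohort_records` data frame.
#' @export
read_cohort_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort_records", class(out))
  out
}

#' Write a synthetic cohort to disk
#'
#' Materializes a cohort as files: per-patient NIfTI volumes (all DCE
#' frames at both time points, the ground-truth masks, and the true
#' displacement field), the cohort CSV, and a JSON manifest with the
#' true per-patient simulation parameters.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if missing).
#' @param records optional pre-generated cohort records (default:
#'   [generate_cohort()] on `config`).
#' @return The manifest, invisibly.
#' @export
simulate_cohort_dir <- function(config, dir, records = NULL) {
  if (is.null(records)) records <- generate_cohort(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_csv(records, file.path(dir, "cohort.csv"))
  manifest <- list(n = nrow(records), seed = config$seed, patients = list())
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    pdir <- file.path(dir, rec$id)
    dir.create(pdir, showWarnings = FALSE)
    pair <- patient_images(config, rec)
    for (k in seq_along(pair$baseline$frames))
      write_volume(pair$baseline$frames[[k]],
                   file.path(pdir, sprintf("baseline_frame%02d.nii.gz", k - 1)))
    for (k in seq_along(pair$followup$frames))
      write_volume(pair$followup$frames[[k]],
                   file.path(pdir, sprintf("followup_frame%02d.nii.gz", k - 1)))
    write_volume(pair$baseline_mask, file.path(pdir, "baseline_mask.nii.gz"))
    write_volume(pair$followup_mask, file.path(pdir, "followup_mask.nii.gz"))
    write_volume(pair$true_field, file.path(pdir, "true_field.nii.gz"))
    manifest$patients[[rec$id]] <- pair$meta
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
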