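#' Relative net feature change (deltaRAD)
#'
#' For each feature i, `(f_baseline - f_followup) / f_baseline`: a positive
#' value means the feature decreased after treatment. Features whose
#' baseline value is exactly 0 are undefined; they are returned as `NA`
#' (the documented sentinel) and flagged in the `zero_baseline` attribute.
#' [assemble_design_matrix()] later imputes such entries with the
#' development-arm median.
#'
#' @param f_baseline,f_followup named numeric feature vectors with
#'   identical name sets (e.g. from [extract_all_features()]).
#' @return Named numeric vector of the same length, attribute
#'   `zero_baseline` (character names with zero baseline, possibly empty).
#' @export
delta_rad <- function(f_baseline, f_followup) {
  if (!identical(names(f_baseline), names(f_followup)))
    stop("feature name sets must be identical")
  zero <- f_baseline == 0
  out <- (f_baseline - f_followup) / f_baseline
  out[zero] <- NA_real_
  attr(out, "zero_baseline") <- names(f_baseline)[zero]
  out
}

#' Assemble a modeling design matrix from per-patient feature tables
#'
#' Builds the feature matrix for one source set: `"baseline"`,
#' `"followup"`, `"delta"` or `"jacobian"` (102 columns each), `"fusion"`
#' (the four concatenated, 408 columns), optionally plus indicator-coded
#' molecular subtype (3 columns, luminal A reference). Columns are
#' standardized with mean/SD fitted on the development arm only and applied
#' unchanged to the testing arm; `NA` entries (zero-baseline deltaRAD) are
#' imputed with the development-arm median before standardization.
#'
#' @param features a data frame with columns `id`, `arm`, `responder`,
#'   `source` and the 102 feature columns; one row per (patient, source).
#' @param sources character, subset of
#'   `c("baseline", "followup", "delta", "jacobian")` or `"fusion"`.
#' @param with_subtype logical; append indicator-coded molecular subtype
#'   from `records`.
#' @param records cohort records (needed when `with_subtype = TRUE`).
#' @return A list with `x` (numeric matrix, rows = patients), `y`
#'   (0/1 responder), `arm`, `id`, `standardization` (per-column mean/SD),
#'   `column_sources` (provenance of each column), and `excluded`
#'   (patients dropped for missing sources, with reasons).
#' @export
assemble_design_matrix <- function(features, sources = "fusion",
                                   with_subtype = FALSE, records = NULL) {
  stopifnot(is.data.frame(features))
  base_sources <- c("baseline", "followup", "delta", "jacobian")
  if (identical(sources, "fusion")) sources <- base_sources
  if (!all(sources %in% base_sources))
    stop("unknown source(s): ",
         paste(setdiff(sources, base_sources), collapse = ", "))
  fn <- feature_names()
  ids <- unique(features$id)
  keep <- character(0)
  excluded <- data.frame(id = character(0), reason = character(0))
  for (pid in ids) {
    have <- features$source[features$id == pid]
    miss <- setdiff(sources, have)
    if (length(miss)) {
      excluded <- rbind(excluded, data.frame(
        id = pid, reason = paste("missing source:", miss[1])))
    } else keep <- c(keep, pid)
  }
  if (!length(keep)) stop("no patient has all requested sources")
  blocks <- lapply(sources, function(src) {
    sub <- features[features$source == src & features$id %in% keep, ,
                    drop = FALSE]
    sub <- sub[match(keep, sub$id), , drop = FALSE]
    m <- as.matrix(sub[, fn, drop = FALSE])
    colnames(m) <- paste(src, fn, sep = "_")
    m
  })
  x <- do.call(cbind, blocks)
  col_src <- rep(sources, each = length(fn))
  meta <- features[match(keep, features$id), c("id", "arm", "responder")]
  if (with_subtype) {
    if (is.null(records)) stop("`records` required for subtype coding")
    st <- records$subtype[match(keep, records$id)]
    if (anyNA(st)) stop("subtype missing for some patients")
    lev <- c("luminal_A", "luminal_B", "basal_like", "HER2_enriched")
    ind <- sapply(lev[-1], function(l) as.numeric(st == l))
    colnames(ind) <- paste0("subtype_", lev[-1])
    x <- cbind(x, ind)
    col_src <- c(col_src, rep("subtype", 3))
  }
  dev <- meta$arm == "development"
  if (!any(dev)) stop("no development-arm patients after assembly")
  # Median-impute NA (zero-baseline deltaRAD) from the development arm.
  for (jc in seq_len(ncol(x))) {
    nas <- is.na(x[, jc])
    if (any(nas)) {
      med <- median(x[dev, jc], na.rm = TRUE)
      if (!is.finite(med)) med <- 0
      x[nas, jc] <- med
    }
  }
  mu <- colMeans(x[dev, , drop = FALSE])
  sdv <- apply(x[dev, , drop = FALSE], 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  list(x = xs, y = as.integer(meta$responder), arm = meta$arm, id = keep,
       standardization = list(mean = mu, sd = sdv),
       column_sources = col_src, excluded = excluded)
}

#' Extract per-patient longitudinal feature tables for a synthetic cohort
#'
#' Runs the full imaging pipeline for each retained patient of a synthetic
#' cohort: regenerate the image pair, pick the peak-enhancement frame and
#' subtraction image at both time points, segment the tumor (spatial FCM on
#' the subtraction image, or the ground-truth mask when
#' `segmentation = "truth"`), register follow-up to baseline, compute the
#' Jacobian map, and extract the 102 features from the baseline
#' subtraction, follow-up subtraction and Jacobian map (over the baseline
#' tumor mask for the Jacobian source).
#'
#' @param config a [sim_config()].
#' @param records cohort records from [generate_cohort()] (already
#'   filtered).
#' @param params a [feature_params()] for the subtraction images
#'   (default: fixed bin width).
#' @param jac_params a [feature_params()] for the Jacobian map (default:
#'   fixed bin count 32 — the map is a unitless ratio).
#' @param reg_config a [registration_config()].
#' @param segmentation `"fcm"` or `"truth"`.
#' @param bias_correct logical, run [correct_bias()] on the subtraction
#'   images before feature extraction.
#' @param verbose print per-patient progress.
#' @return A list with `features` (long data frame: one row per patient and
#'   source in baseline/followup/delta/jacobian) and `jacobian_summary`
#'   (per-patient mean/SD of the Jacobian map inside the baseline tumor).
#' @export
cohort_feature_tables <- function(config, records,
                                  params = feature_params(),
                                  jac_params = feature_params("count", 32),
                                  reg_config = registration_config(),
                                  segmentation = c("fcm", "truth"),
                                  bias_correct = FALSE,
                                  verbose = FALSE) {
  segmentation <- match.arg(segmentation)
  rows <- list()
  jrows <- list()
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    pair <- patient_images(config, rec)
    sel_b <- select_enhancement_frame(pair$baseline)
    sel_f <- select_enhancement_frame(pair$followup)
    sub_b <- sel_b$subtraction
    sub_f <- sel_f$subtraction
    if (bias_correct) {
      sub_b <- correct_bias(sub_b)$corrected
      sub_f <- correct_bias(sub_f)$corrected
    }
    if (segmentation == "fcm") {
      mask_b <- segment_tumor_fcm(sub_b, bbox = "auto")
      mask_f <- segment_tumor_fcm(sub_f, bbox = "auto")
    } else {
      mask_b <- pair$baseline_mask
      mask_f <- pair$followup_mask
    }
    reg <- register_deformable(sub_b, sub_f, reg_config)
    jac <- suppressWarnings(compute_jacobian_map(reg$field))
    f_b <- extract_all_features(sub_b, mask_b, params)
    f_f <- extract_all_features(sub_f, mask_f, params)
    f_j <- extract_all_features(jac, mask_b, jac_params)
    f_d <- delta_rad(f_b, f_f)
    mk <- function(src, v) {
      df <- data.frame(id = rec$id, arm = rec$arm,
                       responder = rec$responder, source = src)
      df[names(v)] <- as.list(unname(v))
      df
    }
    rows[[length(rows) + 1L]] <- rbind(
      mk("baseline", f_b), mk("followup", f_f),
      mk("delta", f_d), mk("jacobian", f_j))
    js <- summarize_jacobian(jac, mask_b)
    jrows[[length(jrows) + 1L]] <- data.frame(
      id = rec$id, responder = rec$responder, arm = rec$arm,
      jac_mean = js$mean, jac_sd = js$sd,
      true_jac = pair$meta$jacobian_det)
    if (verbose)
      message(sprintf("[%d/%d] %s done", r, nrow(records), rec$id))
  }
  feats <- do.call(rbind, rows)
  list(features = feats, jacobian_summary = do.call(rbind, jrows))
}
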