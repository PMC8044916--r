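#' Run the full longitudinal radiomics pipeline on a synthetic cohort
#'
#' Orchestrates cohort simulation, patient-selection filtering,
#' preprocessing (frame selection/subtraction and segmentation),
#' deformable registration with Jacobian maps, 102-feature extraction on
#' the baseline/follow-up subtraction images and the Jacobian map,
#' deltaRAD, model training on the development arm and evaluation on the
#' testing arm for six source sets (baseline, follow-up, deltaRAD,
#' Jacobian, feature fusion, fusion + molecular subtype), paired AUC
#' comparisons against the baseline-image model, and the arm-comparison
#' statistics table.
#'
#' @param config a [sim_config()].
#' @param params a [feature_params()].
#' @param reg_config a [registration_config()].
#' @param mod_config a [model_config()].
#' @param segmentation `"fcm"` or `"truth"` (see
#'   [cohort_feature_tables()]).
#' @param verbose print progress.
#' @return A list with `results` (one row per source set: AUC, SE,
#'   threshold, sensitivity, specificity, PPV, NPV, and the DeLong p-value
#'   against the baseline model), `evals` (the underlying `eval_result`s),
#'   `models`, `cohort_table` (arm-comparison statistics),
#'   `exclusion_report`, `jacobian_summary`, `records`, and `features`.
#' @export
run_pipeline <- function(config = sim_config(),
                         params = feature_params(),
                         reg_config = registration_config(),
                         mod_config = model_config(),
                         segmentation = c("fcm", "truth"),
                         verbose = FALSE) {
  segmentation <- match.arg(segmentation)
  records <- generate_cohort(config)
  filt <- filter_cohort(records)
  records <- filt$retained
  stopifnot(identical(records$responder, dichotomize_mp(records$mp_grade)))
  if (verbose) message("cohort: ", nrow(records), " patients retained")
  tabs <- cohort_feature_tables(config, records, params = params,
                                reg_config = reg_config,
                                segmentation = segmentation,
                                verbose = verbose)
  source_sets <- list(
    baseline = list(sources = "baseline", subtype = FALSE),
    followup = list(sources = "followup", subtype = FALSE),
    delta = list(sources = "delta", subtype = FALSE),
    jacobian = list(sources = "jacobian", subtype = FALSE),
    fusion = list(sources = "fusion", subtype = FALSE),
    fusion_subtype = list(sources = "fusion", subtype = TRUE))
  evals <- list()
  models <- list()
  for (nm in names(source_sets)) {
    ss <- source_sets[[nm]]
    dm <- assemble_design_matrix(tabs$features, ss$sources,
                                 with_subtype = ss$subtype,
                                 records = records)
    dev <- dm$arm == "development"
    if (verbose) message("training ", nm, " model (",
                         sum(dev), " dev / ", sum(!dev), " test)")
    fit <- tune_and_select(dm$x[dev, , drop = FALSE], dm$y[dev], mod_config)
    scores <- predict_scores(fit, dm$x[!dev, , drop = FALSE])
    evals[[nm]] <- evaluate_roc(scores, dm$y[!dev])
    models[[nm]] <- fit
  }
  comps <- vapply(names(source_sets), function(nm) {
    if (nm == "baseline") return(NA_real_)
    compare_auc(evals[[nm]], evals[["baseline"]])$p_value
  }, numeric(1))
  results <- data.frame(
    source = names(source_sets),
    auc = vapply(evals, function(e) e$auc, numeric(1)),
    auc_se = vapply(evals, function(e) e$auc_se, numeric(1)),
    threshold = vapply(evals, function(e) e$threshold, numeric(1)),
    sensitivity = vapply(evals, function(e) e$sensitivity, numeric(1)),
    specificity = vapply(evals, function(e) e$specificity, numeric(1)),
    ppv = vapply(evals, function(e) e$ppv, numeric(1)),
    npv = vapply(evals, function(e) e$npv, numeric(1)),
    p_vs_baseline = comps,
    row.names = NULL)
  list(results = results, evals = evals, models = models,
       cohort_table = cohort_comparison_table(records),
       exclusion_report = filt$report,
       jacobian_summary = tabs$jacobian_summary,
       records = records, features = tabs$features)
}
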