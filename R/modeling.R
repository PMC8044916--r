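#' Model configuration for the SVM pipeline
#'
#' The classifier is a Gaussian-kernel support vector machine. Features are
#' first ranked by linear SVM-RFE; the top-k subsets (k = 1..`max_features`)
#' are then tuned over the (cost, gamma) grid by stratified 10-fold
#' cross-validated AUC on the development arm.
#'
#' @param cost_grid SVM cost (regularization) grid.
#' @param gamma_grid Gaussian kernel width grid.
#' @param n_folds cross-validation folds (stratified).
#' @param fold_seed seed for fold assignment.
#' @param rfe_step number (or fraction in (0,1)) of features eliminated per
#'   RFE iteration.
#' @param max_features largest candidate subset size.
#' @param rfe_cost cost used for the linear ranking SVMs.
#' @return A `model_config` list.
#' @export
model_config <- function(cost_grid = 2^seq(-5, 10, by = 1),
                         gamma_grid = 2^seq(-10, 3, by = 1),
                         n_folds = 10L, fold_seed = 1L,
                         rfe_step = 0.1, max_features = 15L,
                         rfe_cost = 1) {
  stopifnot(length(cost_grid) >= 1, length(gamma_grid) >= 1, n_folds >= 2)
  structure(list(cost_grid = cost_grid, gamma_grid = gamma_grid,
                 n_folds = as.integer(n_folds),
                 fold_seed = as.integer(fold_seed),
                 rfe_step = rfe_step, max_features = as.integer(max_features),
                 rfe_cost = rfe_cost),
            class = "model_config")
}

svm_linear_weights <- function(x, y, cost) {
  fit <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- t(fit$coefs) %*% fit$SV
  as.numeric(w)
}

#' Rank features by linear SVM recursive feature elimination
#'
#' Repeatedly fits a linear SVM and removes the features with the smallest
#' squared weight until none remain; the elimination order, reversed, is
#' the ranking (rank 1 = most relevant, eliminated last). Ties are broken
#' by larger absolute weight first, then by column order. Deterministic
#' for fixed inputs and configuration.
#'
#' @param x numeric feature matrix (standardized).
#' @param y 0/1 labels (>= 2 samples per class).
#' @param config a [model_config()].
#' @return Character vector: all column names of `x`, most relevant first.
#' @export
svm_rfe_rank <- function(x, y, config = model_config()) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("labels are single-class")
  if (min(table(y)) < 2) stop("need >= 2 samples per class")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  remaining <- colnames(x)
  eliminated <- character(0)
  while (length(remaining) > 0) {
    if (length(remaining) == 1) {
      eliminated <- c(eliminated, remaining)
      break
    }
    w <- svm_linear_weights(x[, remaining, drop = FALSE], y, config$rfe_cost)
    crit <- w^2
    k <- if (config$rfe_step < 1) {
      max(1L, floor(config$rfe_step * length(remaining)))
    } else min(as.integer(config$rfe_step), length(remaining) - 1L)
    # Smallest criterion first; ties by column order (stable sort).
    ord <- order(crit, seq_along(remaining))
    drop_idx <- ord[seq_len(k)]
    eliminated <- c(eliminated, remaining[drop_idx])
    remaining <- remaining[-drop_idx]
  }
  rev(eliminated)
}

stratified_folds <- function(y, n_folds, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < n_folds && length(idx) < 1)
        stop("a class has no samples")
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    fold
  })
}

fit_gaussian_svm <- function(x, y, cost, gamma) {
  e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

svm_scores <- function(fit, x) {
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
  s <- as.numeric(dv)
  # e1071 orients decision values by the order classes appear in training
  # ("A/B" means positive favors A); flip so higher score means class "1".
  if (colnames(dv)[1] == "0/1") -s else s
}

#' ROC evaluation with Youden operating point
#'
#' AUC by the trapezoidal (Mann-Whitney rank) rule with ties counted 1/2;
#' the standard error uses the distribution-free Hanley-McNeil formula.
#' The operating threshold maximizes sensitivity + specificity (Youden
#' index); among ties the highest-specificity point is taken. PPV and NPV
#' come from the confusion table at that point.
#'
#' @param scores numeric decision scores (higher = more likely responder).
#' @param labels 0/1 labels, both classes present.
#' @return An `eval_result` list: `auc`, `auc_se`, `threshold`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `scores`, `labels`.
#' @export
evaluate_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("labels are single-class")
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  n1 <- length(pos)
  n0 <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  # Candidate thresholds: midpoints between consecutive distinct scores,
  # plus sentinels below/above everything.
  su <- sort(unique(scores))
  cand <- c(su[1] - 1, if (length(su) > 1) (su[-1] + su[-length(su)]) / 2,
            su[length(su)] + 1)
  sens <- vapply(cand, function(t) mean(pos > t), numeric(1))
  spec <- vapply(cand, function(t) mean(neg <= t), numeric(1))
  yj <- sens + spec
  best <- which(yj == max(yj))
  best <- best[which.max(spec[best])]
  thr <- cand[best]
  tp <- sum(pos > thr); fn <- n1 - tp
  fp <- sum(neg > thr); tn <- n0 - fp
  structure(list(auc = auc, auc_se = se, threshold = thr,
                 sensitivity = sens[best], specificity = spec[best],
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                 scores = scores, labels = labels),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("AUC %.3f +/- %.3f | sens %.3f spec %.3f ppv %.3f npv %.3f\n",
              x$auc, x$auc_se, x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

cv_auc <- function(x, y, cost, gamma, fold) {
  scores <- numeric(length(y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) stop("fold with a single class")
    fit <- fit_gaussian_svm(x[tr, , drop = FALSE], y[tr], cost, gamma)
    scores[!tr] <- svm_scores(fit, x[!tr, , drop = FALSE])
  }
  evaluate_roc(scores, y)$auc
}

#' RFE ranking plus grid-search model selection with 10-fold CV
#'
#' On the development arm only: features are ranked by [svm_rfe_rank()];
#' for each subset size k = 1..`max_features` the (cost, gamma) grid is
#' evaluated by stratified cross-validated AUC (out-of-fold scores pooled
#' across folds); the best (k, cost, gamma) — ties resolved toward fewer
#' features, then smaller cost, then smaller gamma — is refit on all
#' development samples.
#'
#' @param x standardized development-arm feature matrix.
#' @param y 0/1 development-arm labels.
#' @param config a [model_config()].
#' @return A `fitted_model` list: `features` (selected, in rank order),
#'   `ranking` (full), `cost`, `gamma`, `fit` (the refit SVM), `cv_curve`
#'   (data frame k x best CV AUC), `cv_auc` (selected model's CV AUC).
#' @export
tune_and_select <- function(x, y, config = model_config()) {
  y <- as.integer(y)
  ranking <- svm_rfe_rank(x, y, config)
  kmax <- min(config$max_features, length(ranking))
  fold <- stratified_folds(y, config$n_folds, config$fold_seed)
  # gamma varies fastest so rows are ordered by (cost, gamma): on CV-AUC
  # ties the first maximum, i.e. smaller cost then smaller gamma, wins.
  grid <- expand.grid(gamma = config$gamma_grid, cost = config$cost_grid)
  grid <- grid[, c("cost", "gamma")]
  best <- list(auc = -Inf, k = NA, cost = NA, gamma = NA)
  curve <- data.frame(k = seq_len(kmax), auc = NA_real_)
  for (k in seq_len(kmax)) {
    xk <- x[, ranking[seq_len(k)], drop = FALSE]
    aucs <- vapply(seq_len(nrow(grid)), function(g)
      cv_auc(xk, y, grid$cost[g], grid$gamma[g], fold), numeric(1))
    gi <- which.max(aucs)  # grid ordered small-to-large: first max wins
    curve$auc[k] <- aucs[gi]
    if (aucs[gi] > best$auc + 1e-12) {
      best <- list(auc = aucs[gi], k = k, cost = grid$cost[gi],
                   gamma = grid$gamma[gi])
    }
  }
  feats <- ranking[seq_len(best$k)]
  fit <- fit_gaussian_svm(x[, feats, drop = FALSE], y, best$cost, best$gamma)
  structure(list(features = feats, ranking = ranking, cost = best$cost,
                 gamma = best$gamma, fit = fit, cv_curve = curve,
                 cv_auc = best$auc),
            class = "fitted_model")
}

#' Score new samples with a fitted model
#'
#' @param model a `fitted_model` from [tune_and_select()].
#' @param x feature matrix containing at least the model's columns,
#'   standardized with the development-arm parameters.
#' @return Numeric decision scores (higher = responder).
#' @export
predict_scores <- function(model, x) {
  svm_scores(model$fit, x[, model$features, drop = FALSE])
}

#' Paired comparison of two AUCs
#'
#' DeLong's test for two correlated ROC curves computed on the same test
#' samples (default), or a paired bootstrap test of the AUC difference.
#'
#' @param result_a,result_b `eval_result`s from [evaluate_roc()] on the
#'   same samples, in the same order.
#' @param method `"delong"` or `"bootstrap"`.
#' @param n_boot bootstrap resamples.
#' @param boot_seed seed for the bootstrap.
#' @return A list with `p_value`, `auc_a`, `auc_b`, `method`.
#' @export
compare_auc <- function(result_a, result_b, method = c("delong", "bootstrap"),
                        n_boot = 2000L, boot_seed = 1L) {
  method <- match.arg(method)
  if (!identical(result_a$labels, result_b$labels))
    stop("results must be paired: same samples in the same order")
  labs <- result_a$labels
  if (identical(result_a$scores, result_b$scores))
    return(list(p_value = 1, auc_a = result_a$auc, auc_b = result_b$auc,
                method = method))
  if (method == "delong") {
    ra <- pROC::roc(labs, result_a$scores, quiet = TRUE, direction = "<")
    rb <- pROC::roc(labs, result_b$scores, quiet = TRUE, direction = "<")
    tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    p <- tst$p.value
  } else {
    obs <- result_a$auc - result_b$auc
    n <- length(labs)
    p <- withr::with_seed(boot_seed, {
      diffs <- replicate(n_boot, {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labs[idx])) < 2) return(NA_real_)
        evaluate_roc(result_a$scores[idx], labs[idx])$auc -
          evaluate_roc(result_b$scores[idx], labs[idx])$auc
      })
      diffs <- diffs[!is.na(diffs)]
      se <- sd(diffs)
      if (se == 0) 1 else 2 * stats::pnorm(-abs(obs) / se)
    })
  }
  list(p_value = min(1, p), auc_a = result_a$auc, auc_b = result_b$auc,
       method = method)
}
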