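small_grid <- function(...) {
  model_config(cost_grid = 2^c(-3, 0, 3), gamma_grid = 2^c(-7, -4, -1), ...)
}

test_that("SVM-RFE recovers planted informative features", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(200 + s, {
      n <- 200
      x <- matrix(rnorm(n * 22), n, 22)
      colnames(x) <- paste0("f", 1:22)
      y <- as.integer(x[, 1] - x[, 2] + rnorm(n, sd = 0.4) > 0)
      r <- svm_rfe_rank(x, y)
      all(match(c("f1", "f2"), r) <= 5)
    })
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a duplicated noise column is eliminated as an adjacent pair", {
  # Identical columns share their weight, so the duplicated pure-noise
  # column and its copy sit below every informative column and leave in
  # consecutive elimination steps.
  withr::with_seed(210, {
    n <- 120
    x <- matrix(rnorm(n * 4), n, 4)
    noise <- rnorm(n)
    x <- cbind(x, noise = noise, dup = noise)
    colnames(x) <- c(paste0("v", 1:4), "noise", "dup")
    y <- as.integer(rowSums(x[, 1:4]) + rnorm(n, sd = 0.5) > 0)
    r <- svm_rfe_rank(x, y, model_config(rfe_step = 1))
    expect_equal(sort(match(c("noise", "dup"), r)), c(5L, 6L))
  })
})

test_that("step-1 RFE equals an exhaustive elimination oracle", {
  withr::with_seed(211, {
    n <- 60
    x <- matrix(rnorm(n * 6), n, 6)
    colnames(x) <- paste0("c", 1:6)
    y <- as.integer(x[, 1] + 0.5 * x[, 3] + rnorm(n, sd = 0.7) > 0)
    cfg <- model_config(rfe_step = 1, rfe_cost = 1)
    r <- svm_rfe_rank(x, y, cfg)
    # independent elimination loop using libsvm directly
    remaining <- colnames(x)
    order_out <- character(0)
    while (length(remaining) > 1) {
      fit <- e1071::svm(x[, remaining, drop = FALSE],
                        factor(y, levels = c(0, 1)),
                        kernel = "linear", cost = 1, scale = FALSE)
      w <- as.numeric(t(fit$coefs) %*% fit$SV)
      worst <- order(w^2, seq_along(remaining))[1]
      order_out <- c(order_out, remaining[worst])
      remaining <- remaining[-worst]
    }
    oracle <- rev(c(order_out, remaining))
    expect_identical(r, oracle)
  })
})

test_that("tuning attains CV AUC >= 0.99 on a separable toy", {
  withr::with_seed(220, {
    x <- matrix(rnorm(120 * 2), 120, 2)
    colnames(x) <- c("u", "v")
    y <- as.integer(x[, 1] + x[, 2] > 0)
    fit <- tune_and_select(x, y, small_grid(max_features = 2L))
    expect_gte(max(fit$cv_curve$auc), 0.99)
    fit2 <- tune_and_select(x, y, small_grid(max_features = 2L))
    expect_identical(fit$features, fit2$features)
    expect_identical(c(fit$cost, fit$gamma), c(fit2$cost, fit2$gamma))
  })
})

test_that("permuted labels give chance-level test AUC", {
  aucs <- vapply(1:20, function(s) {
    withr::with_seed(230 + s, {
      n <- 200
      x <- matrix(rnorm(n * 10), n, 10)
      colnames(x) <- paste0("n", 1:10)
      y <- sample(rep(0:1, each = n / 2))
      dev <- seq_len(n / 2)
      fit <- tune_and_select(x[dev, ], y[dev],
                             small_grid(max_features = 3L, fold_seed = s))
      evaluate_roc(predict_scores(fit, x[-dev, ]), y[-dev])$auc
    })
  }, numeric(1))
  expect_gte(mean(aucs), 0.38)
  expect_lte(mean(aucs), 0.62)
})

test_that("ROC evaluation handles separation, ties, and rank oracle", {
  e <- evaluate_roc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(e$auc, 1)
  expect_equal(e$sensitivity, 1)
  expect_equal(e$specificity, 1)
  expect_equal(e$ppv, 1)
  expect_equal(e$npv, 1)
  expect_equal(evaluate_roc(rep(1, 8), c(0, 1, 0, 1, 1, 0, 0, 1))$auc, 0.5)
  withr::with_seed(240, {
    scores <- round(rnorm(50), 1)  # rounded scores force ties
    labels <- as.integer(runif(50) < 0.45)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    e2 <- evaluate_roc(scores, labels)
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    conc <- 0
    for (a in pos) for (b in neg)
      conc <- conc + (a > b) + 0.5 * (a == b)
    expect_equal(e2$auc, conc / (length(pos) * length(neg)))
    # AUC invariant under strictly monotone transforms of the scores
    e3 <- evaluate_roc(exp(2 * scores) - 3, labels)
    expect_equal(e3$auc, e2$auc)
  })
})

test_that("the Youden point maximizes sensitivity plus specificity", {
  withr::with_seed(241, {
    scores <- rnorm(60)
    labels <- as.integer(scores + rnorm(60) > 0)
    e <- evaluate_roc(scores, labels)
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    grid_thr <- sort(unique(c(scores - 1e-9, scores + 1e-9)))
    best <- max(vapply(grid_thr, function(t)
      mean(pos > t) + mean(neg <= t), numeric(1)))
    expect_equal(e$sensitivity + e$specificity, best, tolerance = 1e-9)
  })
})

test_that("identical paired models compare at p = 1", {
  e <- evaluate_roc(c(0.9, 0.7, 0.4, 0.2), c(1, 1, 0, 0))
  expect_equal(compare_auc(e, e)$p_value, 1)
})

test_that("an informative model beats noise in paired comparison", {
  rejections <- vapply(1:20, function(s) {
    withr::with_seed(250 + s, {
      n <- 300
      y <- rep(0:1, each = n / 2)
      sa <- y + rnorm(n, sd = 0.7)       # informative scores
      sb <- rnorm(n)                      # pure noise scores
      ea <- evaluate_roc(sa, y)
      eb <- evaluate_roc(sb, y)
      compare_auc(ea, eb)$p_value < 0.01
    })
  }, logical(1))
  expect_gte(mean(rejections), 0.9)
})

test_that("DeLong and bootstrap comparisons agree on a fixed toy", {
  withr::with_seed(260, {
    n <- 80
    y <- rep(0:1, each = n / 2)
    sa <- y + rnorm(n, sd = 1.1)
    sb <- 0.5 * y + rnorm(n, sd = 1.1)
    ea <- evaluate_roc(sa, y)
    eb <- evaluate_roc(sb, y)
    pd <- compare_auc(ea, eb, method = "delong")$p_value
    pb <- compare_auc(ea, eb, method = "bootstrap", n_boot = 2000)$p_value
    expect_lt(abs(pd - pb), 0.03)
  })
})

test_that("degenerate modeling inputs raise errors", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(svm_rfe_rank(x, rep(1, 10)), "single-class")
  expect_error(evaluate_roc(rnorm(5), rep(1, 5)), "single-class")
  e1 <- evaluate_roc(c(1, 2, 3, 4), c(0, 1, 0, 1))
  e2 <- evaluate_roc(c(1, 2, 3), c(0, 1, 0))
  expect_error(compare_auc(e1, e2), "paired")
})
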