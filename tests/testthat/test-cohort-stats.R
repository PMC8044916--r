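flagged_records <- function(n, imaging = 0, mp = 0, clinical = 0) {
  rec <- data.frame(id = sprintf("R%03d", seq_len(n)),
                    missing_imaging = FALSE, missing_mp = FALSE,
                    missing_clinical = FALSE)
  # flags are disjoint by construction, as in the study's accounting
  idx <- seq_len(imaging + mp + clinical)
  rec$missing_imaging[head(idx, imaging)] <- TRUE
  rec$missing_mp[idx[imaging + seq_len(mp)]] <- TRUE
  rec$missing_clinical[tail(idx, clinical)] <- TRUE
  rec
}

test_that("patient-selection accounting reproduces both study arms", {
  dev <- filter_cohort(flagged_records(96, imaging = 8, mp = 8,
                                       clinical = 19))
  expect_equal(dev$report$retained, 61)
  expect_equal(unname(dev$report$excluded), c(8, 8, 19))
  tst <- filter_cohort(flagged_records(78, imaging = 5, mp = 9,
                                       clinical = 11))
  expect_equal(tst$report$retained, 53)
  expect_equal(tst$report$initial - sum(tst$report$excluded),
               tst$report$retained)
})

test_that("overlapping flags count under the first applicable reason", {
  rec <- flagged_records(5)
  rec$missing_imaging[1] <- TRUE
  rec$missing_mp[1] <- TRUE       # same record: imaging wins
  rec$missing_mp[2] <- TRUE
  out <- filter_cohort(rec)
  expect_equal(unname(out$report$excluded), c(1, 1, 0))
  expect_equal(out$report$retained, 3)
})

test_that("MP dichotomization reproduces the cohort's response split", {
  grades <- rep(1:5, times = c(9, 21, 40, 10, 34))
  resp <- dichotomize_mp(grades)
  expect_equal(sum(resp), 44)
  expect_equal(sum(!resp), 70)
  expect_false(dichotomize_mp(3))         # boundary grade
  expect_true(all(dichotomize_mp(rep(5, 4))))
  expect_error(dichotomize_mp(c(2, NA)), "missing")
  expect_error(dichotomize_mp(0), "1..5")
})

test_that("group-comparison statistics match the published table", {
  menop <- rbind(dev = c(23, 38), test = c(23, 30))
  expect_lt(abs(chi2_yates_2x2(t(menop))$p_value - 0.670), 1e-3)
  famhist <- rbind(dev = c(45, 16), test = c(42, 11))
  expect_lt(abs(chi2_yates_2x2(t(famhist))$p_value - 0.642), 1e-3)
  subtypes <- rbind(dev = c(9, 30, 9, 13), test = c(3, 28, 11, 11))
  expect_lt(abs(pearson_chi2(subtypes)$p_value - 0.409), 1e-3)
  mp <- rbind(dev = c(6, 10, 24, 5, 16), test = c(3, 11, 16, 5, 18))
  expect_lt(abs(fisher_exact_2xk(mp)$p_value - 0.706), 1e-3)
})

test_that("chi-squared degenerates to zero on homogeneous tables", {
  res <- chi2_yates_2x2(matrix(10, 2, 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  even <- rbind(c(10, 20, 30), c(20, 40, 60))  # identical row proportions
  res2 <- pearson_chi2(even)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  expect_error(chi2_yates_2x2(rbind(c(0, 0), c(3, 5))), "margin")
})

test_that("Yates p agrees with a conditional Monte-Carlo oracle", {
  # The continuity correction is built to approximate the exact conditional
  # tail, so the oracle ranks margin-preserving null tables by their
  # absolute deviation from expectation (the exact-test ordering).
  withr::with_seed(300, {
    for (i in 1:3) {
      a <- rbinom(1, 200, 0.45)
      b <- rbinom(1, 200, 0.58)
      tab <- rbind(c(a, 200 - a), c(b, 200 - b))
      res <- chi2_yates_2x2(tab)
      null_tabs <- r2dtable(1e5, rowSums(tab), colSums(tab))
      e11 <- outer(rowSums(tab), colSums(tab))[1, 1] / sum(tab)
      dev_obs <- abs(tab[1, 1] - e11)
      p_mc <- mean(vapply(null_tabs, function(t) abs(t[1, 1] - e11),
                          numeric(1)) >= dev_obs - 1e-9)
      expect_lt(abs(res$p_value - p_mc), 0.02)
    }
  })
})

test_that("Pearson statistic matches term-by-term expansion on a 2x3 toy", {
  tab <- rbind(c(12, 7, 11), c(5, 9, 8))
  res <- pearson_chi2(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_equal(res$df, 2)
})

test_that("Fisher's exact test covers the enumerable edge cases", {
  expect_equal(fisher_exact_2xk(rbind(c(2, 1), c(1, 2)))$p_value, 1)
  expect_equal(fisher_exact_2xk(rbind(c(4, 6, 2), c(0, 0, 0)))$p_value, 1)
  # exact 2x2 equals the hypergeometric closed form: margins fix the
  # table given its first cell k (rows 10/10, first column 11)
  tab <- rbind(c(3, 7), c(8, 2))
  k <- 1:10
  probs <- dhyper(k, 10, 10, 11)
  obs <- dhyper(3, 10, 10, 11)
  manual <- sum(probs[probs <= obs + 1e-12])
  expect_equal(fisher_exact_2xk(tab)$p_value, manual, tolerance = 1e-9)
})

test_that("one-way ANOVA matches hand arithmetic and is calibrated", {
  same <- anova_oneway(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  toy <- anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(toy$statistic, 13.5, tolerance = 1e-9)
  withr::with_seed(310, {
    rejections <- vapply(1:2000, function(i) {
      v <- rnorm(100)
      anova_oneway(v, rep(c("a", "b"), each = 50))$p_value < 0.05
    }, logical(1))
    expect_gte(mean(rejections), 0.035)
    expect_lte(mean(rejections), 0.065)
  })
})

test_that("the expected-count rule selects the published tests", {
  subtypes <- rbind(dev = c(9, 30, 9, 13), test = c(3, 28, 11, 11))
  expect_equal(test_chooser(subtypes), "chi-squared")
  expect_gte(min(pearson_chi2(subtypes)$expected), 5)
  mp <- rbind(dev = c(6, 10, 24, 5, 16), test = c(3, 11, 16, 5, 18))
  expect_equal(test_chooser(mp), "fisher")
  expect_equal(test_chooser(matrix(100, 2, 2)), "chi-squared")
})

test_that("the cohort comparison table runs on generated records", {
  rec <- generate_cohort(sim_config(n = 114, seed = 2))
  tab <- cohort_comparison_table(rec)
  expect_equal(nrow(tab), 5)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_equal(tab$test[tab$variable == "age"], "anova")
})
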