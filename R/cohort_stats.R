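#' Apply patient-selection rules to cohort records
#'
#' Exclusion reasons are applied in a fixed order (missing imaging
#' sequences, then missing Miller-Payne outcome, then missing clinical
#' information); a record with several flags counts under the first
#' applicable reason. The report always balances:
#' retained + sum(excluded) = initial.
#'
#' @param records a data frame with logical columns `missing_imaging`,
#'   `missing_mp`, `missing_clinical`.
#' @return A list with `retained` (the filtered records) and `report`
#'   (an `exclusion_report`: initial, per-reason counts, retained).
#' @export
filter_cohort <- function(records) {
  stopifnot(all(c("missing_imaging", "missing_mp", "missing_clinical") %in%
                  names(records)))
  n0 <- nrow(records)
  reason <- rep(NA_character_, n0)
  reason[records$missing_imaging] <- "missing_imaging"
  reason[is.na(reason) & records$missing_mp] <- "missing_mp"
  reason[is.na(reason) & records$missing_clinical] <- "missing_clinical"
  keep <- is.na(reason)
  report <- structure(list(
    initial = n0,
    excluded = c(missing_imaging = sum(reason == "missing_imaging",
                                       na.rm = TRUE),
                 missing_mp = sum(reason == "missing_mp", na.rm = TRUE),
                 missing_clinical = sum(reason == "missing_clinical",
                                        na.rm = TRUE)),
    retained = sum(keep)), class = "exclusion_report")
  stopifnot(report$retained + sum(report$excluded) == report$initial)
  list(retained = records[keep, , drop = FALSE], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("initial %d -> retained %d (excluded: imaging %d, MP %d, clinical %d)\n",
              x$initial, x$retained, x$excluded["missing_imaging"],
              x$excluded["missing_mp"], x$excluded["missing_clinical"]))
  invisible(x)
}

#' Dichotomize Miller-Payne grades into response labels
#'
#' Grades 4 and 5 (over 90% cell loss, almost-pCR and pCR) are responders;
#' grades 1-3 are nonresponders.
#'
#' @param mp_grade integer vector of grades in 1..5 (no missing values).
#' @return Logical vector: TRUE = responder.
#' @export
dichotomize_mp <- function(mp_grade) {
  if (anyNA(mp_grade)) stop("missing Miller-Payne grade")
  if (!all(mp_grade %in% 1:5)) stop("MP grades must be in 1..5")
  mp_grade >= 4
}

#' Yates-corrected chi-squared test for a 2x2 table
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @return A list with `statistic`, `p_value`, `df`.
#' @export
chi2_yates_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin")
  ht <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Pearson chi-squared test for an RxC table (no continuity correction)
#'
#' @param table RxC matrix of nonnegative counts.
#' @return A list with `statistic`, `p_value`, `df`, `expected`.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), expected = ht$expected)
}

#' Fisher's exact test for a 2xK table
#'
#' Exact two-sided p by the probability-mass rule: the sum of the
#' probabilities of all margin-consistent tables no more probable than the
#' observed one (network enumeration).
#'
#' @param table 2xK matrix of nonnegative counts.
#' @return A list with `p_value`.
#' @export
fisher_exact_2xk <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2) stop("table must have 2 rows")
  if (sum(table) > 500)
    stop("table total too large for exact enumeration")
  ht <- stats::fisher.test(table, workspace = 2e7)
  list(p_value = ht$p.value)
}

#' One-way analysis of variance
#'
#' @param values numeric vector of the continuous variable.
#' @param groups factor or vector of group labels (>= 2 groups with >= 2
#'   values each).
#' @return A list with `statistic` (F), `p_value`, `df`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 values")
  if (all(vapply(split(values, groups), var, numeric(1)) == 0) &&
      var(vapply(split(values, groups), mean, numeric(1))) == 0)
    return(list(statistic = 0, p_value = 1,
                df = c(nlevels(groups) - 1, length(values) - nlevels(groups))))
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  list(statistic = s[["F value"]][1], p_value = s[["Pr(>F)"]][1],
       df = s[["Df"]])
}

#' Choose between chi-squared and Fisher's exact test
#'
#' Fisher's exact test is selected when any expected cell count under
#' independence is below 5, otherwise the chi-squared test.
#'
#' @param table contingency table of counts.
#' @return `"fisher"` or `"chi-squared"`.
#' @export
test_chooser <- function(table) {
  table <- as.matrix(table)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5)) "fisher" else "chi-squared"
}

#' Group-comparison table for a cohort (development vs testing arm)
#'
#' Compares age (ANOVA), menopausal status and family history (Yates
#' chi-squared on 2x2), molecular subtype and Miller-Payne grade (Pearson
#' chi-squared or Fisher's exact test, chosen by the expected-count rule).
#'
#' @param records cohort records with `arm`, `age`, `menopause`,
#'   `family_history`, `subtype`, `mp_grade` columns.
#' @return A data frame: variable, test used, p-value.
#' @export
cohort_comparison_table <- function(records) {
  arm <- factor(records$arm, levels = c("development", "testing"))
  row_for <- function(variable, values) {
    tab <- t(table(arm, values))
    if (nrow(tab) == 2 && ncol(tab) == 2) {
      list(test = "chi2_yates", p = chi2_yates_2x2(tab)$p_value)
    } else if (test_chooser(t(tab)) == "fisher") {
      list(test = "fisher_exact", p = fisher_exact_2xk(t(tab))$p_value)
    } else {
      list(test = "pearson_chi2", p = pearson_chi2(tab)$p_value)
    }
  }
  men <- row_for("menopause", records$menopause)
  fam <- row_for("family_history", records$family_history)
  sub <- row_for("subtype", records$subtype)
  mp <- row_for("mp_grade", records$mp_grade)
  age <- anova_oneway(records$age, arm)
  data.frame(
    variable = c("age", "menopause", "family_history", "subtype",
                 "mp_grade"),
    test = c("anova", men$test, fam$test, sub$test, mp$test),
    p_value = c(age$p_value, men$p, fam$p, sub$p, mp$p))
}
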