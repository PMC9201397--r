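# Comparison of misclassified (false-negative) against correctly
# classified (true-positive) reference-low subjects on covariates such as
# BMI and fat percentage, per sex, by two-sample t-test.

#' Two-sample t statistic from group summaries
#'
#' Closed-form two-sided two-sample t-test from group sizes, means and SDs,
#' without the raw data. `variant = "pooled"` uses the pooled-variance
#' (Student) form with `n1 + n2 - 2` degrees of freedom; `"welch"` the
#' unequal-variance form with Welch-Satterthwaite degrees of freedom.
#'
#' @param n1,mean1,sd1 First group's size, mean and SD.
#' @param n2,mean2,sd2 Second group's size, mean and SD.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return List with `t`, `df`, `p_value`.
#' @export
t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                           variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) {
    t <- if (mean1 == mean2) 0 else sign(mean1 - mean2) * Inf
  } else {
    t <- (mean1 - mean2) / se
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p_value = p)
}

#' Compare misclassified against correctly classified low-mass subjects
#'
#' Within one sex, derives the lowest-quintile reference cut-off for the
#' given measure, splits the reference-low subjects into false negatives
#' (candidate called them normal) and true positives (candidate agreed),
#' and compares the two groups on each covariate with a two-sample t-test.
#' Refuses with a named error when either group has fewer than 2 usable
#' members — with very few misclassified subjects the comparison cannot be
#' performed.
#'
#' @param cohort A `cohort`.
#' @param measure Measure defining the classification (default `"ALM"`).
#' @param sex `"female"` or `"male"` (the comparison is within one sex
#'   because cut-offs are sex-specific).
#' @param covariates Character vector of cohort column names to compare
#'   (default BMI and fat percentage).
#' @param variant t-test variant: `"welch"` (default) or `"pooled"`.
#' @param p,type Quantile convention for the cut-off, see
#'   [quintile_cutoff()].
#' @return Data frame with one row per covariate: group sizes, means, SDs
#'   (group A = false negatives, group B = true positives), `t_statistic`,
#'   `df`, `p_value`, `variant`.
#' @export
compare_misclassified <- function(cohort, measure = "ALM",
                                  sex = c("female", "male"),
                                  covariates = c("bmi", "fat_pct"),
                                  variant = c("welch", "pooled"),
                                  p = 0.20, type = 7) {
  stopifnot(inherits(cohort, "cohort"))
  sex <- match.arg(sex)
  variant <- match.arg(variant)
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov) > 0) {
    stop("covariate(s) not present in cohort: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  ser <- paired_series(cohort, measure, sex)
  cut <- quintile_cutoff(ser$reference, p = p, type = type)
  ref_low <- classify_low(ser$reference, cut)
  cand_low <- classify_low(ser$candidate, cut)
  fn_ids <- ser$subject_ids[ref_low & !cand_low]
  tp_ids <- ser$subject_ids[ref_low & cand_low]
  if (length(fn_ids) < 2) {
    stop("insufficient group: only ", length(fn_ids),
         " misclassified (false-negative) ", sex,
         " subject(s); comparison cannot be performed", call. = FALSE)
  }
  if (length(tp_ids) < 2) {
    stop("insufficient group: only ", length(tp_ids),
         " correctly classified (true-positive) ", sex, " subject(s)",
         call. = FALSE)
  }
  rows <- lapply(covariates, function(cov) {
    a <- cohort[[cov]][match(fn_ids, cohort$subject_id)]
    b <- cohort[[cov]][match(tp_ids, cohort$subject_id)]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      stop("insufficient non-missing values of '", cov,
           "' in the ", if (length(a) < 2) "false-negative" else "true-positive",
           " group", call. = FALSE)
    }
    tt <- t_from_summary(length(a), mean(a), stats::sd(a),
                         length(b), mean(b), stats::sd(b), variant)
    data.frame(covariate = cov,
               group_a_n = length(a), group_a_mean = mean(a),
               group_a_sd = stats::sd(a),
               group_b_n = length(b), group_b_mean = mean(b),
               group_b_sd = stats::sd(b),
               t_statistic = tt$t, df = tt$df, p_value = tt$p_value,
               variant = variant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- list(false_negative = fn_ids, true_positive = tp_ids)
  out
}
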