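# Method-comparison agreement statistics for paired device measurements:
# mean bias, percent bias, MAE, the within-5% accuracy partition,
# Bland-Altman limits of agreement and the proportional-bias regression
# (difference on mean of methods), plus the sex-interaction test that
# decides whether analyses are stratified.

.measures <- c("ALM", "ALMi", "FFM", "FFMi")
.strata <- c("all", "male", "female")

#' Extract an aligned reference/candidate series for one measure and stratum
#'
#' Index measures (`ALMi`, `FFMi`) are computed per subject as mass divided
#' by height squared (kg/m^2).
#'
#' @param cohort A `cohort`.
#' @param measure One of `"ALM"`, `"ALMi"`, `"FFM"`, `"FFMi"`.
#' @param stratum One of `"all"`, `"male"`, `"female"`.
#' @return A `paired_series`: aligned `reference` and `candidate` vectors
#'   with `subject_ids`, plus `measure`, `stratum` and `unit`.
#' @export
paired_series <- function(cohort, measure = c("ALM", "ALMi", "FFM", "FFMi"),
                          stratum = c("all", "male", "female")) {
  stopifnot(inherits(cohort, "cohort"))
  measure <- match.arg(measure)
  stratum <- match.arg(stratum)
  rows <- .stratum_rows(cohort, stratum)
  if (sum(rows) < 2) {
    stop("insufficient data: stratum '", stratum, "' has ", sum(rows),
         " subject(s), need >= 2", call. = FALSE)
  }
  sub <- cohort[rows, , drop = FALSE]
  h2 <- sub$height_m^2
  vals <- switch(measure,
    ALM  = list(ref = sub$alm_dxa_kg,       cand = sub$alm_bia_kg,       unit = "kg"),
    ALMi = list(ref = sub$alm_dxa_kg / h2,  cand = sub$alm_bia_kg / h2,  unit = "kg/m2"),
    FFM  = list(ref = sub$ffm_dxa_kg,       cand = sub$ffm_bia_kg,       unit = "kg"),
    FFMi = list(ref = sub$ffm_dxa_kg / h2,  cand = sub$ffm_bia_kg / h2,  unit = "kg/m2"))
  structure(list(measure = measure, stratum = stratum, unit = vals$unit,
                 subject_ids = sub$subject_id,
                 reference = vals$ref, candidate = vals$cand),
            class = "paired_series")
}

.check_series <- function(series) {
  stopifnot(inherits(series, "paired_series"))
  n <- length(series$reference)
  if (n < 2 || length(series$candidate) != n) {
    stop("paired series needs aligned vectors of length >= 2", call. = FALSE)
  }
  if (anyNA(series$reference) || anyNA(series$candidate)) {
    stop("paired series must not contain missing values", call. = FALSE)
  }
  n
}

#' Mean bias and percent bias of the candidate device
#'
#' Bias is the per-subject candidate-minus-reference difference; percent
#' bias is `100 * (candidate - reference) / reference` per subject
#' (reference-denominator, mean-of-ratios), each summarized as mean and
#' sample SD (n - 1 denominator).
#'
#' @param series A [paired_series()].
#' @return List with `n`, `ref_mean`, `ref_sd`, `cand_mean`, `cand_sd`,
#'   `bias_mean`, `bias_sd`, `bias_pct_mean`, `bias_pct_sd`.
#' @export
bias_summary <- function(series) {
  n <- .check_series(series)
  if (any(series$reference <= 0)) {
    stop("percent bias requires positive reference values", call. = FALSE)
  }
  d <- series$candidate - series$reference
  pct <- 100 * d / series$reference
  list(n = n,
       ref_mean = mean(series$reference), ref_sd = stats::sd(series$reference),
       cand_mean = mean(series$candidate), cand_sd = stats::sd(series$candidate),
       bias_mean = mean(d), bias_sd = stats::sd(d),
       bias_pct_mean = mean(pct), bias_pct_sd = stats::sd(pct))
}

#' Accuracy partition at the 5% band
#'
#' A candidate value within 5% of the reference (ratio in `[0.95, 1.05]`,
#' boundaries inclusive) is accurate; strictly below 95% of the reference is
#' an under-prediction; strictly above 105% an over-prediction. The three
#' percentages partition the cohort and sum to 100 exactly (as fractions).
#'
#' @param series A [paired_series()]; reference values must be positive.
#' @param band Half-width of the accuracy band as a proportion (default 0.05).
#' @return Named numeric vector `c(pct_accurate, pct_under, pct_over)`.
#' @export
accuracy_classification <- function(series, band = 0.05) {
  n <- .check_series(series)
  if (any(series$reference <= 0)) {
    stop("accuracy classification requires positive reference values",
         call. = FALSE)
  }
  ratio <- series$candidate / series$reference
  under <- ratio < 1 - band
  over <- ratio > 1 + band
  c(pct_accurate = 100 * sum(!under & !over) / n,
    pct_under = 100 * sum(under) / n,
    pct_over = 100 * sum(over) / n)
}

#' Mean absolute error between the two devices
#'
#' @param series A [paired_series()].
#' @return Mean of `|candidate - reference|`, in the units of the measure.
#' @export
mean_absolute_error <- function(series) {
  .check_series(series)
  mean(abs(series$candidate - series$reference))
}

#' Limits of agreement from a bias summary
#'
#' `bias_mean +/- mult * bias_sd`, the Bland-Altman limits.
#'
#' @param bias_mean Mean difference (candidate - reference).
#' @param bias_sd SD of the differences.
#' @param mult Multiplier, 1.96 by convention.
#' @return Named numeric vector `c(loa_low, loa_high)`.
#' @export
loa_limits <- function(bias_mean, bias_sd, mult = 1.96) {
  c(loa_low = bias_mean - mult * bias_sd,
    loa_high = bias_mean + mult * bias_sd)
}

# Simple-regression internals via closed-form sums so degenerate inputs
# (zero residual or zero outcome variance) are handled explicitly.
.ols_slope <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("regression degenerate: zero variance in predictor",
                     call. = FALSE)
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  intercept <- my - slope * mx
  rss <- max(syy - slope * sxy, 0)
  df <- n - 2
  if (syy == 0) {             # constant outcome: flat line, no evidence
    return(list(slope = 0, intercept = my, slope_se = 0, t = 0,
                p_value = 1, r_squared = 0, df = df))
  }
  se <- sqrt(rss / df / sxx)
  if (se == 0) {              # exact nonzero linear relation
    p <- if (slope == 0) 1 else 0
    tstat <- if (slope == 0) 0 else Inf
  } else {
    tstat <- slope / se
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  list(slope = slope, intercept = intercept, slope_se = se, t = tstat,
       p_value = p, r_squared = 1 - rss / syy, df = df)
}

#' Bland-Altman analysis: limits of agreement and proportional bias
#'
#' Limits of agreement are `bias_mean +/- mult * bias_sd`. Proportional bias
#' is the ordinary least-squares regression of the per-subject difference
#' (candidate - reference) on the per-subject mean of the two devices; a
#' slope with `p < 0.05` (two-sided t-test) flags proportional bias.
#'
#' @param series A [paired_series()] with at least 3 pairs.
#' @param mult Limits-of-agreement multiplier (default 1.96).
#' @return List with `bias_mean`, `bias_sd`, `loa_low`, `loa_high`, and
#'   `prop_bias` (list: `slope`, `intercept`, `slope_se`, `p_value`,
#'   `r_squared`, `significant`).
#' @export
bland_altman <- function(series, mult = 1.96) {
  n <- .check_series(series)
  if (n < 3) stop("Bland-Altman regression needs >= 3 pairs", call. = FALSE)
  d <- series$candidate - series$reference
  m <- (series$candidate + series$reference) / 2
  bias_mean <- mean(d)
  bias_sd <- stats::sd(d)
  loa <- loa_limits(bias_mean, bias_sd, mult)
  fit <- .ols_slope(m, d)
  list(bias_mean = bias_mean, bias_sd = bias_sd,
       loa_low = unname(loa["loa_low"]), loa_high = unname(loa["loa_high"]),
       prop_bias = list(slope = fit$slope, intercept = fit$intercept,
                        slope_se = fit$slope_se, p_value = fit$p_value,
                        r_squared = fit$r_squared,
                        significant = fit$p_value < 0.05))
}

#' Full agreement summary for one paired series
#'
#' Combines [bias_summary()], [accuracy_classification()],
#' [mean_absolute_error()] and [bland_altman()] into one record; this is
#' one column of one panel of the validity report.
#'
#' @param series A [paired_series()] with at least 3 pairs.
#' @param mult Limits-of-agreement multiplier.
#' @return An `agreement_summary` list.
#' @export
agreement_summary <- function(series, mult = 1.96) {
  bs <- bias_summary(series)
  acc <- accuracy_classification(series)
  ba <- bland_altman(series, mult)
  structure(c(list(measure = series$measure, stratum = series$stratum,
                   unit = series$unit),
              bs,
              list(mae = mean_absolute_error(series),
                   pct_accurate = unname(acc["pct_accurate"]),
                   pct_under = unname(acc["pct_under"]),
                   pct_over = unname(acc["pct_over"]),
                   loa_low = ba$loa_low, loa_high = ba$loa_high,
                   prop_bias = ba$prop_bias)),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement_summary> %s, %s (n = %d, %s)\n",
              x$measure, x$stratum, x$n, x$unit))
  cat(sprintf("  bias %.2f +/- %.2f (%s)  [%.1f%% +/- %.1f%%]\n",
              x$bias_mean, x$bias_sd, x$unit, x$bias_pct_mean, x$bias_pct_sd))
  cat(sprintf("  MAE %.2f; accurate/under/over %.1f/%.1f/%.1f%%\n",
              x$mae, x$pct_accurate, x$pct_under, x$pct_over))
  cat(sprintf("  LoA [%.2f, %.2f]; prop. bias slope %.3f (p = %.3g)\n",
              x$loa_low, x$loa_high, x$prop_bias$slope, x$prop_bias$p_value))
  invisible(x)
}

#' Sex-interaction test deciding stratification
#'
#' Fits a linear model of the reference value on the candidate value, a sex
#' indicator and their product; the product term's p-value measures whether
#' the candidate-to-reference relation differs by sex. Stratified analysis
#' is indicated when `p < threshold` (0.10 by convention).
#'
#' @param cohort A `cohort` with at least 3 subjects of each sex.
#' @param measure One of `"ALM"`, `"ALMi"`, `"FFM"`, `"FFMi"`.
#' @param threshold Stratification threshold on the interaction p-value.
#' @return List with `measure`, `interaction_p`, `stratify`, `threshold`.
#'   `interaction_p` is `NA` (and `stratify` `FALSE`) when the model is
#'   singular, e.g. when the two devices agree exactly.
#' @export
sex_interaction_test <- function(cohort, measure = c("ALM", "ALMi", "FFM", "FFMi"),
                                 threshold = 0.10) {
  stopifnot(inherits(cohort, "cohort"))
  measure <- match.arg(measure)
  n_m <- sum(cohort$sex == "male")
  n_f <- sum(cohort$sex == "female")
  if (n_m < 3 || n_f < 3) {
    stop("insufficient data: sex-interaction test needs >= 3 subjects of ",
         "each sex (have ", n_m, " male, ", n_f, " female)", call. = FALSE)
  }
  s <- paired_series(cohort, measure, "all")
  sex <- factor(cohort$sex, levels = .sexes)
  fit <- stats::lm(s$reference ~ s$candidate * sex)
  # Degenerate case: the devices agree (near-)exactly, the model is a
  # perfect fit and the interaction t-statistic is meaningless.
  tss <- sum((s$reference - mean(s$reference))^2)
  if (tss == 0 || sum(stats::resid(fit)^2) < 1e-12 * tss) {
    return(list(measure = measure, interaction_p = NA_real_,
                stratify = FALSE, threshold = threshold))
  }
  coefs <- stats::coef(summary(fit))
  term <- grep(":", rownames(coefs), value = TRUE)
  p <- if (length(term) == 1 && !is.na(coefs[term, "Pr(>|t|)"])) {
    unname(coefs[term, "Pr(>|t|)"])
  } else {
    NA_real_
  }
  list(measure = measure, interaction_p = p,
       stratify = isTRUE(p < threshold), threshold = threshold)
}
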