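# Low-muscle-mass classification: sex-specific lowest-quintile cut-offs
# derived from the reference device, confusion tables for the candidate
# device, and prevalence at the fixed EWGSOP2 ALM-index cut-offs.

#' Lowest-quintile cut-off for one sex
#'
#' The 20th percentile of the reference-device values, used as a proxy
#' cut-off for low muscle mass. Default convention is linear interpolation
#' between order statistics at index `h = p * (n - 1)` (quantile type 7);
#' the convention is configurable because published analyses rarely name
#' theirs and conventions can differ by up to one order-statistic gap.
#'
#' @param values Numeric vector of reference values for one sex (n >= 5).
#' @param p Quantile level, default 0.20 (lowest quintile).
#' @param type Quantile algorithm type passed to [stats::quantile()].
#' @return The cut-off value (scalar).
#' @export
quintile_cutoff <- function(values, p = 0.20, type = 7) {
  if (anyNA(values)) stop("cut-off derivation requires complete values",
                          call. = FALSE)
  if (length(values) < 5) {
    stop("insufficient data: need >= 5 values to derive a quintile cut-off",
         call. = FALSE)
  }
  unname(stats::quantile(values, probs = p, type = type, names = FALSE))
}

#' Classify values as low muscle mass
#'
#' Strictly below the cut-off is low; a value exactly at the cut-off is
#' normal (strict `<`, so ties at the cut-off go to normal).
#'
#' @param value Numeric vector.
#' @param cutoff Scalar cut-off.
#' @return Logical vector, `TRUE` for low.
#' @export
classify_low <- function(value, cutoff) value < cutoff

.confusion <- function(ref_low, cand_low) {
  c(tp = sum(ref_low & cand_low), fn = sum(ref_low & !cand_low),
    fp = sum(!ref_low & cand_low), tn = sum(!ref_low & !cand_low))
}

#' Diagnostic cross table for low muscle mass
#'
#' Derives the sex-specific lowest-quintile cut-off from the reference
#' device, classifies both devices' values against that same cut-off, and
#' tallies the confusion table with the reference classification as truth.
#' For `sex = "all"` the per-sex confusion counts are pooled (summed) before
#' computing sensitivity and specificity, which is the only construction
#' consistent with sex-specific cut-offs.
#'
#' @param cohort A `cohort` with >= 5 subjects per relevant sex.
#' @param measure One of `"ALM"`, `"ALMi"`, `"FFM"`, `"FFMi"`.
#' @param sex `"male"`, `"female"`, or `"all"` (pooled).
#' @param p,type Quantile level and algorithm, see [quintile_cutoff()].
#' @return A `cutoff_classification`: `measure`, `sex`, `cutoff` (named
#'   per-sex vector when pooled), counts `tp`, `fn`, `fp`, `tn`, and
#'   `sensitivity` and `specificity` in percent.
#' @export
diagnostic_table <- function(cohort, measure = c("ALM", "ALMi", "FFM", "FFMi"),
                             sex = c("all", "male", "female"),
                             p = 0.20, type = 7) {
  stopifnot(inherits(cohort, "cohort"))
  measure <- match.arg(measure)
  sex <- match.arg(sex)
  sexes <- if (sex == "all") .sexes else sex
  counts <- c(tp = 0L, fn = 0L, fp = 0L, tn = 0L)
  cutoffs <- numeric(0)
  for (s in sexes) {
    ser <- paired_series(cohort, measure, s)
    cut <- quintile_cutoff(ser$reference, p = p, type = type)
    cutoffs[s] <- cut
    counts <- counts + .confusion(classify_low(ser$reference, cut),
                                  classify_low(ser$candidate, cut))
  }
  sens <- 100 * counts[["tp"]] / (counts[["tp"]] + counts[["fn"]])
  spec <- 100 * counts[["tn"]] / (counts[["tn"]] + counts[["fp"]])
  structure(list(measure = measure, sex = sex,
                 cutoff = if (sex == "all") cutoffs else unname(cutoffs),
                 tp = counts[["tp"]], fn = counts[["fn"]],
                 fp = counts[["fp"]], tn = counts[["tn"]],
                 sensitivity = sens, specificity = spec),
            class = "cutoff_classification")
}

#' @export
print.cutoff_classification <- function(x, ...) {
  cat(sprintf("<cutoff_classification> %s, %s\n", x$measure, x$sex))
  if (length(x$cutoff) == 1) {
    cat(sprintf("  cut-off %.2f\n", x$cutoff))
  } else {
    cat(sprintf("  cut-offs male %.2f, female %.2f\n",
                x$cutoff[["male"]], x$cutoff[["female"]]))
  }
  cat(sprintf("  tp %d, fn %d, fp %d, tn %d\n", x$tp, x$fn, x$fp, x$tn))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Prevalence of low ALM-index at the fixed EWGSOP2 cut-offs
#'
#' Per-sex percentage of subjects whose reference ALM-index (ALM divided by
#' height squared) falls strictly below the fixed EWGSOP2 cut-off:
#' 7.0 kg/m^2 for men, 6.0 kg/m^2 for women.
#'
#' @param cohort A `cohort`.
#' @param cutoffs Named vector of ALMi cut-offs in kg/m^2.
#' @return Data frame with one row per sex: `n`, `n_low`, `prevalence_pct`
#'   (exact) and `prevalence_display` (nearest integer percent).
#' @export
prevalence_ewgsop2 <- function(cohort, cutoffs = c(male = 7.0, female = 6.0)) {
  stopifnot(inherits(cohort, "cohort"))
  if (anyNA(cohort$height_m)) stop("height required for ALM-index prevalence",
                                   call. = FALSE)
  almi <- cohort$alm_dxa_kg / cohort$height_m^2
  out <- lapply(.sexes, function(s) {
    rows <- cohort$sex == s
    n <- sum(rows)
    n_low <- sum(classify_low(almi[rows], cutoffs[[s]]))
    pct <- if (n > 0) 100 * n_low / n else NA_real_
    data.frame(sex = s, n = n, n_low = n_low, prevalence_pct = pct,
               prevalence_display = round(pct), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
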