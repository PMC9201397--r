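# Pipeline orchestration and the tabular validity report: all four
# measures (ALM, ALMi, FFM, FFMi) by all three strata (all, male, female),
# with the sex-interaction decision, quintile classification, and the
# misclassified-subject comparison.

#' Read a flat key-value configuration file
#'
#' Accepts `key: value` or `key = value` lines (YAML-style flat mapping);
#' blank lines and `#` comments are ignored. Values are coerced to logical
#' (`true`/`false`) or numeric where possible, otherwise kept as strings.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln, call. = FALSE)
    key <- m[2]
    val <- trimws(m[3])
    if (tolower(val) %in% c("true", "yes")) {
      val <- TRUE
    } else if (tolower(val) %in% c("false", "no")) {
      val <- FALSE
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) val <- num
    }
    out[[key]] <- val
  }
  out
}

.pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full device-validation pipeline
#'
#' Loads (or generates) a cohort, runs the sex-interaction tests, computes
#' agreement statistics for every measure and stratum, derives quintile
#' cut-offs with sensitivity/specificity per measure and sex (plus pooled),
#' and attempts the misclassified-subject comparison per sex. All strata
#' are always emitted, for consistency, regardless of the interaction
#' decision (which is recorded alongside).
#'
#' @param config Named list (or file parsed by [read_config()]). Either
#'   `input` (a cohort CSV path) or `synthetic = TRUE` must be given.
#'   Synthetic runs accept the [synthetic_params()] scalar fields
#'   (`n_male`, `n_female`, `bias_add`, `bias_slope`, `noise_sd`, `seed`).
#'   Other recognized keys: `measures` (comma-separated subset of
#'   ALM,ALMi,FFM,FFMi), `quantile_type`, `ttest_variant`, `height_unit`,
#'   `loa_mult`.
#' @return A `validity_report` list: `cohort`, `interaction`, `agreement`
#'   (per measure x stratum), `classification` (per measure x sex/pooled),
#'   `subgroup` (per sex; an error message string where the comparison was
#'   refused), and `meta`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  measures <- .measures
  if (!is.null(config$measures)) {
    measures <- trimws(strsplit(as.character(config$measures), ",")[[1]])
    bad <- setdiff(measures, .measures)
    if (length(bad) > 0) stop("unknown measure(s): ",
                              paste(bad, collapse = ", "), call. = FALSE)
  }
  qtype <- if (is.null(config$quantile_type)) 7 else as.integer(config$quantile_type)
  variant <- if (is.null(config$ttest_variant)) "welch" else config$ttest_variant
  loa_mult <- if (is.null(config$loa_mult)) 1.96 else as.numeric(config$loa_mult)

  co <- .pipeline_stage("load", {
    if (!is.null(config$input)) {
      read_cohort(config$input,
                  height_unit = if (is.null(config$height_unit)) "m"
                                else config$height_unit,
                  quiet = TRUE)
    } else if (isTRUE(config$synthetic)) {
      keys <- c("n_male", "n_female", "bias_add", "bias_slope",
                "noise_sd", "seed")
      args <- config[intersect(keys, names(config))]
      generate_cohort(do.call(synthetic_params, args))
    } else {
      stop("config must name an input cohort file ('input') or request ",
           "synthetic data ('synthetic: true')")
    }
  })

  interaction <- .pipeline_stage("interaction", {
    res <- lapply(measures, function(m) sex_interaction_test(co, m))
    names(res) <- measures
    res
  })

  agreement <- .pipeline_stage("agreement", {
    res <- lapply(measures, function(m) {
      per <- lapply(.strata, function(s)
        agreement_summary(paired_series(co, m, s), mult = loa_mult))
      names(per) <- .strata
      per
    })
    names(res) <- measures
    res
  })

  classification <- .pipeline_stage("classification", {
    res <- lapply(measures, function(m) {
      per <- lapply(.strata, function(s)
        diagnostic_table(co, m, s, type = qtype))
      names(per) <- .strata
      per
    })
    names(res) <- measures
    res
  })

  subgroup <- .pipeline_stage("subgroup", {
    res <- lapply(c("female", "male"), function(s) {
      tryCatch(compare_misclassified(co, measure = "ALM", sex = s,
                                     variant = variant, type = qtype),
               error = function(e) conditionMessage(e))
    })
    names(res) <- c("female", "male")
    res
  })

  structure(list(
    cohort = co,
    interaction = interaction,
    agreement = agreement,
    classification = classification,
    subgroup = subgroup,
    meta = list(provenance = attr(co, "provenance"),
                n = nrow(co),
                n_male = sum(co$sex == "male"),
                n_female = sum(co$sex == "female"),
                measures = measures,
                quantile_type = qtype,
                ttest_variant = variant,
                loa_mult = loa_mult,
                seed = config$seed)
  ), class = "validity_report")
}

# Tidy long-format table of every reported number: one row per
# measure x stratum x statistic. The text renderer formats from this same
# table, so every number in the text report appears in the CSV.
.report_tidy <- function(report) {
  rows <- list()
  add <- function(measure, stratum, statistic, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, stratum = stratum, statistic = statistic,
      value = as.numeric(value), stringsAsFactors = FALSE)
  }
  for (m in names(report$agreement)) {
    for (s in names(report$agreement[[m]])) {
      a <- report$agreement[[m]][[s]]
      for (f in c("n", "ref_mean", "ref_sd", "cand_mean", "cand_sd",
                  "bias_mean", "bias_sd", "bias_pct_mean", "bias_pct_sd",
                  "mae", "pct_accurate", "pct_under", "pct_over",
                  "loa_low", "loa_high")) {
        add(m, s, f, a[[f]])
      }
      add(m, s, "prop_slope", a$prop_bias$slope)
      add(m, s, "prop_intercept", a$prop_bias$intercept)
      add(m, s, "prop_slope_se", a$prop_bias$slope_se)
      add(m, s, "prop_p", a$prop_bias$p_value)
      cl <- report$classification[[m]][[s]]
      add(m, s, "sensitivity", cl$sensitivity)
      add(m, s, "specificity", cl$specificity)
      for (f in c("tp", "fn", "fp", "tn")) add(m, s, f, cl[[f]])
      if (s %in% c("male", "female")) add(m, s, "cutoff", cl$cutoff)
    }
  }
  for (m in names(report$interaction)) {
    it <- report$interaction[[m]]
    add(m, "all", "interaction_p", it$interaction_p)
    add(m, "all", "stratify", as.numeric(it$stratify))
  }
  for (s in names(report$subgroup)) {
    sg <- report$subgroup[[s]]
    if (is.data.frame(sg)) {
      for (i in seq_len(nrow(sg))) {
        pre <- paste0("subgroup_", sg$covariate[i], "_")
        add("ALM", s, paste0(pre, "fn_n"), sg$group_a_n[i])
        add("ALM", s, paste0(pre, "fn_mean"), sg$group_a_mean[i])
        add("ALM", s, paste0(pre, "fn_sd"), sg$group_a_sd[i])
        add("ALM", s, paste0(pre, "tp_n"), sg$group_b_n[i])
        add("ALM", s, paste0(pre, "tp_mean"), sg$group_b_mean[i])
        add("ALM", s, paste0(pre, "tp_sd"), sg$group_b_sd[i])
        add("ALM", s, paste0(pre, "t"), sg$t_statistic[i])
        add("ALM", s, paste0(pre, "p"), sg$p_value[i])
      }
    }
  }
  do.call(rbind, rows)
}

.fmt1 <- function(x) formatC(x, format = "f", digits = 1)
.fmt2 <- function(x) formatC(x, format = "f", digits = 2)

# One panel (stratum) of the text report across measures.
.render_panel <- function(report, stratum) {
  measures <- report$meta$measures
  a <- lapply(measures, function(m) report$agreement[[m]][[stratum]])
  cl <- lapply(measures, function(m) report$classification[[m]][[stratum]])
  names(a) <- names(cl) <- measures
  n <- a[[1]]$n
  title <- switch(stratum,
                  all = sprintf("All subjects (N = %d)", n),
                  male = sprintf("Males (N = %d)", n),
                  female = sprintf("Females (N = %d)", n))
  head_units <- vapply(measures, function(m)
    sprintf("%s (%s)", m, a[[m]]$unit), character(1))
  row <- function(label, vals) {
    sprintf("%-28s %s", label,
            paste(formatC(vals, width = 16), collapse = " "))
  }
  g <- function(fun) vapply(measures, function(m) fun(a[[m]], cl[[m]]),
                            character(1))
  lines <- c(
    sprintf("== %s ==", title),
    row("", head_units),
    row("Reference mean (SD)", g(function(x, y)
      sprintf("%s (%s)", .fmt1(x$ref_mean), .fmt1(x$ref_sd)))),
    row("Candidate mean (SD)", g(function(x, y)
      sprintf("%s (%s)", .fmt1(x$cand_mean), .fmt1(x$cand_sd)))),
    row("Mean bias (SD)", g(function(x, y)
      sprintf("%s (%s)", .fmt2(x$bias_mean), .fmt2(x$bias_sd)))),
    row("Mean bias % (SD)", g(function(x, y)
      sprintf("%s (%s)", .fmt1(x$bias_pct_mean), .fmt1(x$bias_pct_sd)))),
    row("Mean abs. error", g(function(x, y) .fmt1(x$mae))),
    row("Accurate predictions (%)", g(function(x, y) .fmt1(x$pct_accurate))),
    row("Under predictions (%)", g(function(x, y) .fmt1(x$pct_under))),
    row("Over predictions (%)", g(function(x, y) .fmt1(x$pct_over))),
    row("Limits of agreement", g(function(x, y)
      sprintf("%s to %s", .fmt1(x$loa_low), .fmt1(x$loa_high)))),
    row("Prop. bias slope (p)", g(function(x, y)
      sprintf("%s (%s)", .fmt2(x$prop_bias$slope),
              formatC(x$prop_bias$p_value, format = "g", digits = 2)))),
    row("Sensitivity (%)", g(function(x, y) .fmt1(y$sensitivity))),
    row("Specificity (%)", g(function(x, y) .fmt1(y$specificity)))
  )
  if (stratum %in% c("male", "female")) {
    lines <- c(lines, row("Cut-off (reference)",
                          g(function(x, y) .fmt1(y$cutoff))))
  }
  lines
}

#' Render a validity report as text or tidy CSV
#'
#' The text format mirrors the conventional validity-table layout: one
#' panel per stratum (all, male, female) with one column per measure;
#' biases are shown at 2 decimals, other statistics at 1. The CSV format is
#' tidy (one row per measure x stratum x statistic) at full precision; the
#' text is formatted from the same table, so every number in the text
#' appears in the CSV.
#'
#' @param report A `validity_report` from [run_pipeline()].
#' @param format `"text"` or `"csv"`.
#' @param out_dir Optional directory; when given, writes `report.txt` or
#'   `report.csv` there and returns the path.
#' @return Character vector of lines (`"text"`) or a data frame (`"csv"`);
#'   the output file path when `out_dir` is given.
#' @export
render_report <- function(report, format = c("text", "csv"), out_dir = NULL) {
  stopifnot(inherits(report, "validity_report"))
  format <- match.arg(format)
  if (format == "csv") {
    tidy <- .report_tidy(report)
    if (is.null(out_dir)) return(tidy)
    path <- file.path(out_dir, "report.csv")
    utils::write.csv(tidy, path, row.names = FALSE)
    return(invisible(path))
  }
  lines <- c(
    sprintf("Device-validation report: %s", report$meta$provenance),
    sprintf("N = %d (%d male, %d female)", report$meta$n,
            report$meta$n_male, report$meta$n_female),
    ""
  )
  for (m in report$meta$measures) {
    it <- report$interaction[[m]]
    lines <- c(lines, sprintf(
      "Sex interaction (%s): p = %s -> %s", m,
      if (is.na(it$interaction_p)) "NA"
      else formatC(it$interaction_p, format = "g", digits = 3),
      if (isTRUE(it$stratify)) "stratify" else "no stratification required"))
  }
  lines <- c(lines, "",
             "(all strata reported regardless, for consistency)", "")
  for (s in .strata) lines <- c(lines, .render_panel(report, s), "")
  for (s in names(report$subgroup)) {
    sg <- report$subgroup[[s]]
    lines <- c(lines, sprintf("Misclassified vs correctly classified (%s, ALM):", s))
    if (is.data.frame(sg)) {
      for (i in seq_len(nrow(sg))) {
        lines <- c(lines, sprintf(
          "  %s: %s (%s) vs %s (%s), t = %s, p = %s [%s]",
          sg$covariate[i],
          .fmt1(sg$group_a_mean[i]), .fmt1(sg$group_a_sd[i]),
          .fmt1(sg$group_b_mean[i]), .fmt1(sg$group_b_sd[i]),
          .fmt2(sg$t_statistic[i]),
          formatC(sg$p_value[i], format = "g", digits = 3),
          sg$variant[i]))
      }
    } else {
      lines <- c(lines, paste0("  not performed: ", sg))
    }
  }
  if (is.null(out_dir)) return(lines)
  path <- file.path(out_dir, "report.txt")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.validity_report <- function(x, ...) {
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}
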