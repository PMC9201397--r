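# Canonical subject-level schema shared by every downstream module.
#
# One row per subject: sex, age, height, and paired appendicular-lean-mass
# (ALM) and fat-free-mass (FFM) measurements from a reference device (DXA)
# and a candidate device (BIA), plus optional weight, BMI and fat%.

.cohort_required <- c(
  "subject_id", "sex", "age", "height_m",
  "alm_dxa_kg", "alm_bia_kg", "ffm_dxa_kg", "ffm_bia_kg"
)
.cohort_optional <- c("weight_kg", "bmi", "fat_pct")
.cohort_numeric <- c(
  "age", "height_m", "alm_dxa_kg", "alm_bia_kg",
  "ffm_dxa_kg", "ffm_bia_kg", "weight_kg", "bmi", "fat_pct"
)

#' Canonical cohort column names
#'
#' Column names of the flat subject table every operation in the package
#' consumes. Required columns: `subject_id`, `sex`, `age`, `height_m`,
#' `alm_dxa_kg`, `alm_bia_kg`, `ffm_dxa_kg`, `ffm_bia_kg`. Optional:
#' `weight_kg`, `bmi`, `fat_pct`. Heights are in meters, masses in kg.
#'
#' @return Character vector of canonical column names, required first.
#' @export
cohort_columns <- function() c(.cohort_required, .cohort_optional)

.parse_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("m", "male")] <- "male"
  out[x %in% c("f", "female")] <- "female"
  out
}

# Per-row validation. Returns a character vector: NA for valid rows,
# otherwise a semicolon-joined reason string.
.row_problems <- function(df) {
  n <- nrow(df)
  reasons <- vector("list", n)
  add <- function(bad, msg) {
    bad <- which(bad)
    for (i in bad) reasons[[i]] <<- c(reasons[[i]], msg)
  }
  add(is.na(df$subject_id) | !nzchar(trimws(as.character(df$subject_id))),
      "missing subject_id")
  add(is.na(df$sex), "unrecognized sex (expected m/male/f/female)")
  for (col in c("age", "height_m", "alm_dxa_kg", "alm_bia_kg",
                "ffm_dxa_kg", "ffm_bia_kg")) {
    add(is.na(df[[col]]), paste0("missing or non-numeric ", col))
  }
  add(!is.na(df$height_m) & df$height_m <= 0, "height_m must be > 0")
  for (col in c("alm_dxa_kg", "alm_bia_kg", "ffm_dxa_kg", "ffm_bia_kg",
                "weight_kg")) {
    add(!is.na(df[[col]]) & df[[col]] <= 0, paste0(col, " must be > 0"))
  }
  ok_alm <- function(alm, ffm) is.na(alm) | is.na(ffm) | alm < ffm
  add(!ok_alm(df$alm_dxa_kg, df$ffm_dxa_kg), "alm_dxa_kg not < ffm_dxa_kg")
  add(!ok_alm(df$alm_bia_kg, df$ffm_bia_kg), "alm_bia_kg not < ffm_bia_kg")
  vapply(reasons, function(r) {
    if (is.null(r)) NA_character_ else paste(r, collapse = "; ")
  }, character(1))
}

.new_cohort <- function(df, provenance, exclusions = NULL) {
  rownames(df) <- NULL
  structure(df,
            provenance = provenance,
            exclusions = exclusions,
            class = c("cohort", "data.frame"))
}

#' Construct a cohort from an in-memory data frame
#'
#' Strict constructor: every row must satisfy the subject-record invariants
#' (positive height and masses, ALM strictly below FFM on each device, sex
#' one of male/female). Use [read_cohort()] for the lenient path that
#' excludes and reports invalid rows instead of failing.
#'
#' @param df Data frame with the columns of [cohort_columns()] (optional
#'   columns may be absent; they are added as `NA`).
#' @param provenance Free-text label recording where the rows came from.
#' @return A `cohort` object (a data frame with canonical columns).
#' @export
cohort <- function(df, provenance = "in-memory") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.cohort_required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(.cohort_optional, names(df))) df[[col]] <- NA_real_
  extra <- setdiff(names(df), cohort_columns())
  df_can <- df[, cohort_columns()]
  df_can$subject_id <- as.character(df_can$subject_id)
  df_can$sex <- .parse_sex(df_can$sex)
  for (col in .cohort_numeric) {
    df_can[[col]] <- suppressWarnings(as.numeric(df_can[[col]]))
  }
  problems <- .row_problems(df_can)
  if (any(!is.na(problems))) {
    bad <- which(!is.na(problems))
    stop("invalid subject record(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": ", problems[bad[1]], call. = FALSE)
  }
  if (anyDuplicated(df_can$subject_id)) {
    stop("duplicate subject_id values", call. = FALSE)
  }
  for (col in extra) df_can[[col]] <- df[[col]]
  .new_cohort(df_can, provenance)
}

#' Read a subject-level cohort table from delimited text
#'
#' Reads a CSV (or other delimited) file with a header row, maps columns to
#' the canonical schema, and validates each row. Rows failing validation
#' (missing or non-numeric required values, non-positive masses, ALM not
#' below FFM, unrecognized sex) are excluded and reported, mirroring the
#' usual exclusion of unusable device assessments; structurally valid rows
#' are retained. A missing required *column* is a schema error.
#'
#' @param path Path to the delimited text file.
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(alm_dxa_kg = "ALM.DXA")`.
#' @param height_unit Unit of the height column: `"m"` (default) or `"cm"`
#'   (converted to meters on read).
#' @param sep Field separator, default `","`.
#' @param exclusions_to Optional path; when given, excluded rows are written
#'   there as a sidecar CSV with their input row number and reason.
#' @param quiet Suppress the exclusion-count message.
#' @return A `cohort`. The excluded rows (with `input_row` and `reason`)
#'   are attached as `attr(, "exclusions")`.
#' @seealso [write_cohort()], [cohort()]
#' @export
read_cohort <- function(path, col_map = NULL, height_unit = c("m", "cm"),
                        sep = ",", exclusions_to = NULL, quiet = FALSE) {
  height_unit <- match.arg(height_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (!is.null(col_map)) {
    for (canonical in names(col_map)) {
      src <- col_map[[canonical]]
      if (!src %in% names(raw)) {
        stop("column mapping refers to absent column: ", src, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  missing_cols <- setdiff(.cohort_required, names(raw))
  if (length(missing_cols) > 0) {
    stop("input lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(.cohort_optional, names(raw))) raw[[col]] <- NA
  df <- raw[, cohort_columns()]
  df$subject_id <- as.character(df$subject_id)
  df$sex <- .parse_sex(df$sex)
  for (col in .cohort_numeric) {
    v <- trimws(df[[col]])
    v[v == ""] <- NA
    df[[col]] <- suppressWarnings(as.numeric(v))
  }
  if (height_unit == "cm") df$height_m <- df$height_m / 100
  problems <- .row_problems(df)
  keep <- is.na(problems)
  exclusions <- data.frame(
    input_row = which(!keep),
    subject_id = df$subject_id[!keep],
    reason = problems[!keep],
    stringsAsFactors = FALSE
  )
  kept <- df[keep, , drop = FALSE]
  if (nrow(kept) == 0) {
    stop("no usable rows in ", path, " (", nrow(df), " rows read, all excluded)",
         call. = FALSE)
  }
  dup <- duplicated(kept$subject_id)
  if (any(dup)) stop("duplicate subject_id values in ", path, call. = FALSE)
  if (!quiet && nrow(exclusions) > 0) {
    message(nrow(exclusions), " of ", nrow(df),
            " rows excluded (missing or invalid values); ",
            nrow(kept), " subjects retained")
  }
  if (!is.null(exclusions_to) && nrow(exclusions) > 0) {
    utils::write.csv(exclusions, exclusions_to, row.names = FALSE)
  }
  .new_cohort(kept, provenance = path, exclusions = exclusions)
}

#' Write a cohort to CSV
#'
#' Writes the canonical columns (plus any extra columns carried along) as
#' RFC-4180-style CSV. Round-trips through [read_cohort()] field-for-field
#' for finite decimal values.
#'
#' @param cohort A non-empty `cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  if (nrow(cohort) == 0) stop("refusing to write an empty cohort", call. = FALSE)
  df <- as.data.frame(cohort)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Subset a cohort to one stratum ("all", "male", "female").
.stratum_rows <- function(cohort, stratum) {
  if (stratum == "all") rep(TRUE, nrow(cohort)) else cohort$sex == stratum
}

#' @export
print.cohort <- function(x, ...) {
  n_m <- sum(x$sex == "male")
  n_f <- sum(x$sex == "female")
  cat(sprintf("<cohort> %d subjects (%d male, %d female)\n",
              nrow(x), n_m, n_f))
  cat("  provenance:", attr(x, "provenance"), "\n")
  excl <- attr(x, "exclusions")
  if (!is.null(excl) && nrow(excl) > 0) {
    cat("  excluded on read:", nrow(excl), "row(s)\n")
  }
  invisible(x)
}
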