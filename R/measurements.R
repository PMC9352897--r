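# Per-subject measurement tables: one row per subject, body-composition
# ratios (%) per modality. Missing readings (e.g. subjects without a BIA
# exam) are NA, never zero.

RATIO_COLUMNS <- c("bfr_bca", "bfr_dxa", "bfr_bia", "smr_bca", "smr_bia")
MEASUREMENT_COLUMNS <- c("subject_id", "sex", "age", "height", "weight",
                         "bmi", RATIO_COLUMNS)

#' Validate a per-subject measurement table
#'
#' Checks the contract every downstream stage relies on: unique subject ids,
#' sex coded `male`/`female`, ratio columns (when present) within
#' \eqn{[0, 100]}, and BMI consistent with weight/height to 0.1 kg/m2
#' wherever all three are recorded.
#'
#' @param table A data.frame with columns `subject_id`, `sex`, `age`,
#'   `height` (cm), `weight` (kg), `bmi` (kg/m2) and any of
#'   `bfr_bca`, `bfr_dxa`, `bfr_bia`, `smr_bca`, `smr_bia` (percent).
#' @return The validated data.frame (character/numeric types coerced).
#' @export
validate_measurements <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    validation_error("measurement table must be a non-empty data.frame")
  }
  needed <- c("subject_id", "sex", "age", "height", "weight", "bmi")
  miss <- setdiff(needed, names(table))
  if (length(miss) > 0) {
    validation_error(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  table$subject_id <- as.character(table$subject_id)
  if (anyDuplicated(table$subject_id)) {
    validation_error("duplicate subject_id values")
  }
  table$sex <- as.character(table$sex)
  bad_sex <- !is.na(table$sex) & !table$sex %in% c("male", "female")
  if (any(bad_sex)) {
    validation_error(sprintf("sex must be 'male' or 'female' (row %d)",
                             which(bad_sex)[1]))
  }
  for (col in c("age", "height", "weight", "bmi", RATIO_COLUMNS)) {
    if (col %in% names(table)) table[[col]] <- as.numeric(table[[col]])
  }
  for (col in RATIO_COLUMNS) {
    if (!col %in% names(table)) next
    v <- table[[col]]
    bad <- !is.na(v) & (v < 0 | v > 100)
    if (any(bad)) {
      validation_error(sprintf(
        "%s = %g outside [0, 100] in row %d (subject %s)",
        col, v[which(bad)[1]], which(bad)[1], table$subject_id[which(bad)[1]]))
    }
  }
  ok <- !is.na(table$bmi) & !is.na(table$weight) & !is.na(table$height)
  if (any(ok)) {
    implied <- table$weight[ok] / (table$height[ok] / 100)^2
    off <- abs(implied - table$bmi[ok]) > 0.1
    if (any(off)) {
      row <- which(ok)[which(off)[1]]
      validation_error(sprintf(
        "bmi inconsistent with weight/height in row %d (subject %s): %0.2f vs %0.2f",
        row, table$subject_id[row], table$bmi[row],
        implied[which(off)[1]]))
    }
  }
  table
}

#' Read a per-subject measurement table from CSV
#'
#' Empty cells and `"NA"` are read as missing; the table is validated with
#' [validate_measurements].
#'
#' @param path Path to a CSV file with a header row.
#' @return A validated data.frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) input_format_error(sprintf("file not found: %s", path))
  table <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA")),
    error = function(e) input_format_error(
      sprintf("cannot parse '%s' as CSV: %s", path, conditionMessage(e))))
  validate_measurements(table)
}

#' Write a measurement table to CSV
#'
#' Missing values are written as empty cells so the file round-trips through
#' [read_measurements].
#'
#' @param table A measurement data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}
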