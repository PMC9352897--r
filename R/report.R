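# Cohort description and study assembly: BMI grouping on half-open
# intervals, group-wise mean +/- SD summaries, and the full study report
# (summary + every pairwise comparison in every stratification + a
# normality screen).

BMI_GROUP_LABELS <- c("underweight", "healthy", "overweight", "obese")

#' Assign BMI groups
#'
#' Half-open intervals on the WHO cut points: `[18.5, 25)` healthy,
#' `[25, 30)` overweight, `>= 30` obese, `< 18.5` underweight.
#'
#' @param bmi Numeric vector of BMI values (kg/m2), all positive.
#' @param cut_points Strictly increasing cut points, default
#'   `c(18.5, 25, 30)`.
#' @return Factor with levels underweight/healthy/overweight/obese.
#' @export
assign_bmi_group <- function(bmi, cut_points = c(18.5, 25, 30)) {
  if (is.unsorted(cut_points, strictly = TRUE) || length(cut_points) != 3) {
    validation_error("cut_points must be 3 strictly increasing values")
  }
  bmi <- as.numeric(bmi)
  if (any(!is.na(bmi) & bmi <= 0)) {
    validation_error("bmi must be positive")
  }
  cut(bmi, breaks = c(0, cut_points, Inf), right = FALSE,
      labels = BMI_GROUP_LABELS)
}

SUMMARY_VARIABLES <- c("age", "weight", "height", "bmi",
                       "bfr_bca", "bfr_dxa", "bfr_bia", "smr_bca", "smr_bia")

#' Summarise a cohort by BMI group
#'
#' Mean, sample (n-1) SD and n per BMI group and variable, with sex counts —
#' the conventional patient-characteristics table. Missing values are
#' excluded per variable; a single observation reports its value with SD
#' `NA`.
#'
#' @param table Measurement data.frame.
#' @param cut_points BMI cut points, as in [assign_bmi_group].
#' @return Object of class `cohort_summary`: data.frame `stats` (group,
#'   variable, n, mean, sd), data.frame `sex_counts`, and `n_total`.
#' @export
summarize_cohort <- function(table, cut_points = c(18.5, 25, 30)) {
  table <- validate_measurements(table)
  grp <- assign_bmi_group(table$bmi, cut_points)
  present <- intersect(SUMMARY_VARIABLES, names(table))
  rows <- list()
  for (g in levels(grp)) {
    in_g <- !is.na(grp) & grp == g
    if (!any(in_g)) next
    for (v in present) {
      vals <- table[[v]][in_g]
      vals <- vals[!is.na(vals)]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, variable = v, n = length(vals),
        mean = if (length(vals) > 0) mean(vals) else NA_real_,
        sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  stats_df <- do.call(rbind, rows)
  sex_counts <- as.data.frame(table(group = grp[!is.na(grp)],
                                    sex = table$sex[!is.na(grp)]),
                              stringsAsFactors = FALSE)
  sex_counts <- sex_counts[sex_counts$Freq > 0 |
                             sex_counts$group %in% unique(as.character(grp)), ]
  structure(
    list(stats = stats_df, sex_counts = sex_counts, n_total = nrow(table),
         cut_points = cut_points),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, digits = 2, ...) {
  cat(sprintf("Cohort summary (n = %d)\n", x$n_total))
  df <- x$stats
  df$mean_sd <- sprintf("%.*f +/- %s", digits, df$mean,
                        ifelse(is.na(df$sd), "NA", sprintf("%.*f", digits, df$sd)))
  wide <- stats::reshape(df[, c("group", "variable", "mean_sd")],
                         idvar = "variable", timevar = "group",
                         direction = "wide")
  names(wide) <- sub("^mean_sd\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

STUDY_COMPARISONS <- list(
  list(metric = "bfr", pair = c("bca", "dxa")),
  list(metric = "bfr", pair = c("bca", "bia")),
  list(metric = "bfr", pair = c("dxa", "bia")),
  list(metric = "smr", pair = c("bca", "bia"))
)

#' Run the full study analysis
#'
#' Assembles the cohort summary, every available pairwise method comparison
#' (BFR: CT-based vs DXA, vs BIA, DXA vs BIA; SMR: CT-based vs BIA) in each
#' stratification (overall, by BMI group, by sex), and a Shapiro-Wilk
#' normality screen per modality, metric and BMI group. Comparisons whose
#' columns are absent from the table are skipped. Deterministic given the
#' table.
#'
#' @param table Measurement data.frame.
#' @param config A [bca_config].
#' @return Object of class `bca_study`.
#' @export
run_study <- function(table, config = bca_config()) {
  table <- validate_measurements(table)
  summary <- summarize_cohort(table, cut_points = config$bmi_cut_points)

  comparisons <- list()
  for (cmp in STUDY_COMPARISONS) {
    cols <- paste(cmp$metric, cmp$pair, sep = "_")
    if (!all(cols %in% names(table))) next
    if (all(is.na(table[[cols[1]]])) || all(is.na(table[[cols[2]]]))) next
    for (strat in c("none", "bmi", "sex")) {
      key <- sprintf("%s_%s_vs_%s_by_%s", cmp$metric, cmp$pair[1],
                     cmp$pair[2], strat)
      comparisons[[key]] <- withCallingHandlers(
        compare_methods(table, metric = cmp$metric, pair = cmp$pair,
                        stratify = strat, config = config),
        warning = function(w) invokeRestart("muffleWarning")
      )
    }
  }

  grp <- assign_bmi_group(table$bmi, config$bmi_cut_points)
  normality <- list()
  for (col in intersect(RATIO_COLUMNS, names(table))) {
    for (g in levels(grp)) {
      v <- table[[col]][!is.na(grp) & grp == g]
      v <- v[!is.na(v)]
      if (length(v) >= 3 && stats::var(v) > 0) {
        sw <- shapiro_wilk(v)
        normality[[sprintf("%s_%s", col, g)]] <-
          list(variable = col, group = g, W = sw$W, p = sw$p, n = sw$n)
      }
    }
  }

  structure(
    list(summary = summary, comparisons = comparisons, normality = normality,
         config = list(
           windows = unclass(config$windows),
           air_scope = config$air_scope,
           bmi_cut_points = config$bmi_cut_points,
           ci_level = config$ci_level
         )),
    class = "bca_study"
  )
}

#' @export
print.bca_study <- function(x, ...) {
  print(x$summary)
  cat("\nPairwise agreement (overall strata):\n")
  for (nm in names(x$comparisons)) {
    if (!grepl("_by_none$", nm)) next
    print(x$comparisons[[nm]])
  }
  if (length(x$normality) > 0) {
    pvals <- vapply(x$normality, `[[`, numeric(1), "p")
    cat(sprintf("\nShapiro-Wilk screen: %d tests, p in [%.3g, %.3g]\n",
                length(pvals), min(pvals), max(pvals)))
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits `study.json` (machine-readable, byte-stable for identical studies)
#' plus tab-separated tables `summary.tsv` and `agreement.tsv`.
#'
#' @param study A `bca_study` from [run_study].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "bca_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  agree <- do.call(rbind, lapply(names(study$comparisons), function(nm) {
    s <- summary(study$comparisons[[nm]])
    s$stratify <- study$comparisons[[nm]]$stratify
    s
  }))
  json <- list(
    config = study$config,
    cohort_summary = study$summary$stats,
    sex_counts = study$summary$sex_counts,
    agreement = agree,
    normality = unname(study$normality)
  )
  jsonlite::write_json(json, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  utils::write.table(study$summary$stats, file.path(dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(agree)) {
    utils::write.table(agree, file.path(dir, "agreement.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
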