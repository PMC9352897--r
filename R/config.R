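# Analysis configuration: HU windows, air-exclusion scope, BMI cut points
# and the CI level, overridable from a YAML key-value file.

#' Analysis configuration
#'
#' @param windows [hu_windows] to classify with.
#' @param tissue_map Region/HU-class map ([region_tissue_map]).
#' @param air_scope `"all"` or `"abdominal_cavity"`; see [classify_tissues].
#' @param bmi_cut_points BMI group cut points in kg/m2, strictly increasing.
#' @param ci_level Confidence level for agreement intervals.
#' @param ccc_ci Report a confidence interval for Lin's coefficient?
#' @return A list of class `bca_config`.
#' @export
bca_config <- function(windows = hu_windows(), tissue_map = region_tissue_map(),
                       air_scope = "all",
                       bmi_cut_points = c(18.5, 25, 30),
                       ci_level = 0.95, ccc_ci = TRUE) {
  if (is.unsorted(bmi_cut_points, strictly = TRUE)) {
    validation_error("bmi_cut_points must be strictly increasing")
  }
  if (ci_level <= 0 || ci_level >= 1) validation_error("ci_level must be in (0, 1)")
  structure(
    list(windows = windows, tissue_map = tissue_map,
         air_scope = match.arg(air_scope, c("all", "abdominal_cavity")),
         bmi_cut_points = as.numeric(bmi_cut_points),
         ci_level = ci_level, ccc_ci = isTRUE(ccc_ci)),
    class = "bca_config"
  )
}

#' Read a configuration file
#'
#' YAML key-value overrides on top of the defaults. Recognised keys:
#' `windows.adipose`, `windows.muscle`, `windows.air` (each `[low, high]`),
#' `air_scope`, `bmi_cut_points`, `ci_level`, `ccc_ci`.
#'
#' @param path YAML file path.
#' @return A `bca_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) input_format_error(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  base <- bca_config()
  win <- list(adipose = c(-190, -30), muscle = c(-29, 150), air = c(-1024, -800))
  if (!is.null(raw$windows)) {
    for (nm in intersect(names(raw$windows), names(win))) {
      win[[nm]] <- as.numeric(raw$windows[[nm]])
    }
  }
  bca_config(
    windows = do.call(hu_windows, win),
    air_scope = raw$air_scope %||% base$air_scope,
    bmi_cut_points = raw$bmi_cut_points %||% base$bmi_cut_points,
    ci_level = raw$ci_level %||% base$ci_level,
    ccc_ci = raw$ccc_ci %||% base$ccc_ci
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
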