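# Tissue quantification: subclassify voxels by Hounsfield-unit window within
# semantic body regions, then reduce to compartment volumes and the two
# ratio biomarkers (BFR, SMR).
#
# HU windows follow the established adipose/muscle thresholds: [-190, -30] HU
# adipose, [-29, 150] HU muscle, with [-1024, -800] HU counted as air and
# excluded from the ratio denominator. The printed windows are contiguous at
# integer HU; for non-integer values the adipose/muscle boundary is split at
# the midpoint -29.5.

TISSUE_CLASSES <- c("background", "SAT", "VAT", "IMAT", "EAT", "PAT",
                    "muscle", "bone", "excluded_air", "unclassified")
ADIPOSE_CLASSES <- c("SAT", "VAT", "IMAT", "EAT", "PAT")

#' Hounsfield-unit classification windows
#'
#' @param adipose,muscle,air Length-2 numeric `(low, high)` window bounds in
#'   HU, inclusive. Defaults: adipose \eqn{[-190, -30]}, muscle
#'   \eqn{[-29, 150]}, air \eqn{[-1024, -800]} (the denominator exclusion).
#' @return A list of class `hu_windows`.
#' @export
hu_windows <- function(adipose = c(-190, -30), muscle = c(-29, 150),
                       air = c(-1024, -800)) {
  w <- list(adipose = as.numeric(adipose), muscle = as.numeric(muscle),
            air = as.numeric(air))
  for (nm in names(w)) {
    if (length(w[[nm]]) != 2 || anyNA(w[[nm]]) || w[[nm]][1] > w[[nm]][2]) {
      validation_error(sprintf("window '%s' must be (low, high) with low <= high", nm))
    }
  }
  # pairwise disjoint (as closed intervals up to the float midpoint split)
  ivs <- rbind(w$air, w$adipose, w$muscle)
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  if (any(ivs[-1, 1] < ivs[-nrow(ivs), 2])) {
    validation_error("HU windows must be pairwise disjoint")
  }
  structure(w, class = "hu_windows")
}

# HU -> window class on possibly non-integer values. The adipose and muscle
# windows are contiguous at integer HU; the float boundary sits at the
# midpoint between -30 and -29.
hu_class <- function(hu, windows = hu_windows()) {
  split_am <- (windows$adipose[2] + windows$muscle[1]) / 2
  cls <- rep("other", length(hu))
  cls[hu >= windows$air[1] & hu <= windows$air[2]] <- "air"
  cls[hu >= windows$adipose[1] & hu < split_am] <- "adipose"
  cls[hu >= split_am & hu <= windows$muscle[2]] <- "muscle"
  cls
}

#' Default region x HU-class to tissue map
#'
#' Total function over (region, HU class): adipose-window voxels are
#' subclassified by the region they fall in (subcutaneous tissue to SAT,
#' abdominal cavity to VAT, muscle to IMAT, pericardium to EAT, mediastinum
#' outside the pericardium to PAT); muscle-window voxels count as muscle only
#' inside the muscle region; bone is taken from the bone region label rather
#' than an HU window; air-window voxels are excluded everywhere (see
#' `air_scope` in [classify_tissues]). Everything else is unclassified —
#' including adipose-window voxels in the thoracic cavity or bone, which none
#' of the five adipose compartments cover.
#'
#' @return data.frame with columns `region`, `hu_class`, `tissue`.
#' @export
region_tissue_map <- function() {
  regions <- setdiff(names(region_legend()), "background")
  grid <- expand.grid(region = regions,
                      hu_class = c("air", "adipose", "muscle", "other"),
                      stringsAsFactors = FALSE)
  tissue <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r <- grid$region[i]; h <- grid$hu_class[i]
    tissue[i] <- if (h == "air") "excluded_air"
    else if (h == "adipose") switch(r,
      subcutaneous_tissue = "SAT", abdominal_cavity = "VAT",
      muscle = "IMAT", pericardium = "EAT", mediastinum = "PAT",
      "unclassified")
    else if (h == "muscle") switch(r, muscle = "muscle", bone = "bone",
                                   "unclassified")
    else switch(r, bone = "bone", "unclassified")
  }
  grid$tissue <- tissue
  grid
}

validate_tissue_map <- function(map, legend) {
  need <- c("region", "hu_class", "tissue")
  if (!is.data.frame(map) || !all(need %in% names(map))) {
    validation_error("tissue map needs columns region, hu_class, tissue")
  }
  if (!all(map$tissue %in% TISSUE_CLASSES)) {
    validation_error("tissue map contains unknown tissue class")
  }
  regions <- setdiff(names(legend), "background")
  full <- expand.grid(region = regions,
                      hu_class = c("air", "adipose", "muscle", "other"),
                      stringsAsFactors = FALSE)
  key <- paste(map$region, map$hu_class)
  if (anyDuplicated(key)) validation_error("duplicate (region, hu_class) in map")
  missing <- setdiff(paste(full$region, full$hu_class), key)
  if (length(missing) > 0) {
    validation_error(sprintf("tissue map not total; missing: %s",
                             paste(missing, collapse = "; ")))
  }
  bad <- map$hu_class == "adipose" &
    !map$tissue %in% c(ADIPOSE_CLASSES, "unclassified", "excluded_air")
  if (any(bad)) {
    validation_error("adipose HU class may map only to adipose tissues or unclassified")
  }
  map
}

#' Classify voxels into tissue compartments
#'
#' Combines the HU window of each voxel with its semantic region label:
#' background region stays background; air-window HU is excluded from the
#' body denominator; adipose- and muscle-window HU are subclassified through
#' the region/tissue map.
#'
#' @param ct A [ct_volume].
#' @param regions A [region_labels] volume of the same shape.
#' @param windows An [hu_windows] object.
#' @param map Region x HU-class map, as from [region_tissue_map].
#' @param air_scope `"all"` (default) excludes air-window voxels in every
#'   region; `"abdominal_cavity"` restricts the exclusion to the abdominal
#'   cavity, with air-window voxels elsewhere falling through the map's
#'   `other` class.
#' @return An object of class `tissue_labels`: integer array coded by
#'   `levels` (the tissue class names), plus the spacing carried over.
#' @export
classify_tissues <- function(ct, regions, windows = hu_windows(),
                             map = region_tissue_map(),
                             air_scope = c("all", "abdominal_cavity")) {
  stopifnot(inherits(ct, "ct_volume"), inherits(regions, "region_labels"))
  air_scope <- match.arg(air_scope)
  check_same_shape(ct, regions)
  map <- validate_tissue_map(map, regions$legend)

  hu <- as.vector(ct$values)
  cls <- hu_class(hu, windows)
  if (air_scope == "abdominal_cavity") {
    # outside the abdominal cavity, air-window HU is treated as out-of-window
    code_abd <- regions$legend[["abdominal_cavity"]]
    cls[cls == "air" & as.vector(regions$labels) != code_abd] <- "other"
  }

  region_name <- names(regions$legend)[match(as.vector(regions$labels),
                                             unname(regions$legend))]
  tissue <- rep(NA_character_, length(hu))
  bg <- region_name == "background"
  tissue[bg] <- "background"
  key <- paste(region_name[!bg], cls[!bg])
  map_key <- paste(map$region, map$hu_class)
  tissue[!bg] <- map$tissue[match(key, map_key)]

  idx <- match(tissue, TISSUE_CLASSES) - 1L
  labels <- array(idx, dim = ct$shape)
  structure(
    list(labels = labels, levels = TISSUE_CLASSES, spacing = ct$spacing,
         shape = ct$shape),
    class = "tissue_labels"
  )
}

#' @export
print.tissue_labels <- function(x, ...) {
  cat(sprintf("Tissue labels: %s voxels\n", paste(x$shape, collapse = " x ")))
  print(tissue_counts(x))
  invisible(x)
}

tissue_counts <- function(tl) {
  stopifnot(inherits(tl, "tissue_labels"))
  tab <- tabulate(as.vector(tl$labels) + 1L, nbins = length(tl$levels))
  names(tab) <- tl$levels
  tab
}

#' Reduce a tissue-label volume to a body-composition report
#'
#' Counts voxels per tissue class, converts to litres using the voxel volume,
#' and computes the two ratio biomarkers over the body denominator
#' (non-background voxels minus excluded air):
#' \deqn{BFR = 100 (SAT + VAT + IMAT + EAT + PAT) / body,\quad
#'       SMR = 100 \cdot muscle / body.}
#'
#' @param labels A `tissue_labels` volume from [classify_tissues].
#' @param spacing Voxel spacing in mm (defaults to the spacing carried on
#'   `labels`).
#' @return An object of class `bca_report`: voxel counts, volumes in litres,
#'   the denominator `body_voxels`, `bfr` and `smr` in percent, and the
#'   spacing used.
#' @export
quantify_tissues <- function(labels, spacing = labels$spacing) {
  stopifnot(inherits(labels, "tissue_labels"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    validation_error("spacing must be 3 positive lengths (mm)")
  }
  counts <- tissue_counts(labels)
  non_bg <- sum(counts) - counts[["background"]]
  body <- non_bg - counts[["excluded_air"]]
  if (body <= 0) {
    degenerate_input_error("no body voxels after air exclusion; cannot form ratios")
  }
  voxel_l <- prod(spacing) / 1e6  # mm^3 -> L
  adipose <- sum(counts[ADIPOSE_CLASSES])
  structure(
    list(
      voxel_counts = as.list(counts),
      volumes_l = as.list(counts * voxel_l),
      body_voxels = as.integer(body),
      bfr = 100 * adipose / body,
      smr = 100 * counts[["muscle"]] / body,
      spacing = spacing
    ),
    class = "bca_report"
  )
}

#' @export
print.bca_report <- function(x, digits = 2, ...) {
  cat("Body composition report\n")
  cat(sprintf("  body voxels (denominator): %d\n", x$body_voxels))
  cat(sprintf("  BFR: %.*f %%   SMR: %.*f %%\n", digits, x$bfr, digits, x$smr))
  cat(sprintf("  voxel spacing: %s mm\n", paste(format(x$spacing), collapse = " x ")))
  tab <- data.frame(
    tissue = names(x$voxel_counts),
    voxels = unlist(x$voxel_counts, use.names = FALSE),
    litres = round(unlist(x$volumes_l, use.names = FALSE), 3)
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Run the full per-scan body-composition analysis
#'
#' Reads a CT volume and its co-registered region segmentation, classifies
#' tissues and quantifies them. Deterministic: identical inputs yield an
#' identical report.
#'
#' @param ct_path Path to the CT NIfTI file.
#' @param seg_path Path to the region-label NIfTI file.
#' @param legend Region legend (name to code), default [region_legend].
#' @param config A [bca_config] list overriding windows / air scope.
#' @return A `bca_report`.
#' @export
run_bca <- function(ct_path, seg_path, legend = region_legend(),
                    config = bca_config()) {
  ct <- read_ct_volume(ct_path)
  regions <- read_region_labels(seg_path, legend = legend)
  labels <- classify_tissues(ct, regions, windows = config$windows,
                             map = config$tissue_map,
                             air_scope = config$air_scope)
  quantify_tissues(labels)
}

#' Serialise a body-composition report to JSON
#'
#' @param report A `bca_report`.
#' @param path Output path; the JSON is byte-stable for identical reports.
#' @return `path`, invisibly.
#' @export
write_bca_report <- function(report, path) {
  stopifnot(inherits(report, "bca_report"))
  out <- list(
    voxel_counts = report$voxel_counts,
    volumes_l = report$volumes_l,
    body_voxels = report$body_voxels,
    bfr_percent = report$bfr,
    smr_percent = report$smr,
    spacing_mm = report$spacing
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
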