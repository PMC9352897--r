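# Volumetric containers and NIfTI I/O.
#
# A ct_volume is a plain 3-D numeric array of Hounsfield units plus the voxel
# spacing in mm; a region_labels volume is the co-registered categorical field
# of semantic body regions produced by an upstream segmentation. The two are
# assumed co-registered voxel-for-voxel (no resampling is performed here).

# 12-bit CT convention; the air-exclusion window's floor (-1024) sets the low end.
HU_MIN <- -1024
HU_MAX <- 3071

#' Construct a CT volume
#'
#' Bundles a 3-D array of Hounsfield-unit (HU) values with its voxel spacing.
#' Values are clamped to the 12-bit CT range \eqn{[-1024, 3071]}.
#'
#' @param values 3-D numeric array of HU values.
#' @param spacing Numeric vector of length 3: voxel edge lengths in mm
#'   (defaults to 5 mm isotropic, a common whole-body PET/CT reconstruction).
#' @param clamp Clamp values into \eqn{[-1024, 3071]}? Default `TRUE`.
#' @return An object of class `ct_volume`: a list with elements `values`,
#'   `spacing` and `shape`.
#' @examples
#' vol <- ct_volume(array(0, dim = c(4, 4, 4)), spacing = c(2, 2, 5))
#' vol$shape
#' @export
ct_volume <- function(values, spacing = c(5, 5, 5), clamp = TRUE) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    validation_error("`values` must be a 3-D array")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0)) {
    validation_error("`spacing` must be 3 positive voxel edge lengths (mm)")
  }
  storage.mode(values) <- "double"
  if (anyNA(values)) validation_error("HU values must not contain NA")
  if (clamp) {
    values[values < HU_MIN] <- HU_MIN
    values[values > HU_MAX] <- HU_MAX
  }
  structure(
    list(values = values, spacing = spacing, shape = dim(values)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf(
    "CT volume: %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
    paste(x$shape, collapse = " x "),
    paste(format(x$spacing), collapse = " x "),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Default legend of semantic body regions
#'
#' Region codes produced by the upstream segmentation. Background is always
#' code 0; the remaining codes cover the seven semantic compartments the
#' tissue classifier consumes.
#'
#' @return Named integer vector mapping region name to code.
#' @export
region_legend <- function() {
  c(background = 0L, subcutaneous_tissue = 1L, muscle = 2L,
    abdominal_cavity = 3L, thoracic_cavity = 4L, mediastinum = 5L,
    pericardium = 6L, bone = 7L)
}

#' Construct a region-label volume
#'
#' @param labels 3-D integer array of region codes.
#' @param legend Named integer vector mapping region name to code; must
#'   contain `background = 0` and cover every code present in `labels`.
#' @return An object of class `region_labels`.
#' @export
region_labels <- function(labels, legend = region_legend()) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    validation_error("`labels` must be a 3-D array")
  }
  storage.mode(labels) <- "integer"
  if (anyNA(labels)) validation_error("region labels must not contain NA")
  legend <- validate_legend(legend)
  present <- sort(unique(as.integer(labels)))
  missing <- setdiff(present, unname(legend))
  if (length(missing) > 0) {
    legend_error(sprintf(
      "region code(s) %s present in data but absent from legend",
      paste(missing, collapse = ", ")
    ))
  }
  structure(
    list(labels = labels, legend = legend, shape = dim(labels)),
    class = "region_labels"
  )
}

validate_legend <- function(legend) {
  if (is.null(names(legend)) || any(!nzchar(names(legend)))) {
    legend_error("legend must be a named code mapping")
  }
  legend <- vapply(legend, as.integer, integer(1))
  if (anyDuplicated(legend) || anyDuplicated(names(legend))) {
    legend_error("legend codes and names must be unique")
  }
  if (!"background" %in% names(legend) || legend[["background"]] != 0L) {
    legend_error("legend must map background to code 0")
  }
  legend
}

#' @export
print.region_labels <- function(x, ...) {
  cat(sprintf("Region labels: %s voxels, %d regions\n",
              paste(x$shape, collapse = " x "), length(x$legend)))
  cnt <- table(factor(as.integer(x$labels), levels = unname(x$legend),
                      labels = names(x$legend)))
  print(cnt)
  invisible(x)
}

check_same_shape <- function(ct, regions) {
  if (!identical(as.integer(ct$shape), as.integer(regions$shape))) {
    geometry_error(sprintf(
      "CT shape (%s) and region-label shape (%s) differ",
      paste(ct$shape, collapse = "x"), paste(regions$shape, collapse = "x")
    ))
  }
  invisible(TRUE)
}

read_nifti_checked <- function(path) {
  if (!file.exists(path)) input_format_error(sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) input_format_error(
                    sprintf("cannot read '%s' as a NIfTI volume: %s",
                            path, conditionMessage(e))))
  if (length(dim(img)) != 3L) {
    input_format_error(sprintf("'%s' is not a 3-D volume", path))
  }
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (anyNA(sp) || any(sp <= 0)) {
    metadata_error(sprintf(
      "missing or non-positive voxel spacing (pixdim) in header of '%s'", path))
  }
  list(values = unclass(img)[, , , drop = FALSE], spacing = as.numeric(sp))
}

#' Read a CT volume from a NIfTI file
#'
#' Spacing is taken from the header `pixdim`; HU values are clamped to
#' \eqn{[-1024, 3071]} on load.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume].
#' @export
read_ct_volume <- function(path) {
  raw <- read_nifti_checked(path)
  dim(raw$values) <- dim(raw$values)[seq_len(3)]
  ct_volume(raw$values, spacing = raw$spacing, clamp = TRUE)
}

#' Write a CT volume to a NIfTI file
#'
#' @param vol A [ct_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a region-label volume from a NIfTI file
#'
#' @param path Path to a `.nii` or `.nii.gz` file of integer region codes.
#' @param legend Named integer code mapping; every code present in the data
#'   must appear in it (a `ctbca_legend_error` is raised otherwise).
#' @return A [region_labels] volume.
#' @export
read_region_labels <- function(path, legend = region_legend()) {
  raw <- read_nifti_checked(path)
  vals <- raw$values
  dim(vals) <- dim(vals)[seq_len(3)]
  if (max(abs(vals - round(vals))) > 1e-6) {
    input_format_error(sprintf("'%s' contains non-integer region codes", path))
  }
  region_labels(array(as.integer(round(vals)), dim = dim(vals)), legend = legend)
}

#' Write a region-label volume to a NIfTI file
#'
#' @param reg A [region_labels] volume.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_labels <- function(reg, path) {
  stopifnot(inherits(reg, "region_labels"))
  img <- RNifti::asNifti(reg$labels)
  RNifti::pixdim(img) <- c(5, 5, 5)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}
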