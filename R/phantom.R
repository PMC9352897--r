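# Synthetic CT phantoms with composition known exactly by construction.
#
# The phantom stands in for clinical scans: a cylindrical "torso" whose body
# voxels are partitioned into tissue compartments at exactly the requested
# counts. Each voxel receives a region label consistent with its intended
# tissue (an IMAT voxel carries the muscle region label, an EAT voxel the
# pericardium label, ...) and an HU value drawn strictly inside the tissue's
# classification window, so that noise-free quantification must recover the
# ground truth with zero error. That exactness is what makes the phantom an
# oracle for the classifier and the ratio computation.

PHANTOM_TISSUES <- c("SAT", "VAT", "IMAT", "EAT", "PAT", "muscle", "bone",
                     "air_pockets", "other")

# region label carried by each intended tissue
TISSUE_REGION <- c(
  SAT = "subcutaneous_tissue", VAT = "abdominal_cavity", IMAT = "muscle",
  EAT = "pericardium", PAT = "mediastinum", muscle = "muscle", bone = "bone",
  air_pockets = "abdominal_cavity", other = "abdominal_cavity"
)

# HU sampling interval per tissue, strictly inside the classification window
# (bone and "other" have no window; they sit above the muscle window so that
# "other" quantifies as unclassified and bone is carried by its region label)
TISSUE_HU_RANGE <- list(
  SAT = c(-190, -30), VAT = c(-190, -30), IMAT = c(-190, -30),
  EAT = c(-190, -30), PAT = c(-190, -30),
  muscle = c(-29, 150), bone = c(200, 1000),
  air_pockets = c(-1024, -800), other = c(160, 500)
)

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Specify a synthetic CT phantom
#'
#' @param shape Volume dimensions (3 positive integers).
#' @param spacing Voxel spacing in mm.
#' @param target_fractions Named fractions of body voxels per tissue, among
#'   `SAT`, `VAT`, `IMAT`, `EAT`, `PAT`, `muscle`, `bone`, `air_pockets`,
#'   `other`; nonnegative, summing to at most 1. Any remainder becomes
#'   `other` (soft tissue outside all windows).
#' @param region_layout `"nested_cylinders"` (subcutaneous shell around a
#'   muscle shell around an abdominal core) or `"voxel_list"` (explicit
#'   assignment via `voxel_list`).
#' @param voxel_list For `region_layout = "voxel_list"`: data.frame with
#'   integer columns `x`, `y`, `z` (1-based) and a `tissue` column; these
#'   voxels form the body and `target_fractions` is ignored.
#' @param hu_noise_sd Gaussian HU noise, truncated so each voxel stays
#'   strictly inside its tissue's HU window. Default 3 HU.
#' @param seed Integer seed; same spec and seed give bit-identical phantoms.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 16), spacing = c(5, 5, 5),
                         target_fractions = c(SAT = 0.20, VAT = 0.12,
                                              IMAT = 0.04, EAT = 0.02,
                                              PAT = 0.02, muscle = 0.30,
                                              bone = 0.10, air_pockets = 0.05),
                         region_layout = c("nested_cylinders", "voxel_list"),
                         voxel_list = NULL, hu_noise_sd = 3, seed = 1L) {
  region_layout <- match.arg(region_layout)
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1)) {
    spec_error("shape must be 3 positive integers")
  }
  if (hu_noise_sd < 0) spec_error("hu_noise_sd must be >= 0")
  if (region_layout == "nested_cylinders") {
    if (length(target_fractions) == 0 || is.null(names(target_fractions))) {
      spec_error("target_fractions must be a named vector")
    }
    unknown <- setdiff(names(target_fractions), PHANTOM_TISSUES)
    if (length(unknown) > 0) {
      spec_error(sprintf("unknown tissue(s): %s", paste(unknown, collapse = ", ")))
    }
    if (any(target_fractions < 0) || sum(target_fractions) > 1 + 1e-12) {
      spec_error("target_fractions must be >= 0 and sum to <= 1")
    }
  } else if (is.null(voxel_list)) {
    spec_error("voxel_list layout requires a voxel_list data.frame")
  }
  structure(
    list(shape = shape, spacing = as.numeric(spacing),
         target_fractions = target_fractions, region_layout = region_layout,
         voxel_list = voxel_list, hu_noise_sd = hu_noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# largest-remainder rounding of fraction * n to integer counts whose sum is
# round(sum(fractions) * n)
allocate_counts <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  total <- round(sum(raw))
  rem <- raw - counts
  short <- as.integer(total - sum(counts))
  if (short > 0) {
    up <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[up] <- counts[up] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic CT phantom
#'
#' Builds the CT volume, the co-registered region-label volume, and the
#' ground-truth voxel counts realised by construction. With
#' `hu_noise_sd = 0` (or any noise small enough that truncation never pushes
#' a voxel across a window boundary — guaranteed here, noise is truncated to
#' the window), [classify_tissues] + [quantify_tissues] recover
#' `ground_truth` exactly.
#'
#' @param spec A [phantom_spec].
#' @return List with elements `ct` ([ct_volume]), `regions`
#'   ([region_labels]), `ground_truth` (named voxel counts per tissue),
#'   `body_voxels` (total body voxels) and `expected` (list with the `bfr`
#'   and `smr` the phantom must quantify to).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    dims <- spec$shape
    if (spec$region_layout == "nested_cylinders") {
      # body = cylinder along z
      cx <- (dims[1] + 1) / 2; cy <- (dims[2] + 1) / 2
      r_body <- 0.48 * min(dims[1], dims[2])
      xy <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]))
      rad2 <- (xy$x - cx)^2 + (xy$y - cy)^2
      in_body_slice <- rad2 <= r_body^2
      n_slice <- sum(in_body_slice)
      if (n_slice == 0) spec_error("volume too small to contain a body cylinder")
      body_idx <- which(rep(in_body_slice, dims[3]))  # column-major: z outer
      n_body <- length(body_idx)
      # outer voxels first, so subcutaneous fat forms the outer shell
      body_rad <- rep(rad2[in_body_slice], dims[3])
      ord <- order(-body_rad, body_idx)
      body_idx <- body_idx[ord]

      fr <- spec$target_fractions
      counts <- allocate_counts(fr, n_body)
      names(counts) <- names(fr)
      if (sum(counts) > n_body) {
        spec_error("target fractions round to more voxels than the body contains")
      }
      # remainder is nondescript soft tissue outside every window
      leftover <- n_body - sum(counts)
      if (!"other" %in% names(counts)) counts <- c(counts, other = 0L)
      counts[["other"]] <- counts[["other"]] + as.integer(leftover)
      # outer-to-inner ordering of compartments
      order_tissues <- c("SAT", "IMAT", "muscle", "PAT", "EAT", "bone",
                         "VAT", "air_pockets", "other")
      tissue_of <- rep(NA_character_, n_body)
      pos <- 1L
      for (t in order_tissues) {
        k <- if (t %in% names(counts)) counts[[t]] else 0L
        if (k > 0) {
          tissue_of[pos:(pos + k - 1L)] <- t
          pos <- pos + k
        }
      }
      voxel_idx <- body_idx
    } else {
      vl <- spec$voxel_list
      need <- c("x", "y", "z", "tissue")
      if (!is.data.frame(vl) || !all(need %in% names(vl))) {
        spec_error("voxel_list needs columns x, y, z, tissue")
      }
      if (!all(vl$tissue %in% PHANTOM_TISSUES)) {
        spec_error("voxel_list contains unknown tissue names")
      }
      if (any(vl$x < 1 | vl$x > dims[1] | vl$y < 1 | vl$y > dims[2] |
              vl$z < 1 | vl$z > dims[3])) {
        spec_error("voxel_list coordinates outside the volume")
      }
      voxel_idx <- (vl$z - 1L) * dims[1] * dims[2] + (vl$y - 1L) * dims[1] + vl$x
      if (anyDuplicated(voxel_idx)) spec_error("voxel_list assigns a voxel twice")
      tissue_of <- as.character(vl$tissue)
    }

    n_total <- prod(dims)
    legend <- region_legend()
    labels <- integer(n_total)  # background = 0
    labels[voxel_idx] <- legend[TISSUE_REGION[tissue_of]]
    hu <- rep(HU_MIN, n_total)  # background is air-density

    for (t in unique(tissue_of)) {
      sel <- voxel_idx[tissue_of == t]
      rng <- TISSUE_HU_RANGE[[t]]
      margin <- 0.01 * (rng[2] - rng[1])
      lo <- rng[1] + margin; hi <- rng[2] - margin
      base <- stats::runif(length(sel), lo, hi)
      if (spec$hu_noise_sd > 0) {
        base <- base + stats::rnorm(length(sel), 0, spec$hu_noise_sd)
        base <- pmin(pmax(base, lo), hi)  # truncate: never leaves the window
      }
      hu[sel] <- base
    }

    ct <- ct_volume(array(hu, dim = dims), spacing = spec$spacing)
    regions <- region_labels(array(labels, dim = dims), legend = legend)
    gt <- vapply(PHANTOM_TISSUES, function(t) sum(tissue_of == t), integer(1))
    body <- length(voxel_idx) - gt[["air_pockets"]]
    adipose <- sum(gt[c("SAT", "VAT", "IMAT", "EAT", "PAT")])
    list(
      ct = ct, regions = regions, ground_truth = gt,
      body_voxels = as.integer(body),
      expected = list(bfr = 100 * adipose / body,
                      smr = 100 * gt[["muscle"]] / body)
    )
  })
}
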