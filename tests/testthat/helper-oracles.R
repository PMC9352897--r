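# Independent oracles and fixture builders shared across the suite.

# Brute-force per-voxel reference classifier, written directly from the
# classification rules (HU windows within semantic regions) with a plain
# if-chain. Deliberately independent of the package's vectorised
# implementation; used to check voxel-for-voxel equivalence.
ref_classify <- function(ct, regions) {
  legend <- regions$legend
  region_name <- names(legend)[match(as.vector(regions$labels), unname(legend))]
  hu <- as.vector(ct$values)
  out <- character(length(hu))
  for (i in seq_along(hu)) {
    h <- hu[i]
    rn <- region_name[i]
    out[i] <- if (rn == "background") {
      "background"
    } else if (h >= -1024 && h <= -800) {
      "excluded_air"
    } else if (h >= -190 && h < -29.5) {
      if (rn == "subcutaneous_tissue") "SAT"
      else if (rn == "abdominal_cavity") "VAT"
      else if (rn == "muscle") "IMAT"
      else if (rn == "pericardium") "EAT"
      else if (rn == "mediastinum") "PAT"
      else "unclassified"
    } else if (h >= -29.5 && h <= 150) {
      if (rn == "muscle") "muscle" else if (rn == "bone") "bone" else "unclassified"
    } else if (rn == "bone") {
      "bone"
    } else {
      "unclassified"
    }
  }
  array(out, dim = ct$shape)
}

tissue_label_names <- function(tl) {
  array(tl$levels[as.vector(tl$labels) + 1L], dim = tl$shape)
}

# Random CT + region volume pair spanning all HU windows and the window
# boundary values.
random_volume_pair <- function(dims = c(8, 8, 8)) {
  boundary_hu <- c(-190, -30, -29, 150, -800, -1024, -29.5, -190.5, 150.5)
  n <- prod(dims)
  hu <- stats::runif(n, -1100, 400)
  swap <- sample.int(n, size = max(1L, n %/% 4L))
  hu[swap] <- sample(boundary_hu, length(swap), replace = TRUE)
  codes <- unname(region_legend())
  labels <- sample(codes, n, replace = TRUE)
  list(
    ct = ct_volume(array(hu, dim = dims), spacing = c(2, 2, 2)),
    regions = region_labels(array(labels, dim = dims))
  )
}

# Random noise-free phantom spec with fractions that partition exactly.
random_phantom_spec <- function(seed, max_dim = 24) {
  dims <- sample(8:max_dim, 3, replace = TRUE)
  fr <- stats::runif(8)
  fr <- fr / sum(fr) * stats::runif(1, 0.5, 0.95)
  names(fr) <- c("SAT", "VAT", "IMAT", "EAT", "PAT", "muscle", "bone",
                 "air_pockets")
  phantom_spec(shape = dims, target_fractions = fr, hu_noise_sd = 0,
               seed = seed)
}

# Mixture moments of the latent biomarker implied by a cohort spec (clipping
# to [0, 100] ignored; negligible at the default parameter ranges).
latent_mixture_var <- function(weights, means, sds) {
  w <- weights / sum(weights)
  m <- sum(w * means)
  sum(w * sds^2) + sum(w * (means - m)^2)
}

cli_script <- function() {
  path <- system.file("cli", "bca.R", package = "ctbca")
  stopifnot(nzchar(path))
  path
}

run_cli <- function(...) {
  rscript <- file.path(R.home("bin"), "Rscript")
  # non-zero exit is a legitimate outcome under test; keep the R-side warning quiet
  out <- suppressWarnings(
    system2(rscript, c(cli_script(), ...), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(output = out, status = if (is.null(status)) 0L else status)
}
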