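# Tissue classification and ratio computation.

make_pair <- function(hu, region_name, dims = NULL) {
  # single-column volume with given HU values and region names
  n <- length(hu)
  dims <- dims %||% c(n, 1, 1)
  legend <- region_legend()
  ct <- ct_volume(array(hu, dim = dims), spacing = c(5, 5, 5))
  reg <- region_labels(array(unname(legend[region_name]), dim = dims))
  list(ct = ct, regions = reg)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

classify_names <- function(p, ...) {
  tissue_label_names(classify_tissues(p$ct, p$regions, ...))
}

test_that("window boundaries classify as printed", {
  cases <- list(
    list(hu = -30, region = "subcutaneous_tissue", tissue = "SAT"),
    list(hu = -190, region = "subcutaneous_tissue", tissue = "SAT"),
    list(hu = -29, region = "muscle", tissue = "muscle"),
    list(hu = 150, region = "muscle", tissue = "muscle"),
    list(hu = -900, region = "abdominal_cavity", tissue = "excluded_air"),
    list(hu = -800, region = "muscle", tissue = "excluded_air"),
    list(hu = -1024, region = "subcutaneous_tissue", tissue = "excluded_air"),
    list(hu = -200, region = "subcutaneous_tissue", tissue = "unclassified"),
    list(hu = 151, region = "abdominal_cavity", tissue = "unclassified"),
    list(hu = -100, region = "abdominal_cavity", tissue = "VAT"),
    list(hu = -100, region = "muscle", tissue = "IMAT"),
    list(hu = -100, region = "pericardium", tissue = "EAT"),
    list(hu = -100, region = "mediastinum", tissue = "PAT"),
    list(hu = -100, region = "thoracic_cavity", tissue = "unclassified"),
    list(hu = 50, region = "bone", tissue = "bone"),
    list(hu = 500, region = "bone", tissue = "bone"),
    list(hu = 0, region = "background", tissue = "background")
  )
  for (cs in cases) {
    p <- make_pair(cs$hu, cs$region)
    expect_equal(classify_names(p)[1], cs$tissue,
                 label = sprintf("HU %g in %s", cs$hu, cs$region))
  }
})

test_that("non-integer HU splits adipose/muscle at the -29.5 midpoint", {
  p <- make_pair(c(-29.6, -29.5, -29.4), rep("muscle", 3))
  expect_equal(as.vector(classify_names(p)), c("IMAT", "muscle", "muscle"))
})

test_that("classifier matches the brute-force reference voxel-for-voxel", {
  set.seed(42)
  for (i in 1:25) {
    dims <- sample(4:12, 3, replace = TRUE)
    p <- random_volume_pair(dims)
    got <- classify_names(p)
    expect_identical(got, ref_classify(p$ct, p$regions))
  }
})

test_that("shape mismatch raises a geometry error", {
  ct <- ct_volume(array(0, dim = c(4, 4, 4)))
  reg <- region_labels(array(0L, dim = c(4, 4, 5)))
  expect_error(classify_tissues(ct, reg), class = "ctbca_geometry_error")
})

test_that("air-exclusion scope can be restricted to the abdominal cavity", {
  p <- make_pair(c(-900, -900), c("abdominal_cavity", "thoracic_cavity"))
  all_scope <- classify_names(p)
  expect_equal(as.vector(all_scope), c("excluded_air", "excluded_air"))
  abd_scope <- classify_names(p, air_scope = "abdominal_cavity")
  expect_equal(as.vector(abd_scope), c("excluded_air", "unclassified"))
})

test_that("quantification computes ratios over the air-excluded denominator", {
  # 1000 non-background voxels: 400 adipose, 0 air -> BFR 40%
  hu <- c(rep(-100, 400), rep(50, 300), rep(300, 300))
  region <- c(rep("subcutaneous_tissue", 400), rep("muscle", 300),
              rep("abdominal_cavity", 300))
  p <- make_pair(hu, region, dims = c(10, 10, 10))
  rep1 <- quantify_tissues(classify_tissues(p$ct, p$regions))
  expect_equal(rep1$bfr, 40)
  expect_equal(rep1$smr, 30)
  expect_equal(rep1$body_voxels, 1000L)

  # turning 100 of the "other" voxels into air shrinks the denominator
  hu[901:1000] <- -900
  p2 <- make_pair(hu, region, dims = c(10, 10, 10))
  rep2 <- quantify_tissues(classify_tissues(p2$ct, p2$regions))
  expect_equal(rep2$body_voxels, 900L)
  expect_equal(rep2$bfr, 100 * 400 / 900)
  expect_equal(rep2$smr, 100 * 300 / 900)

  # volumes: count x voxel volume in litres
  expect_equal(rep2$volumes_l$SAT, 400 * 125 / 1e6)
})

test_that("every voxel gets exactly one class and counts partition", {
  set.seed(1)
  p <- random_volume_pair(c(10, 10, 10))
  tl <- classify_tissues(p$ct, p$regions)
  counts <- unlist(quantify_tissues(tl)$voxel_counts)
  expect_equal(sum(counts), 1000)
  expect_true(all(tl$labels %in% 0:(length(tl$levels) - 1L)))
})

test_that("all-background volume is a degenerate input", {
  ct <- ct_volume(array(0, dim = c(3, 3, 3)))
  reg <- region_labels(array(0L, dim = c(3, 3, 3)))
  tl <- classify_tissues(ct, reg)
  expect_error(quantify_tissues(tl), class = "ctbca_degenerate_input_error")
})

test_that("BFR/SMR are spacing-invariant; volumes scale cubically", {
  set.seed(5)
  for (i in 1:5) {
    p <- random_volume_pair(c(8, 8, 8))
    tl <- classify_tissues(p$ct, p$regions)
    base <- quantify_tissues(tl, spacing = c(2, 2, 2))
    for (f in c(0.5, 3)) {
      scaled <- quantify_tissues(tl, spacing = c(2, 2, 2) * f)
      expect_equal(scaled$bfr, base$bfr)
      expect_equal(scaled$smr, base$smr)
      expect_equal(unlist(scaled$volumes_l), unlist(base$volumes_l) * f^3)
    }
  }
})

test_that("adding excluded-air voxels strictly increases BFR and SMR", {
  set.seed(9)
  for (i in 1:10) {
    dims <- c(8, 8, 8)
    p <- random_volume_pair(dims)
    tl <- classify_tissues(p$ct, p$regions)
    counts <- unlist(quantify_tissues(tl)$voxel_counts)
    if (counts[["SAT"]] + counts[["VAT"]] == 0 || counts[["muscle"]] == 0) next
    base <- quantify_tissues(tl)
    # convert some unclassified body voxels into air
    hu <- as.vector(p$ct$values)
    reg <- as.vector(p$regions$labels)
    conv <- which(hu > 150 & hu <= 400 & reg != 0L)
    if (length(conv) == 0) next
    hu[conv] <- -900
    p2 <- list(ct = ct_volume(array(hu, dim = dims), spacing = p$ct$spacing),
               regions = p$regions)
    more_air <- quantify_tissues(classify_tissues(p2$ct, p2$regions))
    expect_gt(more_air$bfr, base$bfr)
    expect_gt(more_air$smr, base$smr)
  }
})

test_that("run_bca is deterministic end to end", {
  ph <- generate_phantom(phantom_spec(shape = c(16, 16, 8), seed = 4))
  ct_path <- withr::local_tempfile(fileext = ".nii.gz")
  seg_path <- withr::local_tempfile(fileext = ".nii.gz")
  write_ct_volume(ph$ct, ct_path)
  write_region_labels(ph$regions, seg_path)
  r1 <- run_bca(ct_path, seg_path)
  r2 <- run_bca(ct_path, seg_path)
  expect_identical(r1, r2)
  expect_equal(r1$bfr, ph$expected$bfr)
  out1 <- withr::local_tempfile(fileext = ".json")
  out2 <- withr::local_tempfile(fileext = ".json")
  write_bca_report(r1, out1); write_bca_report(r2, out2)
  expect_identical(readLines(out1), readLines(out2))
})
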