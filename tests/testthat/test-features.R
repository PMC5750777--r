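test_that("pixel counts and bounding-box aspect are exact on a rectangle", {
  mask <- matrix(0L, 30, 40)
  mask[3:6, 3:6] <- 1L            # token cytoplasm patch
  mask[16:25, 8:27] <- 2L         # 10 rows x 20 cols filled rectangle
  cell <- segmented_cell(matrix(128, 30, 40), mask)
  g <- region_geometry(cell)
  expect_identical(g$A_n, 200L)
  expect_equal(g$R_n, 20 / 10)    # W_n / H_n of the bounding box
  expect_gte(g$L_n, g$D_n)
})

test_that("disk roundness approaches 1 and grows with radius", {
  vals <- vapply(c(10, 20, 40), function(r) {
    region <- disk_region(r)
    mask <- matrix(0L, nrow(region), ncol(region))
    mask[region] <- 2L
    mask[1, 1] <- 1L  # token cytoplasm pixel to satisfy the invariant
    g <- region_geometry(segmented_cell(matrix(100, nrow(region), ncol(region)), mask))
    g$N_roundness
  }, numeric(1))
  expect_true(all(abs(vals - 1) < 0.05))
  expect_true(all(diff(abs(vals - 1)) <= 0))  # monotone approach to 1
})

test_that("moment-ellipse axes match a brute-force moment oracle", {
  region <- ellipse_region(20, 10)
  mask <- matrix(0L, nrow(region), ncol(region))
  mask[region] <- 2L; mask[1, 1] <- 1L
  g <- region_geometry(segmented_cell(matrix(1, nrow(region), ncol(region)), mask))
  expect_equal(g$L_n, 40, tolerance = 0.05)
  expect_equal(g$D_n, 20, tolerance = 0.05)
  ax <- oracle_axes(region)
  expect_equal(g$L_n, ax[["major"]], tolerance = 1e-10)
  expect_equal(g$D_n, ax[["minor"]], tolerance = 1e-10)
})

test_that("disk compactness approaches 4*pi under the corrected perimeter", {
  for (r in c(10, 20, 40)) {
    region <- disk_region(r)
    A <- sum(region)
    P <- region_perimeter(region)
    expect_equal(P^2 / A, 4 * pi, tolerance = 0.15)
  }
  # raw boundary-pixel count converges to the staircase limit 32/pi instead
  region <- disk_region(40)
  expect_equal(region_perimeter(region, correct = FALSE)^2 / sum(region),
               32 / pi, tolerance = 0.05)
})

test_that("local extrema counting is strict and matches an exhaustive scan", {
  region <- matrix(TRUE, 9, 9)
  expect_identical(local_extrema_count(matrix(5, 9, 9), region, "max"), 0L)
  expect_identical(local_extrema_count(matrix(5, 9, 9), region, "min"), 0L)

  img <- matrix(0, 9, 9); img[5, 5] <- 255
  expect_identical(local_extrema_count(img, region, "max"), 1L)

  img2 <- matrix(0, 9, 9); img2[3, 3] <- 9; img2[7, 7] <- 7
  expect_identical(local_extrema_count(img2, region, "max"), 2L)

  set.seed(42)
  rimg <- matrix(sample(0:255, 15 * 15, TRUE), 15, 15)
  rreg <- matrix(runif(15 * 15) < 0.8, 15, 15)
  for (mode in c("max", "min"))
    expect_identical(local_extrema_count(rimg, rreg, mode),
                     oracle_extrema(rimg, rreg, mode))
})

test_that("border pixels compare only against available in-region neighbours", {
  # a ramp: the region's corner pixel is a strict max over its visible part
  img <- matrix(rep(1:4, each = 4), 4, 4)
  region <- matrix(TRUE, 4, 4)
  expect_identical(local_extrema_count(img, region, "max"),
                   oracle_extrema(img, region, "max"))
})

test_that("GLCM homogeneity hits its analytic anchors and the loop oracle", {
  region <- matrix(TRUE, 8, 8)
  expect_equal(glcm_homogeneity(matrix(77, 8, 8), region), 1.0)

  checker <- outer(1:8, 1:8, function(r, c) ifelse((r + c) %% 2 == 0, 0, 255))
  expect_equal(glcm_homogeneity(checker, region, levels = 2L), 0.5)

  set.seed(7)
  patch <- matrix(sample(0:255, 16 * 16, TRUE), 16, 16)
  reg <- matrix(runif(16 * 16) < 0.7, 16, 16)
  expect_equal(glcm_homogeneity(patch, reg, levels = 8L),
               oracle_glcm(patch, reg, 8L, c(0L, 1L)), tolerance = 1e-12)
  expect_error(glcm_homogeneity(patch, matrix(FALSE, 16, 16)), "pair")
})

test_that("mean brightness is the arithmetic mean over the region", {
  expect_equal(mean_brightness(matrix(37, 5, 5), matrix(TRUE, 5, 5)), 37)
  img <- matrix(c(10, 20, 99, 99), 2, 2)
  reg <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(mean_brightness(img, reg), 15)
  set.seed(3)
  rimg <- matrix(runif(100, 0, 255), 10, 10)
  rreg <- matrix(runif(100) < 0.5, 10, 10)
  expect_equal(mean_brightness(rimg, rreg),
               sum(rimg[rreg]) / sum(rreg))
})

test_that("the full feature vector has the fixed 54-entry schema", {
  cell <- toy_cell()
  fv <- extract_features(cell)
  expect_length(fv, 54)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_features(cell))   # bit-for-bit determinism
  # disk-in-disk: nucleus/cytoplasm pixel-count ratio
  expect_equal(fv[["R_cell"]],
               sum(cell$mask == 2L) / sum(cell$mask == 1L))
  expect_true(fv[["H_n"]] >= 0 && fv[["H_n"]] <= 1)
  expect_gte(fv[["L_n"]], fv[["D_n"]])
})

test_that("feature extraction is invariant to translating the cell", {
  set.seed(11)
  base <- toy_cell(noise = 6)
  a <- shift_cell(base, 60, 3, 5)
  b <- shift_cell(base, 60, 12, 9)
  expect_identical(extract_features(a), extract_features(b))
})

test_that("degenerate segmentations are rejected", {
  img <- matrix(1, 10, 10)
  no_nuc <- matrix(0L, 10, 10); no_nuc[3:7, 3:7] <- 1L
  expect_error(segmented_cell(img, no_nuc), "nucleus")
  no_cyto <- matrix(0L, 10, 10); no_cyto[3:7, 3:7] <- 2L
  expect_error(segmented_cell(img, no_cyto), "cytoplasm")
  expect_error(segmented_cell(matrix(1, 9, 10), no_nuc), "shape")
})

test_that("feature tables round-trip through CSV with the schema enforced", {
  cells <- list(toy_cell(), toy_cell(r_nuc = 8L))
  tab <- extract_feature_table(cells, labels = c("a", "b"))
  expect_identical(names(tab)[1:2], c("cell_id", "class"))
  expect_identical(names(tab)[-(1:2)], feature_names())
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back[feature_names()], tab[feature_names()], tolerance = 1e-12)
  expect_error(read_feature_table({
    p2 <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(tab[, 1:10], p2, row.names = FALSE); p2
  }), "schema")
})
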