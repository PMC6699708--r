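# The 65-parameter feature extraction: colour channels and statistics,
# GLCM texture, contour morphology.

test_that("channel conversions hit the colour-space anchors", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  m1 <- matrix(TRUE, 1, 1)
  red <- convert_channels(px(255, 0, 0), m1)
  expect_equal(red$H, 0)
  expect_equal(red$S, 1)
  expect_equal(red$V, 1)
  gray <- convert_channels(px(128, 128, 128), m1)
  expect_lt(abs(gray$a), 0.5)
  expect_lt(abs(gray$b), 0.5)
  white <- convert_channels(px(255, 255, 255), m1)
  expect_equal(white$L, 100, tolerance = 1e-3)
  expect_error(convert_channels(px(1, 2, 3), matrix(FALSE, 1, 1)), "empty")
})

test_that("channel_stats implements the five statistics", {
  s <- channel_stats(c(10, 20, 30, 40, 100))
  expect_equal(unname(s["mean"]), 40)
  expect_equal(unname(s["median"]), 30)
  expect_equal(unname(s["range"]), 90)
  expect_equal(unname(s["sd"]), sqrt(1250))          # n-1 denominator
  expect_equal(unname(s["cv"]), sqrt(1250) / 40)
  expect_equal(unname(channel_stats(rep(7, 4))), c(7, 0, 7, 0, 0))
  # CV is invariant under positive scaling
  x <- with_seed(5, runif(50, 1, 9))
  expect_equal(channel_stats(x)[["cv"]], channel_stats(3.7 * x)[["cv"]])
  expect_equal(channel_stats(5)[["sd"]], 0)          # single value
})

test_that("GLCM matches hand-computed and brute-force values", {
  # two-column image: horizontal pairs are always (0, high)
  g <- matrix(c(0, 0, 255, 255), 2, 2)
  P <- glcm_matrix(g, glcm_config(levels = 2, distance = 1, angles = 0))
  expect_equal(P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  ts <- texture_stats(P)
  expect_equal(unname(ts["contrast"]), 1)
  expect_equal(unname(ts["dissimilarity"]), 1)
  expect_equal(unname(ts["homogeneity"]), 0.5)
  expect_equal(unname(ts["asm"]), 0.5)
  expect_equal(unname(ts["energy"]), sqrt(0.5))
  expect_equal(unname(ts["correlation"]), -1)

  # constant image: single diagonal entry, degenerate statistics
  Pc <- glcm_matrix(matrix(100, 4, 4), glcm_config(levels = 8))
  expect_equal(sum(Pc), 1)
  expect_equal(Pc[4, 4], 1)   # level floor(100*8/256) = 3 -> index 4
  tc <- texture_stats(Pc)
  expect_equal(unname(tc[c("contrast", "dissimilarity")]), c(0, 0))
  expect_equal(unname(tc[c("homogeneity", "energy", "asm")]), c(1, 1, 1))

  # brute-force oracle on random 8x8 images at 4 levels
  for (seed in 1:10) {
    g <- with_seed(seed, matrix(sample(0:255, 64, TRUE), 8, 8))
    P <- glcm_matrix(g, glcm_config(levels = 4))
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(texture_stats(P), brute_texture(g, 4), tolerance = 1e-10)
  }
  expect_error(texture_stats(matrix(1, 2, 2)), "normalized")
})

test_that("texture pairs never cross the mask boundary", {
  sc <- tiny_scene(9)
  # tight crop of the fruit vs full frame with zeroed background:
  # identical pair sets, identical statistics
  rows <- range(which(rowSums(sc$mask) > 0))
  cols <- range(which(colSums(sc$mask) > 0))
  crop_img <- sc$image[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  crop_mask <- sc$mask[rows[1]:rows[2], cols[1]:cols[2]]
  P_full <- glcm_matrix(melonpheno:::luma_matrix(sc$image, sc$mask))
  P_crop <- glcm_matrix(melonpheno:::luma_matrix(crop_img, crop_mask))
  expect_equal(P_full, P_crop, tolerance = 1e-12)
})

test_that("morphology descriptors match analytic shapes", {
  # disk of radius 50
  disk <- generate_scene(scene_params(image_size = c(200, 200),
                                      fruit_axes = c(50, 50), net_density = 0,
                                      pixel_noise_sd = 0))$mask
  m <- morphology_stats(disk)
  expect_equal(unname(m["contour_area"]), pi * 50^2, tolerance = 0.02)
  expect_equal(unname(m["equivalent_diameter"]), 100, tolerance = 0.02)
  expect_gte(unname(m["solidity"]), 0.98)
  expect_equal(unname(m["aspect_ratio"]), 1, tolerance = 0.05)
  expect_equal(unname(m["equivalent_diameter"]),
               sqrt(4 * m[["contour_area"]] / pi))    # exact identity

  # axis-aligned ellipse, semi-axes (80, 40): vertical major axis
  ell <- generate_scene(scene_params(image_size = c(200, 200),
                                     fruit_axes = c(80, 40), net_density = 0,
                                     pixel_noise_sd = 0))$mask
  e <- morphology_stats(ell)
  expect_equal(unname(e["MA"]), 160, tolerance = 0.03)
  expect_equal(unname(e["ma"]), 80, tolerance = 0.03)
  expect_equal(unname(e["extent"]), pi / 4, tolerance = 0.03)
  expect_gte(unname(e["MA"]), unname(e["ma"]))

  # filled square, side 100
  sq <- matrix(FALSE, 140, 140); sq[21:120, 21:120] <- TRUE
  s <- morphology_stats(sq)
  expect_equal(unname(s["w"]), 100)
  expect_equal(unname(s["h"]), 100)
  expect_equal(unname(s["extent"]), 1, tolerance = 0.01)
  expect_equal(unname(s["solidity"]), 1, tolerance = 0.01)

  expect_error(morphology_stats(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 20, 20); two[2:4, 2:4] <- TRUE; two[10:14, 10:14] <- TRUE
  expect_error(morphology_stats(two), "one component")
})

test_that("morphology bounds hold on random blobs", {
  for (seed in 1:100) {
    m <- morphology_stats(blob_mask(seed))
    expect_lte(m[["solidity"]], 1 + 1e-6)
    expect_lte(m[["extent"]], 1 + 1e-6)
    expect_gte(m[["hull_area"]], m[["contour_area"]])
    expect_gte(m[["MA"]], m[["ma"]])
    expect_gte(m[["aspect_ratio"]], 1)
  }
})

test_that("morphology is robust to 90-degree rotation", {
  for (seed in c(3, 14)) {
    b <- blob_mask(seed, size = 70)
    rot <- t(b)[, nrow(b):1]      # 90-degree rotation
    m0 <- morphology_stats(b); m1 <- morphology_stats(rot)
    expect_identical(m0[["contour_area"]], m1[["contour_area"]])
    expect_equal(m0[["perimeter"]], m1[["perimeter"]], tolerance = 0.03)
    expect_equal(m0[["equivalent_diameter"]], m1[["equivalent_diameter"]],
                 tolerance = 1e-12)
    expect_identical(m0[["w"]], m1[["h"]])
    expect_identical(m0[["h"]], m1[["w"]])
  }
})

test_that("extract_features returns the 65 named parameters", {
  sc <- tiny_scene(4)
  seg <- segment_image(sc$image)
  fv <- extract_features(sc$image, seg$mask, image_id = "t1")
  expect_length(fv, 65)
  expect_identical(names(fv), feature_names())
  expect_false(anyNA(fv))
  counts <- as.vector(table(feature_categories())[c("color", "texture", "morphology")])
  expect_identical(counts, as.integer(c(45, 6, 14)))
  expect_identical(attr(fv, "image_id"), "t1")
  # determinism
  expect_identical(as.numeric(fv), as.numeric(extract_features(sc$image, seg$mask)))
})

test_that("global brightness scaling moves V but barely moves H", {
  sc <- tiny_scene(6)
  dim_img <- round(sc$image * 0.8)
  f1 <- extract_features(sc$image, sc$mask)
  f2 <- extract_features(dim_img, sc$mask)
  expect_lt(abs(f1[["H_mean"]] - f2[["H_mean"]]), 1)
  expect_equal(f2[["V_mean"]], 0.8 * f1[["V_mean"]], tolerance = 0.02)
})
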