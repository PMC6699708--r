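# Excess-blue index, Otsu thresholding, mask cleaning, masking.

test_that("excess_blue computes the clipped 2B-R-G index", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(excess_blue(px(100, 50, 200))[1, 1], 250)
  for (g in c(0, 17, 128, 255))
    expect_equal(excess_blue(px(g, g, g))[1, 1], 0)
  expect_equal(excess_blue(px(0, 0, 255))[1, 1], 255)    # clipped at 255
  expect_equal(excess_blue(px(200, 200, 10))[1, 1], 0)   # clipped at 0

  # invariance under swapping R and G at each pixel
  img <- with_seed(8, array(sample(0:255, 10 * 10 * 3, TRUE), c(10, 10, 3)))
  swapped <- img[, , c(2, 1, 3)]
  expect_identical(excess_blue(img), excess_blue(swapped))
})

test_that("Otsu threshold matches exhaustive between-class-variance search", {
  # independent oracle: try every threshold, maximize between-class variance
  otsu_oracle <- function(v) {
    best <- -Inf; tbest <- NA
    for (t in 0:254) {
      lo <- v[v <= t]; hi <- v[v > t]
      if (!length(lo) || !length(hi)) next
      bcv <- (length(lo) / length(v)) * (length(hi) / length(v)) *
        (mean(lo) - mean(hi))^2
      if (bcv > best) { best <- bcv; tbest <- t }
    }
    tbest
  }
  expect_equal(otsu_threshold(c(10, 10, 200, 200)),
               otsu_oracle(c(10, 10, 200, 200)))
  for (seed in 1:15) {
    v <- with_seed(seed, sample(0:255, 40, TRUE))
    if (length(unique(v)) < 2) next
    expect_equal(otsu_threshold(v), otsu_oracle(v))
  }
  expect_error(otsu_threshold(rep(7, 10)), "degenerate")
})

test_that("threshold polarity selects the right side and complements", {
  idx <- matrix(c(10, 10, 200, 200), 2, 2)
  fh <- threshold_mask(idx, "fruit_high")
  expect_identical(fh$mask, idx > 10)
  bh <- threshold_mask(idx, "backdrop_high")
  expect_identical(bh$mask, !fh$mask)
})

test_that("clean_mask removes specks, fills holes, and is idempotent", {
  m <- matrix(FALSE, 120, 120)
  m[20:100, 20:100] <- TRUE                      # 81x81 blob
  m[50:51, 50:51] <- FALSE                       # interior hole (4 px)
  speck <- m; speck[5:6, 5:6] <- TRUE            # 4-px speck far away
  cp <- cleaning_params(min_object_area = 50, min_hole_area = 50,
                        opening_radius = 0)
  out <- clean_mask(speck, cp)
  expect_false(any(out[5:6, 5:6]))               # speck removed
  expect_true(all(out[50:51, 50:51]))            # hole filled
  expect_equal(sum(out), 81 * 81)

  # idempotence on random blobs with the default opening
  for (seed in 1:8) {
    b <- blob_mask(seed, size = 80)
    c1 <- clean_mask(b)
    expect_identical(clean_mask(c1), c1)
  }

  # a clean convex blob is a fixed point: a mask that is a dilation by the
  # structuring disk is open with respect to it, so opening leaves it alone
  core <- matrix(FALSE, 160, 160); core[60:100, 60:100] <- TRUE
  rounded <- melonpheno:::cpp_dilate(core, melonpheno:::disk_offsets(5))
  expect_identical(clean_mask(rounded), rounded)

  expect_error(clean_mask(matrix(FALSE, 10, 10)), "no fruit")
})

test_that("apply_mask zeroes exactly the background", {
  sc <- tiny_scene(2)
  expect_identical(apply_mask(sc$image, matrix(TRUE, 160, 160)), sc$image)
  expect_error(apply_mask(sc$image, matrix(FALSE, 160, 160)), "no fruit")
  expect_error(apply_mask(sc$image, matrix(TRUE, 10, 10)), "mismatch")
  half <- matrix(FALSE, 160, 160); half[, 1:80] <- TRUE
  out <- apply_mask(sc$image, half)
  expect_true(all(out[, 81:160, ] == 0))
  expect_identical(out[, 1:80, ], sc$image[, 1:80, ])
})

test_that("segmentation recovers the ground-truth ellipse", {
  for (seed in c(1, 12, 33, 54, 75)) {
    p <- with_seed(seed, scene_params(
      image_size = c(200, 200),
      fruit_axes = c(runif(1, 55, 70), runif(1, 45, 55)),
      base_hue = runif(1, 50, 110), net_density = runif(1, 0.2, 0.5),
      seed = seed))
    sc <- generate_scene(p)
    seg <- segment_image(sc$image)
    expect_gte(jaccard(seg$mask, sc$mask), 0.95)
  }
})

test_that("working-resolution downscale logs its scale", {
  sc <- tiny_scene(3)
  seg <- segment_image(sc$image, max_side = 80)
  expect_equal(max(dim(seg$mask)), 80)
  expect_equal(seg$scale, 0.5)
  full <- segment_image(sc$image)
  expect_equal(full$scale, 1)
})
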