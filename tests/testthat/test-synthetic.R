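# Synthetic scene and phenotype generator.

test_that("scenes are seeded-deterministic and geometry-validated", {
  p <- scene_params(seed = 3)
  s1 <- generate_scene(p)
  s2 <- generate_scene(p)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  # different seed moves the sensor noise / netting
  s3 <- generate_scene(scene_params(seed = 4))
  expect_false(identical(s1$image, s3$image))

  expect_error(scene_params(image_size = c(100, 100), fruit_axes = c(60, 40)),
               "outside the image frame")
  expect_error(scene_params(net_density = 1.2), "net_density")
  expect_error(scene_params(backdrop_color = c(200, 40, 30)), "blue-dominant")
})

test_that("ground-truth mask equals the analytic ellipse raster", {
  p <- scene_params(image_size = c(200, 200), fruit_axes = c(50, 50),
                    net_density = 0, pixel_noise_sd = 0, seed = 1)
  sc <- generate_scene(p)
  # independent lattice-point count of the disk
  g <- expand.grid(r = 1:200, c = 1:200)
  inside <- (g$r - 100)^2 + (g$c - 100)^2 <= 50^2
  expect_identical(sum(sc$mask), sum(inside))
  expect_equal(sum(sc$mask), pi * 50^2, tolerance = 0.02)

  # no netting -> no high-frequency texture inside the fruit
  fv <- extract_features(sc$image, sc$mask)
  expect_lt(fv[["contrast"]], 1e-8)
})

test_that("phenotypes hit the envelope ends and respect seeding", {
  lo <- generate_phenotypes(0, noise_sd = 0)
  hi <- generate_phenotypes(1, noise_sd = 0)
  env <- melon_traits()
  expect_equal(unname(lo$traits), env$min)
  expect_equal(unname(hi$traits), env$max)
  expect_equal(lo$traits[["carotenoids"]], 0.12)
  expect_equal(hi$traits[["carotenoids"]], 0.40)

  a <- generate_phenotypes(0.4, noise_sd = "calibrated", seed = 99)
  b <- generate_phenotypes(0.4, noise_sd = "calibrated", seed = 99)
  expect_identical(a$traits, b$traits)

  expect_error(generate_phenotypes(1.3), "ripeness")
  expect_error(generate_phenotypes(0.5, noise_sd = -1), "non-negative")
})

test_that("generated traits always stay inside their envelopes", {
  env <- melon_traits()
  for (seed in 1:25) {
    ph <- with_seed(seed, generate_phenotypes(runif(1), noise_sd = 40,
                                              seed = seed))
    expect_true(all(ph$traits >= env$min - 1e-12))
    expect_true(all(ph$traits <= env$max + 1e-12))
  }
})

test_that("cohorts have the right shape and shared per-fruit state", {
  co <- generate_cohort(cohort_spec(n_fruits = 2, views_per_fruit = 3,
                                    seed = 7))
  expect_length(co$scenes, 6)
  expect_equal(nrow(co$phenotypes), 2)
  hues <- vapply(co$scenes, function(s) s$params$base_hue, numeric(1))
  ids <- vapply(co$scenes, function(s) s$fruit_id, character(1))
  expect_true(all(tapply(hues, ids, function(h) length(unique(h))) == 1))

  # study-scale geometry: 134 fruits x 3 views = 402 images
  big <- generate_cohort(cohort_spec(seed = 1))
  expect_length(big$scenes, 402)
  expect_equal(nrow(big$phenotypes), 134)
})

test_that("noise-free cohorts inject a monotone hue signal", {
  co <- generate_cohort(cohort_spec(n_fruits = 20, views_per_fruit = 1,
                                    image_size = c(128, 128),
                                    param_ranges = list(
                                      axes_major = c(36, 44),
                                      axes_minor = c(30, 36),
                                      net_density = c(0.2, 0.5),
                                      net_brightness = c(30, 50),
                                      illumination_gain = c(0.95, 1.05)),
                                    noise_sd = 0, pixel_noise_sd = 0,
                                    seed = 31))
  hue <- vapply(co$scenes, function(sc) {
    s <- generate_scene(sc$params)
    mean(convert_channels(s$image, s$mask)$H)
  }, numeric(1))
  base <- vapply(co$scenes, function(sc) sc$params$base_hue, numeric(1))
  ord <- order(co$phenotypes$ripeness)
  expect_true(all(diff(base[ord]) < 0))  # strictly decreasing in ripeness
  # measured mean hue tracks the constructed hue up to 8-bit rounding
  expect_lt(max(abs(hue - base)), 1)
  for (tr in c("sucrose", "tss", "carotenoids"))
    expect_gt(abs(cor(hue, co$phenotypes[[tr]])), 0.99)
})

test_that("write_cohort round-trips images, masks and tables", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(n_fruits = 2, views_per_fruit = 2,
                                    image_size = c(96, 96),
                                    param_ranges = list(
                                      axes_major = c(28, 34),
                                      axes_minor = c(24, 28),
                                      net_density = c(0.2, 0.5),
                                      net_brightness = c(30, 50),
                                      illumination_gain = c(0.95, 1.05)),
                                    seed = 5))
  mf <- write_cohort(co, dir)
  expect_equal(nrow(mf), 4)
  img <- read_image(mf$image[1])
  mask <- read_mask(mf$mask[1])
  scene <- generate_scene(co$scenes[[1]]$params)
  expect_identical(img, scene$image * 1)
  expect_identical(mask, scene$mask)
  pheno <- read.csv(file.path(dir, "phenotypes.csv"))
  expect_equal(nrow(pheno), 2)
})
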