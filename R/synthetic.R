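# Seeded synthetic data: melon-on-backdrop scenes with procedural netting,
# exact ground-truth masks, and internal phenotypes driven by a latent
# ripeness. Gives every downstream stage a reproducible, structured input
# when no raw images are available.

# Published min-max envelopes and summary statistics of the nine internal
# traits (per-trait sample sizes differ because not every assay was run on
# every fruit).
melon_trait_envelopes <- data.frame(
  trait = c("fructose", "glucose", "sucrose", "total_sugar", "tss",
            "vitamin_c", "chl_a", "chl_b", "carotenoids"),
  unit = c("mg/g", "mg/g", "mg/g", "mg/g", "%", "mg/100g", "mg/g", "mg/g",
           "mg/100g"),
  n = c(123L, 123L, 123L, 123L, 101L, 129L, 130L, 130L, 101L),
  min = c(4.79, 0.21, 1.05, 10.20, 5.80, 3.38, 0.27, 0.16, 0.12),
  max = c(71.12, 72.25, 46.90, 164.20, 18.50, 110.84, 1.64, 1.12, 0.40),
  mean = c(16.83, 9.90, 12.99, 39.71, 10.64, 41.11, 0.84, 0.39, 0.24),
  sd = c(3.75, 3.18, 4.23, 10.32, 3.20, 16.75, 0.23, 0.14, 0.05),
  stringsAsFactors = FALSE
)

#' Internal trait vocabulary and value envelopes
#'
#' The nine internal quality traits the pipeline predicts, with units,
#' per-trait sample sizes and the min/max/mean/sd envelope used by the
#' synthetic phenotype generator.
#'
#' @return a data.frame with columns trait, unit, n, min, max, mean, sd.
#' @export
melon_traits <- function() melon_trait_envelopes

# Strictly monotone ripeness -> [0,1] link: a logistic rescaled so that
# link(0) = 0 and link(1) = 1. Steepness k = 4 keeps the link visibly
# sigmoid while the hue-trait correlation in the noise-free cohort stays
# above 0.99 (see the methods vignette).
ripeness_link <- function(r, k = 4) {
  (plogis(k * (r - 0.5)) - plogis(-k / 2)) / (plogis(k / 2) - plogis(-k / 2))
}

#' Calibrated per-trait noise scale
#'
#' Gaussian noise standard deviations chosen so that the generative signal
#' fraction var(signal) / (var(signal) + sd^2) equals `target_r2` for every
#' trait, with the signal variance taken over the default ripeness range.
#'
#' @param target_r2 generative R-squared of each trait on its latent
#'   ripeness; default 0.9.
#' @param ripeness_range range over which cohort ripeness is drawn.
#' @return named numeric vector of per-trait noise SDs (trait units).
#' @export
default_noise_sd <- function(target_r2 = 0.9, ripeness_range = c(0.05, 0.95)) {
  grid <- seq(ripeness_range[1], ripeness_range[2], length.out = 2001)
  sd_link <- sd(ripeness_link(grid))
  env <- melon_trait_envelopes
  setNames((env$max - env$min) * sd_link * sqrt(1 / target_r2 - 1), env$trait)
}

#' Scene parameters for one synthetic fruit view
#'
#' Describes a single melon-on-backdrop scene: an ellipse-shaped fruit of a
#' given hue with procedural surface netting, on a uniform blue-dominant
#' backdrop (blue-dominant so the 2B-R-G excess-blue index separates
#' backdrop from fruit).
#'
#' @param image_size (H, W) in pixels.
#' @param fruit_center (row, col) of the ellipse centre; default image centre.
#' @param fruit_axes (vertical, horizontal) semi-axes in pixels.
#' @param base_hue fruit hue in degrees (0-360); ripe fruit drift from green
#'   (~110) towards yellow (~50).
#' @param net_density fraction of fruit pixels covered by netting, in \[0, 1\].
#' @param net_brightness 8-bit brightness offset added to netting pixels
#'   (equal on all channels, so pixel hue is preserved).
#' @param backdrop_color RGB triple; must be blue-dominant.
#' @param illumination_gain multiplicative illumination factor.
#' @param pixel_noise_sd per-pixel Gaussian sensor noise SD (8-bit units).
#' @param seed integer seed; identical parameters give byte-identical scenes.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(image_size = c(256, 256), fruit_center = NULL,
                         fruit_axes = c(85, 72), base_hue = 95,
                         net_density = 0.35, net_brightness = 40,
                         backdrop_color = c(30, 40, 230),
                         illumination_gain = 1, pixel_noise_sd = 2,
                         seed = 1L) {
  image_size <- as.integer(image_size)
  fruit_center <- fruit_center %||% (image_size / 2)
  if (any(image_size < 8)) stopf("image_size too small")
  if (net_density < 0 || net_density > 1) stopf("net_density must be in [0, 1]")
  if (backdrop_color[3] <= max(backdrop_color[1:2]))
    stopf("backdrop_color must be blue-dominant for excess-blue segmentation")
  if (fruit_center[1] - fruit_axes[1] < 1.5 ||
      fruit_center[1] + fruit_axes[1] > image_size[1] - 0.5 ||
      fruit_center[2] - fruit_axes[2] < 1.5 ||
      fruit_center[2] + fruit_axes[2] > image_size[2] - 0.5)
    stopf("invalid geometry: fruit ellipse extends outside the image frame")
  structure(list(image_size = image_size, fruit_center = fruit_center,
                 fruit_axes = fruit_axes, base_hue = base_hue,
                 net_density = net_density, net_brightness = net_brightness,
                 backdrop_color = backdrop_color,
                 illumination_gain = illumination_gain,
                 pixel_noise_sd = pixel_noise_sd, seed = as.integer(seed)),
            class = "scene_params")
}

# Separable box blur (5-tap, two passes), circular at the border. Used to
# band-limit white noise before thresholding it into a netting pattern.
box_blur <- function(m, passes = 2) {
  k <- rep(1 / 5, 5)
  for (i in seq_len(passes)) {
    m <- apply(m, 2, function(col) as.numeric(filter(col, k, circular = TRUE)))
    m <- t(apply(m, 1, function(row) as.numeric(filter(row, k, circular = TRUE))))
  }
  m
}

#' Generate one synthetic scene and its ground-truth mask
#'
#' Rasterizes the fruit ellipse analytically (this exact raster is returned
#' as the ground-truth mask), paints the fruit at `base_hue`, overlays a
#' netting pattern obtained by thresholding band-limited noise at quantile
#' `1 - net_density`, applies the illumination gain and adds seeded sensor
#' noise. Netting and illumination change pixel brightness but not hue.
#'
#' @param params a [scene_params()] object.
#' @return list with `image` (H x W x 3 array, 0-255) and `mask` (logical
#'   matrix, the analytic ellipse raster).
#' @export
generate_scene <- function(params) {
  if (!inherits(params, "scene_params")) params <- do.call(scene_params, params)
  H <- params$image_size[1]; W <- params$image_size[2]
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  mask <- ((rows - params$fruit_center[1]) / params$fruit_axes[1])^2 +
    ((cols - params$fruit_center[2]) / params$fruit_axes[2])^2 <= 1

  base_rgb <- as.numeric(col2rgb(hsv(params$base_hue / 360, 0.75, 0.65)))
  img <- with_seed(params$seed, {
    im <- array(0, c(H, W, 3))
    for (ch in 1:3) im[, , ch] <- params$backdrop_color[ch]
    for (ch in 1:3) im[, , ch][mask] <- base_rgb[ch]
    if (params$net_density > 0) {
      noise <- box_blur(matrix(runif(H * W), H, W))
      thr <- quantile(noise[mask], 1 - params$net_density, names = FALSE)
      net <- mask & noise > thr
      for (ch in 1:3) im[, , ch][net] <- im[, , ch][net] + params$net_brightness
    }
    im <- im * params$illumination_gain
    if (params$pixel_noise_sd > 0)
      im <- im + array(rnorm(length(im), 0, params$pixel_noise_sd), dim(im))
    round(clip255(im))
  })
  list(image = img, mask = mask)
}

#' Generate internal phenotypes from a latent ripeness
#'
#' Each trait is its envelope minimum plus the envelope span warped by a
#' fixed strictly monotone (scaled logistic) link of ripeness, plus seeded
#' Gaussian noise, clipped back to the envelope. All traits share the same
#' latent ripeness, so colour-trait correlations emerge downstream.
#'
#' @param ripeness latent maturity in \[0, 1\].
#' @param noise_sd per-trait Gaussian noise SD: a scalar (recycled), a named
#'   vector over traits, or "calibrated" for [default_noise_sd()].
#' @param seed integer seed.
#' @return list with `ripeness`, `traits` (named numeric vector, trait
#'   units) and `noise_sd` (the per-trait vector used).
#' @export
generate_phenotypes <- function(ripeness, noise_sd = 0, seed = 1L) {
  if (ripeness < 0 || ripeness > 1) stopf("ripeness must be in [0, 1]")
  env <- melon_trait_envelopes
  if (identical(noise_sd, "calibrated")) noise_sd <- default_noise_sd()
  if (is.null(names(noise_sd))) {
    noise_sd <- setNames(rep_len(as.numeric(noise_sd), nrow(env)), env$trait)
  } else {
    missing <- setdiff(env$trait, names(noise_sd))
    if (length(missing)) stopf("noise_sd missing traits: %s",
                               paste(missing, collapse = ", "))
    noise_sd <- noise_sd[env$trait]
  }
  if (any(noise_sd < 0)) stopf("noise_sd must be non-negative")
  vals <- with_seed(seed, {
    signal <- env$min + (env$max - env$min) * ripeness_link(ripeness)
    pmin(pmax(signal + rnorm(nrow(env), 0, noise_sd), env$min), env$max)
  })
  list(ripeness = ripeness, traits = setNames(vals, env$trait),
       noise_sd = noise_sd)
}

#' Cohort specification
#'
#' Defaults reproduce the study geometry: 134 fruits imaged from 3 angles
#' each (402 views), ripeness drawn uniformly, scene geometry and netting
#' sampled per view within `param_ranges`, and trait noise calibrated to a
#' generative R-squared of 0.9.
#'
#' @param n_fruits number of fruits.
#' @param views_per_fruit camera views per fruit.
#' @param image_size (H, W) of each synthetic view.
#' @param ripeness_range sampling range of the latent ripeness.
#' @param noise_sd per-trait phenotype noise; default "calibrated".
#' @param param_ranges list of sampling ranges for per-view scene fields.
#' @param pixel_noise_sd per-pixel sensor noise SD forwarded to every scene.
#' @param seed integer master seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_fruits = 134, views_per_fruit = 3,
                        image_size = c(256, 256),
                        ripeness_range = c(0.05, 0.95),
                        noise_sd = "calibrated",
                        param_ranges = list(
                          axes_major = c(78, 95), axes_minor = c(64, 78),
                          net_density = c(0.2, 0.5),
                          net_brightness = c(30, 50),
                          illumination_gain = c(0.95, 1.05)),
                        pixel_noise_sd = 2,
                        seed = 1L) {
  if (n_fruits < 1 || views_per_fruit < 1)
    stopf("n_fruits and views_per_fruit must be >= 1")
  structure(list(n_fruits = as.integer(n_fruits),
                 views_per_fruit = as.integer(views_per_fruit),
                 image_size = as.integer(image_size),
                 ripeness_range = ripeness_range, noise_sd = noise_sd,
                 param_ranges = param_ranges,
                 pixel_noise_sd = pixel_noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Fruit hue as a strictly monotone function of ripeness: green -> yellow.
ripeness_hue <- function(ripeness) 110 - 60 * ripeness

#' Generate a seeded cohort of scenes and phenotypes
#'
#' Draws one latent ripeness per fruit; all views of a fruit share its
#' phenotypes and its base hue (a strictly monotone, decreasing function of
#' ripeness, green towards yellow), while netting, geometry and illumination
#' vary per view. Scenes are returned as parameter records so that cohorts
#' of hundreds of views stay lightweight; call [generate_scene()] on a
#' record's `$params` (or use `materialize = TRUE` for small cohorts, or
#' [write_cohort()] to rasterize to disk).
#'
#' @param spec a [cohort_spec()].
#' @param materialize if TRUE, include the rasterized `image`/`mask` in each
#'   scene record (memory-heavy for large cohorts).
#' @return list with `scenes` (one record per view: image_id, fruit_id,
#'   view, ripeness, params) and `phenotypes` (data.frame, one row per
#'   fruit: fruit_id, ripeness, nine trait columns).
#' @export
generate_cohort <- function(spec = cohort_spec(), materialize = FALSE) {
  if (!inherits(spec, "cohort_spec")) stopf("spec must be a cohort_spec")
  n <- spec$n_fruits; v <- spec$views_per_fruit
  pr <- spec$param_ranges
  draws <- with_seed(spec$seed, {
    list(ripeness = runif(n, spec$ripeness_range[1], spec$ripeness_range[2]),
         pheno_seeds = sample.int(.Machine$integer.max - 1L, n),
         scene_seeds = sample.int(.Machine$integer.max - 1L, n * v),
         axes_major = runif(n * v, pr$axes_major[1], pr$axes_major[2]),
         axes_minor = runif(n * v, pr$axes_minor[1], pr$axes_minor[2]),
         net_density = runif(n * v, pr$net_density[1], pr$net_density[2]),
         net_brightness = runif(n * v, pr$net_brightness[1], pr$net_brightness[2]),
         gain = runif(n * v, pr$illumination_gain[1], pr$illumination_gain[2]))
  })
  env <- melon_trait_envelopes
  pheno <- data.frame(fruit_id = sprintf("fruit%03d", seq_len(n)),
                      ripeness = draws$ripeness, stringsAsFactors = FALSE)
  for (tr in env$trait) pheno[[tr]] <- NA_real_
  scenes <- vector("list", n * v)
  k <- 0L
  for (i in seq_len(n)) {
    ph <- generate_phenotypes(draws$ripeness[i], spec$noise_sd,
                              seed = draws$pheno_seeds[i])
    pheno[i, env$trait] <- as.list(ph$traits)
    for (j in seq_len(v)) {
      k <- k + 1L
      # semi-major axis is vertical; keep the ellipse inside the frame
      amax <- min(draws$axes_major[k], spec$image_size[1] / 2 - 3)
      bmax <- min(draws$axes_minor[k], spec$image_size[2] / 2 - 3)
      params <- scene_params(
        image_size = spec$image_size,
        fruit_axes = c(amax, min(bmax, amax)),
        base_hue = ripeness_hue(draws$ripeness[i]),
        net_density = draws$net_density[k],
        net_brightness = draws$net_brightness[k],
        illumination_gain = draws$gain[k],
        pixel_noise_sd = spec$pixel_noise_sd,
        seed = draws$scene_seeds[k])
      rec <- list(image_id = sprintf("fruit%03d_view%d", i, j),
                  fruit_id = sprintf("fruit%03d", i), view = j,
                  ripeness = draws$ripeness[i], params = params)
      if (materialize) rec <- c(rec, generate_scene(params))
      scenes[[k]] <- rec
    }
  }
  list(scenes = scenes, phenotypes = pheno)
}

#' Rasterize a cohort to disk
#'
#' Writes `images/<id>.png`, ground-truth `masks/<id>.png`,
#' `phenotypes.csv` and a `scenes.csv` manifest under `dir`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param format image format, "png" (default, lossless) or "jpg".
#' @return data.frame manifest of image ids, fruit ids and file paths.
#' @export
write_cohort <- function(cohort, dir, format = c("png", "jpg")) {
  format <- match.arg(format)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$scenes, function(sc) {
    scene <- if (!is.null(sc[["image"]])) sc else generate_scene(sc$params)
    img_path <- file.path(dir, "images", paste0(sc$image_id, ".", format))
    mask_path <- file.path(dir, "masks", paste0(sc$image_id, ".png"))
    write_image(scene$image, img_path)
    write_mask(scene$mask, mask_path)
    data.frame(image_id = sc$image_id, fruit_id = sc$fruit_id, view = sc$view,
               image = img_path, mask = mask_path, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
            row.names = FALSE)
  write.csv(manifest, file.path(dir, "scenes.csv"), row.names = FALSE)
  manifest
}
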