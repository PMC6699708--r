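# Fruit/backdrop segmentation: excess-blue colour index -> Otsu threshold
# -> small-object removal -> hole filling -> morphological opening ->
# masking. The backdrop is blue-dominant, so the index is high on backdrop
# and the fruit mask is, by default, the complement of the thresholded
# blue-excess region.

#' Excess-blue colour index (2B - R - G)
#'
#' Per-pixel 2*Blue - Red - Green, clipped to \[0, 255\]. A blue-excess
#' variant of the excess-green (2G - R - B) vegetation index: against a
#' saturated blue backdrop the backdrop scores high and the fruit near zero.
#' Invariant under swapping R and G at any pixel.
#'
#' @param image H x W x 3 array, 0-255.
#' @return H x W numeric matrix of clipped index values.
#' @export
excess_blue <- function(image) {
  check_image(image)
  v <- clip255(2 * image[, , 3] - image[, , 1] - image[, , 2])
  matrix(v, dim(image)[1], dim(image)[2])
}

#' Otsu threshold of an 8-bit index image
#'
#' Exhaustively maximizes the between-class variance of the 256-bin
#' histogram; returns the bin value t such that the classes are
#' `{x <= t}` and `{x > t}`.
#'
#' @param values numeric vector or matrix of values in \[0, 255\].
#' @return the threshold t (numeric scalar).
#' @export
otsu_threshold <- function(values) {
  v <- as.integer(round(as.numeric(values)))
  if (length(unique(v)) < 2L)
    stopf("degenerate histogram: index image is constant")
  h <- as.numeric(tabulate(v + 1L, nbins = 256L))
  n <- sum(h)
  lev <- 0:255
  w1 <- cumsum(h)
  m1 <- cumsum(h * lev)
  mtot <- m1[256]
  # between-class variance for threshold at each level t = 0..254
  w1t <- w1[1:255]; m1t <- m1[1:255]
  w2t <- n - w1t
  valid <- w1t > 0 & w2t > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mtot * w1t[valid] / n - m1t[valid])^2 /
    (w1t[valid] / n * w2t[valid] / n) / n^2
  lev[which.max(bcv)]
}

#' Threshold an index image into a fruit mask
#'
#' Applies the Otsu threshold to the excess-blue index. With the default
#' `backdrop_high` polarity the blue backdrop carries the high index values
#' and the fruit mask is `{index <= t}`; `fruit_high` takes the complement
#' convention. Flipping polarity yields exact mask complements.
#'
#' @param index matrix from [excess_blue()].
#' @param polarity which side of the threshold is fruit.
#' @return list with `mask` (logical matrix) and `threshold` (the Otsu t).
#' @export
threshold_mask <- function(index, polarity = c("backdrop_high", "fruit_high")) {
  polarity <- match.arg(polarity)
  t <- otsu_threshold(index)
  mask <- if (polarity == "backdrop_high") index <= t else index > t
  list(mask = mask, threshold = t)
}

#' Mask-cleaning parameters
#'
#' Defaults follow common practice at the working resolution: specks below
#' 0.5% of the image area are removed, background holes below 0.1% filled,
#' and a disk of radius 5 px used for the opening.
#'
#' @param min_object_area minimum connected-component area kept, px; `NULL`
#'   defers to `min_object_frac` of the image area at clean time.
#' @param min_hole_area maximum hole area filled, px; `NULL` defers to
#'   `min_hole_frac`.
#' @param opening_radius structuring-disk radius for the opening, px.
#' @param min_object_frac,min_hole_frac fractions of image area used when
#'   the absolute areas are `NULL`.
#' @return an object of class `cleaning_params`.
#' @export
cleaning_params <- function(min_object_area = NULL, min_hole_area = NULL,
                            opening_radius = 5, min_object_frac = 0.005,
                            min_hole_frac = 0.001) {
  if (!is.null(min_object_area) && min_object_area < 0) stopf("min_object_area < 0")
  if (!is.null(min_hole_area) && min_hole_area < 0) stopf("min_hole_area < 0")
  if (opening_radius < 0) stopf("opening_radius < 0")
  structure(list(min_object_area = min_object_area,
                 min_hole_area = min_hole_area,
                 opening_radius = opening_radius,
                 min_object_frac = min_object_frac,
                 min_hole_frac = min_hole_frac),
            class = "cleaning_params")
}

#' Clean a thresholded mask
#'
#' Removes small 8-connected components (the largest component is always
#' kept, which makes cleaning idempotent), fills small background holes,
#' applies a binary opening with a disk, and keeps the largest surviving
#' component (single-fruit assumption). Errors if nothing survives.
#'
#' @param mask logical matrix.
#' @param params a [cleaning_params()] object.
#' @return cleaned logical matrix.
#' @export
clean_mask <- function(mask, params = cleaning_params()) {
  check_mask(mask)
  npx <- length(mask)
  min_obj <- params$min_object_area %||% (params$min_object_frac * npx)
  min_hole <- params$min_hole_area %||% (params$min_hole_frac * npx)

  if (any(mask)) {
    lab <- cpp_label(mask, 8L)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_obj)
    keep <- union(keep, which.max(sizes))  # never drop the largest blob
    mask <- matrix(lab %in% keep & lab > 0, nrow(mask), ncol(mask))
  }
  if (min_hole > 0 && any(mask)) mask <- cpp_fill_holes(mask, min_hole)
  if (params$opening_radius > 0 && any(mask)) {
    se <- disk_offsets(params$opening_radius)
    mask <- cpp_dilate(cpp_erode(mask, se), se)
  }
  if (any(mask)) {
    lab <- cpp_label(mask, 8L)
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
  }
  if (!any(mask)) stopf("no fruit found: mask empty after cleaning")
  mask
}

#' Apply a mask to an image
#'
#' Zeroes background pixels and leaves foreground pixels untouched. All
#' downstream statistics are computed on foreground pixels only.
#'
#' @param image H x W x 3 array.
#' @param mask logical H x W matrix with at least one foreground pixel.
#' @return masked image array.
#' @export
apply_mask <- function(image, mask) {
  check_image(image); check_mask(mask)
  if (!all(dim(image)[1:2] == dim(mask))) stopf("image/mask shape mismatch")
  if (!any(mask)) stopf("no fruit found: mask is empty")
  out <- image
  for (ch in 1:3) out[, , ch][!mask] <- 0
  out
}

#' Gray-world white balance
#'
#' Scales each channel so its mean matches the global mean intensity. An
#' optional stand-in for colour-card correction; off by default everywhere.
#'
#' @param image H x W x 3 array.
#' @return balanced image array (0-255).
#' @export
gray_world <- function(image) {
  check_image(image)
  means <- apply(image, 3, mean)
  target <- mean(means)
  out <- image
  for (ch in 1:3) out[, , ch] <- image[, , ch] * (target / max(means[ch], 1e-8))
  clip255(out)
}

#' Segment a fruit image end to end
#'
#' Optional gray-world balance and downscaling, then the index ->
#' threshold -> clean chain. The logged threshold and scale accompany the
#' mask so that features can be traced to the working resolution.
#'
#' @param image H x W x 3 array, 0-255.
#' @param polarity passed to [threshold_mask()].
#' @param cleaning a [cleaning_params()] object.
#' @param white_balance apply [gray_world()] first (default FALSE).
#' @param max_side working-resolution bound passed to [resize_longest()].
#' @return list with `mask`, `image` (at working resolution), `index`,
#'   `threshold` and `scale`.
#' @export
segment_image <- function(image, polarity = c("backdrop_high", "fruit_high"),
                          cleaning = cleaning_params(), white_balance = FALSE,
                          max_side = 1024) {
  polarity <- match.arg(polarity)
  check_image(image)
  if (white_balance) image <- gray_world(image)
  rs <- resize_longest(image, max_side)
  image <- rs$x
  idx <- excess_blue(image)
  th <- threshold_mask(idx, polarity)
  mask <- clean_mask(th$mask, cleaning)
  list(mask = mask, image = image, index = idx, threshold = th$threshold,
       scale = rs$scale)
}
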