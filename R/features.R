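# Extraction of the 65 external phenotype parameters from a segmented
# image: 45 colour statistics (5 statistics x 9 channels over RGB, CIELAB
# and HSV), 6 gray-level co-occurrence texture statistics of the surface
# netting, and 14 contour morphology descriptors, in a fixed order.

feature_channel_names <- c("R", "G", "B", "L", "a", "b", "H", "S", "V")
feature_stat_names <- c("mean", "sd", "median", "range", "cv")
feature_texture_names <- c("contrast", "dissimilarity", "homogeneity",
                           "energy", "correlation", "asm")
feature_morpho_names <- c("contour_area", "perimeter", "w", "h", "hull_area",
                          "x_w", "x_h", "MA", "ma", "r",
                          "equivalent_diameter", "aspect_ratio", "extent",
                          "solidity")

#' Names and categories of the 65 external parameters
#'
#' `feature_names()` returns the 65 parameter names in their fixed
#' numbering order (1-45 colour, 46-51 texture, 52-65 morphology);
#' `feature_categories()` the matching category labels.
#'
#' @return character vector of length 65.
#' @export
feature_names <- function() {
  color <- as.vector(t(outer(feature_channel_names, feature_stat_names,
                             paste, sep = "_")))
  c(color, feature_texture_names, feature_morpho_names)
}

#' @rdname feature_names
#' @export
feature_categories <- function() {
  setNames(rep(c("color", "texture", "morphology"), c(45L, 6L, 14L)),
           feature_names())
}

#' Per-pixel colour channels over the fruit region
#'
#' Computes the nine channels on foreground pixels only: R, G, B read
#' directly (0-255); CIELAB via sRGB -> XYZ (D65) -> Lab (L in 0-100, a/b
#' signed); HSV via the hexcone model (H in degrees 0-360, S and V in 0-1).
#'
#' @param image H x W x 3 array, 0-255.
#' @param mask logical matrix; must have at least one foreground pixel.
#' @return named list of nine numeric vectors of equal length.
#' @export
convert_channels <- function(image, mask) {
  check_image(image); check_mask(mask)
  if (!all(dim(image)[1:2] == dim(mask))) stopf("image/mask shape mismatch")
  if (!any(mask)) stopf("empty mask: no foreground pixels")
  rgb <- cbind(R = image[, , 1][mask], G = image[, , 2][mask],
               B = image[, , 3][mask])
  lab <- convertColor(rgb / 255, from = "sRGB", to = "Lab")
  hsv <- rgb2hsv(t(rgb), maxColorValue = 255)
  list(R = unname(rgb[, 1]), G = unname(rgb[, 2]), B = unname(rgb[, 3]),
       L = unname(lab[, 1]), a = unname(lab[, 2]), b = unname(lab[, 3]),
       H = unname(hsv[1, ]) * 360, S = unname(hsv[2, ]), V = unname(hsv[3, ]))
}

#' The five summary statistics of one channel
#'
#' Mean, sample SD (n-1 denominator), median (mean-of-middle-two), range
#' (max - min) and coefficient of variation (SD/mean; 0 when the mean is 0).
#'
#' @param values numeric vector, length >= 1.
#' @return named numeric vector (mean, sd, median, range, cv).
#' @export
channel_stats <- function(values) {
  if (length(values) < 1L) stopf("channel_stats needs at least one value")
  m <- mean(values)
  s <- if (length(values) > 1L) sd(values) else 0
  cv <- if (m != 0) s / m else 0
  c(mean = m, sd = s, median = median(values),
    range = max(values) - min(values), cv = cv)
}

#' Co-occurrence matrix configuration
#'
#' @param levels gray quantization bins (>= 2).
#' @param distance pixel offset distance (>= 1).
#' @param angles offset angles in degrees; 0 is horizontal, angles measured
#'   counter-clockwise with image rows running downwards.
#' @param symmetric add the transposed counts (default TRUE).
#' @param normalized scale each matrix to sum 1 (default TRUE).
#' @return an object of class `glcm_config`.
#' @export
glcm_config <- function(levels = 64, distance = 1,
                        angles = c(0, 45, 90, 135),
                        symmetric = TRUE, normalized = TRUE) {
  if (levels < 2) stopf("levels must be >= 2")
  if (distance < 1) stopf("distance must be >= 1")
  structure(list(levels = as.integer(levels), distance = as.integer(distance),
                 angles = angles, symmetric = symmetric,
                 normalized = normalized),
            class = "glcm_config")
}

glcm_offsets <- function(angles, d) {
  dr <- integer(length(angles)); dc <- integer(length(angles))
  for (i in seq_along(angles)) {
    a <- angles[i] %% 180
    if (a == 0) { dr[i] <- 0L; dc[i] <- d }
    else if (a == 45) { dr[i] <- -d; dc[i] <- d }
    else if (a == 90) { dr[i] <- -d; dc[i] <- 0L }
    else if (a == 135) { dr[i] <- -d; dc[i] <- -d }
    else stopf("unsupported GLCM angle %s (use multiples of 45)", angles[i])
  }
  list(dr = dr, dc = dc)
}

#' Gray-level co-occurrence matrix of the fruit region
#'
#' Quantizes an 8-bit gray image into `levels` uniform bins, counts level
#' pairs at the configured offsets restricted to pixel pairs that are both
#' inside the mask, symmetrizes and normalizes each per-angle matrix, then
#' averages over angles.
#'
#' @param gray numeric matrix of 0-255 gray values (NAs treated as outside).
#' @param config a [glcm_config()].
#' @param mask optional logical matrix restricting the region of interest.
#' @return `levels` x `levels` co-occurrence probability matrix.
#' @export
glcm_matrix <- function(gray, config = glcm_config(), mask = NULL) {
  if (!is.matrix(gray)) stopf("gray must be a matrix")
  q <- matrix(NA_integer_, nrow(gray), ncol(gray))
  inside <- !is.na(gray)
  if (!is.null(mask)) inside <- inside & mask
  q[inside] <- pmin(as.integer(floor(gray[inside] * config$levels / 256)),
                    config$levels - 1L)
  off <- glcm_offsets(config$angles, config$distance)
  counts <- cpp_glcm(q, config$levels, off$dr, off$dc)
  acc <- matrix(0, config$levels, config$levels)
  used <- 0L
  for (a in seq_along(off$dr)) {
    C <- counts[, , a]
    if (config$symmetric) C <- C + t(C)
    s <- sum(C)
    if (s == 0) next
    used <- used + 1L
    acc <- acc + (if (config$normalized) C / s else C)
  }
  if (used == 0L) stopf("no valid pixel pairs for the GLCM")
  acc / used
}

#' Texture statistics of a co-occurrence matrix
#'
#' The six netting texture statistics: contrast, dissimilarity,
#' homogeneity, energy, correlation, and angular second moment (ASM, with
#' energy = sqrt(ASM)). Correlation is defined as 0 when either marginal
#' SD vanishes.
#'
#' @param P normalized (sum 1) square co-occurrence matrix.
#' @return named numeric vector of the six statistics.
#' @export
texture_stats <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) stopf("P must be square")
  if (abs(sum(P) - 1) > 1e-6) stopf("P must be normalized to sum 1")
  n <- nrow(P)
  i <- matrix(0:(n - 1), n, n)
  j <- t(i)
  d <- i - j
  contrast <- sum(P * d^2)
  dissimilarity <- sum(P * abs(d))
  homogeneity <- sum(P / (1 + d^2))
  asm <- sum(P^2)
  pi_ <- rowSums(P); pj <- colSums(P)
  mui <- sum((0:(n - 1)) * pi_); muj <- sum((0:(n - 1)) * pj)
  sdi <- sqrt(sum((0:(n - 1) - mui)^2 * pi_))
  sdj <- sqrt(sum((0:(n - 1) - muj)^2 * pj))
  correlation <- if (sdi * sdj > 0)
    sum((i - mui) * (j - muj) * P) / (sdi * sdj) else 0
  c(contrast = contrast, dissimilarity = dissimilarity,
    homogeneity = homogeneity, energy = sqrt(asm),
    correlation = correlation, asm = asm)
}

# Shoelace polygon area.
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Minimum-area rotated rectangle of a point set via rotating calipers over
# hull edges; returns side lengths (along-edge, perpendicular).
min_area_rect <- function(x, y) {
  h <- chull(x, y)
  hx <- x[h]; hy <- y[h]
  m <- length(hx)
  if (m < 2) return(c(0, 0))
  best <- c(Inf, 0, 0)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    dx <- hx[j] - hx[i]; dy <- hy[j] - hy[i]
    len <- sqrt(dx^2 + dy^2)
    if (len == 0) next
    ux <- dx / len; uy <- dy / len
    pu <- hx * ux + hy * uy
    pv <- -hx * uy + hy * ux
    w <- max(pu) - min(pu); hgt <- max(pv) - min(pv)
    if (w * hgt < best[1]) best <- c(w * hgt, w, hgt)
  }
  best[2:3]
}

# Exact minimum enclosing circle (Welzl, deterministic shuffle).
min_enclosing_circle <- function(x, y) {
  h <- chull(x, y)
  px <- x[h]; py <- y[h]
  ord <- with_seed(20260911L, sample.int(length(px)))
  px <- px[ord]; py <- py[ord]
  circ2 <- function(ax, ay, bx, by)
    c((ax + bx) / 2, (ay + by) / 2, sqrt((ax - bx)^2 + (ay - by)^2) / 2)
  circ3 <- function(ax, ay, bx, by, cx, cy) {
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  inc <- function(c3, qx, qy)
    sqrt((qx - c3[1])^2 + (qy - c3[2])^2) <= c3[3] + 1e-9
  n <- length(px)
  circ <- c(px[1], py[1], 0)
  for (i in seq_len(n)) {
    if (inc(circ, px[i], py[i])) next
    circ <- c(px[i], py[i], 0)
    for (j in seq_len(i - 1L)) {
      if (inc(circ, px[j], py[j])) next
      circ <- circ2(px[i], py[i], px[j], py[j])
      for (k in seq_len(j - 1L)) {
        if (inc(circ, px[k], py[k])) next
        c3 <- circ3(px[i], py[i], px[j], py[j], px[k], py[k])
        if (!is.null(c3)) circ <- c3
      }
    }
  }
  circ
}

#' The 14 morphology descriptors of a fruit mask
#'
#' Contour-based shape descriptors of a single-component mask: pixel area,
#' traced-boundary perimeter, axis-aligned bounding box (w, h), convex hull
#' area (hull of the boundary pixels' corners, so hull_area >= area),
#' minimum-area rotated rectangle sides (x_w, x_h), moment-fitted ellipse
#' axes (MA >= ma, full axes), minimum enclosing circle radius r,
#' equivalent diameter sqrt(4*area/pi), aspect ratio (long/short rotated
#' side, >= 1), extent (area / bounding-box area) and solidity
#' (area / hull area, <= 1).
#'
#' @param mask logical matrix with one 8-connected foreground component.
#' @param mm_per_px optional scale; lengths reported in mm and areas in mm^2
#'   when given, otherwise working-resolution pixels.
#' @return named numeric vector of the 14 descriptors.
#' @export
morphology_stats <- function(mask, mm_per_px = NULL) {
  check_mask(mask)
  if (!any(mask)) stopf("empty mask")
  lab <- cpp_label(mask, 8L)
  if (max(lab) != 1L) stopf("mask must contain exactly one component, found %d",
                            max(lab))
  area <- sum(mask)
  bnd <- cpp_boundary(mask)
  bx <- as.numeric(bnd[, 2]); by <- as.numeric(bnd[, 1]) # x = col, y = row
  nb <- length(bx)
  perimeter <- if (nb > 1)
    sum(sqrt(diff(c(bx, bx[1]))^2 + diff(c(by, by[1]))^2)) else 0

  rows <- which(mask, arr.ind = TRUE)
  w <- diff(range(rows[, 2])) + 1
  h <- diff(range(rows[, 1])) + 1

  # hull over the pixel corners of the boundary (covers the pixel squares)
  cx <- c(bx - 0.5, bx + 0.5, bx - 0.5, bx + 0.5)
  cy <- c(by - 0.5, by - 0.5, by + 0.5, by + 0.5)
  hidx <- chull(cx, cy)
  hull_area <- polygon_area(cx[hidx], cy[hidx])
  hull_area <- max(hull_area, area)

  rect <- min_area_rect(cx, cy)
  x_w <- rect[1]; x_h <- rect[2]
  aspect_ratio <- if (min(rect) > 0) max(rect) / min(rect) else 1

  # moment-fitted ellipse (second central moments, + 1/12 pixel variance)
  my <- mean(rows[, 1]); mx <- mean(rows[, 2])
  cyy <- mean((rows[, 1] - my)^2) + 1 / 12
  cxx <- mean((rows[, 2] - mx)^2) + 1 / 12
  cxy <- mean((rows[, 1] - my) * (rows[, 2] - mx))
  tr <- cxx + cyy
  det2 <- sqrt(max((cxx - cyy)^2 / 4 + cxy^2, 0))
  l1 <- tr / 2 + det2; l2 <- max(tr / 2 - det2, 0)
  MA <- 4 * sqrt(l1); ma <- 4 * sqrt(l2)

  mec <- min_enclosing_circle(cx, cy)
  r <- mec[3]

  out <- c(contour_area = area, perimeter = perimeter, w = w, h = h,
           hull_area = hull_area, x_w = x_w, x_h = x_h, MA = MA, ma = ma,
           r = r, equivalent_diameter = sqrt(4 * area / pi),
           aspect_ratio = aspect_ratio, extent = area / (w * h),
           solidity = area / hull_area)
  if (!is.null(mm_per_px)) {
    len <- c("perimeter", "w", "h", "x_w", "x_h", "MA", "ma", "r",
             "equivalent_diameter")
    ar <- c("contour_area", "hull_area")
    out[len] <- out[len] * mm_per_px
    out[ar] <- out[ar] * mm_per_px^2
  }
  out
}

# Rec. 601 luma of the masked image, NA outside the mask.
luma_matrix <- function(image, mask) {
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  g[!mask] <- NA_real_
  g
}

#' Extract the full 65-parameter feature vector
#'
#' Concatenates, in the fixed numbering order, the 45 colour statistics
#' ([convert_channels()] + [channel_stats()]), the 6 texture statistics of
#' the masked-region GLCM, and the 14 morphology descriptors.
#'
#' @param image H x W x 3 array, 0-255.
#' @param mask cleaned single-component fruit mask.
#' @param glcm a [glcm_config()].
#' @param mm_per_px optional morphology scale.
#' @param image_id optional provenance id stored as an attribute.
#' @return named numeric vector of length 65 (see [feature_names()]).
#' @export
extract_features <- function(image, mask, glcm = glcm_config(),
                             mm_per_px = NULL, image_id = NULL) {
  ch <- convert_channels(image, mask)
  color <- unlist(lapply(feature_channel_names, function(nm)
    setNames(channel_stats(ch[[nm]]),
             paste(nm, feature_stat_names, sep = "_"))))
  P <- glcm_matrix(luma_matrix(image, mask), glcm)
  texture <- texture_stats(P)
  morpho <- morphology_stats(mask, mm_per_px)
  out <- c(color, texture, morpho)
  names(out) <- feature_names()
  if (!is.null(image_id)) attr(out, "image_id") <- image_id
  out
}
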