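# Shared fixtures: all inputs are generated in code, seeded, and small.

# A quick default scene (160 px) for tests that only need "a valid image".
tiny_scene <- function(seed = 1, ...) {
  generate_scene(scene_params(image_size = c(160, 160),
                              fruit_axes = c(55, 45), seed = seed, ...))
}

# Random single-component blob mask: union of overlapping disks on a grid.
blob_mask <- function(seed, size = 60, ndisks = 4) {
  with_seed(seed, {
    m <- matrix(FALSE, size, size)
    rows <- matrix(seq_len(size), size, size)
    cols <- t(rows)
    cy <- size / 2; cx <- size / 2
    for (i in seq_len(ndisks)) {
      r <- runif(1, size / 10, size / 5)
      # each disk overlaps the previous centre, keeping the blob connected
      ny <- cy + runif(1, -r, r); nx <- cx + runif(1, -r, r)
      ny <- min(max(ny, r + 2), size - r - 2)
      nx <- min(max(nx, r + 2), size - r - 2)
      m <- m | ((rows - ny)^2 + (cols - nx)^2 <= r^2)
      cy <- ny; cx <- nx
    }
    m
  })
}

# Brute-force GLCM texture statistics: double loop over all pixel pairs,
# fully independent of the package's matrix path.
brute_texture <- function(gray, levels, distance = 1,
                          angles = c(0, 45, 90, 135)) {
  q <- pmin(floor(gray * levels / 256), levels - 1)
  H <- nrow(q); W <- ncol(q)
  offs <- list(`0` = c(0, distance), `45` = c(-distance, distance),
               `90` = c(-distance, 0), `135` = c(-distance, -distance))
  acc <- matrix(0, levels, levels)
  used <- 0
  for (a in as.character(angles)) {
    o <- offs[[a]]
    C <- matrix(0, levels, levels)
    for (r in seq_len(H)) for (c in seq_len(W)) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr < 1 || rr > H || cc < 1 || cc > W) next
      if (is.na(q[r, c]) || is.na(q[rr, cc])) next
      C[q[r, c] + 1, q[rr, cc] + 1] <- C[q[r, c] + 1, q[rr, cc] + 1] + 1
    }
    C <- C + t(C)
    if (sum(C) == 0) next
    acc <- acc + C / sum(C)
    used <- used + 1
  }
  P <- acc / used
  i <- matrix(0:(levels - 1), levels, levels); j <- t(i)
  pi_ <- rowSums(P); pj <- colSums(P)
  mui <- sum((0:(levels - 1)) * pi_); muj <- sum((0:(levels - 1)) * pj)
  sdi <- sqrt(sum((0:(levels - 1) - mui)^2 * pi_))
  sdj <- sqrt(sum((0:(levels - 1) - muj)^2 * pj))
  c(contrast = sum(P * (i - j)^2),
    dissimilarity = sum(P * abs(i - j)),
    homogeneity = sum(P / (1 + (i - j)^2)),
    energy = sqrt(sum(P^2)),
    correlation = if (sdi * sdj > 0) sum((i - mui) * (j - muj) * P) / (sdi * sdj) else 0,
    asm = sum(P^2))
}

# Exhaustive two-sided permutation p-value for a Pearson correlation
# (n <= 6 keeps n! enumerable); the independent oracle for the t-based p.
perm_pearson_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (rest in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  r_obs <- abs(cor(x, y))
  rs <- vapply(perms(seq_along(y)), function(p) abs(cor(x, y[p])), numeric(1))
  mean(rs >= r_obs - 1e-12)
}

# A small fully-processed cohort at fruit level (features from predicted
# masks + phenotypes), used by screening/modeling tests.
small_cohort_tables <- function(n_fruits = 24, views = 1, seed = 402,
                                noise_sd = "calibrated") {
  co <- generate_cohort(cohort_spec(n_fruits = n_fruits,
                                    views_per_fruit = views,
                                    image_size = c(160, 160),
                                    param_ranges = list(
                                      axes_major = c(45, 55),
                                      axes_minor = c(38, 45),
                                      net_density = c(0.2, 0.5),
                                      net_brightness = c(30, 50),
                                      illumination_gain = c(0.95, 1.05)),
                                    noise_sd = noise_sd, seed = seed))
  rows <- lapply(co$scenes, function(sc) {
    scene <- generate_scene(sc$params)
    seg <- segment_image(scene$image)
    data.frame(image_id = sc$image_id, fruit_id = sc$fruit_id, view = sc$view,
               as.list(extract_features(scene$image, seg$mask)),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  list(features = do.call(rbind, rows), phenotypes = co$phenotypes,
       cohort = co)
}
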