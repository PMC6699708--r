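# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded generators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Validate an H x W x 3 numeric image with 8-bit intensities.
check_image <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stopf("%s must be an H x W x 3 array", arg)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stopf("%s has empty dimensions", arg)
  invisible(img)
}

check_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stopf("%s must be a logical matrix", arg)
  invisible(mask)
}

# Disk structuring element as (dr, dc) offsets.
disk_offsets <- function(radius) {
  if (radius <= 0) return(matrix(0L, 1, 2))
  r <- as.integer(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

#' Jaccard index of two binary masks
#'
#' Intersection-over-union, the standard segmentation agreement score.
#'
#' @param a,b logical matrices of identical dimensions.
#' @return a number in \[0, 1\]; 1 if both masks are empty.
#' @export
jaccard <- function(a, b) {
  check_mask(a, "a"); check_mask(b, "b")
  if (!all(dim(a) == dim(b))) stopf("mask dimensions differ")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
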