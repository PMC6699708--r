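# Image file I/O. Images are held in memory as H x W x 3 numeric arrays of
# 8-bit intensities (0..255), channel order (R, G, B) regardless of file
# dialect; masks as logical matrices.

#' Read an RGB image
#'
#' Reads PNG (or JPEG, if the `jpeg` package is installed) into an
#' H x W x 3 array of 0-255 intensities. Grayscale images are expanded to
#' three channels; an alpha channel is dropped.
#'
#' @param path file path ending in .png, .jpg or .jpeg.
#' @return numeric H x W x 3 array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stopf("the 'jpeg' package is needed to read %s", path)
      jpeg::readJPEG(path)
    },
    stopf("unsupported image extension '%s'", ext))
  if (length(dim(raw)) == 2L) raw <- array(raw, c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3] == 1L) raw <- array(raw[, , 1L], c(dim(raw)[1:2], 3L))
  round(raw * 255)
}

#' Write an RGB image as PNG (or JPEG)
#'
#' @param img H x W x 3 array of 0-255 intensities.
#' @param path destination; format chosen by extension. PNG is lossless and
#'   is the reproducible default; JPEG is provided for export only.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  check_image(img)
  ext <- tolower(tools::file_ext(path))
  scaled <- clip255(img) / 255
  switch(ext,
    png = png::writePNG(scaled, path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stopf("the 'jpeg' package is needed to write %s", path)
      jpeg::writeJPEG(scaled, path, quality = 0.95)
    },
    stopf("unsupported image extension '%s'", ext))
  invisible(path)
}

#' Read / write a binary mask as single-channel PNG
#'
#' Masks are stored with foreground = 255, background = 0.
#'
#' @param path PNG path.
#' @return `read_mask`: logical matrix. `write_mask`: `path`, invisibly.
#' @export
read_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  raw >= 0.5
}

#' @rdname read_mask
#' @param mask logical matrix.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Downscale an image or mask to a working resolution
#'
#' Nearest-neighbour subsampling so that the longest side is at most
#' `max_side` pixels. Returns the input unchanged when already small enough.
#'
#' @param x image array or logical mask matrix.
#' @param max_side maximum length of the longer side, in pixels.
#' @return list with elements `x` (resized object) and `scale` (the factor
#'   applied; 1 when untouched).
#' @export
resize_longest <- function(x, max_side = 1024) {
  d <- dim(x)[1:2]
  long <- max(d)
  if (long <= max_side) return(list(x = x, scale = 1))
  s <- max_side / long
  ri <- pmin(d[1], round(seq(1, d[1], length.out = max(1, floor(d[1] * s)))))
  ci <- pmin(d[2], round(seq(1, d[2], length.out = max(1, floor(d[2] * s)))))
  out <- if (length(dim(x)) == 3L) x[ri, ci, , drop = FALSE] else x[ri, ci, drop = FALSE]
  list(x = out, scale = s)
}
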