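#' Color raster images
#'
#' A `raster_image` is the unit every processing operator transforms: an
#' `height x width x 3` integer array of red, green and blue intensities in
#' `[0, 255]`. The channel order is red, green, blue everywhere in the data
#' model; file readers and writers convert from whatever the codec stores.
#'
#' @param x An integer or numeric array `h x w x 3` with values in `[0, 255]`,
#'   or an `h x w` matrix (promoted to 3 identical channels).
#' @return An object of class `raster_image`.
#' @examples
#' img <- raster_image(array(0L, dim = c(4, 5, 3)))
#' dim(img)
#' @export
raster_image <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("a raster image must be an h x w x 3 array", call. = FALSE)
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    stop("image height and width must both be >= 1", call. = FALSE)
  storage.mode(x) <- "integer"
  if (anyNA(x) || min(x) < 0L || max(x) > 255L)
    stop("intensities must be integers in [0, 255]", call. = FALSE)
  structure(x, class = "raster_image")
}

is_raster_image <- function(x) inherits(x, "raster_image")

assert_raster <- function(x, arg = "image") {
  if (!is_raster_image(x))
    stop(sprintf("`%s` must be a raster_image (see raster_image())", arg),
         call. = FALSE)
  x
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_image> %d x %d pixels, 3 channels (RGB), range [%d, %d]\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(unclass(x))

#' Display a raster image or binary mask
#'
#' @param x A `raster_image`.
#' @param ... Passed to [graphics::plot.window()]; unused.
#' @return `x`, invisibly.
#' @export
plot.raster_image <- function(x, ...) {
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = dim(x)[1] / dim(x)[2])
  graphics::rasterImage(unclass(x) / 255, 0, 0, 1, 1, interpolate = FALSE)
  invisible(x)
}

#' Read a plant image from disk
#'
#' PNG and JPEG files are supported. Grayscale files are promoted to three
#' identical channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return A [raster_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (is.matrix(a)) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 2L)  # gray + alpha
    a <- array(rep(a[, , 1L], 3L), dim = c(dim(a)[1:2], 3L))
  raster_image(array(as.integer(round(a * 255)), dim = dim(a)))
}

#' Write a raster image to a PNG file
#'
#' PNG is lossless, so `read_image(write_image(img, path))` recovers `img`
#' exactly; tests and the workflow engine rely on this.
#'
#' @param image A [raster_image()].
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  assert_raster(image)
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}

#' Convert a processed image to a binary foreground mask
#'
#' After filtering, background pixels are exactly `(0, 0, 0)`; a pixel is
#' foreground if and only if any channel is greater than zero.
#'
#' @param image A [raster_image()].
#' @return A logical `h x w` matrix, `TRUE` = foreground.
#' @export
to_binary <- function(image) {
  assert_raster(image)
  x <- unclass(image)
  x[, , 1L] > 0L | x[, , 2L] > 0L | x[, , 3L] > 0L
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("`%s` must be a logical matrix", arg), call. = FALSE)
  if (anyNA(mask)) stop(sprintf("`%s` contains NA", arg), call. = FALSE)
  mask
}

# Validate a region of interest against an image shape. ROIs are 0-based and
# half-open on both axes: [ystart, yend) x [xstart, xend).
assert_roi <- function(roi, h, w) {
  if (length(roi) != 4L || anyNA(roi) || !is.numeric(roi))
    stop("roi must be numeric [ystart, yend, xstart, xend]", call. = FALSE)
  roi <- as.integer(roi)
  names(roi) <- c("ystart", "yend", "xstart", "xend")
  if (roi[1] >= roi[2] || roi[3] >= roi[4])
    stop(sprintf("empty ROI: [%d, %d, %d, %d]", roi[1], roi[2], roi[3], roi[4]),
         call. = FALSE)
  if (roi[1] < 0L) stop("ROI out of bounds: ystart = ", roi[1], call. = FALSE)
  if (roi[3] < 0L) stop("ROI out of bounds: xstart = ", roi[3], call. = FALSE)
  if (roi[2] > h) stop("ROI out of bounds: yend = ", roi[2], " > height ", h, call. = FALSE)
  if (roi[4] > w) stop("ROI out of bounds: xend = ", roi[4], " > width ", w, call. = FALSE)
  roi
}
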