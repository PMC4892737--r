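#' Crop an image to a region of interest
#'
#' The first processing step for fixed-camera setups: remove features outside
#' the controlled background at the edges of the frame. ROIs are 0-based and
#' half-open on both axes, `[ystart, yend) x [xstart, xend)` with y = row and
#' x = column.
#'
#' @param image A [raster_image()].
#' @param roi Numeric `[ystart, yend, xstart, xend]`.
#' @return A `raster_image` of shape `(yend - ystart) x (xend - xstart)`;
#'   output pixel `(i, j)` is input pixel `(ystart + i, xstart + j)`.
#' @examples
#' img <- raster_image(array(7L, dim = c(10, 10, 3)))
#' dim(crop(img, c(2, 5, 3, 7)))  # 3 x 4 x 3
#' @export
crop <- function(image, roi) {
  assert_raster(image)
  d <- dim(image)
  roi <- assert_roi(roi, d[1], d[2])
  out <- unclass(image)[(roi[1] + 1L):roi[2], (roi[3] + 1L):roi[4], , drop = FALSE]
  raster_image(out)
}

#' Remove background pixels by a color expression
#'
#' Every pixel for which the filter expression is false is set to the
#' background fill color `(0, 0, 0)`; pixels satisfying the expression are
#' untouched. With the standard rule `"g > b"` this retains pixels whose
#' green value exceeds their blue value — plant tissue against a blue or
#' white background. An optional ROI restricts the filter: pixels outside it
#' are never modified.
#'
#' The operation is idempotent: black pixels fail `g > b` (and any expression
#' that black fails), so re-filtering the output is a no-op.
#'
#' @param image A [raster_image()].
#' @param expr A filter expression string or [parse_filter()] result.
#' @param roi Optional `[ystart, yend, xstart, xend]` region to filter.
#' @return The filtered `raster_image`, same shape as the input.
#' @examples
#' img <- raster_image(array(c(100L, 120L, 80L), dim = c(1, 1, 3)))
#' color_filter(img, "g > b")  # kept: green exceeds blue
#' @export
color_filter <- function(image, expr, roi = NULL) {
  assert_raster(image)
  keep <- filter_apply(expr, image)
  x <- unclass(image)
  if (!is.null(roi)) {
    roi <- assert_roi(roi, dim(x)[1], dim(x)[2])
    inside <- matrix(FALSE, dim(x)[1], dim(x)[2])
    inside[(roi[1] + 1L):roi[2], (roi[3] + 1L):roi[4]] <- TRUE
    keep <- keep | !inside
  }
  drop <- !keep
  for (ch in 1:3) {
    plane <- x[, , ch]
    plane[drop] <- 0L
    x[, , ch] <- plane
  }
  raster_image(x)
}

#' Find connected foreground components
#'
#' Components ("contours") are connected sets of foreground pixels under
#' 8-connectivity — diagonal contact joins components, which matters for thin
#' plant organs such as tillers and leaf tips. Component area is the pixel
#' count of the filled component.
#'
#' @param mask A logical foreground matrix (see [to_binary()]).
#' @return A list of contours, each `list(area = <pixel count>,
#'   pixels = <n x 2 matrix of (row, col), 1-based>)`; empty list for an
#'   empty mask. Components are ordered by first-encountered pixel in
#'   column-major scan order.
#' @export
find_contours <- function(mask) {
  assert_mask(mask)
  lab <- .label_components(mask)
  k <- max(lab)
  if (k == 0L) return(list())
  idx <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[lab > 0L]
  lapply(seq_len(k), function(i) {
    px <- idx[labs == i, , drop = FALSE]
    colnames(px) <- c("row", "col")
    list(area = nrow(px), pixels = px)
  })
}

#' Remove small foreground components (noise)
#'
#' After color filtering, small background features (soil debris, container
#' specks) may survive. They are removed by size: every connected foreground
#' component with area strictly less than `min_area` pixels has all its
#' pixels set to `(0, 0, 0)`. Components with area `>= min_area` are
#' untouched, so the operation is monotone in `min_area`.
#'
#' @param image A [raster_image()] (foreground = any channel `> 0`).
#' @param min_area Minimum component area (pixel count) to survive; `0` is
#'   the identity.
#' @return The cleaned `raster_image`.
#' @export
contour_chop <- function(image, min_area) {
  assert_raster(image)
  if (!is.numeric(min_area) || length(min_area) != 1L || is.na(min_area) ||
      min_area < 0)
    stop("`min_area` must be a single number >= 0", call. = FALSE)
  if (min_area == 0) return(image)
  lab <- .label_components(to_binary(image))
  if (max(lab) == 0L) return(image)
  areas <- tabulate(lab[lab > 0L])
  small <- which(areas < min_area)
  if (length(small) == 0L) return(image)
  drop <- matrix(lab %in% small, nrow = nrow(lab))
  x <- unclass(image)
  for (ch in 1:3) {
    plane <- x[, , ch]
    plane[drop] <- 0L
    x[, , ch] <- plane
  }
  raster_image(x)
}

#' Morphological opening of the foreground
#'
#' An alternative noise-reduction step: erosion shrinks every object's
#' border, deleting objects smaller than the structuring element, and the
#' subsequent dilation restores the borders of the objects that survived.
#' The opening is computed on the binary support (any channel `> 0`) with a
#' square structuring element and applied as a mask, so surviving pixels
#' keep their original colors. Output foreground is always a subset of the
#' input foreground, and opening is idempotent.
#'
#' @param image A [raster_image()].
#' @param kernel Side length of the square structuring element; odd, `>= 1`.
#' @param iterations Number of erosion passes before the matching number of
#'   dilation passes; `>= 1`.
#' @return The opened `raster_image`.
#' @export
morphological_open <- function(image, kernel = 3L, iterations = 1L) {
  assert_raster(image)
  if (!is.numeric(kernel) || length(kernel) != 1L || is.na(kernel) ||
      kernel < 1 || kernel %% 2 != 1)
    stop("`kernel` must be a single odd integer >= 1", call. = FALSE)
  if (!is.numeric(iterations) || length(iterations) != 1L || is.na(iterations) ||
      iterations < 1)
    stop("`iterations` must be >= 1", call. = FALSE)
  if (kernel == 1) return(image)
  supp <- to_binary(image)
  m <- matrix(as.numeric(supp), nrow = nrow(supp))
  brush <- EBImage::makeBrush(as.integer(kernel), shape = "box")
  for (i in seq_len(iterations)) m <- EBImage::erode(m, brush)
  for (i in seq_len(iterations)) m <- EBImage::dilate(m, brush)
  keep <- m > 0.5 & supp
  x <- unclass(image)
  for (ch in 1:3) {
    plane <- x[, , ch]
    plane[!keep] <- 0L
    x[, , ch] <- plane
  }
  raster_image(x)
}

#' Crop an image to its large foreground components
#'
#' The final processing step: crop the image to just the plant so that
#' height and width can be measured accurately. The tight bounding box of
#' the union of all components with area strictly greater than `min_area`
#' is computed, expanded by `padding` pixels (clamped to the image bounds),
#' and the image is cropped to it. This is cropping only — small components
#' that happen to fall inside the box are retained, no pixel is rewritten.
#'
#' @param image A [raster_image()].
#' @param min_area Only components with area `> min_area` define the box.
#' @param padding Pixels of margin added on every side, clamped to bounds.
#' @return `list(image = <cropped raster_image>, roi = <the ROI used>)`.
#'   If no component qualifies, an error of class `empty_plant_error` is
#'   raised carrying the component-area list in its `areas` field.
#' @export
contour_cut <- function(image, min_area = 0, padding = 0) {
  assert_raster(image)
  if (!is.numeric(min_area) || length(min_area) != 1L || is.na(min_area) ||
      min_area < 0)
    stop("`min_area` must be a single number >= 0", call. = FALSE)
  if (!is.numeric(padding) || length(padding) != 1L || is.na(padding) ||
      padding < 0)
    stop("`padding` must be a single number >= 0", call. = FALSE)
  lab <- .label_components(to_binary(image))
  areas <- if (max(lab) > 0L) tabulate(lab[lab > 0L]) else integer()
  big <- which(areas > min_area)
  if (length(big) == 0L) {
    stop(structure(class = c("empty_plant_error", "error", "condition"),
                   list(message = sprintf(
                          "empty plant: no component with area > %g (component areas: %s)",
                          min_area,
                          if (length(areas)) paste(sort(areas, decreasing = TRUE),
                                                   collapse = ", ") else "none"),
                        call = NULL, areas = areas)))
  }
  sel <- which(matrix(lab %in% big, nrow = nrow(lab)), arr.ind = TRUE)
  d <- dim(image)
  roi <- c(max(0L, min(sel[, 1]) - 1L - as.integer(padding)),
           min(d[1], max(sel[, 1]) + as.integer(padding)),
           max(0L, min(sel[, 2]) - 1L - as.integer(padding)),
           min(d[2], max(sel[, 2]) + as.integer(padding)))
  list(image = crop(image, roi), roi = roi)
}

#' Run the standard four-stage segmentation pipeline
#'
#' Convenience wrapper chaining the local-workflow stages: [crop()] (if an
#' ROI is given), [color_filter()], [contour_chop()], and [contour_cut()].
#'
#' @param image A [raster_image()].
#' @param expr Filter expression; default `"g > b"`.
#' @param roi Optional initial crop ROI.
#' @param min_chop Area threshold for [contour_chop()] (0 = skip).
#' @param min_cut Area threshold for [contour_cut()].
#' @param padding Padding for [contour_cut()].
#' @return `list(image, roi)` as from [contour_cut()], where `roi` is given
#'   in the coordinates of the *original* (pre-crop) image.
#' @export
segment_plant <- function(image, expr = "g > b", roi = NULL, min_chop = 0,
                          min_cut = 0, padding = 0) {
  offset <- c(0L, 0L)
  if (!is.null(roi)) {
    image <- crop(image, roi)
    offset <- c(as.integer(roi[1]), as.integer(roi[3]))
  }
  image <- color_filter(image, expr)
  image <- contour_chop(image, min_chop)
  res <- contour_cut(image, min_area = min_cut, padding = padding)
  res$roi <- res$roi + c(offset[1], offset[1], offset[2], offset[2])
  res
}
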