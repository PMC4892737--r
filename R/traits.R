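#' Raw image moments of a binary mask
#'
#' The raw moment of order `(i, j)` is `M_ij = sum over foreground pixels of
#' x^i * y^j`, with x = column index, y = row index, both 0-based, and
#' binary weight 1 per pixel (moments are computed on binary masks, not
#' intensity-weighted). `M00` is the foreground area; `(M10/M00, M01/M00)`
#' is the centroid. Raw moments numerically describe position, scale and
#' orientation of the plant object and feed the architecture clustering.
#'
#' @param mask Logical foreground matrix.
#' @param max_order Highest order per axis (default 3 gives the 16 moments
#'   `M00 .. M33`).
#' @return A `(max_order+1) x (max_order+1)` numeric matrix `M` with
#'   `M[i+1, j+1] = M_ij`; all zeros for an empty mask.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[5, 4] <- TRUE  # row 4, col 3 (0-based)
#' raw_moments(m)["M1", "M0"]  # M10 = 3
#' @export
raw_moments <- function(mask, max_order = 3L) {
  assert_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  M <- matrix(0, max_order + 1L, max_order + 1L,
              dimnames = list(paste0("M", 0:max_order), paste0("M", 0:max_order)))
  if (nrow(idx) == 0L) return(M)
  x <- as.numeric(idx[, 2] - 1L)  # column, 0-based
  y <- as.numeric(idx[, 1] - 1L)  # row, 0-based
  xp <- outer(x, 0:max_order, `^`)  # n x (max_order+1)
  yp <- outer(y, 0:max_order, `^`)
  M[] <- crossprod(xp, yp)          # M[i+1, j+1] = sum x^i y^j
  M
}

moment_of <- function(M, i, j) M[i + 1L, j + 1L]

#' Center of mass of a foreground mask
#'
#' @param m A [raw_moments()] matrix or a logical mask.
#' @return `c(x = M10/M00, y = M01/M00)` in 0-based (column, row) pixel
#'   coordinates.
#' @export
center_of_mass <- function(m) {
  if (is.logical(m)) m <- raw_moments(m, 1L)
  if (moment_of(m, 0, 0) == 0)
    stop("centroid undefined: empty mask (M00 = 0)", call. = FALSE)
  c(x = moment_of(m, 1, 0) / moment_of(m, 0, 0),
    y = moment_of(m, 0, 1) / moment_of(m, 0, 0))
}

#' Height and width of the foreground
#'
#' Measured on the tight bounding box of the foreground: `height = rowmax -
#' rowmin + 1`, `width = colmax - colmin + 1`. Run after [contour_cut()] so
#' the box spans the plant, not the frame.
#'
#' @param mask Logical foreground matrix; must be nonempty.
#' @return `c(height = , width = )` in pixels.
#' @export
mask_dimensions <- function(mask) {
  assert_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("dimensions undefined: empty mask", call. = FALSE)
  c(height = diff(range(idx[, 1])) + 1L, width = diff(range(idx[, 2])) + 1L)
}

#' Foreground pixel count
#'
#' The number of plant pixels in one view; equals `M00`. Used as a proxy for
#' shoot biomass.
#'
#' @param mask Logical foreground matrix.
#' @return Integer pixel count.
#' @export
pixel_area <- function(mask) {
  assert_mask(mask)
  sum(mask)
}

#' Projected shoot area (PSA)
#'
#' The summation of plant pixels from two side-view images taken 90 degrees
#' apart — the digital proxy for shoot biomass. The two views are summed,
#' never averaged.
#'
#' @param area_sv0,area_sv90 Foreground pixel counts of the two side views.
#' @return Their sum.
#' @examples
#' projected_shoot_area(1200, 1350)  # 2550
#' @export
projected_shoot_area <- function(area_sv0, area_sv90) {
  if (any(c(area_sv0, area_sv90) < 0)) stop("areas must be >= 0", call. = FALSE)
  area_sv0 + area_sv90
}

#' Convex hull area, perimeter and plant density
#'
#' The convex hull (CH) is the smallest convex region containing the
#' foreground. Hull area is measured discretely, as the number of pixel
#' centers inside or on the hull of the foreground pixel centers — so a
#' filled convex shape has density exactly 1. Density (Den) = pixel area /
#' hull area, in `(0, 1]`; it measures canopy compactness.
#'
#' @param mask Logical foreground matrix; must be nonempty.
#' @return `list(hull_area, hull_perimeter, density)`; `hull_perimeter` is
#'   the Euclidean boundary length of the hull polygon of pixel centers.
#' @export
convex_hull_metrics <- function(mask) {
  assert_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("convex hull undefined: empty mask", call. = FALSE)
  pts <- unique(cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L))  # 0-based centers
  area_px <- nrow(idx)
  if (nrow(pts) == 1L)
    return(list(hull_area = 1, hull_perimeter = 0, density = area_px / 1))
  h <- grDevices::chull(pts[, 1], pts[, 2])  # clockwise vertex order
  hull <- pts[rev(h), , drop = FALSE]        # counter-clockwise
  if (nrow(hull) <= 2L || hull_is_degenerate(hull)) {
    # collinear foreground: hull is a segment; lattice points on it
    ex <- pts[which.min(pts[, 1] * 1e9 + pts[, 2]), ]
    d <- pts[, 1] - ex[1] + 1i * (pts[, 2] - ex[2])
    far <- pts[which.max(Mod(d)), ]
    g <- gcd2(abs(far[[1]] - ex[[1]]), abs(far[[2]] - ex[[2]]))
    ha <- unname(g + 1)
    per <- 2 * sqrt(sum((far - ex)^2))
    return(list(hull_area = ha, hull_perimeter = per, density = area_px / ha))
  }
  ha <- lattice_points_in_hull(hull, range(pts[, 1]), range(pts[, 2]))
  per <- sum(sqrt(rowSums((hull - hull[c(2:nrow(hull), 1), , drop = FALSE])^2)))
  list(hull_area = ha, hull_perimeter = per, density = area_px / ha)
}

hull_is_degenerate <- function(hull) {
  v1 <- hull[2, ] - hull[1, ]
  for (k in 3:nrow(hull)) {
    v <- hull[k, ] - hull[1, ]
    if (v1[1] * v[2] - v1[2] * v[1] != 0) return(FALSE)
  }
  TRUE
}

gcd2 <- function(a, b) { while (b > 0) { t <- a %% b; a <- b; b <- t }; a }

# Count integer lattice points inside or on a CCW convex polygon with
# integer vertices. Cross products of integer coordinates are exact in
# double precision for any realistic image size.
lattice_points_in_hull <- function(hull, xr, yr) {
  gx <- seq.int(xr[1], xr[2])
  gy <- seq.int(yr[1], yr[2])
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  inside <- rep(TRUE, length(px))
  n <- nrow(hull)
  for (k in seq_len(n)) {
    a <- hull[k, ]; b <- hull[if (k == n) 1L else k + 1L, ]
    cr <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    inside <- inside & cr >= 0
    if (!any(inside)) break
  }
  sum(inside)
}

#' Per-channel color histogram over the foreground
#'
#' Fixed-width binning of the red, green and blue values of foreground
#' pixels only. With the default 8 bins per channel each bin spans 32
#' intensity levels of `[0, 256)`.
#'
#' @param image A [raster_image()].
#' @param mask Logical foreground matrix, same shape.
#' @param bins Bins per channel; must divide 256.
#' @return An object of class `color_histogram`: `list(bins, counts,
#'   proportions)` where `counts` is a `bins x 3` matrix (columns r, g, b)
#'   summing per channel to the foreground pixel count; `proportions` are
#'   counts normalized by that count, all-`NA` (flagged via the `empty`
#'   field) for an empty mask.
#' @export
color_histogram <- function(image, mask, bins = 8L) {
  assert_raster(image)
  assert_mask(mask)
  if (!identical(dim(mask), dim(image)[1:2]))
    stop("mask and image shapes differ", call. = FALSE)
  if (!is.numeric(bins) || length(bins) != 1L || bins < 1 || 256 %% bins != 0)
    stop("`bins` must divide 256", call. = FALSE)
  bins <- as.integer(bins)
  width <- 256L %/% bins
  x <- unclass(image)
  counts <- sapply(1:3, function(ch) {
    v <- x[, , ch][mask]
    tabulate(v %/% width + 1L, nbins = bins)
  })
  colnames(counts) <- c("r", "g", "b")
  rownames(counts) <- sprintf("[%d,%d)", (0:(bins - 1L)) * width, (1:bins) * width)
  n <- sum(mask)
  props <- if (n > 0L) counts / n else counts * NA_real_
  structure(list(bins = bins, counts = counts, proportions = props,
                 n_foreground = n, empty = n == 0L),
            class = "color_histogram")
}

#' @export
print.color_histogram <- function(x, ...) {
  cat(sprintf("<color_histogram> %d bins/channel over %d foreground pixels%s\n",
              x$bins, x$n_foreground, if (x$empty) " (empty mask)" else ""))
  print(x$counts)
  invisible(x)
}

#' Base per-view digital traits
#'
#' Computes every single-view quantity the composite catalog builds on:
#' area, bounding-box dimensions and origin, centroid, convex-hull metrics,
#' elongation (minor/major axis ratio from central second moments),
#' eccentricity, and the 16 raw moments `M00..M33`.
#'
#' @param mask Logical foreground matrix; must be nonempty.
#' @return A named numeric vector.
#' @export
extract_base_traits <- function(mask) {
  assert_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no foreground: cannot extract traits", call. = FALSE)
  M <- raw_moments(mask)
  dims <- mask_dimensions(mask)
  com <- center_of_mass(M)
  hull <- convex_hull_metrics(mask)
  # central second moments -> principal axis lengths
  m00 <- moment_of(M, 0, 0)
  mu20 <- moment_of(M, 2, 0) / m00 - com["x"]^2
  mu02 <- moment_of(M, 0, 2) / m00 - com["y"]^2
  mu11 <- moment_of(M, 1, 1) / m00 - com["x"] * com["y"]
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc
  l2 <- max(0, tr / 2 - disc)
  elong <- if (l1 > 0) sqrt(l2 / l1) else 1   # 1 = round, 0 = a line
  ecc <- if (l1 > 0) sqrt(1 - l2 / l1) else 0
  mom <- as.vector(M)
  names(mom) <- paste0("M", rep(0:3, times = 4), rep(0:3, each = 4))
  c(area = sum(mask),
    height = unname(dims["height"]), width = unname(dims["width"]),
    ymin = min(idx[, 1]) - 1, xmin = min(idx[, 2]) - 1,
    centroid_x = unname(com["x"]), centroid_y = unname(com["y"]),
    hull_area = hull$hull_area, hull_perimeter = hull$hull_perimeter,
    density = hull$density,
    elongation = unname(elong), eccentricity = unname(ecc),
    mom)
}
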