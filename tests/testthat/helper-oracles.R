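# Independent brute-force oracles. These deliberately share no code with
# the package internals: the flood fill is a plain R BFS, moments are a
# double loop, and hull membership is tested point by point.

# 8-connectivity flood fill: returns list of sorted pixel-index vectors,
# one per component, in no particular order.
oracle_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    queue <- list(c(i, j))
    seen[i, j] <- TRUE
    members <- integer()
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      members <- c(members, (p[2] - 1L) * nr + p[1])
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        qi <- p[1] + di; qj <- p[2] + dj
        if (qi < 1 || qi > nr || qj < 1 || qj > nc) next
        if (mask[qi, qj] && !seen[qi, qj]) {
          seen[qi, qj] <- TRUE
          queue[[length(queue) + 1L]] <- c(qi, qj)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

# All 16 raw moments by an explicit double loop over the grid.
oracle_moments <- function(mask, max_order = 3L) {
  M <- matrix(0, max_order + 1L, max_order + 1L)
  for (row in seq_len(nrow(mask))) for (col in seq_len(ncol(mask))) {
    if (!mask[row, col]) next
    x <- col - 1L; y <- row - 1L
    for (i in 0:max_order) for (j in 0:max_order)
      M[i + 1L, j + 1L] <- M[i + 1L, j + 1L] + x^i * y^j
  }
  M
}

# Lattice points inside/on the convex hull of the foreground pixel centers,
# by testing every candidate against every hull half-plane.
oracle_hull_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  pts <- unique(cbind(idx[, 2] - 1L, idx[, 1] - 1L))
  if (nrow(pts) < 3L) return(NULL)  # degenerate handled elsewhere
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[rev(h), , drop = FALSE]
  count <- 0L
  for (px in min(pts[, 1]):max(pts[, 1])) for (py in min(pts[, 2]):max(pts[, 2])) {
    ok <- TRUE
    for (k in seq_len(nrow(hull))) {
      a <- hull[k, ]; b <- hull[if (k == nrow(hull)) 1L else k + 1L, ]
      if ((b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1]) < 0) {
        ok <- FALSE; break
      }
    }
    if (ok) count <- count + 1L
  }
  count
}

random_mask <- function(nr, nc, p = 0.3) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# A flat-color image from a mask (foreground green, background black).
mask_to_image <- function(mask, fg = c(30L, 200L, 40L)) {
  a <- array(0L, dim = c(dim(mask), 3L))
  for (ch in 1:3) a[, , ch][mask] <- fg[ch]
  raster_image(a)
}

random_image <- function(nr, nc) {
  raster_image(array(sample(0:255, nr * nc * 3, replace = TRUE),
                     dim = c(nr, nc, 3L)))
}

# Standard four-stage template fixtures used by workflow tests.
standard_jobs <- function(canvas = c(160, 120), min_chop = 10) {
  list(
    list(name = "crop1", operation = "crop",
         arguments = list(roi = c(0, canvas[1], 0, canvas[2])),
         inputs = list(image = "raw"), outputs = list(image = "cropped")),
    list(name = "filter1", operation = "colorFilter",
         arguments = list(expr = "g > b"),
         inputs = list(image = "cropped"), outputs = list(image = "filtered")),
    list(name = "chop1", operation = "contourChop",
         arguments = list(min_area = min_chop),
         inputs = list(image = "filtered"), outputs = list(image = "chopped")),
    list(name = "cut1", operation = "contourCut",
         arguments = list(min_area = 0),
         inputs = list(image = "chopped"), outputs = list(image = "final")),
    list(name = "extract1", operation = "extract", arguments = list(),
         inputs = list(image = "final"), outputs = list()))
}

write_templates <- function(dir, output_root, max_concurrent = 1,
                            jobs = standard_jobs()) {
  ld <- list(pattern = list("{id}_{date}", "{imtype}", "{angle}.png"),
             metadata = "metadata.csv", key_column = "id")
  pr <- list(workflows = list(rgbsv = jobs, rgbtv = jobs))
  cf <- list(max_concurrent = max_concurrent, output_root = output_root)
  paths <- file.path(dir, c("loading.json", "processing.json", "config.json"))
  jsonlite::write_json(ld, paths[1], auto_unbox = TRUE)
  jsonlite::write_json(pr, paths[2], auto_unbox = TRUE)
  jsonlite::write_json(cf, paths[3], auto_unbox = TRUE)
  paths
}

# Reassemble a full-frame mask from a segment_plant()/contour_cut() result.
reassemble_mask <- function(res, h, w) {
  m <- matrix(FALSE, h, w)
  m[(res$roi[1] + 1):res$roi[2], (res$roi[3] + 1):res$roi[4]] <-
    to_binary(res$image)
  m
}
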