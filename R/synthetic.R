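## Deterministic synthetic fixtures: plant-like images with exact ground
## truth, LemnaTec-style directory trees, and planted-partition trait
## tables. Every quantity the pipeline should recover is computed from the
## exact rasterized plant pixel set before compositing, so segmentation and
## trait extraction can be validated to pixel-exact equality without any
## external dataset.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Specify a synthetic plant image
#'
#' Describes one rendered plant: a vertical stem with angled leaves drawn
#' in green-dominant colors (every plant pixel satisfies `g > b`, the
#' filter rule) on a uniform background, with an optional pot band at the
#' bottom of the frame and optional debris blobs. Default debris is colored
#' to *fail* the `g > b` filter (blue/gray specks), so the basic filter
#' pipeline removes it; `hard_noise = TRUE` makes green-like debris that
#' only contour-area filtering can remove, placed clear of the plant, to
#' exercise the noise-reduction stage distinctly.
#'
#' @param seed Integer; the same seed yields a byte-identical image.
#' @param canvas `c(height, width)` in pixels.
#' @param stem_height Range the stem height is drawn from.
#' @param stem_thickness Range of stem thickness (pixels).
#' @param n_leaves Range of leaf counts.
#' @param leaf_length Range of leaf lengths (pixels).
#' @param background `"blue"` or `"white"`; both fail `g > b`.
#' @param pot_rows Height of the pot band at the bottom (0 = none).
#' @param n_debris Number of debris blobs.
#' @param debris_radius Range of debris blob radii.
#' @param hard_noise If `TRUE` debris passes the color filter.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(seed, canvas = c(160L, 120L), stem_height = c(60, 100),
                       stem_thickness = c(3, 5), n_leaves = c(3, 7),
                       leaf_length = c(15, 45), background = "blue",
                       pot_rows = 12L, n_debris = 0L, debris_radius = c(1, 3),
                       hard_noise = FALSE) {
  structure(list(seed = as.integer(seed), canvas = as.integer(canvas),
                 stem_height = stem_height, stem_thickness = stem_thickness,
                 n_leaves = n_leaves, leaf_length = leaf_length,
                 background = match.arg(background, c("blue", "white")),
                 pot_rows = as.integer(pot_rows), n_debris = as.integer(n_debris),
                 debris_radius = debris_radius, hard_noise = isTRUE(hard_noise)),
            class = "plant_spec")
}

rng_int <- function(lo, hi) if (lo >= hi) as.integer(lo) else
  sample.int(as.integer(hi) - as.integer(lo) + 1L, 1L) + as.integer(lo) - 1L

# Thick line segment rasterized as (row, col) pixels.
thick_line_pixels <- function(r0, c0, r1, c1, half) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) * 2L + 2L
  t <- seq(0, 1, length.out = n)
  pts <- unique(cbind(round(r0 + t * (r1 - r0)), round(c0 + t * (c1 - c0))))
  if (half > 0) {
    off <- expand.grid(dr = -half:half, dc = -half:half)
    pts <- unique(cbind(rep(pts[, 1], each = nrow(off)) + off$dr,
                        rep(pts[, 2], each = nrow(off)) + off$dc))
  }
  pts
}

disk_pixels <- function(r0, c0, rad) {
  off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  off <- off[off$dr^2 + off$dc^2 <= rad^2, ]
  cbind(r0 + off$dr, c0 + off$dc)
}

#' Render a synthetic plant image with exact ground truth
#'
#' Composites background, pot band, debris and finally the plant (the plant
#' always overdraws). Ground truth is computed from the exact plant pixel
#' set: the foreground mask, pixel count, bounding box, raw moments to
#' order 3, convex-hull area, and the per-channel 8-bin color histogram.
#'
#' @param spec A [plant_spec()].
#' @return `list(image = <raster_image>, truth = <list>)`. `truth$roi` is
#'   the bounding box in the 0-based half-open ROI convention.
#' @export
generate_plant_image <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed(spec$seed, {
    h <- spec$canvas[1]; w <- spec$canvas[2]
    base_row <- h - spec$pot_rows               # lowest plant row
    hi <- min(spec$stem_height[2], base_row - 2L)
    stem_h <- rng_int(min(spec$stem_height[1], hi), hi)
    if (stem_h < 2L || base_row < 4L)
      stop("plant spec error: stem does not fit the canvas", call. = FALSE)
    half_t <- rng_int(spec$stem_thickness[1], spec$stem_thickness[2]) %/% 2L
    cx <- w %/% 2L + rng_int(-5L, 5L)
    top_row <- base_row - stem_h + 1L
    # endpoints pulled in by the stroke half-width so strokes stay on canvas
    plant <- thick_line_pixels(base_row - half_t, cx, top_row + half_t, cx, half_t)
    n_lv <- rng_int(spec$n_leaves[1], spec$n_leaves[2])
    for (k in seq_len(n_lv)) {
      ar <- rng_int(top_row + 2L, base_row - stem_h %/% 3L)
      ang <- stats::runif(1, 20, 75) * pi / 180 * sample(c(-1, 1), 1)
      len <- rng_int(spec$leaf_length[1], spec$leaf_length[2])
      er <- round(ar - cos(abs(ang)) * len * 0.6)
      ec <- round(cx + sin(ang) * len)
      ec <- max(2L, min(w - 1L, ec))
      er <- max(2L, min(base_row - 1L, er))
      plant <- rbind(plant, thick_line_pixels(ar, cx, er, ec, 1L))
    }
    plant <- unique(plant)
    if (any(plant[, 1] < 1L | plant[, 1] > base_row |
            plant[, 2] < 1L | plant[, 2] > w))
      stop("plant spec error: plant exceeds the canvas", call. = FALSE)
    mask <- matrix(FALSE, h, w)
    mask[plant] <- TRUE

    # compositing
    bg <- if (spec$background == "blue") c(50L, 70L, 200L) else c(255L, 255L, 255L)
    img <- array(0L, dim = c(h, w, 3L))
    for (ch in 1:3) img[, , ch] <- bg[ch]
    if (spec$pot_rows > 0L) {
      pot <- c(205L, 205L, 220L)                 # gray-blue: fails g > b
      for (ch in 1:3) img[(base_row + 1L):h, , ch] <- pot[ch]
    }
    debris_px <- 0L
    if (spec$n_debris > 0L) {
      for (k in seq_len(spec$n_debris)) {
        for (try in 1:50) {
          rad <- rng_int(spec$debris_radius[1], spec$debris_radius[2])
          r0 <- rng_int(rad + 1L, base_row - rad)
          c0 <- rng_int(rad + 1L, w - rad)
          px <- disk_pixels(r0, c0, rad)
          # keep debris clear of the plant (Chebyshev distance >= 2 so the
          # two never touch under 8-connectivity)
          box <- expand.grid(dr = -1:1, dc = -1:1)
          touch <- FALSE
          for (bk in seq_len(nrow(box))) {
            rr <- px[, 1] + box$dr[bk]; cc <- px[, 2] + box$dc[bk]
            ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
            if (any(mask[cbind(rr[ok], cc[ok])])) { touch <- TRUE; break }
          }
          if (touch) next
          col <- if (spec$hard_noise) {
            gg <- rng_int(130L, 200L)
            c(rng_int(20L, 80L), gg, rng_int(0L, gg - 50L))  # passes g > b
          } else c(140L, 140L, 170L)                         # fails g > b
          for (ch in 1:3) img[, , ch][px] <- col[ch]
          debris_px <- debris_px + nrow(px)
          break
        }
      }
    }
    # plant pixels last, green-dominant: g > b always, g > 0
    np <- nrow(plant)
    gg <- sample(120:220, np, replace = TRUE)
    rr <- sample(0:110, np, replace = TRUE)
    bb <- vapply(gg, function(g) rng_int(0L, g - 41L), integer(1))
    img[, , 1L][plant] <- rr
    img[, , 2L][plant] <- gg
    img[, , 3L][plant] <- bb

    idx <- which(mask, arr.ind = TRUE)
    bbox <- c(rowmin = min(idx[, 1]), rowmax = max(idx[, 1]),
              colmin = min(idx[, 2]), colmax = max(idx[, 2]))
    image <- raster_image(img)
    truth <- list(
      mask = mask,
      count = nrow(idx),
      bbox = bbox,
      roi = c(bbox[["rowmin"]] - 1L, bbox[["rowmax"]],
              bbox[["colmin"]] - 1L, bbox[["colmax"]]),
      moments = raw_moments(mask),
      hull_area = convex_hull_metrics(mask)$hull_area,
      histogram = {
        width <- 32L
        counts <- sapply(list(rr, gg, bb), function(v)
          tabulate(v %/% width + 1L, nbins = 8L))
        colnames(counts) <- c("r", "g", "b")
        counts
      },
      debris_pixels = debris_px)
    list(image = image, truth = truth)
  })
}

#' Generate a synthetic image tree with manifest and metadata
#'
#' Writes a LemnaTec-style directory tree
#' `<id>_<date>/<imtype>/<angle>.png` for `n_plants` plants over `n_days`
#' consecutive days, plus a `metadata.csv` (id, genotype, replicate) and a
#' `manifest.json` listing every record with its ground-truth pixel count
#' and bounding box. Stem height grows with the day index, so per-plant
#' area increases over time. Refuses to write into a nonempty directory.
#'
#' @param root Target directory (empty or absent).
#' @param n_plants,n_days Tree size.
#' @param imtypes Named list mapping image type to its camera angles, e.g.
#'   `list(rgbsv = c(0, 90), rgbtv = 0)`.
#' @param seed Master seed; all per-image seeds derive from it.
#' @param canvas Passed to [plant_spec()].
#' @param n_debris,hard_noise Debris settings passed to every image.
#' @return The manifest: `list(pattern, metadata, key_column, records)`
#'   where `records` is a data frame with one row per written file.
#' @export
generate_tree <- function(root, n_plants = 2L, n_days = 3L,
                          imtypes = list(rgbsv = c(0L, 90L), rgbtv = 0L),
                          seed = 1L, canvas = c(160L, 120L), n_debris = 0L,
                          hard_noise = FALSE) {
  if (dir.exists(root) && length(list.files(root, all.files = TRUE, no.. = TRUE)))
    stop("refusing to write into nonempty directory: ", root, call. = FALSE)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("p%03d", seq_len(n_plants))
  meta <- with_seed(seed, data.frame(
    id = ids,
    genotype = paste0("G", sample.int(max(2L, ceiling(n_plants / 2)), n_plants,
                                      replace = TRUE)),
    replicate = sample.int(3L, n_plants, replace = TRUE),
    stringsAsFactors = FALSE))
  dates <- format(as.Date("2024-01-05") + seq_len(n_days) - 1L)
  rows <- list()
  counter <- 0L
  for (p in seq_len(n_plants)) for (d in seq_len(n_days)) {
    day_dir <- file.path(root, paste0(ids[p], "_", dates[d]))
    for (ty in names(imtypes)) for (ang in imtypes[[ty]]) {
      counter <- counter + 1L
      img_seed <- (as.integer(seed) * 7919L + counter * 104729L) %% 2147483647L
      # stem height grows with the day, scaled to the available canvas rows
      avail <- canvas[1] - 12L - 4L
      grow <- round(avail * (0.45 + 0.4 * d / n_days))
      sp <- plant_spec(img_seed, canvas = canvas,
                       stem_height = c(grow, min(avail, grow + 15L)),
                       n_debris = n_debris, hard_noise = hard_noise)
      gen <- generate_plant_image(sp)
      dir.create(file.path(day_dir, ty), recursive = TRUE, showWarnings = FALSE)
      rel <- file.path(paste0(ids[p], "_", dates[d]), ty, paste0(ang, ".png"))
      write_image(gen$image, file.path(root, rel))
      rows[[counter]] <- data.frame(
        id = ids[p], date = dates[d], imtype = ty, angle = as.character(ang),
        path = rel, area = gen$truth$count,
        rowmin = gen$truth$bbox[["rowmin"]], rowmax = gen$truth$bbox[["rowmax"]],
        colmin = gen$truth$bbox[["colmin"]], colmax = gen$truth$bbox[["colmax"]],
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  utils::write.csv(meta, file.path(root, "metadata.csv"), row.names = FALSE,
                   quote = FALSE)
  manifest <- list(pattern = c("{id}_{date}", "{imtype}", "{angle}.png"),
                   metadata = "metadata.csv", key_column = "id",
                   records = records)
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate a planted-partition trait table
#'
#' Multivariate normal trait vectors with unit within-group standard
#' deviation; group `k` is displaced by `effect_size` (in units of sigma)
#' along trait axis `k`, so groups are separated by `effect_size * sqrt(2)`
#' between centers. With `effect_size = 0` all groups share one
#' distribution (for calibration checks).
#'
#' @param k_groups Number of groups (>= 2).
#' @param n_per_group Observations per group.
#' @param effect_size Group mean separation in sigma units.
#' @param n_traits Number of trait columns (defaults to `k_groups`).
#' @param seed Seed.
#' @return `list(traits = <matrix>, labels = <integer vector>)`.
#' @export
generate_trait_table <- function(k_groups = 3L, n_per_group = 20L,
                                 effect_size = 10, n_traits = NULL, seed = 1L) {
  if (k_groups < 2L) stop("need k_groups >= 2", call. = FALSE)
  n_traits <- n_traits %||% k_groups
  with_seed(seed, {
    labels <- rep(seq_len(k_groups), each = n_per_group)
    x <- matrix(stats::rnorm(length(labels) * n_traits), ncol = n_traits)
    for (k in seq_len(k_groups)) {
      ax <- ((k - 1L) %% n_traits) + 1L
      x[labels == k, ax] <- x[labels == k, ax] + effect_size
    }
    rownames(x) <- sprintf("obs%03d", seq_along(labels))
    colnames(x) <- sprintf("trait%d", seq_len(n_traits))
    list(traits = x, labels = labels)
  })
}

#' Generate a multi-experiment phenotype table with known genotype effects
#'
#' Simulates replicate trait measurements for `n_genotypes` genotypes in
#' each of several experiments, with additive experiment offsets and
#' N(0, `genotype_sd`^2) genotype effects; optionally drops a fraction of
#' (genotype, experiment) cells to create an unbalanced design. Supports
#' validating adjusted-mean recovery.
#'
#' @param n_genotypes,n_experiments,reps Design size.
#' @param genotype_sd SD of true genotype effects.
#' @param experiment_offsets Additive offset per experiment (recycled).
#' @param residual_sd Within-cell noise SD.
#' @param drop_fraction Fraction of genotype-by-experiment cells removed
#'   (never leaves a genotype with zero cells).
#' @param seed Seed.
#' @return `list(table = <data.frame genotype, experiment, replicate,
#'   value>, effects = <named true genotype effects>)`.
#' @export
generate_phenotype_table <- function(n_genotypes = 20L, n_experiments = 2L,
                                     reps = 3L, genotype_sd = 1,
                                     experiment_offsets = c(0, 5),
                                     residual_sd = 0.5, drop_fraction = 0,
                                     seed = 1L) {
  with_seed(seed, {
    gl <- sprintf("g%03d", seq_len(n_genotypes))
    eff <- stats::setNames(stats::rnorm(n_genotypes, 0, genotype_sd), gl)
    offs <- rep(experiment_offsets, length.out = n_experiments)
    cells <- expand.grid(genotype = gl, experiment = paste0("E", seq_len(n_experiments)),
                         stringsAsFactors = FALSE)
    if (drop_fraction > 0) {
      droppable <- unlist(lapply(split(seq_len(nrow(cells)), cells$genotype),
                                 function(ix) ix[-1]))   # keep >= 1 cell each
      k <- floor(drop_fraction * nrow(cells))
      drop <- sample(droppable, min(k, length(droppable)))
      if (length(drop)) cells <- cells[-drop, , drop = FALSE]
    }
    tab <- cells[rep(seq_len(nrow(cells)), each = reps), , drop = FALSE]
    tab$replicate <- rep(seq_len(reps), times = nrow(cells))
    ei <- as.integer(sub("E", "", tab$experiment))
    tab$value <- eff[tab$genotype] + offs[ei] +
      stats::rnorm(nrow(tab), 0, residual_sd)
    rownames(tab) <- NULL
    list(table = tab, effects = eff)
  })
}
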