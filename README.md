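# phenopipe

High-throughput plant phenotyping platforms image each plant daily from
several camera angles against a controlled background, producing directory
trees with millions of files. Turning those images into *digital traits* —
numeric descriptors of plant size, shape and color that stand in for
destructive measurements like shoot biomass — requires (1) a segmentation
pipeline that isolates plant pixels, (2) trait extraction, (3) metadata
ingestion at scale, and (4) batch execution that scales from a laptop to
many workers without changing results. `phenopipe` is an R toolkit covering
that whole path, aimed at plant biologists running greenhouse or
growth-chamber phenomics experiments (rice, wheat, maize, ...) with
LemnaTec-style imaging or simple fixed-camera setups.

## The method

**Segmentation** is a four-stage operator pipeline applied per image:

1. `crop(image, roi)` — cut away frame edges outside the controlled
   background; ROIs are `[ystart, yend, xstart, xend]`, 0-based, half-open.
2. `color_filter(image, expr)` — keep pixels whose color satisfies a
   logical expression over the channels; the standard rule for plants on a
   blue or white background is `g > b` (green exceeds blue). Rejected
   pixels become `(0,0,0)`, making the filter idempotent.
3. `contour_chop(image, min_area)` / `morphological_open(image)` — noise
   reduction: remove connected components (8-connectivity) smaller than
   `min_area` pixels, or open the foreground with a square structuring
   element.
4. `contour_cut(image, min_area)` — crop to the bounding box of all
   components larger than `min_area`, yielding the final plant object.

**Traits.** From the binary foreground mask the package computes raw image
moments `M_ij = Σ x^i y^j` (so `M00` is area and `(M10/M00, M01/M00)` the
center of mass), bounding-box height/width, convex-hull area and density
(plant area / hull area), per-channel color histograms, and composite
descriptors across the three standard views — two side views 90° apart and
a top view. Projected shoot area, `PSA = area_sv0 + area_sv90`, is the
digital proxy for shoot biomass. The full catalog with formulas is in
`trait_registry()`.

**Scale.** A run is parameterized by three JSON templates: *loading* (a
path pattern such as `{id}_{date}/{imtype}/{angle}.png` that the crawler
uses to parse metadata from the directory tree, plus a metadata CSV keyed
on plant id), *processing* (one job list per image type, wired by named
image slots into a DAG — execution order follows dependencies, not list
order), and *configuration* (concurrency, output root, seed).
`run_workflow()` crawls, loads an SQLite `images` table, executes every
(image × job) task — each image writes an isolated worker database — and
aggregates workers into one final database with tables `images`, `traits`
and `tasks`. Results are identical at any concurrency level.

**Statistics.** Downstream analysis mirrors standard phenomics practice:
`adjusted_means()` (least-squares means from an additive
genotype + experiment model), `pearson()`, `cluster_complete_linkage()`
(Euclidean distance, complete linkage, Newick export) and
`one_way_anova()` across the resulting architecture clusters.

Every component is validated against a deterministic synthetic-plant
generator (`plant_spec()`, `generate_plant_image()`, `generate_tree()`)
that records exact ground truth — the true pixel set, moments, hull and
histogram — so segmentation and trait extraction are tested to pixel-exact
equality without any external dataset.

## Worked example

```r
library(phenopipe)

# a synthetic rice-like plant with 4 debris blobs, plus exact ground truth
g   <- generate_plant_image(plant_spec(seed = 42, n_debris = 4))
seg <- segment_plant(g$image, expr = "g > b", min_chop = 40)
mask <- to_binary(seg$image)

seg$roi                      # 52 148 45 96   (bounding box found)
pixel_area(mask)             # 607
g$truth$count                # 607            (exact recovery)

round(extract_base_traits(mask)[c("area", "height", "width",
                                  "hull_area", "density")], 3)
#      area   height    width hull_area  density
#   607.000   96.000   51.000  2639.000    0.230

center_of_mass(raw_moments(mask))   # x 20.96  y 38.19 (pixels, 0-based)

# PSA from two side views
g2 <- generate_plant_image(plant_spec(seed = 43))
projected_shoot_area(pixel_area(mask), g2$truth$count)   # 1602

# architecture clustering on a planted 3-group trait table
tt <- generate_trait_table(k_groups = 3, n_per_group = 15,
                           effect_size = 10, seed = 7)
cl <- cluster_complete_linkage(tt$traits, k = 3)
adjusted_rand_index(cl$labels, tt$labels)   # 1: planted groups recovered
one_way_anova(tt$traits[, 1], cl$labels)    # F = 538.1, p < 2.2e-16
```

The numbers above are what the code prints: the pipeline recovers the
generator's 607 ground-truth plant pixels exactly (debris removed by the
color filter and the 40-pixel area threshold), density 0.23 indicates a
sparse, spreading architecture, and the planted clusters separate
perfectly at ten-sigma effect size.

A shell front end is installed with the package
(`system.file("cli", "ph", package = "phenopipe")`) with subcommands
`crawl`, `run`, `aggregate` and `extract`; it exits nonzero on any
validation error.

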