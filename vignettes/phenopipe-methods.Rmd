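---
title: "Segmentation, digital traits and workflow execution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation, digital traits and workflow execution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenopipe)
```

`phenopipe` turns controlled-background plant images into digital traits
and runs that extraction at scale. This vignette documents the model
behind each stage, the tunable parameters, the conventions chosen where
more than one reasonable definition exists, and what the synthetic
validation does and does not demonstrate.

## The segmentation model and its assumptions

The pipeline assumes the imaging conditions under which channel-expression
filtering is sound: a single plant in front of a uniform background whose
color differs strongly from plant tissue (blue, white or black work well),
fixed camera and plant positions, consistent lighting, and a scene free of
stray plant matter or soil. Under those conditions plant pixels are
green-dominant and the background is not, so a single per-pixel rule
separates the two.

Four stages run in order:

1. **Crop.** `crop(image, roi)` removes frame edges outside the
   controlled background. ROIs are `[ystart, yend, xstart, xend]`,
   0-based and half-open on both axes, with `y` the row and `x` the
   column. Half-open intervals make shapes exactly
   `(yend − ystart) × (xend − xstart)` with no ±1 ambiguity.
2. **Color filtering.** `color_filter(image, expr)` evaluates a logical
   expression over the channel values of every pixel and sets failing
   pixels to `(0, 0, 0)`. The expression grammar covers the operands
   `r`, `g`, `b`, integer literals, `+ − * /` (real-valued division),
   the comparisons `> >= < <= = !=`, and `and`/`or`/`not` with
   parentheses. The background fill `(0,0,0)` is deliberate: a binary
   mask is then simply "any channel > 0", and any expression that black
   fails (such as the default `g > b`, which is strict) makes the filter
   exactly idempotent.
3. **Noise reduction.** `contour_chop(image, min_area)` deletes connected
   foreground components with area *strictly below* `min_area` pixels.
   `morphological_open(image, kernel, iterations)` is the alternative:
   erosion then dilation on the binary support with a square structuring
   element (default 3×3, one iteration), applied as a mask so surviving
   pixels keep their colors.
4. **Plant cropping.** `contour_cut(image, min_area, padding)` computes
   the tight bounding box of all components with area *strictly above*
   `min_area`, pads and clamps it, and crops. It only crops — small
   components inside the box are retained. If nothing qualifies it raises
   an `empty_plant_error` carrying the component-area list, because a
   fully-background image is almost always an upstream failure worth
   noticing rather than an empty result worth propagating.

**Connectivity and areas.** Foreground components use 8-connectivity:
thin plant organs (tillers, leaf tips) frequently touch only diagonally,
and 4-connectivity would fragment them. Component area is the pixel count
of the filled component, not a polygonal boundary area; this makes every
area claim exactly checkable against a flood-fill enumeration, at the cost
that boundary-polygon implementations may report slightly different
values.

**Threshold strictness.** Whether the chop threshold is `<` or `≤` is a
genuine convention choice; this package removes components with
`area < min_area` (so `min_area = 0` is the identity) and cuts to
components with `area > min_area`. Both are documented here rather than
inferred, and tests pin them.

## Digital traits

All shape traits are computed on the binary mask with unit pixel weight
(not intensity-weighted). Raw moments are
`M_ij = Σ x^i y^j` over foreground pixels, `x` = column, `y` = row,
0-based, up to order 3 — 16 values. `M00` is area; the centroid is
`(M10/M00, M01/M00)`. Moments are accumulated in double precision; every
term is an exact integer and remains exact below 2^53, which holds for
any realistic image size at order ≤ 3 per axis (a 10^4-pixel-wide image
would be needed to break it).

The convex hull is the hull of foreground *pixel centers*, and hull area
is counted discretely as the number of pixel centers inside or on the
hull. This makes the density trait `area / hull_area` exactly 1 for any
filled convex shape and keeps the quantity verifiable by brute-force
point-in-polygon testing; it differs from the real polygon area by a
boundary term of order the hull perimeter. Collinear foregrounds (a
1-pixel-wide line) get the lattice-point count of their segment, so
density remains 1 for a straight line of pixels.

Composite traits combine the three standard views (side views at 0° and
90°, one top view). Conventions, all recorded in `trait_registry()`:

* `_SV` quantities average the two side views, **except** `PSA`, which is
  by definition the *sum* `area_sv0 + area_sv90` (the biomass proxy; the
  two views are never averaged).
* Three density variants are provided because normalization by hull,
  bounding box, or hull perimeter are all in circulation and the mapping
  to any particular tool's `Den1/Den2/Den3` is a naming convention:
  here `Den1` = area/hull, `Den2` = area/bounding box,
  `Den3` = `4π·area/perimeter²` (a circularity against the hull boundary).
* Growth-habit traits: `GH1` = width/height; `GH2` = relative centroid
  height within the bounding box (`(ȳ − ymin + 0.5)/height`, in (0, 1));
  `GH3` = side-view minor/major principal-axis ratio from central second
  moments; `GH4` = top-view eccentricity `sqrt(1 − λ₂/λ₁)`. `GH3`/`GH4`
  are this package's definitions of "hull aspect"-style shape ratios;
  users can audit and substitute their own via the registry.

Color histograms bin foreground pixels per channel into fixed-width bins
over `[0, 256)`; the default 8 bins (width 32) trades resolution for
stable proportions at typical plant sizes. `bins` must divide 256 so bin
edges are exact.

## Crawler and workflow engine

Path templates describe each directory level as literal text plus
`{name}` captures (`{name:regex}` to constrain); within a component an
unconstrained capture matches non-greedily up to the next literal and the
last capture takes the remainder. A template must capture at least `id`
and `imtype`. Files that do not match are counted and reported — never
silently dropped — so `records + skipped = files` always holds. `date` or
`timestamp` captures are parsed to ISO-8601; unparseable values are kept
verbatim with a flag rather than rejected, because a malformed folder
name should not discard an image. Metadata joins are left joins keyed on
`id`; duplicate keys in the metadata CSV are an error (they would silently
duplicate trait rows downstream).

The processing template maps each image type to a job list. Dependencies
come from named input/output slots, not list position, so a reordered but
correctly wired list yields the identical DAG. Validation is *complete*:
all violations (unknown operation, unparseable filter expression, dangling
slot, duplicate name, cycle, workflow/image-type mismatch) are collected
into one `template_error` rather than failing one at a time.

Execution groups tasks by image record: each record's jobs run in
topological order in an isolated worker that writes its own SQLite
database, mirroring worker-node execution on a computing grid where
concurrent writes to one database are not safe. Because workers share
nothing and trait rows are sorted canonically at aggregation, the final
database is a pure function of (templates, image tree, seed) and is
byte-identical at any concurrency level. A failing job marks only its
descendants `skipped`; completed upstream outputs (processed images,
trait rows of other images) are preserved, the right behavior when one
corrupt image sits among tens of thousands. Aggregation refuses schema
drift, inserts rows in sorted order (worker order cannot matter), and
conserves row counts exactly.

## Downstream statistics

`adjusted_means()` fits `value ~ genotype + experiment` by least squares
and evaluates each genotype at the unweighted average of experiment
levels — the least-squares mean. On balanced data this equals the raw
genotype mean; with one experiment it is the plain mean. Genotype is
fitted as a **fixed** effect: shrinkage toward the grand mean under a
random-effects treatment requires a variance ratio this package has no
principled default for, and the fixed-effect adjusted means are the
quantity the rest of the pipeline (clustering, ANOVA) consumes. The
implementation is cross-checked in the tests against `emmeans`.

`cluster_complete_linkage()` uses Euclidean distance and complete linkage
(`stats::hclust`). Standardization is **off by default**: raw moments of
different orders live at wildly different scales, and that scale is part
of the architecture signal this clustering is meant to capture (cuts are
made at raw Euclidean heights); a `standardize` flag exists for users who
want z-scores. Cut labels are renumbered by each cluster's smallest
observation index, so labels are stable under input reordering; exactly
tied merges can still regroup, which is measure-zero for continuous
traits. The function also accepts a precomputed `dist` object, since
complete linkage is well-defined for arbitrary dissimilarities.

`one_way_anova()` is the standard between/within decomposition via
`stats::lm`/`anova`, with explicit errors for groups smaller than 2.
`adjusted_rand_index()` is provided for planted-partition validation and
is cross-checked against `mclust`.

## What the synthetic generator emulates — and what it does not

`generate_plant_image()` renders a stem plus angled leaves in
green-dominant colors (`g > b` holds for every plant pixel by
construction) on a uniform blue or white background, with an optional pot
band and debris. Default debris is blue/gray — it *fails* the color
filter, emulating soil or container specks that background removal alone
handles. `hard_noise = TRUE` makes green-like debris placed at Chebyshev
distance ≥ 2 from the plant: it *passes* the filter and only the
area-based noise-reduction stage can remove it, exercising that stage
separately. Ground truth (pixel set, count, bounding box, moments, hull
area, histogram) is computed from the exact rasterized plant pixel set
before compositing; all randomness flows from the single spec seed, and
the same seed reproduces the image byte-for-byte.

The generator deliberately does **not** emulate shadows, specular
highlights, blur from plant motion, overlapping pots, fluorescence
intensity physics, or color gradients within organs. Passing the
pixel-exact recovery tests therefore shows the operators implement their
definitions exactly under the stated imaging assumptions; it does not
show robustness to violations of those assumptions, which on real images
is governed by the user's choice of filter expression and thresholds.

`generate_tree()` writes a LemnaTec-style tree
(`<id>_<date>/<imtype>/<angle>.png`) with a metadata CSV and a ground-truth
manifest; stem height grows with the day index so per-plant areas rise
over time. `generate_trait_table()` plants `k` groups displaced by
`effect_size · σ` along distinct trait axes (unit within-group SD);
`generate_phenotype_table()` adds genotype effects, experiment offsets and
optional cell dropping for unbalanced designs.

## Numerical choices and degenerate inputs

* Channel order is red, green, blue everywhere in the data model; readers
  convert on load. Images are integer arrays in `[0, 255]`; PNG round
  trips are exact (tests depend on this), JPEG is read-only.
* Empty masks: moments are all-zero; centroid, dimensions and hull raise
  errors (undefined); histograms return zero counts with flagged
  `NA` proportions. Every operator propagates an all-background image
  except `contour_cut`, which raises `empty_plant_error`.
* Component labelling scans in column-major order, so component numbering
  is deterministic for a given mask.
* Histogram proportions are compared to 1 within 1e−9 in tests; all other
  pixel-level checks are exact integer equality.

## Validation scale

The test suite and `scripts/acceptance.R` size their simulations to run
comfortably on a single CPU: 200 random masks up to 64×64 for the moment
oracle, 500 small masks for the component oracle, 50 noise-free plus 20
hard-noise plants for segmentation exactness, a 1008-file tree for the
crawler round trip, an 18-image tree at concurrency 1 vs 8 for schedule
invariance, 20 planted-partition seeds for clustering, and 400 null
simulations for ANOVA calibration (rejection rate checked against the
binomial 95% interval around 0.05). These sizes were chosen as the
smallest that make each property's failure modes visible; all exactness
claims are scale-free, so larger inputs add runtime, not information.

## Known limitations

* Segmentation is purely color-and-size based; no texture, mean-shift or
  learned segmentation is provided.
* Skeletonization, leaf counting and organ-level traits are out of scope.
* The hull-area convention (pixel centers) differs from polygon-area
  implementations by a boundary term; comparisons across tools should
  recompute density from the same convention.
* Distributed execution across machines is out of scope: the executor is
  an in-process scheduler honoring the same template contract as
  grid-based systems, so templates port, but the scheduling itself is
  local.
* Genotype effects are fixed, not shrunk; with very few replicates per
  genotype, adjusted means will be noisier than a random-effects BLUP.
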