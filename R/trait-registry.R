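#' The composite digital-trait catalog
#'
#' Composite traits combine the base metrics of the three standard views of
#' one plant on one day — two side views (sv0, sv90, 90 degrees apart) and
#' one top view (tv) — into the morphological descriptors used downstream:
#' projected shoot area, convex-hull (CH), density (Den) and growth-habit
#' (GH) traits. Every formula lives in this one registry so users can audit
#' or override it; the conventions are:
#'
#' * side-view (`_SV`) quantities are the mean over the two angles, except
#'   `PSA`, which is by definition the *sum* of the two side-view areas;
#' * `Den1` normalizes plant area by convex-hull area, `Den2` by
#'   bounding-box area, `Den3` is the hull-perimeter-normalized variant
#'   `4 * pi * area / perimeter^2` (a circularity); the numbering is a
#'   package convention;
#' * `GH1` = width/height (erect vs spreading), `GH2` = relative centroid
#'   height within the bounding box, `GH3` = side-view elongation
#'   (minor/major axis ratio), `GH4` = top-view eccentricity.
#'
#' @param base Logical; if `TRUE` also list the per-view raw-moment traits.
#' @return A data frame with columns `trait`, `formula`, `units`.
#' @export
trait_registry <- function(base = FALSE) {
  reg <- data.frame(
    trait = c("Height_SV", "Width_SV", "CA_SV", "Area_TV", "PSA",
              "CH_SV", "CH_TV",
              "Den1_SV", "Den1_TV", "Den2_SV", "Den2_TV", "Den3_SV", "Den3_TV",
              "GH1", "GH2", "GH3", "GH4"),
    formula = c(
      "mean over side views of foreground bounding-box height",
      "mean over side views of foreground bounding-box width",
      "mean over side views of foreground pixel count (cropped area)",
      "top-view foreground pixel count",
      "area_sv0 + area_sv90 (sum of the two side-view pixel counts)",
      "mean over side views of convex-hull area (pixel centers in hull)",
      "top-view convex-hull area",
      "CA_SV / CH_SV", "Area_TV / CH_TV",
      "mean over side views of area / (height * width)",
      "Area_TV / (height_TV * width_TV)",
      "mean over side views of 4*pi*area / hull_perimeter^2",
      "4*pi*Area_TV / hull_perimeter_TV^2",
      "Width_SV / Height_SV",
      "mean over side views of (centroid_y - ymin + 0.5) / height",
      "mean over side views of minor/major principal-axis ratio",
      "top-view eccentricity sqrt(1 - lambda2/lambda1)"),
    units = c("pixels", "pixels", "pixels^2 (count)", "pixels^2 (count)",
              "pixels^2 (count)", "pixels^2 (count)", "pixels^2 (count)",
              rep("ratio", 10)),
    stringsAsFactors = FALSE)
  if (base) {
    mom <- paste0("M", rep(0:3, times = 4), rep(0:3, each = 4))
    reg <- rbind(reg, data.frame(
      trait = c(paste0(mom, "_SV0"), paste0(mom, "_SV90"), paste0(mom, "_TV")),
      formula = "raw moment sum(x^i y^j) over the view's foreground",
      units = "pixel moments", stringsAsFactors = FALSE))
  }
  reg
}

#' Compute composite traits for one plant-day
#'
#' Takes the per-view base traits of the three standard views (see
#' [extract_base_traits()]) and emits the composite catalog documented in
#' [trait_registry()], plus the 16 raw moments of every view.
#'
#' @param sv0,sv90,tv Named base-trait vectors from [extract_base_traits()],
#'   or logical masks (converted automatically).
#' @return A data frame `(trait, value)` in catalog order.
#' @examples
#' sq <- matrix(TRUE, 10, 10)
#' tr <- composite_traits(sq, sq, sq)
#' tr[tr$trait == "GH1", "value"]   # 1: equal width and height
#' @export
composite_traits <- function(sv0, sv90, tv) {
  views <- list(sv0 = sv0, sv90 = sv90, tv = tv)
  missing <- names(views)[vapply(views, is.null, logical(1))]
  if (length(missing))
    stop("missing required view(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  views <- lapply(views, function(v) if (is.logical(v)) extract_base_traits(v) else v)
  s0 <- views$sv0; s90 <- views$sv90; t <- views$tv
  sv <- function(field) mean(c(s0[[field]], s90[[field]]))
  vals <- c(
    Height_SV = sv("height"),
    Width_SV  = sv("width"),
    CA_SV     = sv("area"),
    Area_TV   = t[["area"]],
    PSA       = projected_shoot_area(s0[["area"]], s90[["area"]]),
    CH_SV     = sv("hull_area"),
    CH_TV     = t[["hull_area"]],
    Den1_SV   = sv("area") / sv("hull_area"),
    Den1_TV   = t[["area"]] / t[["hull_area"]],
    Den2_SV   = mean(c(s0[["area"]] / (s0[["height"]] * s0[["width"]]),
                       s90[["area"]] / (s90[["height"]] * s90[["width"]]))),
    Den2_TV   = t[["area"]] / (t[["height"]] * t[["width"]]),
    Den3_SV   = mean(c(den3_of(s0), den3_of(s90))),
    Den3_TV   = den3_of(t),
    GH1       = sv("width") / sv("height"),
    GH2       = mean(c(gh2_of(s0), gh2_of(s90))),
    GH3       = sv("elongation"),
    GH4       = t[["eccentricity"]])
  mom <- paste0("M", rep(0:3, times = 4), rep(0:3, each = 4))
  vals <- c(vals,
            stats::setNames(s0[mom], paste0(mom, "_SV0")),
            stats::setNames(s90[mom], paste0(mom, "_SV90")),
            stats::setNames(t[mom], paste0(mom, "_TV")))
  data.frame(trait = names(vals), value = unname(vals),
             stringsAsFactors = FALSE)
}

# Den3: hull-perimeter-normalized area (circularity of the plant against
# its hull boundary). Degenerate hulls (perimeter 0) yield NA.
den3_of <- function(v) {
  if (v[["hull_perimeter"]] <= 0) return(NA_real_)
  4 * pi * v[["area"]] / v[["hull_perimeter"]]^2
}

# GH2: relative centroid height within the bounding box, in (0, 1).
gh2_of <- function(v) {
  (v[["centroid_y"]] - v[["ymin"]] + 0.5) / v[["height"]]
}
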