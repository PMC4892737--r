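#' Adjusted genotype means across experiments
#'
#' Data combined across experiments are adjusted for experiment effects
#' before downstream analysis: an additive two-factor linear model
#' (`value ~ genotype + experiment`, no interaction) is fitted by least
#' squares, and the adjusted mean of a genotype is its prediction averaged
#' with equal weight over the experiment levels — the least-squares mean.
#' On a balanced design this collapses to the raw genotype means, and with
#' a single experiment it is the plain arithmetic mean. Genotype is fitted
#' as a fixed effect.
#'
#' @param table Data frame with one row per observation.
#' @param trait Name of the numeric trait column.
#' @param genotype,experiment Names of the grouping columns.
#' @return Named numeric vector of adjusted means, one per genotype present
#'   in the data. Genotypes with no non-missing observations are excluded
#'   and reported in the `excluded` attribute (with a message).
#' @export
adjusted_means <- function(table, trait, genotype = "genotype",
                           experiment = "experiment") {
  for (col in c(trait, genotype))
    if (!col %in% names(table)) stop("no column `", col, "`", call. = FALSE)
  df <- data.frame(y = table[[trait]],
                   g = as.character(table[[genotype]]),
                   stringsAsFactors = FALSE)
  df$e <- if (experiment %in% names(table)) as.character(table[[experiment]]) else "1"
  keep <- !is.na(df$y)
  all_g <- unique(df$g)
  df <- df[keep, , drop = FALSE]
  excluded <- setdiff(all_g, unique(df$g))
  if (length(excluded))
    message("excluded genotype(s) with no data: ", paste(excluded, collapse = ", "))
  if (nrow(df) == 0L) stop("no non-missing observations", call. = FALSE)
  gl <- sort(unique(df$g)); el <- sort(unique(df$e))
  if (length(el) == 1L) {
    out <- stats::setNames(as.numeric(tapply(df$y, df$g, mean)[gl]), gl)
  } else {
    fit <- stats::lm(y ~ g + e, data = transform(df, g = factor(g, gl),
                                                 e = factor(e, el)))
    grid <- expand.grid(g = factor(gl, gl), e = factor(el, el))
    pred <- matrix(stats::predict(fit, newdata = grid), nrow = length(gl))
    out <- stats::setNames(rowMeans(pred), gl)
  }
  structure(out, excluded = excluded)
}

#' Pearson product-moment correlation
#'
#' Used to compare digital traits (e.g. projected shoot area) with manual
#' phenotypic measurements.
#'
#' @param x,y Numeric vectors of equal length, at least 3, each with
#'   nonzero variance.
#' @return The correlation coefficient `r`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values: drop or impute first", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}

#' Complete-linkage hierarchical clustering of trait profiles
#'
#' Agglomerative clustering with Euclidean distance and complete linkage
#' (merge height = maximum inter-cluster pairwise distance), as used to
#' identify major plant-architecture groups from raw image moments. By
#' default traits are clustered at their native scale — raw moments of
#' different orders differ by many orders of magnitude and that scale
#' information is part of the signal; set `standardize = TRUE` to cluster
#' z-scores instead.
#'
#' Cutting the tree at a Euclidean height `h` or into `k` groups yields
#' cluster labels, renumbered canonically by each cluster's smallest
#' observation index so that labels do not depend on input order
#' (observation reordering can still regroup exactly tied merges;
#' continuous traits make ties measure-zero).
#'
#' @param x Numeric matrix or data frame, observations x traits (Euclidean
#'   distances are computed), or a precomputed [stats::dist] object —
#'   complete linkage is defined for arbitrary dissimilarities. No missing
#'   values.
#' @param k Number of clusters to cut into, or `NULL`.
#' @param h Height threshold to cut at, or `NULL`.
#' @param standardize Scale each trait to unit variance first.
#' @return An object of class `trait_clustering`: `list(labels, hclust,
#'   merge_heights, k)`; `labels` is `NULL` when neither `k` nor `h` is
#'   given.
#' @export
cluster_complete_linkage <- function(x, k = NULL, h = NULL, standardize = FALSE) {
  if (inherits(x, "dist")) {
    if (anyNA(x)) stop("missing values in distances", call. = FALSE)
    d <- x
    obs_names <- attr(x, "Labels")
  } else {
    x <- as.matrix(x)
    if (anyNA(x))
      stop("missing values in trait matrix: impute or drop upstream", call. = FALSE)
    if (nrow(x) < 2L) stop("need at least 2 observations", call. = FALSE)
    if (standardize) x <- scale(x)
    d <- stats::dist(x, method = "euclidean")
    obs_names <- rownames(x)
  }
  hc <- stats::hclust(d, method = "complete")
  labels <- NULL
  if (!is.null(k) || !is.null(h)) {
    raw <- if (!is.null(k)) stats::cutree(hc, k = k) else stats::cutree(hc, h = h)
    first <- tapply(seq_along(raw), raw, min)     # smallest member index
    relabel <- stats::setNames(rank(first), names(first))
    labels <- unname(relabel[as.character(raw)])
    names(labels) <- obs_names
  }
  structure(list(labels = labels, hclust = hc, merge_heights = hc$height,
                 k = if (!is.null(labels)) length(unique(labels))),
            class = "trait_clustering")
}

#' @export
print.trait_clustering <- function(x, ...) {
  cat(sprintf("<trait_clustering> %d observations, complete linkage\n",
              length(x$hclust$order)))
  if (!is.null(x$labels))
    cat("  clusters:", paste(table(x$labels), collapse = " / "), "\n")
  cat(sprintf("  merge heights: %.4g .. %.4g\n",
              min(x$merge_heights), max(x$merge_heights)))
  invisible(x)
}

#' @export
plot.trait_clustering <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}

#' Export a dendrogram as Newick text
#'
#' @param clustering A [cluster_complete_linkage()] result.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if written to a file.
#' @export
dendrogram_newick <- function(clustering, path = NULL) {
  phy <- ape::as.phylo(clustering$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' One-way analysis of variance across clusters
#'
#' Tests whether a digital trait differs between groups (e.g. architecture
#' clusters) by the standard between/within sum-of-squares decomposition;
#' the p-value comes from the F distribution with `(k - 1, n - k)` degrees
#' of freedom.
#'
#' @param values Numeric observations.
#' @param groups Group label per observation; at least 2 groups, each with
#'   at least 2 observations.
#' @return `list(F, p, df, group_means, n)`.
#' @export
one_way_anova <- function(values, groups) {
  if (length(values) != length(groups)) stop("lengths differ", call. = FALSE)
  keep <- !is.na(values)
  values <- values[keep]; groups <- as.character(groups)[keep]
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
  small <- names(sizes)[sizes < 2L]
  if (length(small))
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "), call. = FALSE)
  fit <- stats::lm(values ~ factor(groups))
  a <- stats::anova(fit)
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1],
       df = c(between = a$Df[1], within = a$Df[2]),
       group_means = tapply(values, groups, mean),
       n = length(values))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between a recovered clustering and reference
#' labels; 1 means identical partitions, 0 is the expectation under random
#' labelling. Used to verify planted-partition recovery.
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
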