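#' Two-sided rank-sum (Mann-Whitney) comparison
#'
#' Unpaired two-sample Wilcoxon rank-sum test. The exact permutation
#' distribution is used when the pooled sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction is used. Delegates to [stats::wilcox.test()].
#'
#' @param a,b Numeric samples.
#' @param group_a,group_b Labels for the report row.
#' @return A `comparison_result`: group labels, sample sizes, the
#'   Mann-Whitney U statistic (for sample `a`), the two-sided p-value, the
#'   branch used (`"exact"` or `"normal_approx"`), and the significance
#'   tier.
#' @export
rank_sum_test <- function(a, b, group_a = "a", group_b = "b") {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("empty sample", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  p <- min(1, ht$p.value)
  structure(list(group_a = group_a, group_b = group_b,
                 n_a = length(a), n_b = length(b),
                 U = unname(ht$statistic),
                 p_two_sided = p,
                 branch = if (exact) "exact" else "normal_approx",
                 tier = significance_tier(p)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s (n=%d) vs %s (n=%d): U=%.1f, p=%.4g [%s] %s\n",
              x$group_a, x$n_a, x$group_b, x$n_b, x$U, x$p_two_sided,
              x$branch, x$tier))
  invisible(x)
}

#' Significance tier of a p-value
#'
#' `ns` for p >= 0.05, `*` for p < 0.05, `**` for p < 0.01 and `***` for
#' p < 0.001 (the boundary p = 0.05 is not significant).
#'
#' @param p P-value in \[0, 1\].
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @export
significance_tier <- function(p) {
  if (!is.numeric(p) || is.na(p) || p < 0 || p > 1) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  if (p >= 0.05) "ns" else if (p >= 0.01) "*" else if (p >= 0.001) "**"
  else "***"
}

#' Filter out near-clone fragments
#'
#' Removes small clones (1 to `fragment_max_cells` cells) whose boundary
#' lies within `proximity_um` of a clone of at least `min_cells` cells —
#' presumed to have split off from the bigger clone — from shape analyses.
#' Isolated small clones are kept (they are sub-threshold for circularity
#' but are not fragments). Optionally also removes border-touching clones,
#' whose perimeters are truncated by the field of view.
#'
#' @param clones List of `clone` objects.
#' @param min_cells Size from which a clone anchors fragment removal
#'   (default 10).
#' @param fragment_max_cells Maximum size of a removable fragment
#'   (default 10; 0 disables the filter).
#' @param proximity_um Boundary-to-boundary distance within which a small
#'   clone counts as "close" (default 20 µm).
#' @param exclude_border Also remove border-touching clones (default FALSE).
#' @return List with `kept` and `removed` clone lists; removed clones carry
#'   a `removal_reason` field.
#' @export
filter_fragments <- function(clones, min_cells = 10L,
                             fragment_max_cells = 10L, proximity_um = 20,
                             exclude_border = FALSE) {
  removed <- list(); kept <- list()
  big <- Filter(function(cl) cl$n_cells >= min_cells, clones)
  for (cl in clones) {
    reason <- NULL
    if (exclude_border && cl$touches_border) {
      reason <- "border"
    } else if (fragment_max_cells > 0 && cl$n_cells >= 1 &&
               cl$n_cells <= fragment_max_cells) {
      near <- any(vapply(big, function(bg) {
        if (identical(bg$cell_ids, cl$cell_ids)) return(FALSE)
        boundary_distance(cl$boundary, bg$boundary) <= proximity_um
      }, logical(1)))
      if (near) reason <- "fragment"
    }
    if (is.null(reason)) {
      kept[[length(kept) + 1]] <- cl
    } else {
      cl$removal_reason <- reason
      removed[[length(removed) + 1]] <- cl
    }
  }
  list(kept = kept, removed = removed)
}

# minimum distance between two polygon boundaries (vertex-to-segment,
# both directions)
boundary_distance <- function(p1, p2) {
  if (is.null(p1) || is.null(p2)) return(Inf)
  min(points_to_segments(p1, p2), points_to_segments(p2, p1))
}

points_to_segments <- function(pts, poly) {
  m <- nrow(poly)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  best <- Inf
  for (i in seq_len(nrow(pts))) {
    t <- ((pts[i, 1] - ax) * dx + (pts[i, 2] - ay) * dy) / pmax(len2, 1e-300)
    t <- pmin(pmax(t, 0), 1)
    d2 <- (ax + t * dx - pts[i, 1])^2 + (ay + t * dy - pts[i, 2])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Box-plot summary
#'
#' Quartiles by linear interpolation ([stats::quantile()] type 7), whiskers
#' at the most extreme data within 1.5 interquartile ranges of the
#' quartiles, and the points beyond the whiskers listed as outliers.
#'
#' @param x Numeric sample (n >= 1).
#' @return A `box_summary`: `q25`, `q50`, `q75`, `whisker_low`,
#'   `whisker_high`, `outliers`, `n`.
#' @export
box_summary <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0 || any(is.na(x))) {
    stop("x must be a nonempty sample without NA", call. = FALSE)
  }
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  structure(list(q25 = q[1], q50 = q[2], q75 = q[3],
                 whisker_low = min(x[inside]),
                 whisker_high = max(x[inside]),
                 outliers = sort(x[!inside]), n = length(x)),
            class = "box_summary")
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf(
    "<box_summary> n=%d median=%.3g [%.3g, %.3g], whiskers [%.3g, %.3g], %d outlier(s)\n",
    x$n, x$q50, x$q25, x$q75, x$whisker_low, x$whisker_high,
    length(x$outliers)))
  invisible(x)
}

#' Render a cell-area heatmap
#'
#' Colors each cell by its apical area on a fixed diverging scale, deep red
#' at/below `scale[1]` to light green at/above `scale[2]` (defaults
#' 0.2-12 µm², the convention that makes heatmaps comparable across
#' experiments), with clone boundaries overdrawn in blue.
#'
#' @param tissue A `tissue`.
#' @param scale Length-2 numeric, low and high area bounds in µm².
#' @param pixel_size_um Raster pixel size; defaults to the tissue's.
#' @param n_colors Number of color bins.
#' @return An `nrow x ncol x 3` RGB array in \[0, 1\].
#' @export
render_area_heatmap <- function(tissue, scale = c(0.2, 12),
                                pixel_size_um = tissue$pixel_size_um,
                                n_colors = 64L) {
  if (scale[2] <= scale[1]) stop("scale must satisfy hi > lo", call. = FALSE)
  pal <- colorRampPalette(c("#67000D", "#D7301F", "#FC8D59", "#FEE08B",
                            "#D9EF8B", "#A6D96A"))(n_colors)
  labels <- rasterize_tissue(tissue, pixel_size_um)
  areas <- tissue$cells$area_um2
  bin <- 1L + as.integer(round((n_colors - 1) *
    pmin(pmax((areas - scale[1]) / (scale[2] - scale[1]), 0), 1)))
  rgb_cell <- t(col2rgb(pal[bin])) / 255
  nr <- nrow(labels); nc <- ncol(labels)
  img <- array(0, c(nr, nc, 3))
  for (k in 1:3) img[, , k] <- matrix(rgb_cell[labels, k], nr, nc)
  # overdraw heterotypic (clone) boundaries in blue
  geno <- ifelse(is.na(tissue$cells$clone_id), 0L, 1L)
  gl <- matrix(geno[labels], nr, nc)
  edge <- matrix(FALSE, nr, nc)
  heth <- (labels[, -1] != labels[, -nc]) & (gl[, -1] != gl[, -nc])
  e <- edge[, -1]; e[heth] <- TRUE; edge[, -1] <- e
  e <- edge[, -nc]; e[heth] <- TRUE; edge[, -nc] <- e
  hetv <- (labels[-1, ] != labels[-nr, ]) & (gl[-1, ] != gl[-nr, ])
  e <- edge[-1, ]; e[hetv] <- TRUE; edge[-1, ] <- e
  e <- edge[-nr, ]; e[hetv] <- TRUE; edge[-nr, ] <- e
  for (k in 1:3) {
    ch <- img[, , k]
    ch[edge] <- c(0.1, 0.3, 0.9)[k]
    img[, , k] <- ch
  }
  img
}
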