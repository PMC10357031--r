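#' Interface circularity (isoperimetric quotient)
#'
#' `4 * pi * area / perimeter^2` of the clone's exterior boundary: 1 for a
#' circle, `pi/4` for a square, decreasing as the interface becomes more
#' ragged. Scale and rotation invariant; bounded by 1 for simple polygons
#' (rasterized boundaries may exceed it by a small smoothing tolerance).
#'
#' @param x A `clone` or a two-column polygon vertex matrix.
#' @param ... Unused.
#' @return Circularity (dimensionless).
#' @export
circularity <- function(x, ...) UseMethod("circularity")

#' @rdname circularity
#' @export
circularity.clone <- function(x, ...) {
  if (x$touches_border) {
    stop("clone touches the field border; its perimeter is truncated",
         call. = FALSE)
  }
  if (is.null(x$boundary)) stop("clone has no boundary", call. = FALSE)
  circularity.default(x$boundary)
}

#' @rdname circularity
#' @export
circularity.default <- function(x, ...) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("degenerate polygon", call. = FALSE)
  p <- polygon_perimeter(x)
  a <- polygon_area(x)
  if (p <= 0 || a <= 0) stop("degenerate polygon", call. = FALSE)
  4 * pi * a / p^2
}

#' Apical-area statistics inside and outside a clone
#'
#' Arithmetic mean apical (polygon) area of clone member cells and of the
#' wild-type neighborhood ring, and their ratio — the readout of apical
#' constriction of enclosed minority cells. Border-flagged cells are
#' excluded on both sides (their polygons are truncated by the field edge).
#'
#' @param clone A `clone`.
#' @param nbhd Its [neighborhood()].
#' @param tissue The tissue both came from.
#' @return List: `mean_inside`, `mean_outside`, `ratio` (inside/outside),
#'   `per_cell` (data.frame of cell areas with a `side` column).
#' @export
apical_area_stats <- function(clone, nbhd, tissue) {
  inside_ids <- clone$cell_ids[!tissue$cells$on_border[clone$cell_ids]]
  if (length(inside_ids) == 0) {
    stop("clone has no non-border cells", call. = FALSE)
  }
  outside_ids <- nbhd$ring$cell_id
  if (length(outside_ids) == 0) stop("empty neighborhood", call. = FALSE)
  ain <- tissue$cells$area_um2[inside_ids]
  aout <- tissue$cells$area_um2[outside_ids]
  list(mean_inside = mean(ain), mean_outside = mean(aout),
       ratio = mean(ain) / mean(aout),
       per_cell = rbind(
         data.frame(cell_id = inside_ids, area_um2 = ain, side = "inside"),
         data.frame(cell_id = outside_ids, area_um2 = aout,
                    side = "outside")))
}

#' Cell-mixing index
#'
#' Mean number of distinct wild-type cells in direct junctional contact
#' with one clonal cell at the frontline. High values mean clone cells are
#' interdigitated with (or dispersed among) wild-type neighbors; the
#' minimum for a nonempty frontline is 1.
#'
#' @param clone A `clone`.
#' @param tissue The tissue it came from.
#' @param aggregate `"mean"` (default) or `"max"` over frontline cells.
#' @return Mixing index (dimensionless).
#' @export
mixing_index <- function(clone, tissue, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  fl <- frontline(clone, tissue)
  if (nrow(fl) == 0) stop("empty frontline", call. = FALSE)
  switch(aggregate, mean = mean(fl$n_wt_contacts), max = max(fl$n_wt_contacts))
}

#' Contact length
#'
#' Clone perimeter divided by the number of frontline cells (µm per
#' frontline cell). Rises when clone cells disperse: fewer shared
#' boundaries per unit of interface.
#'
#' @inheritParams mixing_index
#' @return Contact length in µm.
#' @export
contact_length <- function(clone, tissue) {
  fl <- frontline(clone, tissue)
  if (nrow(fl) == 0) stop("empty frontline", call. = FALSE)
  clone$perimeter_um / nrow(fl)
}

#' Region of interest polygon
#'
#' @param name ROI name (e.g. `"dorsal_pouch"`).
#' @param polygon Two-column vertex matrix in µm.
#' @return A `region_roi`.
#' @export
region_roi <- function(name, polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3 || polygon_area(polygon) <= 0) {
    stop("ROI must be a simple polygon with positive area", call. = FALSE)
  }
  structure(list(name = name, polygon = polygon), class = "region_roi")
}

#' Clone-area fraction within a region
#'
#' Fraction of the ROI area covered by the clone mask — the clone-recovery
#' readout (how much of a compartment remains occupied by clones at a fixed
#' time after induction).
#'
#' @param mask A [detect_clone_mask()] result or logical matrix.
#' @param roi A [region_roi()].
#' @param pixel_size_um Pixel size of the mask in µm.
#' @return Fraction in \[0, 1\].
#' @export
clone_area_fraction <- function(mask, roi, pixel_size_um) {
  m <- if (inherits(mask, "clone_mask")) mask$mask else mask
  nr <- nrow(m); nc <- ncol(m)
  cc <- rep(seq_len(nc), each = nr)
  rr <- rep(seq_len(nr), nc)
  roi_px <- points_in_polygon((cc - 0.5) * pixel_size_um,
                              (rr - 0.5) * pixel_size_um, roi$polygon)
  n_roi <- sum(roi_px)
  if (n_roi == 0) stop("empty ROI: no pixels fall inside it", call. = FALSE)
  sum(m[cbind(rr[roi_px], cc[roi_px])]) / n_roi
}

#' Count clones remaining in a region
#'
#' Number of clones whose boundary centroid lies inside the ROI and whose
#' size is at least `min_cells` — the remaining-clone readout.
#'
#' @param clones List of `clone` objects.
#' @param roi A [region_roi()].
#' @param min_cells Minimum clone size to count.
#' @return Integer count.
#' @export
count_remaining_clones <- function(clones, roi, min_cells = 1L) {
  if (length(clones) == 0) return(0L)
  inside <- vapply(clones, function(cl) {
    if (cl$n_cells < min_cells || is.null(cl$boundary)) return(FALSE)
    ctr <- polygon_centroid(cl$boundary)
    points_in_polygon(ctr[1], ctr[2], roi$polygon)
  }, logical(1))
  sum(inside)
}

#' Mask-based clone circularity
#'
#' Circularity of each connected component of a clone mask, measured on the
#' traced (and lightly smoothed) component outline. This is the readout for
#' workflows where clones are outlined by blurred-and-thresholded staining
#' rather than by segmented cell polygons; blurring inflates circularity
#' relative to the polygon-based measure, so the two are reported
#' separately.
#'
#' @param mask A [detect_clone_mask()] result or logical matrix.
#' @param pixel_size_um Pixel edge in µm.
#' @param min_area_um2 Components smaller than this are skipped.
#' @return `data.frame(component, area_um2, circularity)`.
#' @export
mask_circularity <- function(mask, pixel_size_um, min_area_um2 = 1) {
  m <- if (inherits(mask, "clone_mask")) mask$mask else mask
  comp <- EBImage::bwlabel(EBImage::Image(t(matrix(as.integer(m),
                                                   nrow(m), ncol(m)))))
  ct <- EBImage::ocontour(comp)
  areas <- tabulate(as.integer(EBImage::imageData(comp)))
  rows <- list()
  for (i in seq_along(ct)) {
    a <- areas[i] * pixel_size_um^2
    if (a < min_area_um2 || nrow(ct[[i]]) < 8) next
    ring <- smooth_ring((ct[[i]] + 0.5) * pixel_size_um, px = pixel_size_um)
    rows[[length(rows) + 1]] <- data.frame(
      component = i, area_um2 = a,
      circularity = min(circularity.default(ring), 1.02))
  }
  if (length(rows) == 0) {
    return(data.frame(component = integer(), area_um2 = numeric(),
                      circularity = numeric()))
  }
  do.call(rbind, rows)
}

# bilinear interpolation of image (rows = y) at continuous pixel
# coordinates (x, y), where pixel (r, c) has center (c - 0.5, r - 0.5)
bilinear_sample <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  cx <- pmin(pmax(x - 0.5, 0), nc - 1)
  cy <- pmin(pmax(y - 0.5, 0), nr - 1)
  c0 <- pmin(floor(cx), nc - 2); r0 <- pmin(floor(cy), nr - 2)
  fx <- cx - c0; fy <- cy - r0
  i00 <- image[cbind(r0 + 1, c0 + 1)]
  i01 <- image[cbind(r0 + 1, c0 + 2)]
  i10 <- image[cbind(r0 + 2, c0 + 1)]
  i11 <- image[cbind(r0 + 2, c0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Intensity profile along a line segment
#'
#' Mean bilinear-interpolated intensity along the segment from `p0` to
#' `p1` (pixel coordinates), averaged over `width_px` perpendicular
#' offsets — the "plot profile" readout used for junction-intensity scans.
#'
#' @param image 2D intensity matrix (rows = y).
#' @param p0,p1 Numeric length-2 segment end points, in pixel units.
#' @param width_px Odd number of perpendicular samples to average.
#' @param step_px Sample spacing along the segment (default 0.5 px).
#' @return `data.frame(distance_px, intensity)`.
#' @export
intensity_profile <- function(image, p0, p1, width_px = 1L, step_px = 0.5) {
  d <- sqrt(sum((p1 - p0)^2))
  if (d <= 0) stop("zero-length segment", call. = FALSE)
  n <- max(2L, floor(d / step_px) + 1L)
  t <- seq(0, 1, length.out = n)
  ux <- (p1[1] - p0[1]) / d; uy <- (p1[2] - p0[2]) / d
  offsets <- seq_len(width_px) - (width_px + 1) / 2
  acc <- 0
  for (o in offsets) {
    x <- p0[1] + t * (p1[1] - p0[1]) - o * uy
    y <- p0[2] + t * (p1[2] - p0[2]) + o * ux
    acc <- acc + bilinear_sample(image, x, y)
  }
  data.frame(distance_px = t * d, intensity = acc / length(offsets))
}

#' Interfacial junction-intensity enrichment ratio
#'
#' Mean junction-channel intensity over heterotypic junction pixels
#' (junctions between cells of different genotype) divided by the same over
#' homotypic junction pixels. Each class's junction line is dilated by
#' `half_width_px` to form its band, and junction pixels falling inside the
#' other class's band are excluded, so signal near triple points where the
#' two junction types meet does not cross-contaminate the two means. A
#' ratio of 1 means no interfacial enrichment.
#'
#' @param tissue A `tissue` with clones.
#' @param junction_image 2D junction-intensity matrix aligned with the
#'   tissue raster.
#' @param half_width_px Dilation half-width of the junction band in pixels.
#' @return Enrichment ratio (dimensionless).
#' @export
interface_enrichment_ratio <- function(tissue, junction_image,
                                       half_width_px = 2L) {
  labels <- if (!is.null(tissue$labels)) tissue$labels else {
    rasterize_tissue(tissue, tissue$field_size_um[2] / nrow(junction_image))
  }
  if (!all(dim(labels) == dim(junction_image))) {
    stop("junction image is not aligned with the tissue raster",
         call. = FALSE)
  }
  nr <- nrow(labels); nc <- ncol(labels)
  geno <- ifelse(is.na(tissue$cells$clone_id), 0L, 1L)
  gl <- matrix(geno[labels], nr, nc)
  het <- matrix(FALSE, nr, nc); hom <- matrix(FALSE, nr, nc)
  mark <- function(band, sel, margin) {
    if (margin == "h") {
      b <- band[, -1]; b[sel] <- TRUE; band[, -1] <- b
      b <- band[, -nc]; b[sel] <- TRUE; band[, -nc] <- b
    } else {
      b <- band[-1, ]; b[sel] <- TRUE; band[-1, ] <- b
      b <- band[-nr, ]; b[sel] <- TRUE; band[-nr, ] <- b
    }
    band
  }
  difh <- labels[, -1] != labels[, -nc]
  heth <- difh & (gl[, -1] != gl[, -nc])
  het <- mark(het, heth, "h"); hom <- mark(hom, difh & !heth, "h")
  difv <- labels[-1, ] != labels[-nr, ]
  hetv <- difv & (gl[-1, ] != gl[-nr, ])
  het <- mark(het, hetv, "v"); hom <- mark(hom, difv & !hetv, "v")
  if (!any(het)) stop("no heterotypic junctions", call. = FALSE)
  het_band <- het; hom_band <- hom
  if (half_width_px > 0) {
    brush <- EBImage::makeBrush(2 * half_width_px + 1, shape = "disc")
    het_band <- t(EBImage::imageData(EBImage::dilate(EBImage::Image(t(het)),
                                                     brush))) > 0
    hom_band <- t(EBImage::imageData(EBImage::dilate(EBImage::Image(t(hom)),
                                                     brush))) > 0
  }
  het_px <- het & !hom_band
  hom_px <- hom & !het_band
  if (!any(het_px) || !any(hom_px)) {
    stop("junction bands fully overlap; decrease half_width_px",
         call. = FALSE)
  }
  mean(junction_image[het_px]) / mean(junction_image[hom_px])
}
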