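# EBImage stores images as (x, y); this package stores matrices as
# (row = y, col = x). These two helpers keep the transposition in one place.
as_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(img) t(EBImage::imageData(img))

get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (!channel %in% names(stack$channels)) {
    stop("no channel named '", channel, "' in stack", call. = FALSE)
  }
  stack$channels[[channel]]
}

#' Maximum-intensity projection
#'
#' Per-pixel maximum over the retained z-slices. Slices containing signal
#' from outside the layer of interest (e.g. a peripodial membrane) can be
#' excluded; a 2D channel projects to itself.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name.
#' @param z_range Integer vector of slice indices to consider
#'   (default: all).
#' @param exclude_slices Slice indices to drop from the projection.
#' @return 2D intensity matrix.
#' @export
max_project <- function(stack, channel, z_range = NULL,
                        exclude_slices = NULL) {
  ch <- get_channel(stack, channel)
  if (length(dim(ch)) == 2) return(ch)
  nz <- dim(ch)[1]
  keep <- if (is.null(z_range)) seq_len(nz) else intersect(z_range, seq_len(nz))
  keep <- setdiff(keep, exclude_slices)
  if (length(keep) == 0) stop("empty slice selection", call. = FALSE)
  out <- ch[keep[1], , ]
  for (z in keep[-1]) out <- pmax(out, ch[z, , ])
  out
}

#' Apical projection (brightest-slice selection)
#'
#' Maximum projection restricted to the `n_slices` z-slices with the
#' highest total intensity in the reference (membrane) channel — a stand-in
#' for surface-following selective-plane projection: in an apically stained
#' epithelium the junction signal concentrates in the apical slices, which
#' are exactly the brightest ones.
#'
#' @param stack An [image_stack()] with 3D channels.
#' @param channel Channel to project.
#' @param n_slices Number of slices to retain (2 to z-depth).
#' @param ref_channel Channel whose intensity selects the slices.
#' @return 2D matrix; `attr(, "slices")` records the selected indices.
#' @export
apical_project <- function(stack, channel, n_slices,
                           ref_channel = "membrane") {
  ch <- get_channel(stack, channel)
  if (length(dim(ch)) == 2) return(ch)
  nz <- dim(ch)[1]
  if (n_slices < 2 || n_slices > nz) {
    stop("n_slices must lie in [2, z-depth]", call. = FALSE)
  }
  ref <- get_channel(stack, ref_channel)
  totals <- vapply(seq_len(nz), function(z) sum(ref[z, , ]), numeric(1))
  keep <- sort(order(totals, decreasing = TRUE)[seq_len(n_slices)])
  out <- max_project(stack, channel, z_range = keep)
  attr(out, "slices") <- keep
  out
}

#' Detect a clone mask by blur-and-threshold
#'
#' Gaussian blur at `blur_sigma_px` followed by intensity thresholding.
#' `mode = "gain"` keeps pixels above the threshold (marker expressed in
#' clones, default sigma 2.0); `mode = "loss"` keeps pixels below it
#' (clones identified by loss of staining, default sigma 3.5).
#'
#' @param image 2D intensity matrix.
#' @param mode `"gain"` or `"loss"`.
#' @param blur_sigma_px Blur sigma in pixels; defaults to 2.0 (gain) or
#'   3.5 (loss); 0 disables blurring.
#' @param threshold_method `"otsu"` or a fixed numeric threshold on the
#'   image intensity scale.
#' @return A `clone_mask`: logical matrix plus detection metadata.
#' @export
detect_clone_mask <- function(image, mode = c("gain", "loss"),
                              blur_sigma_px = NULL,
                              threshold_method = "otsu") {
  mode <- match.arg(mode)
  if (is.null(blur_sigma_px)) {
    blur_sigma_px <- if (mode == "gain") 2.0 else 3.5
  }
  if (blur_sigma_px < 0) stop("blur sigma must be >= 0", call. = FALSE)
  if (identical(threshold_method, "otsu") &&
      diff(range(image)) < .Machine$double.eps) {
    stop("no signal: constant image with automatic threshold", call. = FALSE)
  }
  blurred <- if (blur_sigma_px > 0) {
    from_ebi(EBImage::gblur(as_ebi(image), sigma = blur_sigma_px))
  } else image
  if (identical(threshold_method, "otsu")) {
    rng <- range(blurred)
    if (diff(rng) < .Machine$double.eps) {
      stop("no signal: constant image with automatic threshold",
           call. = FALSE)
    }
    scaled <- (blurred - rng[1]) / diff(rng)
    thr <- EBImage::otsu(as_ebi(scaled), range = c(0, 1)) * diff(rng) + rng[1]
  } else if (is.numeric(threshold_method)) {
    thr <- threshold_method
    threshold_method <- "fixed"
  } else {
    stop("threshold_method must be 'otsu' or a numeric value", call. = FALSE)
  }
  mask <- if (mode == "gain") blurred > thr else blurred < thr
  structure(list(mask = mask, detection_mode = mode,
                 blur_sigma_px = blur_sigma_px,
                 threshold_method = threshold_method,
                 threshold_value = as.numeric(thr)),
            class = "clone_mask")
}

#' @export
print.clone_mask <- function(x, ...) {
  cat(sprintf(
    "<clone_mask> %s mode, sigma %.1f px, %s threshold %.4g, %.1f%% positive\n",
    x$detection_mode, x$blur_sigma_px, x$threshold_method,
    x$threshold_value, 100 * mean(x$mask)))
  invisible(x)
}

#' Segment cells from a membrane channel
#'
#' Seeded watershed on the blurred membrane image: cell interiors are the
#' sub-threshold (dark) regions, seeds are the maxima of their distance
#' transform, and the watershed partition is propagated across the membrane
#' ridge so every pixel is assigned to a cell. Regions smaller than
#' `min_cell_area_um2` are merged into the neighbor with the longest shared
#' contact. Cell polygons are traced from the label image and lightly
#' smoothed; adjacency (with shared-junction lengths) comes from
#' neighboring pixel-pair counts.
#'
#' @param membrane 2D membrane-channel matrix (bright junctions on dark
#'   interiors).
#' @param pixel_size_um Pixel edge in µm.
#' @param min_cell_area_um2 Minimum region area; smaller regions merged.
#' @param blur_sigma_px Pre-watershed blur sigma (pixels).
#' @param watershed_tolerance Minimum distance-map depth separating two
#'   seeds (pixels).
#' @return A `tissue` with provenance `"segmented"` and a `labels` raster.
#' @export
segment_cells <- function(membrane, pixel_size_um, min_cell_area_um2 = 1,
                          blur_sigma_px = 0.5, watershed_tolerance = 1) {
  img <- as_ebi(membrane / max(membrane))
  blurred <- if (blur_sigma_px > 0) {
    EBImage::gblur(img, sigma = blur_sigma_px)
  } else img
  thr <- EBImage::otsu(blurred, range = range(blurred))
  interior <- blurred < thr
  dm <- EBImage::distmap(interior)
  ws <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  if (max(ws) == 0) {
    stop("segmentation failure: no watershed seeds found", call. = FALSE)
  }
  full <- EBImage::propagate(dm, seeds = ws)
  labels <- from_ebi(full)
  storage.mode(labels) <- "integer"
  labels <- merge_small_regions(labels, pixel_size_um, min_cell_area_um2)
  tissue_from_labels(labels, pixel_size_um)
}

# merge regions below the area threshold into the neighbor sharing the
# longest pixel contact
merge_small_regions <- function(labels, px, min_area_um2) {
  repeat {
    tab <- tabulate(labels)
    small <- which(tab > 0 & tab * px^2 < min_area_um2)
    if (length(small) == 0) break
    pairs <- label_pair_counts(labels)
    merged_any <- FALSE
    for (s in small) {
      cand <- pairs[pairs$a == s | pairs$b == s, , drop = FALSE]
      if (nrow(cand) == 0) next
      other <- ifelse(cand$a == s, cand$b, cand$a)
      target <- other[which.max(cand$n)]
      labels[labels == s] <- target
      merged_any <- TRUE
    }
    if (!merged_any) break
  }
  # relabel sequentially
  u <- sort(unique(as.vector(labels)))
  u <- u[u > 0]
  remap <- integer(max(u))
  remap[u] <- seq_along(u)
  labels[labels > 0] <- remap[labels[labels > 0]]
  labels
}

# counts of adjacent (4-neighborhood) pixel pairs between different labels
label_pair_counts <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  a <- c(labels[, -nc], labels[-nr, ])
  b <- c(labels[, -1], labels[-1, ])
  dif <- a != b & a > 0 & b > 0
  if (!any(dif)) return(data.frame(a = integer(), b = integer(),
                                   n = integer()))
  lo <- pmin(a[dif], b[dif]); hi <- pmax(a[dif], b[dif])
  key <- paste(lo, hi)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  data.frame(a = as.integer(vapply(parts, `[`, "", 1)),
             b = as.integer(vapply(parts, `[`, "", 2)),
             n = as.integer(tab))
}

# build a segmented tissue object from a label raster
tissue_from_labels <- function(labels, px) {
  n <- max(labels)
  tab <- tabulate(labels, nbins = n)
  # centroids from pixel coordinates
  nr <- nrow(labels); nc <- ncol(labels)
  rr <- rep(seq_len(nr), nc); cc <- rep(seq_len(nc), each = nr)
  cx <- vapply(split((cc - 0.5) * px, labels), mean, numeric(1))
  cy <- vapply(split((rr - 0.5) * px, labels), mean, numeric(1))
  border_labs <- unique(c(labels[1, ], labels[nr, ], labels[, 1],
                          labels[, nc]))
  ct <- EBImage::ocontour(EBImage::Image(t(labels)))
  polygons <- lapply(seq_len(n), function(i) {
    ring <- (ct[[i]] + 0.5) * px
    smooth_ring(ring, px = px)
  })
  pairs <- label_pair_counts(labels)
  adj <- data.frame(a = pairs$a, b = pairs$b, length_um = pairs$n * px)
  cells <- data.frame(cell_id = seq_len(n), genotype = "wt",
                      clone_id = NA_integer_,
                      area_um2 = tab * px^2,
                      cx = as.numeric(cx[as.character(seq_len(n))]),
                      cy = as.numeric(cy[as.character(seq_len(n))]),
                      on_border = seq_len(n) %in% border_labs,
                      stringsAsFactors = FALSE)
  structure(list(cells = cells, polygons = polygons, edge_nb = NULL,
                 adjacency = adj, seeds = NULL, weights = NULL,
                 field_size_um = c(nc * px, nr * px),
                 pixel_size_um = px, provenance = "segmented",
                 labels = labels),
            class = "tissue")
}

#' Assign clone labels to cells from a clone mask
#'
#' A cell is clonal iff the mask covers at least `min_overlap_frac` of its
#' pixel area; distinct connected components of the mask become distinct
#' clone labels.
#'
#' @param tissue A `tissue` (ground truth or segmented).
#' @param mask A [detect_clone_mask()] result or logical matrix in the same
#'   coordinate frame as the tissue raster.
#' @param min_overlap_frac Minimum covered area fraction (default 0.5).
#' @return The tissue with `clone_id` and `genotype` updated.
#' @export
assign_clone_labels <- function(tissue, mask, min_overlap_frac = 0.5) {
  m <- if (inherits(mask, "clone_mask")) mask$mask else mask
  labels <- if (!is.null(tissue$labels)) tissue$labels else {
    rasterize_tissue(tissue)
  }
  if (!all(dim(labels) == dim(m))) {
    stop("mask and tissue raster frames do not match", call. = FALSE)
  }
  comp <- from_ebi(EBImage::bwlabel(as_ebi(matrix(as.integer(m),
                                                  nrow(m), ncol(m)))))
  n <- nrow(tissue$cells)
  covered <- vapply(split(as.vector(m), as.vector(labels)), mean, numeric(1))
  cov_vec <- rep(0, n)
  cov_vec[as.integer(names(covered))] <- covered
  clone_of <- rep(NA_integer_, n)
  clonal <- which(cov_vec >= min_overlap_frac & seq_len(n) > 0)
  for (i in clonal) {
    comps <- comp[labels == i & m]
    if (length(comps) == 0) next
    clone_of[i] <- as.integer(names(which.max(table(comps))))
  }
  tissue$cells$clone_id <- clone_of
  tissue$cells$genotype <- ifelse(is.na(clone_of), "wt", "mut")
  tissue
}
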