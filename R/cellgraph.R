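#' Extract clone objects from a labeled tissue
#'
#' Connected components of clonal cells on the adjacency graph (cells with
#' the same `clone_id` that are joined by positive-length junctions).
#' Components smaller than `min_cells` are retained but flagged
#' `sub_threshold`, matching the convention of only analysing clones of at
#' least `min_cells` cells for shape statistics while keeping fragments
#' available for the fragment filter and area-recovery readouts.
#'
#' For ground-truth tissues the boundary is chained exactly from the
#' per-edge neighbor labels (exterior ring plus any enclosed-islet holes);
#' for segmented tissues it is traced from the clone's pixel mask and
#' lightly smoothed to suppress pixel staircasing.
#'
#' @param tissue A `tissue` with clone labels.
#' @param min_cells Size threshold for shape statistics (default 10).
#' @return List of `clone` objects: `clone_id`, `source_label`, `cell_ids`,
#'   `n_cells`, `boundary` (exterior polygon, µm), `holes`, `area_um2`
#'   (sum of member-cell areas), `perimeter_um` (exterior boundary),
#'   `touches_border`, `sub_threshold`.
#' @export
extract_clones <- function(tissue, min_cells = 10L) {
  lab <- tissue$cells$clone_id
  clones <- list()
  if (!any(!is.na(lab))) return(clones)
  adj <- tissue$adjacency
  for (src in sort(unique(lab[!is.na(lab)]))) {
    members_all <- tissue$cells$cell_id[!is.na(lab) & lab == src]
    sub <- adj[adj$a %in% members_all & adj$b %in% members_all, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      sub[, c("a", "b")], directed = FALSE,
      vertices = data.frame(name = members_all))
    comp <- igraph::components(g)$membership
    for (cc in sort(unique(comp))) {
      members <- members_all[comp[as.character(members_all)] == cc]
      clones[[length(clones) + 1]] <-
        new_clone(tissue, members, source_label = src, min_cells = min_cells)
    }
  }
  for (i in seq_along(clones)) clones[[i]]$clone_id <- i
  clones
}

new_clone <- function(tissue, members, source_label, min_cells) {
  if (!is.null(tissue$edge_nb)) {
    rings <- exterior_ring(chain_rings(tissue, members))
    boundary <- rings$exterior
    holes <- rings$holes
  } else {
    rings <- mask_boundary(tissue, members)
    boundary <- rings$exterior
    holes <- rings$holes
  }
  structure(list(
    clone_id = NA_integer_,
    source_label = source_label,
    cell_ids = members,
    n_cells = length(members),
    boundary = boundary,
    holes = holes,
    area_um2 = sum(tissue$cells$area_um2[members]),
    perimeter_um = if (is.null(boundary)) NA_real_ else {
      polygon_perimeter(boundary)
    },
    touches_border = any(tissue$cells$on_border[members]),
    sub_threshold = length(members) < min_cells), class = "clone")
}

#' @export
print.clone <- function(x, ...) {
  cat(sprintf(
    "<clone %s> %d cells, area %.2f um2, perimeter %.2f um%s%s\n",
    x$clone_id, x$n_cells, x$area_um2, x$perimeter_um,
    if (x$touches_border) ", touches border" else "",
    if (x$sub_threshold) ", sub-threshold" else ""))
  invisible(x)
}

# Boundary of a clone in a segmented tissue, traced from its pixel mask.
# The traced contour is smoothed with a short circular moving average so the
# perimeter is not inflated by pixel staircasing.
mask_boundary <- function(tissue, members, smooth_window = NULL) {
  if (is.null(tissue$labels)) {
    stop("segmented tissue lacks a label image; cannot trace clone boundary",
         call. = FALSE)
  }
  px <- tissue$pixel_size_um
  mask <- matrix(0L, nrow(tissue$labels), ncol(tissue$labels))
  mask[matrix(tissue$labels %in% members, nrow(mask))] <- 1L
  comp <- EBImage::bwlabel(EBImage::Image(t(mask)))
  ct <- EBImage::ocontour(comp)
  if (length(ct) == 0) return(list(exterior = NULL, holes = list()))
  rings <- lapply(ct, function(xy) (xy + 0.5) * px)  # 0-based px -> um
  rings <- lapply(rings, smooth_ring, window = smooth_window, px = px)
  exterior_ring(rings)
}

smooth_ring <- function(ring, window = NULL, px) {
  if (is.null(window)) window <- max(3L, round(0.4 / px))
  m <- nrow(ring)
  if (m < window + 2) return(ring)
  half <- window %/% 2
  idx <- outer(seq_len(m), -half:half, function(i, o) ((i + o - 1) %% m) + 1)
  cbind(rowMeans(matrix(ring[idx, 1], m)),
        rowMeans(matrix(ring[idx, 2], m)))
}

#' Frontline cells of a clone
#'
#' Clonal cells sharing at least one positive-length junction with a
#' wild-type (non-clonal) cell, with the number of distinct wild-type
#' contacts per frontline cell.
#'
#' @param clone A `clone`.
#' @param tissue The tissue it was extracted from.
#' @return `data.frame(cell_id, n_wt_contacts)`, one row per frontline cell.
#' @export
frontline <- function(clone, tissue) {
  adj <- tissue$adjacency
  wt <- is.na(tissue$cells$clone_id)
  in_clone_a <- adj$a %in% clone$cell_ids
  in_clone_b <- adj$b %in% clone$cell_ids
  het <- rbind(
    data.frame(member = adj$a[in_clone_a & wt[adj$b]],
               other = adj$b[in_clone_a & wt[adj$b]]),
    data.frame(member = adj$b[in_clone_b & wt[adj$a]],
               other = adj$a[in_clone_b & wt[adj$a]]))
  if (nrow(het) == 0) {
    return(data.frame(cell_id = integer(), n_wt_contacts = integer()))
  }
  counts <- aggregate(other ~ member, data = het,
                      FUN = function(v) length(unique(v)))
  data.frame(cell_id = counts$member, n_wt_contacts = counts$other)
}

#' Wild-type neighborhood ring of a clone
#'
#' All non-clonal, non-border cells within graph distance `k` of any clone
#' cell on the adjacency graph — the "surrounding bulk" against which
#' clonal apical areas are compared.
#'
#' @param clone A `clone`.
#' @param tissue The tissue it was extracted from.
#' @param k Maximum graph distance (default 2).
#' @return A `neighborhood`: list with `clone_id` and
#'   `ring` = `data.frame(cell_id, graph_distance)`.
#' @export
neighborhood <- function(clone, tissue, k = 2L) {
  stopifnot(k >= 1)
  nbl <- neighbor_list(tissue)
  clonal_any <- !is.na(tissue$cells$clone_id)
  seen <- rep(FALSE, nrow(tissue$cells))
  seen[clone$cell_ids] <- TRUE
  frontier <- clone$cell_ids
  rows <- list()
  for (d in seq_len(k)) {
    nxt <- setdiff(unique(unlist(nbl[frontier])), which(seen))
    if (length(nxt) == 0) break
    seen[nxt] <- TRUE
    keep <- nxt[!clonal_any[nxt] & !tissue$cells$on_border[nxt]]
    if (length(keep)) {
      rows[[d]] <- data.frame(cell_id = keep, graph_distance = d)
    }
    frontier <- nxt
  }
  ring <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(cell_id = integer(), graph_distance = integer())
  }
  structure(list(clone_id = clone$clone_id, ring = ring),
            class = "neighborhood")
}
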