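# Boundary chaining on the shared-vertex structure of a ground-truth tiling.
#
# Adjacent power-diagram cells are clipped against the same radical axes, so
# shared vertices agree to ~1e-12 um; rounding coordinates to 1e-6 um gives a
# stable shared-vertex key.

vkey <- function(x, y) sprintf("%.6f_%.6f", round(x, 6), round(y, 6))

# Cluster coordinate values closer than `tol` to their group mean so that a
# vertex shared by adjacent polygons becomes bit-identical in all of them
# (clipping computes it independently per cell, to ~1e-12 um).
snap_axis <- function(v, tol) {
  u <- sort(unique(v))
  if (length(u) > 1) {
    grp <- cumsum(c(TRUE, diff(u) > tol))
    canon <- vapply(split(u, grp), mean, numeric(1))
    u_to <- canon[grp]
    v <- u_to[match(v, u)]
  }
  v
}

snap_shared_vertices <- function(polygons, tol) {
  nv <- vapply(polygons, nrow, integer(1))
  allv <- do.call(rbind, polygons)
  allv[, 1] <- snap_axis(allv[, 1], tol)
  allv[, 2] <- snap_axis(allv[, 2], tol)
  split_idx <- rep(seq_along(polygons), nv)
  lapply(seq_along(polygons), function(i) {
    allv[split_idx == i, , drop = FALSE]
  })
}

# Directed boundary edges of a cell set: edges whose neighbor is outside the
# set (field border counts as outside). Returns closed rings of vertex
# coordinates, ordered; ring orientation follows the member polygons.
chain_rings <- function(tissue, cell_ids) {
  cell_set <- rep(FALSE, nrow(tissue$cells))
  cell_set[cell_ids] <- TRUE
  from <- character(0); to <- character(0)
  fx <- numeric(0); fy <- numeric(0)
  for (i in cell_ids) {
    poly <- tissue$polygons[[i]]
    nb <- tissue$edge_nb[[i]]
    outside <- nb == 0L | !cell_set[pmax(nb, 1L)]
    if (!any(outside)) next
    k <- which(outside)
    k2 <- k %% nrow(poly) + 1L
    from <- c(from, vkey(poly[k, 1], poly[k, 2]))
    to <- c(to, vkey(poly[k2, 1], poly[k2, 2]))
    fx <- c(fx, poly[k, 1]); fy <- c(fy, poly[k, 2])
  }
  if (length(from) == 0) return(list())
  nxt <- split(seq_along(from), from)
  used <- rep(FALSE, length(from))
  rings <- list()
  for (e0 in seq_along(from)) {
    if (used[e0]) next
    idx <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      idx <- c(idx, e)
      cand <- nxt[[to[e]]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      e <- cand[1]
    }
    # closed ring iff the last edge returns to the start vertex
    if (to[idx[length(idx)]] == from[idx[1]] && length(idx) >= 3) {
      rings[[length(rings) + 1]] <- cbind(fx[idx], fy[idx])
    }
  }
  rings
}

# Exterior ring = largest enclosed area; the rest are holes (enclosed islets).
exterior_ring <- function(rings) {
  if (length(rings) == 0) return(NULL)
  areas <- vapply(rings, function(r) abs(polygon_area_signed(r)), numeric(1))
  list(exterior = rings[[which.max(areas)]],
       holes = rings[areas < max(areas)])
}

# Laplacian smoothing of the exterior boundary ring of each clone. Shared
# vertices are moved consistently in every polygon that references them, so
# the tissue remains a tiling; vertices on the field border are pinned.
# Moves that would flip a polygon's orientation or shrink it below
# `min_area_frac` of its pre-smoothing area are frozen for that iteration,
# which keeps all cells simple under strong smoothing.
smooth_clone_boundaries <- function(tissue, iters, lambda = 0.3,
                                    min_area_frac = 0.25) {
  if (iters <= 0) return(tissue)
  W <- tissue$field_size_um[1]; H <- tissue$field_size_um[2]
  tol <- 1e-9 * max(W, H)
  clone_ids <- sort(unique(tissue$cells$clone_id[!is.na(tissue$cells$clone_id)]))
  rings <- list()
  for (cid in clone_ids) {
    members <- tissue$cells$cell_id[!is.na(tissue$cells$clone_id) &
                                      tissue$cells$clone_id == cid]
    ext <- exterior_ring(chain_rings(tissue, members))
    if (is.null(ext) || nrow(ext$exterior) < 4) next
    r <- ext$exterior
    rings[[length(rings) + 1]] <- list(
      keys = vkey(r[, 1], r[, 2]),
      pinned = r[, 1] < tol | r[, 1] > W - tol |
        r[, 2] < tol | r[, 2] > H - tol)
  }
  if (length(rings) == 0) return(tissue)
  ring_keys <- unique(unlist(lapply(rings, `[[`, "keys")))

  polys <- tissue$polygons
  pkeys <- lapply(polys, function(p) vkey(p[, 1], p[, 2]))  # stable identity
  pos <- new.env(parent = emptyenv())   # key -> current coordinates
  inc <- list()                         # key -> (polygon, row) incidences
  affected <- integer(0)
  for (i in seq_along(polys)) {
    hit <- which(pkeys[[i]] %in% ring_keys)
    if (length(hit) == 0) next
    affected <- c(affected, i)
    for (h in hit) {
      k <- pkeys[[i]][h]
      inc[[k]] <- rbind(inc[[k]], c(i, h))
      assign(k, polys[[i]][h, ], envir = pos)
    }
  }
  A0 <- vapply(affected, function(i) polygon_area_signed(polys[[i]]),
               numeric(1))

  for (it in seq_len(iters)) {
    prop <- new.env(parent = emptyenv())
    for (rg in rings) {
      m <- length(rg$keys)
      P <- t(vapply(rg$keys, function(k) get(k, envir = pos), numeric(2)))
      prv <- P[c(m, seq_len(m - 1)), , drop = FALSE]
      nxt <- P[c(seq_len(m - 1) + 1, 1), , drop = FALSE]
      Tm <- P + lambda * ((prv + nxt) / 2 - P)
      for (q in seq_len(m)) {
        if (!rg$pinned[q]) assign(rg$keys[q], Tm[q, ], envir = prop)
      }
    }
    frozen <- character(0)
    newpolys <- polys
    repeat {
      newpolys <- polys
      movers <- setdiff(ls(prop), frozen)
      for (k in movers) {
        ij <- inc[[k]]
        if (is.null(ij)) next
        for (r2 in seq_len(nrow(ij))) {
          newpolys[[ij[r2, 1]]][ij[r2, 2], ] <- get(k, envir = prop)
        }
      }
      A1 <- vapply(affected, function(i) polygon_area_signed(newpolys[[i]]),
                   numeric(1))
      bad <- sign(A1) != sign(A0) | abs(A1) < min_area_frac * abs(A0)
      if (!any(bad)) break
      badkeys <- unique(unlist(lapply(affected[bad], function(i) {
        k <- pkeys[[i]]
        k[k %in% movers]
      })))
      if (length(badkeys) == 0) break
      frozen <- c(frozen, badkeys)
    }
    polys <- newpolys
    for (k in setdiff(ls(prop), frozen)) {
      assign(k, get(k, envir = prop), envir = pos)
    }
  }
  tissue$polygons <- polys
  refresh_tissue_geometry(tissue)
}

# Recompute per-cell areas/centroids and junction lengths after vertex moves.
refresh_tissue_geometry <- function(tissue) {
  tissue$cells$area_um2 <- vapply(tissue$polygons, polygon_area, numeric(1))
  cents <- t(vapply(tissue$polygons, polygon_centroid, numeric(2)))
  tissue$cells$cx <- cents[, 1]
  tissue$cells$cy <- cents[, 2]
  tissue$adjacency <- adjacency_from_edges(tissue)
  tissue
}
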