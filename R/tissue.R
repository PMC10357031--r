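#' Specify a synthetic epithelium
#'
#' Parameters of the ground-truth tissue generator. The generated epithelium
#' is a centroidal Voronoi tessellation: `n_cells` seed points in a
#' rectangular field, relaxed by `lloyd_iterations` rounds of Lloyd's
#' algorithm (seeds moved to cell centroids), which regularizes cell areas
#' the way packed apical surfaces look in imaginal-disc epithelia.
#'
#' @param n_cells Number of cells (>= 4).
#' @param field_size_um Numeric length-2, field width and height in µm.
#' @param lloyd_iterations Non-negative integer; centroidal relaxation rounds.
#' @param rng_seed Integer seed; the generator is deterministic given it.
#' @param pixel_size_um Pixel edge in µm used when rasterizing this tissue.
#' @return A `tissue_spec` object (list).
#' @export
tissue_spec <- function(n_cells = 400, field_size_um = c(60, 60),
                        lloyd_iterations = 3, rng_seed = 1L,
                        pixel_size_um = 0.1) {
  stopifnot(length(field_size_um) == 2)
  if (!is.numeric(n_cells) || n_cells < 4) {
    stop("invalid tissue spec: n_cells must be >= 4", call. = FALSE)
  }
  if (any(field_size_um <= 0)) {
    stop("invalid tissue spec: field_size_um components must be > 0",
         call. = FALSE)
  }
  if (pixel_size_um <= 0) {
    stop("invalid tissue spec: pixel_size_um must be > 0", call. = FALSE)
  }
  if (lloyd_iterations < 0) {
    stop("invalid tissue spec: lloyd_iterations must be >= 0", call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells),
                 field_size_um = as.numeric(field_size_um),
                 lloyd_iterations = as.integer(lloyd_iterations),
                 rng_seed = as.integer(rng_seed),
                 pixel_size_um = pixel_size_um),
            class = "tissue_spec")
}

# Assemble a tissue object from the power-diagram output.
build_tissue <- function(seeds, weights, field_size_um, pixel_size_um,
                         provenance = "ground_truth") {
  pd <- .power_diagram_cpp(seeds, weights, field_size_um[1], field_size_um[2])
  empty <- vapply(pd, is.null, logical(1))
  if (any(empty)) {
    stop("degenerate tessellation: ", sum(empty), " empty power cell(s)",
         call. = FALSE)
  }
  polygons <- snap_shared_vertices(lapply(pd, `[[`, "poly"),
                                   tol = 1e-6 * max(field_size_um))
  edge_nb <- lapply(pd, `[[`, "nb")
  n <- length(polygons)
  areas <- vapply(polygons, polygon_area, numeric(1))
  cents <- t(vapply(polygons, polygon_centroid, numeric(2)))
  on_border <- vapply(edge_nb, function(nb) any(nb == 0L), logical(1))
  cells <- data.frame(cell_id = seq_len(n),
                      genotype = "wt",
                      clone_id = NA_integer_,
                      area_um2 = areas,
                      cx = cents[, 1], cy = cents[, 2],
                      on_border = on_border,
                      stringsAsFactors = FALSE)
  tis <- structure(list(cells = cells,
                        polygons = polygons,
                        edge_nb = edge_nb,
                        adjacency = NULL,
                        seeds = seeds,
                        weights = weights,
                        field_size_um = as.numeric(field_size_um),
                        pixel_size_um = pixel_size_um,
                        provenance = provenance),
                   class = "tissue")
  tis$adjacency <- adjacency_from_edges(tis)
  tis
}

# Adjacency (cell pairs + shared-junction lengths in µm) from the per-edge
# neighbor labels. Zero-length contacts (four-way vertex artifacts) dropped.
adjacency_from_edges <- function(tissue, tol = 1e-8) {
  rows <- vector("list", length(tissue$polygons))
  for (i in seq_along(tissue$polygons)) {
    poly <- tissue$polygons[[i]]
    nb <- tissue$edge_nb[[i]]
    keep <- nb > i  # each unordered pair once, from the smaller id
    if (!any(keep)) next
    k <- which(keep)
    k2 <- k %% nrow(poly) + 1L
    len <- sqrt((poly[k2, 1] - poly[k, 1])^2 + (poly[k2, 2] - poly[k, 2])^2)
    rows[[i]] <- data.frame(a = i, b = nb[k], length_um = len)
  }
  adj <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(adj)) {
    return(data.frame(a = integer(), b = integer(), length_um = numeric()))
  }
  # a cell pair can share several collinear-split segments; pool them
  adj <- stats::aggregate(length_um ~ a + b, data = adj, FUN = sum)
  adj <- adj[adj$length_um > tol, , drop = FALSE]
  adj[order(adj$a, adj$b), , drop = FALSE]
}

#' Generate a ground-truth epithelium
#'
#' Draws `n_cells` uniform seed points in the field, applies
#' `lloyd_iterations` rounds of centroidal (Lloyd) relaxation, and returns
#' the bounded Voronoi tessellation as a `tissue`: cell polygons in µm,
#' genotype labels, and the cell-adjacency graph with shared-junction
#' lengths.
#'
#' @param spec A [tissue_spec()].
#' @return A `tissue` object with provenance `"ground_truth"`.
#' @export
generate_epithelium <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  seeds <- with_seed(spec$rng_seed, {
    cbind(stats::runif(spec$n_cells, 0, spec$field_size_um[1]),
          stats::runif(spec$n_cells, 0, spec$field_size_um[2]))
  })
  w <- rep(0, spec$n_cells)
  for (it in seq_len(spec$lloyd_iterations)) {
    tis <- build_tissue(seeds, w, spec$field_size_um, spec$pixel_size_um)
    seeds <- cbind(tis$cells$cx, tis$cells$cy)
  }
  tis <- build_tissue(seeds, w, spec$field_size_um, spec$pixel_size_um)
  tis$spec <- spec
  tis
}

#' Build a tissue from explicit seed points
#'
#' Bounded power diagram of user-supplied seeds, e.g. a triangular lattice
#' (whose Voronoi diagram is the regular hexagonal tiling) for analytic
#' fixtures.
#'
#' @param seeds Two-column matrix of seed coordinates in µm.
#' @param field_size_um Numeric length-2 field size in µm.
#' @param weights Power-diagram weights (µm²), default all zero (= Voronoi).
#' @param pixel_size_um Pixel edge in µm for rasterization.
#' @return A `tissue` object.
#' @export
tissue_from_seeds <- function(seeds, field_size_um, weights = NULL,
                              pixel_size_um = 0.1) {
  seeds <- as.matrix(seeds)
  if (is.null(weights)) weights <- rep(0, nrow(seeds))
  build_tissue(seeds, weights, field_size_um, pixel_size_um)
}

#' Regular hexagonal-lattice tissue
#'
#' Voronoi diagram of a triangular point lattice: every interior cell is a
#' regular hexagon with the given side length. Used as an analytic fixture
#' for graph metrics (a hexagon of side s has area (3*sqrt(3)/2) s² and
#' perimeter 6 s).
#'
#' @param rows,cols Lattice extent in cells.
#' @param side_um Hexagon side length in µm.
#' @param pixel_size_um Pixel edge in µm.
#' @return A `tissue`; `attr(, "lattice")` holds the (row, col) of each cell.
#' @export
hex_lattice_tissue <- function(rows = 9, cols = 9, side_um = 1,
                               pixel_size_um = 0.1) {
  s <- side_um
  dx <- sqrt(3) * s     # horizontal center spacing
  dy <- 1.5 * s         # vertical center spacing
  ij <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  x <- (ij$col - 0.5) * dx + ifelse(ij$row %% 2 == 0, dx / 2, 0)
  y <- (ij$row - 0.5) * dy + s / 4
  field <- c((cols + 1) * dx, rows * dy + s)
  tis <- tissue_from_seeds(cbind(x, y), field, pixel_size_um = pixel_size_um)
  attr(tis, "lattice") <- ij
  tis
}

#' @export
print.tissue <- function(x, ...) {
  nc <- sum(!is.na(x$cells$clone_id))
  cat(sprintf(
    "<tissue> %d cells (%d clonal), field %.1f x %.1f um, provenance: %s\n",
    nrow(x$cells), nc, x$field_size_um[1], x$field_size_um[2], x$provenance))
  invisible(x)
}

#' Rasterize a ground-truth tissue into a label image
#'
#' @param tissue A `tissue`.
#' @param pixel_size_um Pixel edge in µm; defaults to the tissue's.
#' @return Integer matrix (rows = y) of cell ids; pixel (r, c) has its
#'   center at ((c - 0.5) px, (r - 0.5) px).
#' @export
rasterize_tissue <- function(tissue, pixel_size_um = tissue$pixel_size_um) {
  if (!is.null(tissue$labels) &&
      identical(pixel_size_um, tissue$pixel_size_um)) {
    return(tissue$labels)
  }
  nr <- round(tissue$field_size_um[2] / pixel_size_um)
  nc <- round(tissue$field_size_um[1] / pixel_size_um)
  .rasterize_labels_cpp(tissue$polygons, tissue$cells$cell_id, nr, nc,
                        pixel_size_um)
}
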