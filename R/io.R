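#' Write an image stack as a multi-channel TIFF
#'
#' Channels are written as 32-bit float TIFF directories in list order
#' (channels-first); channel names go into a `<path>.channels.txt` sidecar
#' so [read_image_stack()] can restore them.
#'
#' @param stack An [image_stack()] with 2D channels.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(dim(stack$channels[[1]])) != 2) {
    stop("write_image_stack handles 2D channels", call. = FALSE)
  }
  # TIFF stores [0, 1]; rescale and keep the factor in the sidecar
  scale <- max(1, vapply(stack$channels, max, numeric(1)))
  tiff::writeTIFF(lapply(stack$channels, function(ch) ch / scale), path,
                  bits.per.sample = 32L, reduce = FALSE)
  writeLines(c(names(stack$channels), sprintf("%.17g", stack$pixel_size_um),
               sprintf("%.17g", scale)),
             paste0(path, ".channels.txt"))
  invisible(path)
}

#' Read a multi-channel TIFF written by [write_image_stack()]
#'
#' @param path TIFF path.
#' @param channel_names Optional channel names; defaults to the sidecar file
#'   or `ch1`, `ch2`, ...
#' @param pixel_size_um Pixel size override; defaults to the sidecar value.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, channel_names = NULL,
                             pixel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".channels.txt")
  if (file.exists(sidecar)) {
    lines <- readLines(sidecar)
    if (is.null(channel_names)) channel_names <- lines[seq_along(pages)]
    if (is.null(pixel_size_um)) {
      pixel_size_um <- as.numeric(lines[length(pages) + 1])
    }
    if (length(lines) >= length(pages) + 2) {
      scale <- as.numeric(lines[length(pages) + 2])
      if (is.finite(scale) && scale != 1) {
        pages <- lapply(pages, function(p) p * scale)
      }
    }
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_along(pages))
  }
  if (is.null(pixel_size_um) || is.na(pixel_size_um)) pixel_size_um <- 1
  names(pages) <- channel_names
  image_stack(pages, pixel_size_um)
}

#' Write a 16-bit label TIFF
#'
#' @param labels Integer matrix of labels (0..65535).
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  if (max(labels) > 65535L) stop("labels exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label TIFF written by [write_labels()]
#' @param path TIFF path.
#' @return Integer matrix.
#' @export
read_labels <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write tissue geometry as JSON
#'
#' Cells (id, genotype, clone id, polygon vertices in µm), the adjacency
#' edge list with shared-junction lengths, and per-edge neighbor labels, so
#' a read round-trip reconstructs the full ground-truth structure.
#'
#' @param tissue A `tissue`.
#' @param path Output JSON path.
#' @export
write_tissue_json <- function(tissue, path) {
  obj <- list(
    field_size_um = tissue$field_size_um,
    pixel_size_um = tissue$pixel_size_um,
    provenance = tissue$provenance,
    cells = lapply(seq_len(nrow(tissue$cells)), function(i) {
      out <- list(id = tissue$cells$cell_id[i],
                  genotype = tissue$cells$genotype[i],
                  clone_id = tissue$cells$clone_id[i],
                  polygon = unname(tissue$polygons[[i]]))
      if (!is.null(tissue$edge_nb)) {
        out$edge_neighbors <- as.integer(tissue$edge_nb[[i]])
      }
      out
    }),
    adjacency = unname(as.list(as.data.frame(t(as.matrix(tissue$adjacency)))))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' Read tissue geometry written by [write_tissue_json()]
#' @param path JSON path.
#' @return A `tissue`.
#' @export
read_tissue_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  polygons <- lapply(obj$cells, function(cl) {
    p <- cl$polygon
    if (is.list(p)) p <- do.call(rbind, p)
    matrix(as.numeric(p), ncol = 2)
  })
  edge_nb <- lapply(obj$cells, function(cl) as.integer(cl$edge_neighbors))
  if (all(vapply(edge_nb, length, integer(1)) == 0)) edge_nb <- NULL
  n <- length(polygons)
  areas <- vapply(polygons, polygon_area, numeric(1))
  cents <- t(vapply(polygons, polygon_centroid, numeric(2)))
  cells <- data.frame(
    cell_id = vapply(obj$cells, function(cl) as.integer(cl$id), integer(1)),
    genotype = vapply(obj$cells, function(cl) as.character(cl$genotype),
                      character(1)),
    clone_id = vapply(obj$cells, function(cl) {
      if (is.null(cl$clone_id)) NA_integer_ else as.integer(cl$clone_id)
    }, integer(1)),
    area_um2 = areas, cx = cents[, 1], cy = cents[, 2],
    on_border = if (!is.null(edge_nb)) {
      vapply(edge_nb, function(nb) any(nb == 0L), logical(1))
    } else {
      fs <- as.numeric(obj$field_size_um)
      tol <- 1e-6 * max(fs)
      vapply(polygons, function(p) {
        any(p[, 1] < tol | p[, 1] > fs[1] - tol |
              p[, 2] < tol | p[, 2] > fs[2] - tol)
      }, logical(1))
    },
    stringsAsFactors = FALSE)
  am <- obj$adjacency
  if (is.list(am)) am <- do.call(rbind, lapply(am, as.numeric))
  adj <- if (is.null(am) || length(am) == 0) {
    data.frame(a = integer(), b = integer(), length_um = numeric())
  } else {
    data.frame(a = as.integer(am[, 1]), b = as.integer(am[, 2]),
               length_um = as.numeric(am[, 3]))
  }
  structure(list(cells = cells, polygons = polygons, edge_nb = edge_nb,
                 adjacency = adj, seeds = NULL, weights = NULL,
                 field_size_um = as.numeric(obj$field_size_um),
                 pixel_size_um = as.numeric(obj$pixel_size_um),
                 provenance = obj$provenance),
            class = "tissue")
}
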