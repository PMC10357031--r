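#' Construct a multi-channel image stack
#'
#' @param channels Named list of 2D matrices (rows = y) or 3D arrays
#'   (z, y, x) of non-negative finite intensities, all of one shape.
#' @param pixel_size_um Pixel edge in µm.
#' @param z_step_um Z spacing in µm, or `NULL` for 2D stacks.
#' @return An `image_stack` object.
#' @export
image_stack <- function(channels, pixel_size_um, z_step_um = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1) {
    stop("all channels must share one shape", call. = FALSE)
  }
  for (ch in channels) {
    if (!all(is.finite(ch)) || any(ch < 0)) {
      stop("channel intensities must be finite and >= 0", call. = FALSE)
    }
  }
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0", call. = FALSE)
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> channels: %s; dim %s; pixel %.3g um\n",
              paste(names(x$channels), collapse = ", "),
              paste(d, collapse = "x"), x$pixel_size_um))
  invisible(x)
}

#' Render image channels from a ground-truth tissue
#'
#' Rasterizes the tissue at its pixel size and emits three channels, as in a
#' junction-stained, clone-marked wing-disc acquisition:
#' * `membrane` — bright (1) on every cell-cell junction, dark interiors
#'   (the adherens-junction stain used for segmentation);
#' * `clone` — clone-marker channel; `marker_mode = "gain"` is bright inside
#'   clone cells (GFP-like), `"loss"` is its complement, bright everywhere
#'   except clone interiors (loss-of-staining detection);
#' * `junction` — junction intensity with heterotypic junctions (between
#'   cells of different genotype) multiplied by `interface_enrichment`
#'   (interfacial actomyosin-like enrichment).
#'
#' Additive Gaussian noise of standard deviation `noise_sd` (on the unit
#' intensity scale, clamped at zero) is applied to each channel, and the
#' paired ground-truth cell-label image is attached as
#' `attr(stack, "labels")`.
#'
#' @param tissue A ground-truth `tissue` with clones seeded.
#' @param interface_enrichment Heterotypic junction multiplier (>= 1).
#' @param marker_mode `"gain"` or `"loss"`.
#' @param noise_sd Gaussian noise standard deviation (0 = noise free).
#' @param rng_seed Integer seed for the noise.
#' @param pixel_size_um Pixel edge in µm; defaults to the tissue's.
#' @return An `image_stack` with channels `membrane`, `clone`, `junction`.
#' @export
render_channels <- function(tissue, interface_enrichment = 1,
                            marker_mode = c("gain", "loss"), noise_sd = 0,
                            rng_seed = 1L,
                            pixel_size_um = tissue$pixel_size_um) {
  marker_mode <- match.arg(marker_mode)
  mean_diam <- 2 * sqrt(mean(tissue$cells$area_um2) / pi)
  if (pixel_size_um > mean_diam) {
    warning("degenerate render: pixel size (", pixel_size_um,
            " um) exceeds the mean cell diameter (", round(mean_diam, 2),
            " um)", call. = FALSE)
  }
  labels <- rasterize_tissue(tissue, pixel_size_um)
  nr <- nrow(labels); nc <- ncol(labels)
  geno <- ifelse(is.na(tissue$cells$clone_id), 0L, 1L)
  gl <- matrix(geno[labels], nr, nc)

  membrane <- matrix(0, nr, nc)
  junction <- matrix(0, nr, nc)
  e <- interface_enrichment
  # horizontal neighbor pairs
  difh <- labels[, -1] != labels[, -nc]
  valh <- ifelse(gl[, -1] != gl[, -nc], e, 1)
  mh <- membrane[, -1]; mh[difh] <- 1; membrane[, -1] <- mh
  mh <- membrane[, -nc]; mh[difh] <- 1; membrane[, -nc] <- mh
  jr <- junction[, -1]; jr[difh] <- pmax(jr[difh], valh[difh])
  junction[, -1] <- jr
  jl <- junction[, -nc]; jl[difh] <- pmax(jl[difh], valh[difh])
  junction[, -nc] <- jl
  # vertical neighbor pairs
  difv <- labels[-1, ] != labels[-nr, ]
  valv <- ifelse(gl[-1, ] != gl[-nr, ], e, 1)
  mb <- membrane[-1, ]; mb[difv] <- 1; membrane[-1, ] <- mb
  mb <- membrane[-nr, ]; mb[difv] <- 1; membrane[-nr, ] <- mb
  jb <- junction[-1, ]; jb[difv] <- pmax(jb[difv], valv[difv])
  junction[-1, ] <- jb
  jb <- junction[-nr, ]; jb[difv] <- pmax(jb[difv], valv[difv])
  junction[-nr, ] <- jb

  clonal_ids <- tissue$cells$cell_id[!is.na(tissue$cells$clone_id)]
  clone <- matrix(0, nr, nc)
  clone[matrix(labels %in% clonal_ids, nr, nc)] <- 1
  if (marker_mode == "loss") clone <- 1 - clone

  chans <- list(membrane = membrane, clone = clone, junction = junction)
  if (noise_sd > 0) {
    chans <- with_seed(rng_seed, {
      lapply(chans, function(ch) {
        pmax(ch + matrix(stats::rnorm(length(ch), sd = noise_sd), nr, nc), 0)
      })
    })
  }
  stk <- image_stack(chans, pixel_size_um)
  attr(stk, "labels") <- labels
  stk
}
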