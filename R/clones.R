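#' Specify synthetic clones
#'
#' Parameters controlling clone induction and the interfacial phenotype of
#' the generated tissue. With `compaction = 1`, `interface_enrichment = 1`
#' and `boundary_smoothing_iters = 0` the tissue is neutral: clone cells are
#' geometrically indistinguishable from their wild-type surroundings, as for
#' wild-type control clones. `compaction < 1` shrinks clonal apical areas
#' relative to the surrounding cells (apical constriction of the enclosed
#' minority population), `boundary_smoothing_iters > 0` rounds the clone
#' interface (the high-tension, high-circularity phenotype), and
#' `interface_enrichment > 1` brightens heterotypic junctions in the
#' junction-intensity channel (interfacial actomyosin enrichment).
#'
#' @param n_clones Number of clones to induce.
#' @param cells_per_clone Cells per clone.
#' @param growth_mode `"contiguous"` (neighbor-accretion growth from a random
#'   founder, the lineage-clone geometry) or `"dispersed"` (cells drawn
#'   independently at random, emulating clones whose cells detach and mix).
#' @param compaction Target ratio of clone-cell mean apical area to
#'   surrounding-cell mean apical area, in (0, 1].
#' @param boundary_smoothing_iters Non-negative integer; Laplacian smoothing
#'   iterations applied to each clone's exterior boundary.
#' @param interface_enrichment Junction-intensity multiplier (>= 1) applied
#'   to heterotypic junctions when rendering.
#' @return A `clone_spec` object (list).
#' @export
clone_spec <- function(n_clones = 3, cells_per_clone = 20,
                       growth_mode = c("contiguous", "dispersed"),
                       compaction = 1, boundary_smoothing_iters = 0L,
                       interface_enrichment = 1) {
  growth_mode <- match.arg(growth_mode)
  if (compaction <= 0 || compaction > 1) {
    stop("compaction must lie in (0, 1]", call. = FALSE)
  }
  if (interface_enrichment < 1) {
    stop("interface_enrichment must be >= 1", call. = FALSE)
  }
  if (boundary_smoothing_iters < 0) {
    stop("boundary_smoothing_iters must be >= 0", call. = FALSE)
  }
  structure(list(n_clones = as.integer(n_clones),
                 cells_per_clone = as.integer(cells_per_clone),
                 growth_mode = growth_mode,
                 compaction = compaction,
                 boundary_smoothing_iters = as.integer(boundary_smoothing_iters),
                 interface_enrichment = interface_enrichment),
            class = "clone_spec")
}

# adjacency as a neighbor list (list of integer vectors, 1..n)
neighbor_list <- function(tissue) {
  n <- nrow(tissue$cells)
  adj <- tissue$adjacency
  nbl <- vector("list", n)
  both_a <- c(adj$a, adj$b)
  both_b <- c(adj$b, adj$a)
  sp <- split(both_b, factor(both_a, levels = seq_len(n)))
  for (i in seq_len(n)) nbl[[i]] <- sp[[i]]
  nbl
}

#' Induce clones in a tissue
#'
#' Assigns `clone_id` labels to cells. Contiguous clones grow by repeated
#' accretion of a random unassigned adjacency neighbor from a random founder
#' cell (emulating lineage clones induced by mitotic recombination);
#' dispersed clones draw their member cells independently at random across
#' the tissue.
#'
#' @param tissue A `tissue`.
#' @param clone_spec A [clone_spec()].
#' @param rng_seed Integer seed.
#' @return The tissue with `clone_id` and `genotype` filled in for clonal
#'   cells.
#' @export
seed_clones <- function(tissue, clone_spec, rng_seed = 1L) {
  stopifnot(inherits(clone_spec, "clone_spec"))
  n <- nrow(tissue$cells)
  n_request <- clone_spec$n_clones * clone_spec$cells_per_clone
  if (clone_spec$n_clones == 0L) return(tissue)
  if (n_request > n / 2) {
    stop("infeasible clone packing: ", n_request,
         " clone cells requested for ", n, " cells", call. = FALSE)
  }
  nbl <- neighbor_list(tissue)
  with_seed(rng_seed, {
    assigned <- rep(NA_integer_, n)
    if (clone_spec$growth_mode == "dispersed") {
      picks <- sample(seq_len(n), n_request)
      assigned[picks] <- rep(seq_len(clone_spec$n_clones),
                             each = clone_spec$cells_per_clone)
    } else {
      for (cid in seq_len(clone_spec$n_clones)) {
        grown <- FALSE
        for (attempt in 1:50) {
          # clones grow in the field interior and keep one cell of clearance
          # from previously induced clones (separate induction events with
          # analyzable, non-merging interfaces)
          blocked <- tissue$cells$on_border | !is.na(assigned)
          near_clone <- unique(unlist(nbl[which(!is.na(assigned))]))
          blocked[near_clone] <- TRUE
          free <- which(!blocked)
          if (length(free) == 0) break
          founder <- if (length(free) == 1) free else sample(free, 1)
          members <- founder
          while (length(members) < clone_spec$cells_per_clone) {
            frontier <- setdiff(unique(unlist(nbl[members])),
                                c(members, which(blocked)))
            if (length(frontier) == 0) break
            pick <- if (length(frontier) == 1) frontier else sample(frontier, 1)
            members <- c(members, pick)
          }
          if (length(members) == clone_spec$cells_per_clone) {
            assigned[members] <- cid
            grown <- TRUE
            break
          }
        }
        if (!grown) {
          stop("infeasible clone packing: could not grow contiguous clone ",
               cid, call. = FALSE)
        }
      }
    }
    tissue$cells$clone_id <- assigned
    tissue$cells$genotype <- ifelse(is.na(assigned), "wt", "mut")
  })
  tissue
}

# wild-type cells within graph distance <= k of any clone cell (BFS on the
# neighbor list); border-flagged cells excluded
ring_cells_bfs <- function(nbl, clonal, on_border, k) {
  seen <- clonal
  frontier <- clonal
  ring <- integer(0)
  for (step in seq_len(k)) {
    nxt <- setdiff(unique(unlist(nbl[frontier])), which(seen))
    if (length(nxt) == 0) break
    seen[nxt] <- TRUE
    ring <- c(ring, nxt)
    frontier <- nxt
  }
  ring[!on_border[ring]]
}

#' Apply interfacial compaction and boundary smoothing
#'
#' Implements the apical-constriction phenotype of enclosed minority cells:
#' the tissue is re-tessellated as a power diagram with clone seeds
#' down-weighted so that the ratio of clone-cell mean apical area to
#' surrounding-cell mean apical area (wild-type cells within graph distance
#' 2 of the clone, as measured by [apical_area_stats()]) equals
#' `clone_spec$compaction`. Down-weighting guarantees a valid tiling at any
#' compaction value. `boundary_smoothing_iters` rounds of Laplacian
#' smoothing are then applied to each clone's exterior boundary, raising
#' interface circularity while preserving the tiling (shared vertices move
#' consistently in all incident cells).
#'
#' @param tissue A `tissue` with clones already seeded.
#' @param clone_spec A [clone_spec()].
#' @return The compacted (and smoothed) `tissue`.
#' @export
apply_interface_compaction <- function(tissue, clone_spec) {
  stopifnot(inherits(clone_spec, "clone_spec"))
  if (clone_spec$compaction <= 0) stop("compaction must be > 0", call. = FALSE)
  clonal <- !is.na(tissue$cells$clone_id)
  if (!any(clonal)) stop("no clones seeded", call. = FALSE)
  target <- clone_spec$compaction

  if (target < 1) {
    # per-cell power weights, iterated toward each clone cell's target area
    # (a uniform weight offset would collapse the smallest clone cell long
    # before the pooled ratio reaches strong compaction values)
    n <- nrow(tissue$cells)
    w <- rep(0, n)
    eta <- 0.3
    cur <- tissue
    best <- NULL
    for (iter in 1:60) {
      nbl <- neighbor_list(cur)
      ring <- ring_cells_bfs(nbl, clonal, cur$cells$on_border, k = 2)
      ring_mean <- mean(cur$cells$area_um2[ring])
      ratio <- mean(cur$cells$area_um2[clonal]) / ring_mean
      if (is.null(best) || abs(ratio - target) < abs(best$ratio - target)) {
        best <- list(tissue = cur, ratio = ratio)
      }
      if (abs(ratio - target) < 0.005 * target) break
      step <- eta * (cur$cells$area_um2[clonal] - target * ring_mean)
      w_new <- w
      w_new[clonal] <- w_new[clonal] - step
      nxt <- tryCatch(
        build_tissue(tissue$seeds, w_new, tissue$field_size_um,
                     tissue$pixel_size_um),
        error = function(e) NULL)
      tries <- 0
      while (is.null(nxt) && tries < 6) {
        w_new <- (w + w_new) / 2
        nxt <- tryCatch(
          build_tissue(tissue$seeds, w_new, tissue$field_size_um,
                       tissue$pixel_size_um),
          error = function(e) NULL)
        tries <- tries + 1
      }
      if (is.null(nxt)) break
      w <- w_new
      cur <- nxt
    }
    newt <- best$tissue
    if (abs(best$ratio - target) > 0.1 * target) {
      warning("compaction calibration reached ratio ",
              round(best$ratio, 3), " for target ", target, call. = FALSE)
    }
    newt$cells$clone_id <- tissue$cells$clone_id
    newt$cells$genotype <- tissue$cells$genotype
    newt$spec <- tissue$spec
    tissue <- newt
  }
  if (clone_spec$boundary_smoothing_iters > 0) {
    tissue <- smooth_clone_boundaries(tissue,
                                      clone_spec$boundary_smoothing_iters)
  }
  tissue
}

#' Laplace pressure across a contractile interface
#'
#' The pressure difference across a curved boundary of line tension `gamma`
#' is `gamma / radius`: a smaller enclosed clone sits under higher pressure
#' from the same interfacial tension, which is the physical rationale for
#' size-dependent elimination of misspecified clones.
#'
#' @param gamma Line tension (arbitrary force units), >= 0.
#' @param radius Boundary radius of curvature in µm, > 0.
#' @return Pressure (tension / length units).
#' @export
interface_pressure <- function(gamma, radius) {
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (any(radius <= 0)) stop("radius must be > 0", call. = FALSE)
  gamma / radius
}
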