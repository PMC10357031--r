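# Shared fixtures, built once per test run and memoized.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

# 400-cell relaxed epithelium, 60x60 um, 0.1 um pixels
fx_epithelium <- function() {
  memo("epithelium", generate_epithelium(
    tissue_spec(n_cells = 400, field_size_um = c(60, 60),
                lloyd_iterations = 3, rng_seed = 11, pixel_size_um = 0.1)))
}

# the same epithelium with three 20-cell contiguous neutral clones
fx_clonal_tissue <- function() {
  memo("clonal", seed_clones(fx_epithelium(), clone_spec(3, 20),
                             rng_seed = 21))
}

# noise-free render of the clonal tissue (enrichment 2 on the junction ch.)
fx_render <- function() {
  memo("render", render_channels(fx_clonal_tissue(),
                                 interface_enrichment = 2))
}

# hexagonal lattice (side 1 um) with helpers to pick central cells
fx_hex <- function() {
  memo("hex", hex_lattice_tissue(rows = 11, cols = 11, side_um = 1))
}

hex_center_id <- function(tis, row, col) {
  lat <- attr(tis, "lattice")
  which(lat$row == row & lat$col == col)
}

hex_neighbors <- function(tis, id) {
  adj <- tis$adjacency
  sort(c(adj$b[adj$a == id], adj$a[adj$b == id]))
}

# lattice with the central cell as a single-cell clone
fx_hex_single <- function() {
  memo("hex_single", {
    tis <- fx_hex()
    mid <- hex_center_id(tis, 6, 6)
    tis$cells$clone_id[mid] <- 1L
    tis$cells$genotype[mid] <- "mut"
    tis
  })
}

# lattice with a 7-cell rosette clone (center + its 6 neighbors)
fx_hex_rosette <- function() {
  memo("hex_rosette", {
    tis <- fx_hex()
    mid <- hex_center_id(tis, 6, 6)
    members <- c(mid, hex_neighbors(tis, mid))
    tis$cells$clone_id[members] <- 1L
    tis$cells$genotype[members] <- "mut"
    tis
  })
}

# compacted + smoothed version of the clonal tissue (ratio 0.5, 25 iters)
fx_compacted <- function() {
  memo("compacted", apply_interface_compaction(
    seed_clones(fx_epithelium(),
                clone_spec(3, 20, compaction = 0.5,
                           boundary_smoothing_iters = 25), rng_seed = 21),
    clone_spec(3, 20, compaction = 0.5, boundary_smoothing_iters = 25)))
}

# segmented version of the noise-free render with ground-truth clone mask
fx_segmented <- function() {
  memo("segmented", {
    stk <- fx_render()
    lab <- attr(stk, "labels")
    tis <- fx_clonal_tissue()
    clonal_ids <- tis$cells$cell_id[!is.na(tis$cells$clone_id)]
    gt_mask <- matrix(lab %in% clonal_ids, nrow(lab))
    seg <- segment_cells(stk$channels$membrane, stk$pixel_size_um)
    assign_clone_labels(seg, gt_mask)
  })
}

first_clone <- function(tissue, min_cells = 10) {
  extract_clones(tissue, min_cells)[[1]]
}

# hex-lattice tissue with one big clone, one nearby small group and one
# isolated small group (all labels distinct) — fragment-filter fixture
fragment_fixture <- function() {
  memo("fragment", {
    tis <- hex_lattice_tissue(15, 25, side_um = 1)
    lat <- attr(tis, "lattice")
    pick <- function(row, col) which(lat$row == row & lat$col == col)
    # big clone: 12 contiguous cells around (7, 6)
    members <- pick(7, 6)
    while (length(members) < 12) {
      nbs <- unique(unlist(lapply(members,
                                  function(m) hex_neighbors(tis, m))))
      nbs <- setdiff(nbs[!tis$cells$on_border[nbs]], members)
      members <- c(members,
                   nbs[seq_len(min(length(nbs), 12 - length(members)))])
    }
    tis$cells$clone_id[members] <- 1L
    # near fragment: 3 cells two lattice steps from the big clone (< 20 um)
    tis$cells$clone_id[c(pick(7, 11), pick(7, 12), pick(8, 11))] <- 2L
    # isolated fragment: 3 cells far away (> 20 um)
    tis$cells$clone_id[c(pick(13, 22), pick(13, 23), pick(14, 22))] <- 3L
    tis
  })
}

# regular polygon helper for closed-form circularity checks
regular_polygon <- function(n, r = 1) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(theta), r * sin(theta))
}
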