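test_that("circularity matches closed forms", {
  expect_equal(circularity(regular_polygon(360)), 1.0, tolerance = 1e-3)
  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(circularity(square), pi / 4, tolerance = 1e-12)
  expect_equal(circularity(regular_polygon(6)), pi * sqrt(3) / 6,
               tolerance = 1e-12)
  # scale and rotation invariance
  rot <- function(p, a) p %*% matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  expect_equal(circularity(7.3 * rot(square, 0.7)), circularity(square))
  expect_error(circularity(cbind(0:1, 0:1)), "degenerate")
})

test_that("circularity stays within the isoperimetric bound on clones", {
  for (tis in list(fx_clonal_tissue(), fx_compacted())) {
    for (cl in extract_clones(tis, 10)) {
      if (!cl$touches_border) {
        expect_lte(circularity(cl), 1 + 1e-6)
        expect_gt(circularity(cl), 0)
      }
    }
  }
  # rasterized (segmented) boundaries may exceed 1 only marginally
  for (cl in Filter(function(x) !x$touches_border && x$n_cells >= 10,
                    extract_clones(fx_segmented(), 10))) {
    expect_lte(circularity(cl), 1.02)
  }
})

test_that("apical area statistics are exact on uniform lattices and scale-free", {
  rosette <- fx_hex_rosette()
  cl <- first_clone(rosette)
  st <- apical_area_stats(cl, neighborhood(cl, rosette), rosette)
  expect_equal(st$ratio, 1.0, tolerance = 1e-9)
  # global um rescaling leaves the ratio unchanged
  big <- hex_lattice_tissue(11, 11, side_um = 3)
  mid <- hex_center_id(big, 6, 6)
  members <- c(mid, hex_neighbors(big, mid))
  big$cells$clone_id[members] <- 1L
  clb <- first_clone(big)
  stb <- apical_area_stats(clb, neighborhood(clb, big), big)
  expect_equal(stb$ratio, st$ratio, tolerance = 1e-9)
  expect_error(apical_area_stats(cl, list(ring = data.frame(cell_id = integer())),
                                 rosette), "empty neighborhood")
})

test_that("compaction parameter is recovered by apical_area_stats", {
  tis <- seed_clones(fx_epithelium(), clone_spec(2, 20, compaction = 0.5),
                     rng_seed = 51)
  tc <- apply_interface_compaction(tis, clone_spec(2, 20, compaction = 0.5))
  ratios <- vapply(extract_clones(tc, 10), function(cl) {
    apical_area_stats(cl, neighborhood(cl, tc), tc)$ratio
  }, numeric(1))
  expect_equal(mean(ratios), 0.5, tolerance = 0.05)
})

test_that("mixing index and contact length match lattice enumeration", {
  single <- fx_hex_single()
  cl1 <- first_clone(single)
  expect_equal(mixing_index(cl1, single), 6.0)
  expect_equal(contact_length(cl1, single), 6.0, tolerance = 1e-6)

  rosette <- fx_hex_rosette()
  cl7 <- first_clone(rosette)
  expect_equal(mixing_index(cl7, rosette), 3.0)
  expect_equal(contact_length(cl7, rosette), 3.0, tolerance = 1e-6)

  # fully dispersed single cells sit at the lattice maximum of 6
  t2 <- fx_hex()
  ids <- c(hex_center_id(t2, 4, 4), hex_center_id(t2, 4, 8),
           hex_center_id(t2, 8, 4), hex_center_id(t2, 8, 8))
  t2$cells$clone_id[ids] <- 1L
  for (cl in extract_clones(t2, 10)) {
    expect_equal(mixing_index(cl, t2), 6.0)
  }
})

test_that("clone area fraction counts mask pixels inside the ROI", {
  roi <- region_roi("pouch", cbind(c(1, 5, 5, 1), c(1, 1, 5, 5)))
  full <- matrix(TRUE, 10, 10)
  expect_equal(clone_area_fraction(full, roi, pixel_size_um = 1), 1.0)
  empty <- matrix(FALSE, 10, 10)
  expect_equal(clone_area_fraction(empty, roi, pixel_size_um = 1), 0.0)
  # known pixel budget: left half of the ROI covered
  half <- matrix(FALSE, 10, 10)
  half[, 1:3] <- TRUE  # columns 1-3 -> x in (0,3); ROI x in (1,5)
  expect_equal(clone_area_fraction(half, roi, pixel_size_um = 1), 0.5,
               tolerance = 0.01)
  outside <- region_roi("off", cbind(c(100, 101, 101), c(100, 100, 101)))
  expect_error(clone_area_fraction(full, outside, 1), "empty ROI")
})

test_that("remaining-clone counts respect ROI membership and size", {
  tis <- fx_clonal_tissue()
  clones <- extract_clones(tis, 10)
  all_roi <- region_roi("field", cbind(c(0, 60, 60, 0), c(0, 0, 60, 60)))
  expect_equal(count_remaining_clones(clones, all_roi, min_cells = 10), 3)
  expect_equal(count_remaining_clones(list(), all_roi), 0)
  # raising min_cells never increases the count
  counts <- vapply(c(1, 10, 21), function(m) {
    count_remaining_clones(clones, all_roi, min_cells = m)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[3], 0)  # all clones have exactly 20 cells
})

test_that("intensity profiles interpolate, reverse, and see enrichment", {
  const <- matrix(5, 20, 20)
  pr <- intensity_profile(const, c(2, 2), c(15, 9))
  expect_true(all(abs(pr$intensity - 5) < 1e-12))
  img <- matrix(runif(400), 20, 20)
  fwd <- intensity_profile(img, c(2, 3), c(17, 12))
  bwd <- intensity_profile(img, c(17, 12), c(2, 3))
  expect_equal(fwd$intensity, rev(bwd$intensity), tolerance = 1e-12)
  expect_error(intensity_profile(img, c(3, 3), c(3, 3)), "zero-length")
  # profile across rendered junctions: heterotypic peak ~= 2x homotypic
  tis <- fx_clonal_tissue()
  stk <- fx_render()  # enrichment 2
  jun <- stk$channels$junction
  cross_profile_peak <- function(i, j) {
    nb <- tis$edge_nb[[i]]
    k <- which(nb == j)[1]
    p <- tis$polygons[[i]]
    k2 <- k %% nrow(p) + 1
    mid_um <- (p[k, ] + p[k2, ]) / 2
    ed <- (p[k2, ] - p[k, ]) / sqrt(sum((p[k2, ] - p[k, ])^2))
    nrm <- c(-ed[2], ed[1])
    a <- (mid_um - nrm) / 0.1  # 1 um to each side, in px
    b <- (mid_um + nrm) / 0.1
    max(intensity_profile(jun, a, b)$intensity)
  }
  adj <- tis$adjacency
  clonal <- !is.na(tis$cells$clone_id)
  het <- adj[xor(clonal[adj$a], clonal[adj$b]) & adj$length_um > 0.5, ]
  hom <- adj[!clonal[adj$a] & !clonal[adj$b] & adj$length_um > 0.5, ]
  peak_het <- cross_profile_peak(het$a[1], het$b[1])
  peak_hom <- cross_profile_peak(hom$a[1], hom$b[1])
  expect_equal(peak_het / peak_hom, 2, tolerance = 0.1)
})

test_that("enrichment ratio is a null-safe, scale-invariant ratio", {
  tis <- fx_clonal_tissue()
  stk1 <- render_channels(tis, interface_enrichment = 1)
  expect_equal(interface_enrichment_ratio(tis, stk1$channels$junction), 1,
               tolerance = 0.05)
  stk3 <- render_channels(tis, interface_enrichment = 3)
  r3 <- interface_enrichment_ratio(tis, stk3$channels$junction)
  expect_equal(r3, 3, tolerance = 0.05)
  expect_equal(interface_enrichment_ratio(tis, 42 * stk3$channels$junction),
               r3, tolerance = 1e-12)
  wt_only <- fx_epithelium()
  stk_wt <- render_channels(wt_only)
  expect_error(interface_enrichment_ratio(wt_only, stk_wt$channels$junction),
               "heterotypic")
})

test_that("mask-based circularity ranks smooth above ragged outlines", {
  # a disc mask is near-circular
  xy <- expand.grid(r = 1:100, c = 1:100)
  disc <- matrix((xy$r - 50.5)^2 + (xy$c - 50.5)^2 < 30^2, 100, 100)
  mc <- mask_circularity(disc, pixel_size_um = 0.1)
  expect_equal(nrow(mc), 1)
  expect_gt(mc$circularity, 0.95)
  # loss-mode workflow: clones darker than surroundings, sigma 3.5 blur
  tis <- fx_compacted()
  stk <- render_channels(tis, marker_mode = "loss")
  cm <- detect_clone_mask(stk$channels$clone, "loss")
  expect_equal(cm$blur_sigma_px, 3.5)
  mc2 <- mask_circularity(cm, stk$pixel_size_um, min_area_um2 = 5)
  expect_gte(nrow(mc2), 1)
  expect_true(all(mc2$circularity > 0 & mc2$circularity <= 1.02))
  # smoothed compacted clones outline rounder than ragged neutral clones
  tisn <- fx_clonal_tissue()
  cmn <- detect_clone_mask(render_channels(tisn,
                                           marker_mode = "loss")$channels$clone,
                           "loss")
  mcn <- mask_circularity(cmn, 0.1, min_area_um2 = 5)
  expect_gt(median(mc2$circularity), median(mcn$circularity))
})
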