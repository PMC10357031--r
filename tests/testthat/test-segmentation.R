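make_test_stack <- function() {
  # 6-slice stack: membrane signal lives in slices 3-5
  set.seed(99)
  nz <- 6; ny <- 20; nx <- 20
  mem <- array(0, c(nz, ny, nx))
  for (z in 3:5) mem[z, , ] <- matrix(runif(ny * nx), ny, nx)
  other <- array(runif(nz * ny * nx, 0, 0.1), c(nz, ny, nx))
  image_stack(list(membrane = mem, clone = other), pixel_size_um = 0.5,
              z_step_um = 1)
}

test_that("max projection obeys max semantics and slice exclusion", {
  stk <- make_test_stack()
  mem <- stk$channels$membrane
  # brute-force per-pixel maximum as oracle
  oracle <- apply(mem, c(2, 3), max)
  expect_equal(max_project(stk, "membrane"), oracle)
  # excluding the brightest slice equals max over the remainder
  totals <- apply(mem, 1, sum)
  brightest <- which.max(totals)
  oracle2 <- apply(mem[-brightest, , ], c(2, 3), max)
  expect_equal(max_project(stk, "membrane", exclude_slices = brightest),
               oracle2)
  expect_error(max_project(stk, "membrane", z_range = 1,
                           exclude_slices = 1), "empty")
  # 2D input is the identity
  flat <- image_stack(list(membrane = matrix(1:9 / 9, 3, 3)), 1)
  expect_identical(max_project(flat, "membrane"),
                   flat$channels$membrane)
})

test_that("apical projection selects the brightest membrane slices", {
  stk <- make_test_stack()
  proj <- apical_project(stk, "membrane", n_slices = 3)
  expect_identical(attr(proj, "slices"), 3:5)
  # full depth reduces to the plain maximum projection
  full <- apical_project(stk, "membrane", n_slices = 6)
  expect_equal(unclass(full), max_project(stk, "membrane"),
               ignore_attr = TRUE)
  expect_error(apical_project(stk, "membrane", n_slices = 1), "n_slices")
  expect_error(apical_project(stk, "membrane", n_slices = 7), "n_slices")
})

test_that("projection commutes with positive intensity rescaling", {
  stk <- make_test_stack()
  scaled <- stk
  scaled$channels$membrane <- 3.7 * stk$channels$membrane
  expect_equal(max_project(scaled, "membrane"),
               3.7 * max_project(stk, "membrane"))
})

test_that("clone masks recover ground truth in gain and loss modes", {
  tis <- fx_clonal_tissue()
  stk <- fx_render()
  lab <- attr(stk, "labels")
  clonal_ids <- tis$cells$cell_id[!is.na(tis$cells$clone_id)]
  gt <- matrix(lab %in% clonal_ids, nrow(lab))
  cm <- detect_clone_mask(stk$channels$clone, "gain", blur_sigma_px = 0)
  expect_equal(mask_jaccard(gt, cm$mask), 1.0)
  # loss mode on the inverted channel yields the identical mask
  cm_loss <- detect_clone_mask(max(stk$channels$clone) - stk$channels$clone,
                               "loss", blur_sigma_px = 0)
  expect_identical(cm$mask, cm_loss$mask)
  # defaults: sigma 2.0 in gain mode, 3.5 in loss mode
  expect_equal(detect_clone_mask(stk$channels$clone, "gain")$blur_sigma_px,
               2.0)
  expect_equal(detect_clone_mask(stk$channels$clone, "loss")$blur_sigma_px,
               3.5)
  expect_error(detect_clone_mask(matrix(1, 10, 10), "gain"), "no signal")
})

test_that("clone mask survives 10% noise with the default gain sigma", {
  tis <- fx_clonal_tissue()
  stk <- render_channels(tis, noise_sd = 0.1, rng_seed = 13)
  lab <- attr(stk, "labels")
  clonal_ids <- tis$cells$cell_id[!is.na(tis$cells$clone_id)]
  gt <- matrix(lab %in% clonal_ids, nrow(lab))
  cm <- detect_clone_mask(stk$channels$clone, "gain", blur_sigma_px = 2.0)
  expect_gte(mask_jaccard(gt, cm$mask), 0.9)
})

test_that("watershed segmentation matches ground-truth cells", {
  stk <- fx_render()
  lab <- attr(stk, "labels")
  seg <- segment_cells(stk$channels$membrane, stk$pixel_size_um)
  ov <- segmentation_overlap(lab, seg$labels)
  expect_gte(ov$match_fraction(0.8), 0.95)
  # near-tiling conservation
  expect_equal(sum(seg$cells$area_um2), 3600, tolerance = 0.02)
  # deterministic for a fixed raster
  seg2 <- segment_cells(stk$channels$membrane, stk$pixel_size_um)
  expect_identical(seg$labels, seg2$labels)
})

test_that("segmented adjacency reproduces ground-truth edges", {
  tis <- fx_clonal_tissue()
  stk <- fx_render()
  seg <- segment_cells(stk$channels$membrane, stk$pixel_size_um)
  ov <- segmentation_overlap(attr(stk, "labels"), seg$labels)
  map <- ov$pairs$seg
  names(map) <- ov$pairs$ref
  gt_edges <- paste(tis$adjacency$a, tis$adjacency$b)
  seg_pairs <- cbind(map[as.character(seg$adjacency$a)],
                     map[as.character(seg$adjacency$b)])
  # express segmented edges in ground-truth ids (NA = unmatched cell)
  seg_in_gt <- apply(seg$adjacency, 1, function(e) {
    ga <- ov$pairs$ref[match(e[1], ov$pairs$seg)]
    gb <- ov$pairs$ref[match(e[2], ov$pairs$seg)]
    if (is.na(ga) || is.na(gb)) NA_character_ else {
      paste(min(ga, gb), max(ga, gb))
    }
  })
  recovered <- mean(gt_edges %in% seg_in_gt)
  expect_gte(recovered, 0.9)
})

test_that("clone label assignment recovers generator labels", {
  tis <- fx_clonal_tissue()
  stk <- fx_render()
  lab <- attr(stk, "labels")
  clonal_ids <- tis$cells$cell_id[!is.na(tis$cells$clone_id)]
  gt_mask <- matrix(lab %in% clonal_ids, nrow(lab))
  t2 <- assign_clone_labels(tis, gt_mask)
  expect_identical(!is.na(t2$cells$clone_id), !is.na(tis$cells$clone_id))
  # the all-true mask makes every cell clonal
  t3 <- assign_clone_labels(tis, matrix(TRUE, nrow(lab), ncol(lab)))
  expect_true(all(!is.na(t3$cells$clone_id)))
  # stricter overlap thresholds can only shrink the clonal set
  er <- EBImage::erode(EBImage::Image(t(matrix(as.integer(gt_mask),
                                               nrow(gt_mask)))),
                       EBImage::makeBrush(3, "box"))
  eroded <- t(EBImage::imageData(er)) > 0
  n_strict <- sum(!is.na(assign_clone_labels(
    tis, eroded, min_overlap_frac = 1.0)$cells$clone_id))
  n_default <- sum(!is.na(assign_clone_labels(
    tis, eroded, min_overlap_frac = 0.5)$cells$clone_id))
  expect_lt(n_strict, n_default)
  expect_error(assign_clone_labels(tis, matrix(TRUE, 5, 5)), "frame")
})

test_that("ground-truth and segmented metrics agree on noise-free renders", {
  tis <- fx_clonal_tissue()
  seg <- fx_segmented()
  cg <- extract_clones(tis, 10)
  cs <- Filter(function(x) x$n_cells >= 10, extract_clones(seg, 10))
  for (g in cg) {
    d2 <- vapply(cs, function(s) {
      sum((polygon_centroid(s$boundary) - polygon_centroid(g$boundary))^2)
    }, numeric(1))
    s <- cs[[which.min(d2)]]
    expect_equal(circularity(s), circularity(g), tolerance = 0.05)
    nhg <- neighborhood(g, tis)
    nhs <- neighborhood(s, seg)
    expect_equal(apical_area_stats(s, nhs, seg)$mean_inside,
                 apical_area_stats(g, nhg, tis)$mean_inside,
                 tolerance = 0.05)
    expect_equal(apical_area_stats(s, nhs, seg)$ratio,
                 apical_area_stats(g, nhg, tis)$ratio, tolerance = 0.05)
  }
})
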