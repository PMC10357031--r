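test_that("generated epithelium tiles the field and is deterministic", {
  spec <- tissue_spec(n_cells = 400, field_size_um = c(200, 200),
                      lloyd_iterations = 0, rng_seed = 1)
  t1 <- generate_epithelium(spec)
  expect_equal(sum(t1$cells$area_um2), 200 * 200, tolerance = 1e-3)
  t2 <- generate_epithelium(spec)
  expect_identical(t1$polygons, t2$polygons)
  expect_identical(t1$adjacency, t2$adjacency)
  # adjacency is symmetric-by-construction and junction lengths positive
  expect_true(all(t1$adjacency$length_um > 0))
  expect_true(all(t1$adjacency$a < t1$adjacency$b))
  # polygons are simple with positive area
  expect_true(all(t1$cells$area_um2 > 0))
})

test_that("Lloyd relaxation regularizes cell areas", {
  base <- tissue_spec(n_cells = 300, field_size_um = c(60, 60),
                      lloyd_iterations = 0, rng_seed = 5)
  relaxed <- tissue_spec(n_cells = 300, field_size_um = c(60, 60),
                         lloyd_iterations = 50, rng_seed = 5)
  cv <- function(x) sd(x) / mean(x)
  cv0 <- cv(generate_epithelium(base)$cells$area_um2)
  cv50 <- cv(generate_epithelium(relaxed)$cells$area_um2)
  expect_lt(cv50, cv0)
})

test_that("invalid tissue specs are rejected", {
  expect_error(tissue_spec(n_cells = 3), "n_cells")
  expect_error(tissue_spec(field_size_um = c(0, 10)), "field_size")
  expect_error(tissue_spec(pixel_size_um = 0), "pixel_size")
  expect_error(clone_spec(compaction = 0), "compaction")
  expect_error(clone_spec(compaction = 1.5), "compaction")
  expect_error(clone_spec(interface_enrichment = 0.5), "enrichment")
})

test_that("hex lattice interior cells are regular hexagons", {
  tis <- fx_hex()
  mid <- hex_center_id(tis, 6, 6)
  expect_equal(polygon_area(tis$polygons[[mid]]), 3 * sqrt(3) / 2,
               tolerance = 1e-6)
  expect_equal(polygon_perimeter(tis$polygons[[mid]]), 6, tolerance = 1e-6)
  expect_length(hex_neighbors(tis, mid), 6)
})

test_that("contiguous clones are connected and dispersed clones scatter", {
  tis <- fx_clonal_tissue()
  expect_equal(sum(!is.na(tis$cells$clone_id)), 60)
  for (cid in 1:3) {
    mem <- which(!is.na(tis$cells$clone_id) & tis$cells$clone_id == cid)
    sub <- tis$adjacency[tis$adjacency$a %in% mem & tis$adjacency$b %in% mem, ]
    g <- igraph::graph_from_data_frame(sub[, c("a", "b")], directed = FALSE,
                                       vertices = data.frame(name = mem))
    expect_equal(igraph::components(g)$no, 1)
  }
  # dispersed mode: on average some clone cells have no clonal neighbor
  base <- fx_epithelium()
  n_isolated <- vapply(1:20, function(s) {
    td <- seed_clones(base, clone_spec(1, 20, growth_mode = "dispersed"),
                      rng_seed = s)
    mem <- which(!is.na(td$cells$clone_id))
    adj <- td$adjacency
    both <- adj$a %in% mem & adj$b %in% mem
    touching <- unique(c(adj$a[both], adj$b[both]))
    sum(!(mem %in% touching))
  }, numeric(1))
  expect_gt(mean(n_isolated), 0)
})

test_that("clone seeding identity and feasibility contracts hold", {
  base <- fx_epithelium()
  t0 <- seed_clones(base, clone_spec(n_clones = 0), rng_seed = 1)
  expect_identical(t0$cells, base$cells)
  expect_error(seed_clones(base, clone_spec(11, 20), rng_seed = 1),
               "infeasible")
})

test_that("interface compaction hits its target area ratio", {
  tis <- seed_clones(fx_epithelium(), clone_spec(2, 20, compaction = 0.5),
                     rng_seed = 31)
  tc <- apply_interface_compaction(tis, clone_spec(2, 20, compaction = 0.5))
  # recovery via the metrics module, pooled over clones
  ratios <- vapply(extract_clones(tc, 10), function(cl) {
    apical_area_stats(cl, neighborhood(cl, tc), tc)$ratio
  }, numeric(1))
  expect_equal(mean(ratios), 0.5, tolerance = 0.05)
  # the tissue is still an exact tiling
  expect_equal(sum(tc$cells$area_um2), 60 * 60, tolerance = 1e-3)
  # neutral spec leaves geometry untouched
  tn <- apply_interface_compaction(tis, clone_spec(2, 20, compaction = 1))
  expect_identical(tn$polygons, tis$polygons)
})

test_that("boundary smoothing raises circularity monotonically and keeps the tiling", {
  tis <- seed_clones(fx_epithelium(), clone_spec(1, 20), rng_seed = 41)
  circs <- vapply(c(0, 5, 25), function(it) {
    sm <- apply_interface_compaction(
      tis, clone_spec(1, 20, boundary_smoothing_iters = it))
    expect_equal(sum(sm$cells$area_um2), 3600, tolerance = 1e-3)
    circularity(first_clone(sm))
  }, numeric(1))
  expect_true(all(diff(circs) > 0))
})

test_that("interface pressure follows the Laplace relation", {
  expect_equal(interface_pressure(gamma = 2, radius = 4), 0.5)
  expect_equal(interface_pressure(gamma = 0, radius = 1), 0)
  for (g in c(0.5, 1, 3)) {
    expect_equal(interface_pressure(g, 1) / interface_pressure(g, 2), 2)
  }
  expect_error(interface_pressure(1, 0), "radius")
  expect_error(interface_pressure(-1, 1), "gamma")
})
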