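# full-enumeration oracle for the two-sided Mann-Whitney p-value on
# tie-free samples: U distribution over all C(n, n_a) group assignments
mw_exact_enum <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool)
  na <- length(a)
  idx <- utils::combn(n, na)
  u_of <- function(sel) {
    r <- rank(pool)
    sum(r[sel]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  us <- apply(idx, 2, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

test_that("exact rank-sum branch matches full enumeration on tie-free inputs", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$p_two_sided, 1 / 3, tolerance = 1e-12)
  expect_equal(r$branch, "exact")
  set.seed(42)
  for (rep in 1:40) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    x <- sample(seq_len(50), na + nb)  # distinct -> tie-free
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_equal(rank_sum_test(a, b)$p_two_sided, mw_exact_enum(a, b),
                 tolerance = 1e-12)
  }
})

test_that("identical samples are a null comparison", {
  r <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p_two_sided, 1.0)
  expect_equal(r$tier, "ns")
  expect_error(rank_sum_test(numeric(0), 1:3), "empty")
})

test_that("exact and approximate branches agree on moderate samples", {
  set.seed(7)
  devs <- vapply(1:100, function(i) {
    a <- rnorm(10); b <- rnorm(10)
    p_approx <- rank_sum_test(a, b)$p_two_sided  # n = 20 -> approx branch
    p_exact <- suppressWarnings(
      wilcox.test(a, b, exact = TRUE)$p.value)
    abs(p_approx - p_exact)
  }, numeric(1))
  expect_lt(max(devs), 0.02)
})

test_that("exact-branch type-I error stays near nominal", {
  set.seed(2024)
  rejections <- vapply(1:2000, function(i) {
    rank_sum_test(rnorm(6), rnorm(6))$p_two_sided < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.06)
})

test_that("significance tiers reproduce the reporting thresholds", {
  expect_equal(significance_tier(0.05), "ns")   # boundary is ns
  expect_equal(significance_tier(0.2), "ns")
  expect_equal(significance_tier(0.03), "*")
  expect_equal(significance_tier(0.01), "*")
  expect_equal(significance_tier(0.005), "**")
  expect_equal(significance_tier(0.001), "**")
  expect_equal(significance_tier(0.0009), "***")
  expect_error(significance_tier(1.2), "0, 1")
  expect_error(significance_tier(-0.1), "0, 1")
})

test_that("box summaries follow the quartile/whisker convention", {
  b <- box_summary(1:5)
  expect_equal(b$q50, 3)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 5)
  expect_length(b$outliers, 0)
  b2 <- box_summary(c(1, 2, 3, 4, 100))
  expect_equal(b2$outliers, 100)
  expect_equal(b2$whisker_high, 4)
  b3 <- box_summary(7)
  expect_true(all(c(b3$q25, b3$q50, b3$q75, b3$whisker_low,
                    b3$whisker_high) == 7))
  expect_true(b3$q25 <= b3$q50 && b3$q50 <= b3$q75)
  expect_error(box_summary(numeric(0)), "nonempty")
})

test_that("the fragment filter removes exactly near-clone fragments", {
  tis <- fragment_fixture()
  clones <- extract_clones(tis, min_cells = 10)
  expect_length(clones, 3)
  res <- filter_fragments(clones, min_cells = 10, fragment_max_cells = 10,
                          proximity_um = 20)
  removed_sizes <- vapply(res$removed, function(x) x$n_cells, numeric(1))
  kept_sizes <- vapply(res$kept, function(x) x$n_cells, numeric(1))
  expect_equal(removed_sizes, 3)          # only the near fragment goes
  expect_setequal(kept_sizes, c(12, 3))   # big clone and isolated group stay
  expect_equal(res$removed[[1]]$removal_reason, "fragment")
  # disabled filter removes nothing
  res0 <- filter_fragments(clones, fragment_max_cells = 0)
  expect_length(res0$removed, 0)
  # clones at or above min_cells are never removed as fragments
  res_all <- filter_fragments(clones, min_cells = 10,
                              fragment_max_cells = 10, proximity_um = 1e6)
  expect_false(any(vapply(res_all$removed, function(x) x$n_cells >= 10,
                          logical(1))))
})

test_that("the min_cells gate flags small clones for shape statistics", {
  tis <- fragment_fixture()
  clones <- extract_clones(tis, min_cells = 10)
  gated <- vapply(clones, function(x) x$sub_threshold, logical(1))
  expect_equal(sum(!gated), 1)  # only the 12-cell clone is analyzable
  mt <- clone_metrics_table(tis, min_cells = 10)
  expect_true(all(is.na(mt$circularity[mt$sub_threshold])))
  expect_false(any(is.na(mt$circularity[!mt$sub_threshold & !mt$touches_border])))
})

test_that("area heatmaps clamp to the fixed scale deterministically", {
  tis <- fx_clonal_tissue()
  h1 <- render_area_heatmap(tis, pixel_size_um = 0.5)
  h2 <- render_area_heatmap(tis, pixel_size_um = 0.5)
  expect_identical(h1, h2)
  expect_equal(dim(h1), c(120, 120, 3))
  expect_error(render_area_heatmap(tis, scale = c(12, 0.2)), "hi > lo")
  # cells at/below lo and at/above hi map to the scale end colors
  small <- hex_lattice_tissue(4, 4, side_um = 0.2)   # areas ~0.1 um2 < lo
  hs <- render_area_heatmap(small, pixel_size_um = 0.05)
  big <- hex_lattice_tissue(4, 4, side_um = 4)       # areas ~41 um2 > hi
  hb <- render_area_heatmap(big, pixel_size_um = 0.5)
  pal <- grDevices::colorRampPalette(c("#67000D", "#D7301F", "#FC8D59",
                                       "#FEE08B", "#D9EF8B", "#A6D96A"))(64)
  lo_rgb <- as.numeric(grDevices::col2rgb(pal[1]) / 255)
  hi_rgb <- as.numeric(grDevices::col2rgb(pal[64]) / 255)
  expect_equal(as.numeric(hs[10, 10, ]), lo_rgb, tolerance = 1e-12)
  expect_equal(as.numeric(hb[20, 20, ]), hi_rgb, tolerance = 1e-12)
})
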