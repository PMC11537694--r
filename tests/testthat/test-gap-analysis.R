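test_that("the exclusion mask is the union of excluded classes and the road buffer", {
  g <- grid_spec(6, 6, 100)
  leg <- lulc_legend()
  vals <- matrix(leg[["field"]], 6, 6)
  vals[2, 2] <- leg[["town"]]
  vals[5, ] <- leg[["road"]]
  lulc <- categorical_layer(vals, g, legend = leg)

  expect_true(all(exclusion_mask(lulc)$values == 0))

  road_buf <- buffer_mask(lulc, leg[["road"]], 100)
  m <- exclusion_mask(lulc, excluded_codes = leg[["town"]], road_mask = road_buf)
  expect_equal(m$values[2, 2], 1)                                 # city excluded
  manual <- (vals == leg[["town"]]) | (road_buf$values == 1)      # cell-wise OR
  expect_equal(m$values, matrix(as.numeric(manual), 6, 6))

  expect_warning(exclusion_mask(lulc, excluded_codes = 99L), "ignored")
})

test_that("suitability classification applies the fixed bounds with upper-open top class", {
  g <- grid_spec(1, 8, 100)
  r <- continuous_layer(matrix(c(0.10, 0.249, 0.25, 0.30, 0.55, 0.90, 0.901, 0.95),
                               1, 8), g)
  cl <- classify_suitability(r)
  expect_equal(as.vector(cl$values), c(0, 0, 1, 1, 2, 2, 3, 3))

  mask <- categorical_layer(matrix(c(1, rep(0, 7)), 1, 8), g)
  clm <- classify_suitability(r, mask = mask)
  expect_equal(clm$values[1, 1], 0)

  expect_error(classify_suitability(continuous_layer(matrix(1.2, 1, 8), g)),
               "\\[0, 1\\]")
  expect_error(classify_suitability(r, thresholds = c(0.5, 0.4, 0.9)),
               "strictly increasing")
})

test_that("species hotspots cover the suitable classes and their areas add up", {
  g <- grid_spec(10, 10, 100)
  set.seed(2)
  r <- continuous_layer(matrix(runif(100), 10, 10), g)
  cl <- classify_suitability(r)
  hot <- species_hotspots(cl)
  expect_equal(sum(hot$values), sum(cl$values %in% 1:3))
  rep_cl <- area_report(cl)
  suitable_area <- sum(rep_cl$area_km2[rep_cl$category != "unsuitable"])
  expect_equal(layer_area(hot) * mean(hot$values), suitable_area)

  hot23 <- species_hotspots(cl, classes = c(2L, 3L))
  expect_equal(sum(hot23$values), sum(cl$values %in% 2:3))

  none <- classify_suitability(continuous_layer(matrix(0.1, 10, 10), g))
  expect_true(all(species_hotspots(none)$values == 0))
  one <- matrix(0.1, 10, 10); one[4, 7] <- 0.95
  expect_equal(sum(species_hotspots(
    classify_suitability(continuous_layer(one, g)))$values), 1)
})

test_that("the priority overlay realises all eight tiers and partitions the grid", {
  g <- grid_spec(2, 4, 100)
  me <- categorical_layer(matrix(c(0, 1, 0, 1, 0, 1, 0, 1), 2, 4), g)
  iv <- categorical_layer(matrix(c(0, 0, 1, 1, 0, 0, 1, 1), 2, 4), g)
  pa <- categorical_layer(matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 2, 4), g)
  pr <- overlay_priorities(me, iv, pa)
  expect_equal(as.vector(pr$values), c(0, 2, 1, 3, 7, 5, 4, 6))

  set.seed(11)
  me2 <- categorical_layer(matrix(rbinom(200, 1, 0.4), 10, 20), grid_spec(10, 20, 50))
  iv2 <- categorical_layer(matrix(rbinom(200, 1, 0.4), 10, 20), grid_spec(10, 20, 50))
  pa2 <- categorical_layer(matrix(rbinom(200, 1, 0.3), 10, 20), grid_spec(10, 20, 50))
  pr2 <- overlay_priorities(me2, iv2, pa2)
  rep2 <- area_report(pr2)
  expect_equal(sum(rep2$area_km2), layer_area(pr2))  # exact partition
  # over-protected audit: inside a PA and in neither hotspot set
  over <- pr2$values == 7
  expect_true(all(pa2$values[over] == 1))
  expect_true(all(me2$values[over] == 0))
  expect_true(all(iv2$values[over] == 0))
  # idempotent under re-overlay of its own inputs
  expect_identical(overlay_priorities(me2, iv2, pa2)$values, pr2$values)
})

test_that("area reports recompute printed-style percentages from areas", {
  rep <- area_report(c(core = 14764.14, outside_core = 7858.45),
                     reference = c(total = 144200))
  expect_equal(rep$pct, c(10.24, 5.45))
  expect_equal(rep$area_km2 / rep$reference_km2 * 100,
               c(10.23865, 5.449688), tolerance = 1e-5)
  rep0 <- area_report(c(empty = 0), reference = c(total = 100))
  expect_equal(rep0$area_km2, 0)
  expect_equal(rep0$pct, 0)
  expect_error(area_report(c(a = 1), reference = c(total = 0)), "> 0")
  # half-up rounding at the boundary
  expect_equal(round_half_up(27.305, 2), 27.31)
  expect_equal(round_half_up(2.675, 2), 2.68)
})

test_that("model agreement reports every candidate definition", {
  g <- grid_spec(2, 2, 100)
  a <- categorical_layer(matrix(c(1, 1, 0, 0), 2, 2), g)
  b <- categorical_layer(matrix(c(1, 0, 1, 0), 2, 2), g)
  ag <- model_agreement(a, b)
  expect_equal(ag$pct[ag$definition == "jaccard"], 33.33)
  expect_equal(ag$pct[ag$definition == "overlap_coefficient"], 50)
  expect_equal(ag$pct[ag$definition == "share_of_a"], 50)

  same <- model_agreement(a, a)
  expect_true(all(same$pct == 100))
  disj <- model_agreement(a, categorical_layer(matrix(c(0, 0, 1, 1), 2, 2), g))
  expect_equal(disj$pct[disj$definition == "jaccard"], 0)
  z <- categorical_layer(matrix(0, 2, 2), g)
  expect_warning(empty <- model_agreement(z, z), "undefined")
  expect_equal(nrow(empty), 0)
})

test_that("per-PA priority proportions bin at 25/75 with boundaries upward", {
  g <- grid_spec(10, 12, 100)
  pa <- matrix(0, 10, 12)
  pa[1:5, 1:4] <- 1    # 20 cells
  pa[1:6, 6:11] <- 2   # 36 cells
  pa[9:10, 1:2] <- 3   # 4 cells
  pa_l <- categorical_layer(pa, g)
  pr <- matrix(0, 10, 12)
  pr[1:5, 1:4] <- 6                # PA 1 fully core
  pr[1:3, 6:11] <- 5               # PA 2: 18/36 = 0.5
  pr[pa == 3] <- 7                 # PA 3 over-protected only
  pr[pa == 0] <- 2
  pr_l <- categorical_layer(pr, g, legend = priority_legend())
  act <- pa_actions(pr_l, pa_l)
  expect_equal(act$bin, c(">75%", "25-75%", "<25%"))
  expect_equal(act$proportion, c(1, 0.5, 0))

  # boundary proportions go to the higher bin
  pr2 <- pr; pr2[1:5, 1:4] <- 0; pr2[1:5, 1:3] <- 6  # 15/20 = 0.75
  act2 <- pa_actions(categorical_layer(pr2, g, legend = priority_legend()), pa_l)
  expect_equal(act2$bin[1], ">75%")
  pr3 <- pr; pr3[1:3, 6:11] <- 0; pr3[1:3, 6:8] <- 4  # 9/36 = 0.25
  act3 <- pa_actions(categorical_layer(pr3, g, legend = priority_legend()), pa_l)
  expect_equal(act3$bin[2], "25-75%")

  # a PA rasterizing to no cells is flagged and left unbinned
  expect_warning(act4 <- pa_actions(pr_l, pa_l, all_ids = 9L), "no grid cell")
  expect_true(is.na(act4$bin[act4$pa_id == 9]))
})

test_that("gap area counts model hotspot cells outside every PA", {
  g <- grid_spec(4, 4, 500)
  me <- categorical_layer(matrix(c(rep(1, 8), rep(0, 8)), 4, 4), g)
  iv <- categorical_layer(matrix(c(rep(0, 4), rep(1, 8), rep(0, 4)), 4, 4), g)
  pa <- categorical_layer(matrix(c(rep(1, 6), rep(0, 10)), 4, 4), g)
  pr <- overlay_priorities(me, iv, pa)
  n_gap <- sum(pr$values %in% 1:3)
  expect_equal(gap_area(pr, "cells"), n_gap)
  expect_equal(gap_area(pr, "km2"), n_gap * 0.25)
})
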