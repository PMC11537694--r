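test_that("decay kernels match the printed formulas and truncate at d_max", {
  expect_equal(decay_factor(0, 5, "linear"), 1)
  expect_equal(decay_factor(0, 5, "exponential"), 1)
  expect_equal(decay_factor(5, 5, "linear"), 0)
  expect_equal(decay_factor(5, 5, "exponential"), exp(-2.99))
  expect_equal(decay_factor(2.5, 5, "linear"), 0.5)
  expect_equal(decay_factor(1, 5, "exponential"), exp(-2.99 / 5))
  expect_equal(decay_factor(c(6, 100), 5, "exponential"), c(0, 0))
  expect_equal(decay_factor(c(6, 100), 5, "linear"), c(0, 0))
  expect_error(decay_factor(1, 0, "linear"), "> 0")
})

test_that("the study threat table is shipped as printed", {
  th <- default_threats()
  expect_equal(th$max_dist_km, c(5, 12, 10, 10, 8, 9))
  expect_equal(th$weight, c(0.3, 1.0, 0.9, 0.8, 0.7, 0.8))
  expect_equal(th$decay, c("linear", "exponential", "exponential", "linear",
                           "linear", "exponential"))
})

test_that("threat and sensitivity CSVs round-trip, with 'Index' read as exponential", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("THREAT,MAX_DIST_KM,WEIGHT,DECAY",
               "field,5,0.3,Linear", "town,12,1.0,Index"), tf)
  th <- read_threats(tf)
  expect_equal(th$decay, c("linear", "exponential"))

  sf <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(default_sensitivity(), sf)
  expect_equal(read_sensitivity(sf), default_sensitivity())
  expect_error(sensitivity_table(1, habitat = 1.2, field = 0.5), "\\[0, 1\\]")
})

test_that("degradation equals the naive quadruple-loop oracle", {
  for (n in c(5, 12, 30)) {
    f <- degr_fixture(n = n, seed = n)
    D <- degradation(f$lulc, f$th, list(a = f$t1, b = f$t2), f$sens)
    expect_equal(D$values, oracle_degradation(f$lulc, f$th,
                                              list(a = f$t1, b = f$t2), f$sens),
                 tolerance = 1e-10)
  }
})

test_that("degradation honours the unit, distance and normalization contracts", {
  g <- grid_spec(7, 7, 100)
  lulc <- categorical_layer(matrix(1, 7, 7), g)
  one <- matrix(0, 7, 7); one[4, 4] <- 1
  tl <- list(src = categorical_layer(one, g))
  th1 <- threat_table("src", 0.2, 1, "linear")
  sens1 <- sensitivity_table(1, habitat = 1, src = 1)
  D <- degradation(lulc, th1, tl, sens1)
  # at the threat cell itself: distance 0, all factors unity -> D = 1
  expect_equal(D$values[4, 4], 1)
  # farther than d_max from the single threat -> 0
  expect_equal(D$values[1, 1], 0)

  # additive over disjoint threat-cell sets
  a <- matrix(0, 7, 7); a[2, 2] <- 1
  b <- matrix(0, 7, 7); b[6, 6] <- 1
  Da <- degradation(lulc, th1, list(src = categorical_layer(a, g)), sens1)
  Db <- degradation(lulc, th1, list(src = categorical_layer(b, g)), sens1)
  Dab <- degradation(lulc, th1, list(src = categorical_layer(a + b, g)), sens1)
  expect_equal(Dab$values, Da$values + Db$values, tolerance = 1e-12)

  # doubling all weights changes nothing (normalized by their sum)
  f <- degr_fixture()
  th2 <- f$th; th2$weight <- th2$weight * 2
  expect_equal(degradation(f$lulc, f$th, list(a = f$t1, b = f$t2), f$sens)$values,
               degradation(f$lulc, th2, list(a = f$t1, b = f$t2), f$sens)$values)

  # accessibility multiplies degradation cell-wise
  beta <- continuous_layer(matrix(0.5, 7, 7), g)
  Dhalf <- degradation(lulc, th1, tl, sens1, habitat_config(accessibility = beta))
  expect_equal(Dhalf$values, D$values * 0.5)

  # unknown land-use code is a named error
  bad <- categorical_layer(matrix(rep(c(1, 3), length.out = 49), 7, 7), g)
  expect_error(degradation(bad, th1, tl, sens1), "3")
})

test_that("quality obeys the half-saturation identities and monotonicity", {
  g <- grid_spec(1, 5, 100)
  cfg <- habitat_config(z = 2.5, k = 0.5)
  lulc <- categorical_layer(matrix(c(1, 1, 1, 1, 2), 1, 5), g)
  sens <- sensitivity_table(1:2, habitat = c(0.8, 0), src = c(1, 1))
  D <- continuous_layer(matrix(c(0, 0.5, 2, 10, 0), 1, 5), g)
  Q <- habitat_quality(D, lulc, sens, cfg)
  expect_equal(Q$values[1, 1], 0.8)          # D = 0 -> Q = H
  expect_equal(Q$values[1, 2], 0.4)          # D = k -> Q = H/2
  expect_equal(Q$values[1, 5], 0)            # H = 0 -> Q = 0
  expect_true(all(diff(Q$values[1, 1:4]) < 0))  # monotone non-increasing in D
  expect_true(all(Q$values <= 0.8 + 1e-12))

  # monotone over a dense D grid, any z, k
  for (z in c(1, 2.5)) for (k in c(0.2, 0.5, 2)) {
    d <- seq(0, 5, length.out = 200)
    q <- 0.7 * (1 - d^z / (d^z + k^z))
    Dg <- continuous_layer(matrix(d, 1, 200), grid_spec(1, 200, 100))
    lg <- categorical_layer(matrix(1, 1, 200), grid_spec(1, 200, 100))
    Qg <- habitat_quality(Dg, lg, sensitivity_table(1, habitat = 0.7, src = 1),
                          habitat_config(z = z, k = k))
    expect_equal(as.vector(Qg$values), q)
    expect_true(all(diff(as.vector(Qg$values)) <= 0))
  }
})

test_that("quality hotspots follow the configured binarization rule", {
  g <- grid_spec(10, 10, 100)
  set.seed(4)
  Q <- continuous_layer(matrix(runif(100), 10, 10), g)
  hs <- quality_hotspots(Q, method = "quantile", q = 0.5)
  expect_lte(abs(sum(hs$values) - 50), 1)
  hs25 <- quality_hotspots(Q, method = "quantile", q = 0.25)
  expect_lte(abs(sum(hs25$values) - 25), 1)
  # hotspot area matches a direct count at the applied threshold
  thr <- quantile(Q$values, 0.75, names = FALSE)
  expect_equal(sum(hs25$values), sum(Q$values >= thr))

  fixed <- quality_hotspots(continuous_layer(matrix(c(0.2, 0.95), 10, 10), g),
                            method = "fixed", cut = 0.9)
  expect_equal(fixed$values, matrix(as.numeric(c(0.2, 0.95) >= 0.9), 10, 10))

  expect_warning(zz <- quality_hotspots(continuous_layer(matrix(1, 10, 10), g)),
                 "degenerate")
  expect_true(all(zz$values == 0))
})
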