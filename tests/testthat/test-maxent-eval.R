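test_that("AUC equals the pairwise ordering oracle and handles ties", {
  expect_equal(auc_score(c(3, 4, 5), c(0, 1, 2)), 1)
  expect_equal(auc_score(rep(2, 10), rep(2, 15)), 0.5)
  for (seed in 1:5) {
    set.seed(seed)
    pos <- sample(1:20, 30, TRUE)  # heavy ties on purpose
    neg <- sample(1:20, 50, TRUE)
    expect_identical(auc_score(pos, neg), oracle_auc(pos, neg))
  }
  set.seed(99)
  pos <- rnorm(100, 1); neg <- rnorm(100)
  expect_equal(auc_score(pos, neg), oracle_auc(pos, neg))
  expect_error(auc_score(numeric(), 1:3), "at least one")
})

sc_eval <- landscape_scenario(n_covariates = 4, n_species = 1,
                              species_weights = list(c(cov1 = 2, cov2 = 1)),
                              n_presences = 200, seed = 31)

test_that("replicate split evaluation reports per-replicate and mean AUCs", {
  covs <- gen_covariates(sc_eval)
  occ <- gen_occurrences(sc_eval, covs)
  m <- fit_maxent(occ, covs, rm = 1.1, seed = 4)
  ev <- evaluate_maxent(m, occ, covs, split = 0.75, replicates = 4, seed = 8)
  expect_equal(nrow(ev$replicates), 4)
  expect_true(all(ev$replicates$n_train + ev$replicates$n_test ==
                    ev$replicates$n_train[1] + ev$replicates$n_test[1]))
  expect_equal(ev$auc_test_mean, mean(ev$replicates$auc_test))
  expect_true(all(ev$replicates$auc_train >= 0 & ev$replicates$auc_train <= 1))
  # signal is strong: test AUC well above chance
  expect_gt(ev$auc_test_mean, 0.8)
  # k-fold alternative partitions the presences
  evk <- evaluate_maxent(m, occ, covs, replicates = 4, seed = 8, kfold = TRUE)
  expect_equal(sum(evk$replicates$n_test), m$n_presence)
  expect_named(glance(ev), c("replicates", "split", "kfold",
                             "auc_train_mean", "auc_test_mean"))
  expect_error(evaluate_maxent(m, occ[1:4, ], covs, split = 0.99, replicates = 1),
               "test set empty|at least 5")
})

test_that("variable importance singles out the informative covariate", {
  covs <- gen_covariates(sc_eval)
  occ <- gen_occurrences(sc_eval, covs)
  m <- fit_maxent(occ, covs, rm = 1.1, seed = 4)
  vi <- variable_importance(m, covs, seed = 6)
  expect_equal(sum(vi$contribution), 100, tolerance = 0.1)
  expect_equal(sum(vi$permutation), 100, tolerance = 0.1)
  expect_equal(vi$variable[which.max(vi$permutation)], "cov1")
  # jackknife: the strongest variable alone out-gains the others alone,
  # and removing it hurts more than removing a noise variable
  expect_equal(vi$variable[which.max(vi$jackknife_only)], "cov1")
  expect_lt(vi$jackknife_without[vi$variable == "cov1"],
            vi$jackknife_without[vi$variable == "cov3"])
})

test_that("permuting a constant covariate has zero importance", {
  sc <- landscape_scenario(n_covariates = 2, n_species = 1,
                           species_weights = list(c(cov1 = 2)),
                           n_presences = 200, seed = 13)
  covs <- gen_covariates(sc)
  covs$flat <- continuous_layer(matrix(0, 100, 100), covs$cov1$grid)
  occ <- gen_occurrences(sc, covs[1:2])
  m <- fit_maxent(occ, covs, rm = 1.1, seed = 4)
  vi <- variable_importance(m, covs, seed = 6, components = "permutation")
  expect_equal(vi$permutation[vi$variable == "flat"], 0)
})

test_that("single-variable models report jackknife without-gain as absent", {
  sc1 <- landscape_scenario(n_covariates = 1, n_species = 1,
                            species_weights = list(c(cov1 = 2)),
                            n_presences = 100, seed = 17)
  covs <- gen_covariates(sc1)
  occ <- gen_occurrences(sc1, covs)
  m <- fit_maxent(occ, covs, rm = 1.1, seed = 4)
  vi <- variable_importance(m, covs, seed = 6, components = "jackknife")
  expect_true(is.na(vi$jackknife_without))
})

test_that("richness aggregation min-max normalizes then averages", {
  g <- tiny_grid()
  a <- continuous_layer(matrix(c(0, 1, 2, 3, 4, 5, 6, 7, 8), 3, 3), g)
  # single map: its own normalization
  r1 <- aggregate_richness(list(a))
  expect_equal(r1$values, (a$values - 0) / 8)
  # two identical maps: unchanged
  expect_equal(aggregate_richness(list(a, a))$values, r1$values)
  # disjoint hotspots: maxima 0.5 at each
  b1 <- continuous_layer(matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3), g)
  b2 <- continuous_layer(matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 1), 3, 3), g)
  r2 <- aggregate_richness(list(b1, b2))
  expect_equal(r2$values[1, 1], 0.5)
  expect_equal(r2$values[3, 3], 0.5)
  expect_equal(max(r2$values), 0.5)
  # constant map degenerates to zero with a warning
  expect_warning(r3 <- aggregate_richness(list(continuous_layer(matrix(2, 3, 3), g))),
                 "degenerate")
  expect_true(all(r3$values == 0))
})

test_that("training-presence threshold excludes exactly the lowest fraction", {
  pred <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9)
  thr <- training_presence_threshold(pred, level = 0.10)
  expect_equal(thr, 0.05)
  expect_equal(mean(pred < thr), 0)        # conservative: 10th percentile kept
  thr2 <- training_presence_threshold(pred, level = 0.20)
  expect_equal(mean(pred >= thr2), 0.9)
  g <- tiny_grid()
  s <- continuous_layer(matrix(seq(0.1, 0.9, 0.1), 3, 3), g)
  mask <- binarize_suitability(s, c(5L, 6L, 9L), level = 0)
  expect_equal(sum(mask$values), sum(s$values >= min(s$values[c(5, 6, 9)])))
  u <- hotspot_union(list(mask, mask))
  expect_identical(u$values, mask$values)
})
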