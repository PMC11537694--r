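#' Rank-based AUC for presence vs background scores
#'
#' The probability that a randomly chosen presence scores above a randomly
#' chosen background point, ties counting one half — identical to the
#' Mann-Whitney statistic and to the fraction of correctly ordered
#' (presence, background) pairs.
#'
#' @param pos scores at presences
#' @param neg scores at background points
#' @return AUC in [0, 1]
#' @export
auc_score <- function(pos, neg) {
  abort_if(length(pos) == 0 || length(neg) == 0,
           "AUC needs at least one presence and one background score")
  r <- rank(c(pos, neg))
  m <- length(pos)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(neg))
}

#' Validate a maxent model by replicate train/test splits
#'
#' Repeats the study protocol: each replicate draws a random
#' `split`/`1 - split` partition of the presences, refits the model on the
#' training part with the same features, background and regularization, and
#' scores rank-based AUC (presences vs the full background) on both parts.
#' Replicates are independent random splits ("repeated split-sample"); set
#' `kfold = TRUE` for disjoint k-fold test sets instead.
#'
#' @param model a fitted `maxent_model` (supplies features, rm, background)
#' @param presences presence records or cell indices, as in [fit_maxent()]
#' @param env named list of covariate layers
#' @param split training fraction in (0, 1); study default 0.75
#' @param replicates number of replicates (>= 1); study default 4
#' @param seed integer seed controlling the splits
#' @param kfold use `replicates`-fold cross-validation instead of
#'   independent splits (then `split` is ignored)
#' @return a `maxent_evaluation`: list with `replicates` (tibble of
#'   per-replicate `auc_train`, `auc_test`), `auc_train_mean`,
#'   `auc_test_mean`
#' @export
evaluate_maxent <- function(model, presences, env, split = 0.75, replicates = 4,
                            seed = 1, kfold = FALSE) {
  abort_if(split <= 0 || split >= 1, "split must be in (0, 1)")
  abort_if(replicates < 1, "replicates must be >= 1")
  grid <- do.call(check_same_grid, unname(env))
  pc <- if (is.data.frame(presences)) {
    unique(stats::na.omit(points_to_cells(grid, presences$x, presences$y)))
  } else unique(as.integer(presences))
  m <- length(pc)
  bg_eta <- maxent_eta(model, env, model$bg_cells)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(child_seed(seed, 0))
  folds <- if (kfold) sample(rep_len(seq_len(replicates), m)) else NULL

  rows <- lapply(seq_len(replicates), function(i) {
    if (kfold) {
      test <- pc[folds == i]; train <- pc[folds != i]
    } else {
      set.seed(child_seed(seed, i))
      n_train <- round(split * m)
      tr_idx <- sample(m, n_train)
      train <- pc[tr_idx]; test <- pc[-tr_idx]
    }
    abort_if(length(test) == 0, "test set empty after split; use more presences")
    fit <- fit_maxent(train, env, background = model$bg_cells, rm = model$rm,
                      feature_classes = model$spec$classes, seed = model$seed)
    bg_eta_i <- maxent_eta(fit, env, model$bg_cells)
    tibble::tibble(
      replicate = i, n_train = length(train), n_test = length(test),
      auc_train = auc_score(maxent_eta(fit, env, train), bg_eta_i),
      auc_test = auc_score(maxent_eta(fit, env, test), bg_eta_i)
    )
  })
  rep_tbl <- dplyr::bind_rows(rows)
  structure(list(replicates = rep_tbl,
                 auc_train_mean = mean(rep_tbl$auc_train),
                 auc_test_mean = mean(rep_tbl$auc_test),
                 split = split, kfold = kfold, seed = seed),
            class = "maxent_evaluation")
}

#' @export
print.maxent_evaluation <- function(x, ...) {
  cat(sprintf("<maxent_evaluation> %d replicates (%s)\n", nrow(x$replicates),
              if (x$kfold) "k-fold" else sprintf("%.0f/%.0f split", 100 * x$split,
                                                 100 * (1 - x$split))))
  cat(sprintf("  mean training AUC: %.3f, mean test AUC: %.3f\n",
              x$auc_train_mean, x$auc_test_mean))
  invisible(x)
}

#' Variable importance for a fitted maxent model
#'
#' Three complementary views per covariate: *percent contribution* (share of
#' penalized-objective improvement credited to each variable's features
#' along the optimization path — solver-dependent, as in the original
#' maxent), *permutation importance* (drop in training AUC after permuting
#' one covariate's values across the evaluation cells, normalized to sum to
#' 100 — solver-invariant), and *jackknife gains* (training gain of a model
#' with only that variable, and of one without it). Product features credit
#' half to each parent variable.
#'
#' @param model a fitted `maxent_model`
#' @param env named list of covariate layers
#' @param seed seed for the permutations
#' @param components any of `"contribution"`, `"permutation"`, `"jackknife"`
#' @return tibble with one row per variable: `contribution` and
#'   `permutation` (percentages summing to 100 each), `jackknife_only`,
#'   `jackknife_without` (`NA` for a single-variable model)
#' @export
variable_importance <- function(model, env, seed = 1,
                                components = c("contribution", "permutation",
                                               "jackknife")) {
  components <- match.arg(components, several.ok = TRUE)
  vars <- model$spec$vars
  out <- tibble::tibble(variable = vars)

  if ("contribution" %in% components) {
    cr <- stats::setNames(rep(0, length(vars)), vars)
    for (j in seq_along(model$spec$features)) {
      f <- model$spec$features[[j]]
      cr[f$vars] <- cr[f$vars] + model$credit[j] / length(f$vars)
    }
    out$contribution <- if (sum(cr) > 0) 100 * cr / sum(cr) else rep(0, length(vars))
  }

  if ("permutation" %in% components) {
    cells <- c(model$presence_cells, model$bg_cells)
    is_pos <- seq_along(cells) <= length(model$presence_cells)
    X <- env_matrix(env, cells)
    eta0 <- drop(feature_matrix(model$spec, X) %*% model$lambda)
    auc0 <- auc_score(eta0[is_pos], eta0[!is_pos])
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    drops <- vapply(seq_along(vars), function(k) {
      set.seed(child_seed(seed, k))
      Xp <- X
      Xp[, k] <- sample(Xp[, k])
      eta <- drop(feature_matrix(model$spec, Xp) %*% model$lambda)
      max(0, auc0 - auc_score(eta[is_pos], eta[!is_pos]))
    }, numeric(1))
    out$permutation <- if (sum(drops) > 0) 100 * drops / sum(drops)
                       else rep(0, length(vars))
  }

  if ("jackknife" %in% components) {
    refit_gain <- function(keep_vars) {
      fit_maxent(model$presence_cells, env[keep_vars],
                 background = model$bg_cells, rm = model$rm,
                 feature_classes = model$spec$classes, seed = model$seed)$gain
    }
    out$jackknife_only <- vapply(vars, function(v) refit_gain(v), numeric(1))
    out$jackknife_without <- if (length(vars) == 1) NA_real_ else
      vapply(vars, function(v) refit_gain(setdiff(vars, v)), numeric(1))
  }
  out
}

#' Aggregate per-species suitability into a richness surface
#'
#' Each species map is min-max normalized to [0, 1] over its valid cells and
#' the normalized maps are averaged cell-wise with equal weights, giving the
#' predicted species-richness surface. A constant map cannot be normalized
#' and contributes zeros (with a warning).
#'
#' @param maps list of `pm_continuous` suitability layers on one grid
#' @return a `pm_continuous` richness layer with values in [0, 1]
#' @export
aggregate_richness <- function(maps) {
  abort_if(length(maps) < 1, "need at least one map")
  g <- do.call(check_same_grid, unname(maps))
  norm <- lapply(maps, function(m) {
    v <- m$values
    rng <- range(v, na.rm = TRUE)
    if (diff(rng) == 0) {
      warning("constant suitability map: normalization degenerate, mapped to 0")
      v[!is.na(v)] <- 0
    } else {
      v <- (v - rng[1]) / diff(rng)
    }
    v
  })
  continuous_layer(Reduce(`+`, norm) / length(norm), g)
}

#' Suitability threshold at a training-presence percentile
#'
#' The conservative cut-off under which a given fraction of training
#' presences falls — the "10% training presence" rule uses `level = 0.10`:
#' the threshold excludes the 10% of presences with the lowest predicted
#' suitability.
#'
#' @param pred_at_presences predicted suitability at the training presences
#' @param level fraction of presences allowed below the threshold
#' @return the threshold value
#' @export
training_presence_threshold <- function(pred_at_presences, level = 0.10) {
  abort_if(length(pred_at_presences) == 0, "no presence predictions given")
  unname(stats::quantile(pred_at_presences, probs = level, type = 1))
}

#' Binarize a suitability map at its training-presence threshold
#'
#' Marks every cell whose suitability is at or above the species'
#' training-presence threshold ([training_presence_threshold()] at the given
#' presences). This self-calibrating rule decides each species' hotspot
#' participation; the fixed four-class bounds apply to the aggregated
#' richness surface instead.
#'
#' @param map `pm_continuous` suitability layer
#' @param presences presence records (tibble with `x`, `y`) or cell indices
#' @param level training-presence fraction allowed below the threshold
#'   (default 0.10)
#' @return binary `pm_categorical` layer (1 = at or above threshold)
#' @export
binarize_suitability <- function(map, presences, level = 0.10) {
  cells <- if (is.data.frame(presences)) {
    stats::na.omit(points_to_cells(map$grid, presences$x, presences$y))
  } else as.integer(presences)
  thr <- training_presence_threshold(map$values[cells], level = level)
  v <- map$values
  out <- matrix(NA_real_, map$grid$n_rows, map$grid$n_cols)
  ok <- !is.na(v)
  out[ok] <- as.numeric(v[ok] >= thr)
  categorical_layer(out, map$grid)
}

#' Union of per-species hotspot masks
#'
#' @param masks list of binary `pm_categorical` layers on one grid
#' @return binary `pm_categorical` layer, 1 where any input is 1
#' @export
hotspot_union <- function(masks) {
  abort_if(length(masks) < 1, "need at least one mask")
  g <- do.call(check_same_grid, unname(masks))
  acc <- matrix(0, g$n_rows, g$n_cols)
  na_all <- matrix(TRUE, g$n_rows, g$n_cols)
  for (m in masks) {
    acc <- acc + ifelse(is.na(m$values), 0, m$values)
    na_all <- na_all & is.na(m$values)
  }
  out <- ifelse(na_all, NA_real_, as.numeric(acc > 0))
  categorical_layer(out, g)
}
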