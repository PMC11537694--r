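#' @keywords internal
#' Feature expansion for the maxent model.
#'
#' Covariates are standardized over the background sample; features are
#' linear (the standardized covariate), quadratic (its square) and product
#' (pairwise products of standardized covariates), then each feature column
#' is itself standardized over the background so that one regularization
#' scale is comparable across classes.
make_feature_spec <- function(vars, classes = c("linear", "quadratic", "product")) {
  feats <- list()
  if ("linear" %in% classes) {
    for (v in vars) feats[[length(feats) + 1]] <- list(name = v, kind = "linear", vars = v)
  }
  if ("quadratic" %in% classes) {
    for (v in vars) feats[[length(feats) + 1]] <-
      list(name = paste0(v, "^2"), kind = "quadratic", vars = v)
  }
  if ("product" %in% classes && length(vars) > 1) {
    cmb <- utils::combn(vars, 2)
    for (k in seq_len(ncol(cmb))) feats[[length(feats) + 1]] <-
      list(name = paste0(cmb[1, k], ":", cmb[2, k]), kind = "product", vars = cmb[, k])
  }
  list(vars = vars, classes = classes, features = feats,
       feature_names = vapply(feats, `[[`, "", "name"))
}

# raw covariate matrix (cells x vars) -> feature matrix per spec;
# standardization constants must already be present in spec
feature_matrix <- function(spec, X) {
  Z <- sweep(sweep(X[, spec$vars, drop = FALSE], 2, spec$cov_mean, "-"),
             2, spec$cov_sd, "/")
  F <- matrix(0, nrow(Z), length(spec$features))
  for (j in seq_along(spec$features)) {
    f <- spec$features[[j]]
    F[, j] <- switch(f$kind,
      linear = Z[, f$vars],
      quadratic = Z[, f$vars]^2,
      product = Z[, f$vars[1]] * Z[, f$vars[2]])
  }
  F <- sweep(sweep(F, 2, spec$f_mean, "-"), 2, spec$f_sd, "/")
  colnames(F) <- spec$feature_names
  F
}

# covariate values at given cells, as a cells x vars matrix
env_matrix <- function(env, cells) {
  vapply(env, function(l) l$values[cells], numeric(length(cells)))
}

valid_cells <- function(env) {
  ok <- !is.na(env[[1]]$values)
  for (l in env[-1]) ok <- ok & !is.na(l$values)
  which(ok)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit a regularized maximum-entropy species distribution model
#'
#' Estimates the Gibbs distribution over landscape cells that maximizes the
#' L1-penalized log-likelihood of the presences relative to a background
#' sample: the objective is the regularized training gain
#' `mean(eta_presence) - log mean(exp(eta_background)) - rm * sum_j beta_j |lambda_j|`
#' with linear/quadratic/product features of the standardized covariates and
#' per-feature penalty scales `beta_j = sd_j(presence features) / sqrt(m)`
#' (the classic variance-based maxent scaling). Optimization is by monotone
#' proximal gradient descent with backtracking, so the penalized objective is
#' non-increasing across iterations; the fit is deterministic given the data
#' and `seed`.
#'
#' @param presences occurrence records for one species: a tibble with
#'   `x`, `y` (a `species` column, if present, must hold a single species),
#'   or an integer vector of cell indices
#' @param env named list of `pm_continuous` covariate layers on one grid
#' @param background background cells representing available environment:
#'   either a target count (default 10000; sampled uniformly from valid
#'   cells with `seed`, or all valid cells if fewer) or an explicit integer
#'   vector of cell indices. Background may include presence cells.
#' @param rm regularization multiplier (> 0); the study default is 1.1
#' @param feature_classes subset of `c("linear", "quadratic", "product")`
#' @param seed integer seed for background sampling
#' @param tol relative objective-change convergence tolerance (default 1e-6)
#' @param max_iter maximum optimizer iterations (default 500); failure to
#'   converge is an error carrying the objective trace
#' @return a `maxent_model` with elements `lambda` (named weights), `spec`
#'   (feature expansion + standardization constants), `gain` (training gain),
#'   `gain_reg` (penalized gain), `entropy` (of the fitted background
#'   distribution), `trace` (per-iteration penalized objective), `bg_cells`,
#'   `presence_cells`, and fitting metadata
#' @export
fit_maxent <- function(presences, env, background = 10000, rm = 1.1,
                       feature_classes = c("linear", "quadratic", "product"),
                       seed = 1, tol = 1e-6, max_iter = 500) {
  abort_if(rm <= 0, "rm must be > 0")
  grid <- do.call(check_same_grid, unname(env))
  vc <- valid_cells(env)

  if (is.data.frame(presences)) {
    if ("species" %in% names(presences)) {
      abort_if(length(unique(presences$species)) > 1,
               "fit_maxent models one species at a time")
    }
    pc <- points_to_cells(grid, presences$x, presences$y)
    pc <- pc[!is.na(pc) & pc %in% vc]
  } else {
    pc <- as.integer(presences)
  }
  pc <- unique(pc)
  abort_if(length(pc) < 5, "need at least 5 presence cells inside the valid grid")

  if (length(background) == 1 && is.numeric(background) && is.null(dim(background))) {
    n_bg <- min(as.integer(background), length(vc))
    if (n_bg < length(vc)) {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
      bg <- sort(sample(vc, n_bg))
    } else bg <- vc
  } else {
    bg <- as.integer(background)
  }

  spec <- make_feature_spec(names(env), feature_classes)
  Xb <- env_matrix(env, bg)
  Xp <- env_matrix(env, pc)
  spec$cov_mean <- colMeans(Xb)
  spec$cov_sd <- pmax(apply(Xb, 2, stats::sd), 1e-12)
  # feature standardization constants from the unstandardized feature build
  spec$f_mean <- rep(0, length(spec$features))
  spec$f_sd <- rep(1, length(spec$features))
  Fb_raw <- feature_matrix(spec, Xb)
  spec$f_mean <- colMeans(Fb_raw)
  spec$f_sd <- pmax(apply(Fb_raw, 2, stats::sd), 1e-12)
  Fb <- sweep(sweep(Fb_raw, 2, spec$f_mean, "-"), 2, spec$f_sd, "/")
  Fp <- feature_matrix(spec, Xp)

  m <- length(pc)
  p <- ncol(Fb)
  if (m < p) warning("fewer presences than features; relying on L1 shrinkage")
  beta <- rm * pmax(apply(Fp, 2, stats::sd), 0.05) / sqrt(m)
  fbar <- colMeans(Fp)

  smooth_obj <- function(lam) {
    eta <- drop(Fb %*% lam)
    -sum(fbar * lam) + log_sum_exp(eta) - log(length(bg))
  }
  smooth_grad <- function(lam) {
    eta <- drop(Fb %*% lam)
    w <- exp(eta - max(eta)); w <- w / sum(w)
    -fbar + drop(crossprod(Fb, w))
  }
  penalty <- function(lam) sum(beta * abs(lam))
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

  lam <- rep(0, p)
  lam_prev <- lam
  f_cur <- smooth_obj(lam)
  obj_cur <- f_cur + penalty(lam)
  trace <- obj_cur
  credit <- rep(0, p)
  step <- 1
  tk <- 1
  converged <- FALSE
  prox_step <- function(base, g_base) {
    # backtracking proximal step from `base`; returns candidate and its
    # smooth objective, shrinking `step` until sufficient decrease holds
    repeat {
      cand <- soft(base - step * g_base, step * beta)
      d <- cand - base
      f_cand <- smooth_obj(cand)
      f_base <- smooth_obj(base)
      if (f_cand <= f_base + sum(g_base * d) + sum(d^2) / (2 * step) + 1e-12) {
        return(list(cand = cand, f = f_cand))
      }
      step <<- step / 2
      abort_if(step < 1e-14, "line search failed: step underflow")
    }
  }
  for (it in seq_len(max_iter)) {
    # accelerated (momentum) candidate, accepted only if it decreases the
    # objective; otherwise a plain proximal step keeps the trace monotone
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- lam + ((tk - 1) / tk_new) * (lam - lam_prev)
    ps <- prox_step(y, smooth_grad(y))
    obj_new <- ps$f + penalty(ps$cand)
    if (obj_new > obj_cur) {
      tk_new <- 1  # momentum restart
      g <- smooth_grad(lam)
      ps <- prox_step(lam, g)
      obj_new <- ps$f + penalty(ps$cand)
    } else {
      g <- smooth_grad(lam)
    }
    if (obj_new > obj_cur) { converged <- TRUE; break }  # at the numeric floor
    impr <- obj_cur - obj_new
    share <- abs(ps$cand - lam) * abs(g)
    if (sum(share) > 0) credit <- credit + impr * share / sum(share)
    lam_prev <- lam
    lam <- ps$cand
    tk <- tk_new
    rel <- impr / max(abs(obj_cur), 1e-12)
    obj_cur <- obj_new
    trace <- c(trace, obj_cur)
    step <- step * 1.2
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged && it == max_iter) {
    cond <- structure(
      class = c("priormap_nonconvergence", "error", "condition"),
      list(message = sprintf("maxent optimizer did not converge in %d iterations (last objective %.8g)",
                             max_iter, obj_cur),
           call = NULL, objective_trace = trace))
    stop(cond)
  }

  eta_bg <- drop(Fb %*% lam)
  pr <- exp(eta_bg - log_sum_exp(eta_bg))
  entropy <- -sum(ifelse(pr > 0, pr * log(pr), 0))

  structure(list(
    lambda = stats::setNames(lam, spec$feature_names),
    spec = spec, rm = rm, beta = beta,
    gain = sum(fbar * lam) - (log_sum_exp(eta_bg) - log(length(bg))),
    gain_reg = -obj_cur,
    entropy = entropy,
    trace = trace, credit = stats::setNames(credit, spec$feature_names),
    bg_cells = bg, presence_cells = pc,
    n_presence = m, n_background = length(bg),
    seed = seed, converged = converged, iterations = length(trace) - 1
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d features (%d non-zero), rm = %g\n",
              length(x$lambda), sum(x$lambda != 0), x$rm))
  cat(sprintf("  presences: %d, background: %d, gain: %.4f (regularized %.4f)\n",
              x$n_presence, x$n_background, x$gain, x$gain_reg))
  invisible(x)
}

# linear predictor at given cells
maxent_eta <- function(model, env, cells) {
  missing <- setdiff(model$spec$vars, names(env))
  abort_if(length(missing) > 0,
           paste0("covariate(s) missing from env: ", paste(missing, collapse = ", ")))
  drop(feature_matrix(model$spec, env_matrix(env, cells)) %*% model$lambda)
}

#' Predict habitat suitability from a fitted maxent model
#'
#' `raw` is the fitted Gibbs density normalized over the model's background
#' cells; `logistic` (the default) is the conventional bounded output
#' `c*raw / (1 + c*raw)` with `c = exp(H)`, `H` the entropy of the fitted
#' background distribution, which places a typical cell at 0.5 prevalence
#' and is strictly increasing in the linear predictor.
#'
#' @param object a `maxent_model`
#' @param env named list of covariate layers matching the training variables
#' @param type `"logistic"`, `"raw"`, or `"link"` (the linear predictor)
#' @param ... unused
#' @return a `pm_continuous` suitability layer; logistic values lie in [0, 1]
#' @export
predict.maxent_model <- function(object, env, type = c("logistic", "raw", "link"), ...) {
  type <- match.arg(type)
  grid <- do.call(check_same_grid, unname(env))
  vc <- valid_cells(env)
  eta <- maxent_eta(object, env, vc)
  logZ <- log_sum_exp(maxent_eta(object, env, object$bg_cells))
  out <- switch(type,
    link = eta,
    raw = exp(eta - logZ),
    logistic = {
      raw <- exp(eta - logZ)
      s <- exp(object$entropy) * raw
      s / (1 + s)
    })
  vals <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  vals[vc] <- out
  continuous_layer(vals, grid)
}
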