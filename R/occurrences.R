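#' Spatially thin occurrence records
#'
#' Two-stage filter against spatial autocorrelation and pseudo-replication:
#' exact duplicate locations of the same species are removed first (the first
#' record wins), then a greedy pass in input order keeps a record only if
#' fewer than `max_per_neighborhood` already-kept records of the same species
#' lie within `min_dist` of it. Input (file) order is the canonical scan
#' order, so the result is deterministic for a fixed input. Thinning is per
#' species by default.
#'
#' @param occ tibble with `species`, `x`, `y`
#' @param min_dist neighborhood radius in map units (> 0); distances are
#'   Euclidean, "within" means `<= min_dist`
#' @param max_per_neighborhood maximum kept records per neighborhood disk
#'   (>= 1); the default 2 realises a "fewer than three within the radius"
#'   rule
#' @param by_species thin each species independently (default) or all
#'   records jointly
#' @return the retained subset, same columns, input order preserved
#' @export
thin_occurrences <- function(occ, min_dist, max_per_neighborhood = 2,
                             by_species = TRUE) {
  abort_if(min_dist <= 0, "min_dist must be > 0")
  abort_if(max_per_neighborhood < 1, "max_per_neighborhood must be >= 1")
  if (nrow(occ) == 0) return(occ)
  occ$.ord <- seq_len(nrow(occ))
  thin_one <- function(d) {
    d <- d[!duplicated(d[, c("species", "x", "y")]), , drop = FALSE]
    keep <- logical(nrow(d))
    kx <- ky <- numeric(0)
    for (i in seq_len(nrow(d))) {
      n_near <- if (length(kx)) {
        sum((kx - d$x[i])^2 + (ky - d$y[i])^2 <= min_dist^2)
      } else 0
      if (n_near < max_per_neighborhood) {
        keep[i] <- TRUE
        kx <- c(kx, d$x[i]); ky <- c(ky, d$y[i])
      }
    }
    d[keep, , drop = FALSE]
  }
  out <- if (by_species) {
    dplyr::bind_rows(lapply(split(occ, occ$species), thin_one))
  } else {
    thin_one(occ)
  }
  out <- out[order(out$.ord), , drop = FALSE]
  out$.ord <- NULL
  tibble::as_tibble(out)
}

#' Pairwise Pearson correlation between environmental layers
#'
#' Correlations are computed over cells that are valid (non-nodata) in every
#' layer; when more than `sample_cells` such cells exist, a fixed-seed random
#' sample keeps the computation bounded and reproducible. A constant layer
#' has undefined correlations; these are reported as 0 and flagged.
#'
#' @param env named list of `pm_continuous` layers (>= 2) on one grid
#' @param sample_cells cap on the number of cells used (default 100000)
#' @param seed sampling seed (default 42)
#' @return symmetric correlation matrix with unit diagonal; attribute
#'   `constant` names any constant layers whose correlations were set to 0
#' @export
pearson_matrix <- function(env, sample_cells = 100000, seed = 42) {
  abort_if(length(env) < 2, "need at least two layers")
  do.call(check_same_grid, unname(env))
  vals <- vapply(env, function(l) as.vector(l$values),
                 numeric(length(env[[1]]$values)))
  ok <- rowSums(is.na(vals)) == 0
  idx <- which(ok)
  if (length(idx) > sample_cells) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    idx <- sort(sample(idx, sample_cells))
  }
  m <- vals[idx, , drop = FALSE]
  const <- apply(m, 2, function(v) stats::sd(v) == 0)
  r <- suppressWarnings(stats::cor(m))
  if (any(const)) {
    warning("constant layer(s): ", paste(colnames(m)[const], collapse = ", "),
            "; correlations reported as 0")
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  dimnames(r) <- list(names(env), names(env))
  attr(r, "constant") <- names(env)[const]
  r
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Decorrelate variables by iterative pairwise elimination
#'
#' While any kept pair has `|r|` above the threshold, the pair with the
#' largest `|r|` is resolved by dropping its lower-scored member (scores are
#' any per-variable ranking, e.g. univariate model gain); score ties are
#' broken by input order, first wins. The result is guaranteed to contain no
#' pair with `|r|` above the threshold.
#'
#' @param r_matrix symmetric correlation matrix with named dimensions
#' @param scores named numeric ranking covering all variables
#' @param threshold drop threshold on `|r|` (default 0.8: pairs with
#'   `|r| > 0.8` are resolved)
#' @return list with `kept` (ordered character vector) and `dropped`
#'   (tibble `name`, `partner`, `r` recording each elimination)
#' @export
select_variables <- function(r_matrix, scores, threshold = 0.8) {
  vars <- rownames(r_matrix)
  abort_if(is.null(vars), "r_matrix must have named dimensions")
  abort_if(!all(vars %in% names(scores)), "scores must cover all variables")
  scores <- scores[vars]
  kept <- vars
  dropped <- list()
  repeat {
    r <- abs(r_matrix[kept, kept, drop = FALSE])
    diag(r) <- 0
    if (max(r) <= threshold) break
    ij <- which(r == max(r), arr.ind = TRUE)[1, ]
    a <- kept[ij[1]]; b <- kept[ij[2]]
    # lower score is dropped; tie -> the later-in-input-order variable drops
    loser <- if (scores[a] < scores[b]) a
             else if (scores[b] < scores[a]) b
             else kept[max(ij)]
    winner <- setdiff(c(a, b), loser)
    dropped[[length(dropped) + 1]] <- tibble::tibble(
      name = loser, partner = winner, r = r_matrix[loser, winner])
    kept <- setdiff(kept, loser)
  }
  list(kept = kept,
       dropped = if (length(dropped)) dplyr::bind_rows(dropped)
                 else tibble::tibble(name = character(), partner = character(),
                                     r = numeric()))
}
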