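# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's fast paths: plain loops, direct formula evaluation.

# point-in-polygon rasterization by per-cell even-odd ray casting, one cell
# at a time (later polygons win)
oracle_rasterize <- function(polys, grid) {
  out <- matrix(0, grid$n_rows, grid$n_cols)
  cc <- cell_centers(grid)
  for (k in seq_len(nrow(polys))) {
    rings <- polys$geometry[[k]]
    for (i in seq_len(nrow(cc))) {
      inside <- FALSE
      for (r in rings) {
        n <- nrow(r) - 1
        hit <- FALSE
        for (e in seq_len(n)) {
          y1 <- r[e, 2]; y2 <- r[e + 1, 2]
          if ((y1 > cc$y[i]) != (y2 > cc$y[i])) {
            xint <- r[e, 1] + (cc$y[i] - y1) * (r[e + 1, 1] - r[e, 1]) / (y2 - y1)
            if (cc$x[i] < xint) hit <- !hit
          }
        }
        inside <- xor(inside, hit)
      }
      if (inside) out[cc$row[i], cc$col[i]] <- polys$id[k]
    }
  }
  out
}

# buffer by direct distance scan between every cell pair
oracle_buffer <- function(layer, target_codes, radius) {
  g <- layer$grid
  cc <- cell_centers(g)
  src <- which(!is.na(layer$values) & layer$values %in% target_codes)
  out <- matrix(0, g$n_rows, g$n_cols)
  for (i in seq_len(nrow(cc))) {
    for (s in src) {
      d2 <- (cc$x[i] - cc$x[s])^2 + (cc$y[i] - cc$y[s])^2
      if (d2 <= radius^2) { out[cc$row[i], cc$col[i]] <- 1; break }
    }
  }
  out
}

# two-pass covariance Pearson correlation
oracle_pearson <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# AUC as the fraction of correctly ordered (presence, background) pairs
oracle_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# quadruple-loop degradation: cells x threats x threat cells, raw formula
oracle_degradation <- function(lulc, threats, threat_layers, sens) {
  g <- lulc$grid
  cc <- cell_centers(g)
  w <- threats$weight / sum(threats$weight)
  out <- matrix(0, g$n_rows, g$n_cols)
  for (x in seq_len(nrow(cc))) {
    j <- lulc$values[x]
    if (is.na(j)) { out[x] <- NA; next }
    for (i in seq_len(nrow(threats))) {
      tl <- threat_layers[[threats$threat[i]]]
      s <- sens[[threats$threat[i]]][match(j, sens$lulc_code)]
      dmax <- threats$max_dist_km[i] * 1000
      for (y in seq_len(nrow(cc))) {
        if (!is.na(tl$values[y]) && tl$values[y] == 1) {
          d <- sqrt((cc$x[x] - cc$x[y])^2 + (cc$y[x] - cc$y[y])^2)
          out[x] <- out[x] + w[i] * decay_factor(d, dmax, threats$decay[i]) * s
        }
      }
    }
  }
  out
}

# a small random two-threat landscape for degradation checks
degr_fixture <- function(n = 5, seed = 9, cell = 100) {
  g <- grid_spec(n, n, cell)
  set.seed(seed)
  list(
    g = g,
    lulc = categorical_layer(matrix(sample(1:2, n^2, TRUE), n, n), g),
    t1 = categorical_layer(matrix(rbinom(n^2, 1, 0.15), n, n), g),
    t2 = categorical_layer(matrix(rbinom(n^2, 1, 0.15), n, n), g),
    th = threat_table(c("a", "b"), c(0.25, 0.3), c(0.3, 0.7),
                      c("linear", "exponential")),
    sens = sensitivity_table(1:2, habitat = c(0.5, 1),
                             a = c(0.4, 0.9), b = c(0.2, 0.8))
  )
}

# small standard fixtures
tiny_grid <- function(n = 3, cell = 30) grid_spec(n, n, cell)

random_continuous <- function(grid, seed = 1) {
  set.seed(seed)
  continuous_layer(matrix(rnorm(grid$n_rows * grid$n_cols),
                          grid$n_rows, grid$n_cols), grid)
}
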