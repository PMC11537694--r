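#' Distance-decay factor of a threat
#'
#' Linear decline `1 - d/d_max` or exponential decline `exp(-2.99 d / d_max)`;
#' both are clamped to 0 beyond `d_max` so every threat has compact support
#' (the exponential form alone never reaches zero). The constant 2.99 makes
#' the exponential kernel fall to about 5% (`exp(-2.99)`) at the maximum
#' influence distance.
#'
#' @param d distance(s) from the threat cell, same units as `d_max` (>= 0)
#' @param d_max maximum influence distance (> 0)
#' @param kind `"linear"` or `"exponential"`
#' @return decay factor(s) in [0, 1]
#' @export
decay_factor <- function(d, d_max, kind = c("linear", "exponential")) {
  kind <- match.arg(kind)
  abort_if(d_max <= 0, "d_max must be > 0")
  abort_if(any(d < 0), "distances must be >= 0")
  out <- switch(kind,
    linear = pmax(0, 1 - d / d_max),
    exponential = exp(-2.99 * d / d_max))
  ifelse(d > d_max, 0, out)
}

#' Threat-source parameter table
#'
#' One row per threat: maximum influence distance (km), weight in [0, 1],
#' and decay kind (`"linear"` or `"exponential"`). [default_threats()] ships
#' the study parameterization for the six threat sources.
#'
#' @param threat character threat names
#' @param max_dist_km maximum influence distance in km (> 0)
#' @param weight relative threat weight in [0, 1]
#' @param decay `"linear"` or `"exponential"` per threat
#' @return tibble with columns `threat`, `max_dist_km`, `weight`, `decay`
#' @export
threat_table <- function(threat, max_dist_km, weight, decay) {
  abort_if(any(max_dist_km <= 0), "max_dist_km must be > 0")
  abort_if(any(weight < 0 | weight > 1), "weights must lie in [0, 1]")
  abort_if(!all(decay %in% c("linear", "exponential")),
           "decay must be 'linear' or 'exponential'")
  tibble::tibble(threat = as.character(threat), max_dist_km = max_dist_km,
                 weight = weight, decay = decay)
}

#' @rdname threat_table
#' @export
default_threats <- function() {
  threat_table(
    threat = c("field", "town", "village", "road", "railway", "mine"),
    max_dist_km = c(5, 12, 10, 10, 8, 9),
    weight = c(0.3, 1.0, 0.9, 0.8, 0.7, 0.8),
    decay = c("linear", "exponential", "exponential", "linear", "linear",
              "exponential")
  )
}

#' Read a threat table from CSV
#'
#' Columns `THREAT, MAX_DIST_KM, WEIGHT, DECAY` (case-insensitive); `DECAY`
#' accepts `linear`/`exponential` or the shorthand `index` for exponential.
#'
#' @param path CSV path
#' @return a [threat_table()] tibble
#' @export
read_threats <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  names(d) <- tolower(names(d))
  abort_if(!all(c("threat", "max_dist_km", "weight", "decay") %in% names(d)),
           "threat CSV needs columns THREAT, MAX_DIST_KM, WEIGHT, DECAY")
  dec <- tolower(d$decay)
  dec[dec == "index"] <- "exponential"
  threat_table(d$threat, d$max_dist_km, d$weight, dec)
}

#' Habitat suitability and sensitivity table
#'
#' Per land-use class: intrinsic habitat suitability `habitat` in [0, 1] and
#' one sensitivity column per threat, also in [0, 1]. Every code in the LULC
#' legend must be present. [default_sensitivity()] ships an illustrative
#' synthetic parameterization for the legend of [gen_lulc()] — it is not a
#' field-calibrated table.
#'
#' @param lulc_code integer land-use codes
#' @param habitat habitat suitability per code, in [0, 1]
#' @param ... one numeric sensitivity column per threat, named by threat
#' @return tibble with `lulc_code`, `habitat`, sensitivity columns
#' @export
sensitivity_table <- function(lulc_code, habitat, ...) {
  sens <- tibble::tibble(...)
  vals <- c(habitat, unlist(sens))
  abort_if(any(vals < 0 | vals > 1), "habitat and sensitivities must lie in [0, 1]")
  tibble::tibble(lulc_code = as.integer(lulc_code), habitat = habitat, sens)
}

#' @rdname sensitivity_table
#' @export
default_sensitivity <- function() {
  # synthetic defaults for legend 1 field, 2 grassland, 3 wetland, 4 water,
  # 5 town, 6 village, 7 road, 8 railway, 9 mine: natural classes are good
  # habitat and threat-sensitive, built classes are non-habitat
  sensitivity_table(
    lulc_code = 1:9,
    habitat = c(0.3, 0.8, 1.0, 0.9, 0.0, 0.0, 0.0, 0.0, 0.0),
    field   = c(0.0, 0.5, 0.7, 0.5, 0.0, 0.0, 0.0, 0.0, 0.0),
    town    = c(0.4, 0.8, 0.9, 0.7, 0.0, 0.0, 0.0, 0.0, 0.0),
    village = c(0.3, 0.7, 0.8, 0.6, 0.0, 0.0, 0.0, 0.0, 0.0),
    road    = c(0.2, 0.6, 0.7, 0.5, 0.0, 0.0, 0.0, 0.0, 0.0),
    railway = c(0.2, 0.5, 0.6, 0.4, 0.0, 0.0, 0.0, 0.0, 0.0),
    mine    = c(0.3, 0.7, 0.9, 0.8, 0.0, 0.0, 0.0, 0.0, 0.0)
  )
}

#' Read a sensitivity table from CSV
#'
#' Columns `LULC_CODE, HABITAT`, then one column per threat
#' (case-insensitive).
#'
#' @param path CSV path
#' @return a [sensitivity_table()] tibble
#' @export
read_sensitivity <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  names(d) <- tolower(names(d))
  abort_if(!all(c("lulc_code", "habitat") %in% names(d)),
           "sensitivity CSV needs columns LULC_CODE, HABITAT, then one per threat")
  do.call(sensitivity_table,
          c(list(lulc_code = d$lulc_code, habitat = d$habitat),
            as.list(d[setdiff(names(d), c("lulc_code", "habitat"))])))
}

#' Habitat-quality model configuration
#'
#' @param z scale (shape) exponent of the half-saturation transform (> 0)
#' @param k half-saturation constant: the degradation level at which quality
#'   halves (> 0)
#' @param accessibility optional `pm_continuous` layer of accessibility
#'   multipliers in [0, 1]; default 1 everywhere
#' @return a `habitat_config` list
#' @export
habitat_config <- function(z = 2.5, k = 0.5, accessibility = NULL) {
  abort_if(z <= 0, "z must be > 0")
  abort_if(k <= 0, "k must be > 0")
  structure(list(z = z, k = k, accessibility = accessibility),
            class = "habitat_config")
}

#' Derive binary threat-presence layers from a land-use map
#'
#' @param lulc a `pm_categorical` land-use layer
#' @param codes named list mapping threat name -> land-use code(s)
#' @return named list of binary `pm_categorical` layers (1 = threat present)
#' @export
threat_layers_from_lulc <- function(lulc, codes) {
  lapply(codes, function(cd) {
    v <- matrix(0, lulc$grid$n_rows, lulc$grid$n_cols)
    v[!is.na(lulc$values) & lulc$values %in% cd] <- 1
    categorical_layer(v, lulc$grid)
  })
}

# decay kernel as a dense offset matrix for one threat; distances between
# cell centers in map units, compact support at d_max
decay_kernel <- function(cell_size, d_max, kind) {
  rmax <- floor(d_max / cell_size)
  off <- (-rmax):rmax
  d <- sqrt(outer(off^2, off^2, "+")) * cell_size
  k <- matrix(decay_factor(as.vector(d), d_max, kind), nrow = length(off))
  k
}

# sum of kernel values contributed by all source cells, by shifting the
# kernel patch onto an accumulator; exact, not an approximation
accumulate_kernel <- function(src, kernel) {
  nr <- nrow(src); nc <- ncol(src)
  rmax <- (nrow(kernel) - 1) / 2
  acc <- matrix(0, nr, nc)
  idx <- which(src == 1, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    r0 <- idx[k, 1]; c0 <- idx[k, 2]
    r1 <- max(1, r0 - rmax); r2 <- min(nr, r0 + rmax)
    c1 <- max(1, c0 - rmax); c2 <- min(nc, c0 + rmax)
    acc[r1:r2, c1:c2] <- acc[r1:r2, c1:c2] +
      kernel[(r1 - r0 + rmax + 1):(r2 - r0 + rmax + 1),
             (c1 - c0 + rmax + 1):(c2 - c0 + rmax + 1)]
  }
  acc
}

#' Habitat degradation from weighted distance-decayed threats
#'
#' For every cell `x` with land-use class `j`, degradation is the sum over
#' threats `r` and threat cells `y` within the threat's maximum influence
#' distance of `(W_r / sum(W)) * i_rxy * beta_x * S_jr`, where `i_rxy` is the
#' distance-decay factor ([decay_factor()]), `beta_x` the accessibility and
#' `S_jr` the class sensitivity. The kernel accumulation is exact (equals
#' the naive sum over all threat cells). Weights enter only through their
#' normalized form, so rescaling all weights leaves degradation unchanged.
#'
#' @param lulc `pm_categorical` land-use layer
#' @param threats a [threat_table()]
#' @param threat_layers named list of binary presence layers, one per row of
#'   `threats` (names must match `threats$threat`)
#' @param sens a [sensitivity_table()] covering every land-use code present
#' @param cfg a [habitat_config()]
#' @return a `pm_continuous` degradation layer (`NA` where land use is `NA`)
#' @export
degradation <- function(lulc, threats, threat_layers, sens,
                        cfg = habitat_config()) {
  abort_if(!all(threats$threat %in% names(threat_layers)),
           "threat_layers must cover every threat in the table")
  do.call(check_same_grid, c(list(lulc), unname(threat_layers[threats$threat])))
  g <- lulc$grid
  codes <- unique(lulc$values[!is.na(lulc$values)])
  unknown <- setdiff(codes, sens$lulc_code)
  abort_if(length(unknown) > 0,
           paste0("land-use code(s) missing from sensitivity table: ",
                  paste(sort(unknown), collapse = ", ")))
  w <- threats$weight / sum(threats$weight)
  D <- matrix(0, g$n_rows, g$n_cols)
  for (i in seq_len(nrow(threats))) {
    tl <- threat_layers[[threats$threat[i]]]
    src <- !is.na(tl$values) & tl$values == 1
    if (!any(src)) next
    kern <- decay_kernel(g$cell_size, threats$max_dist_km[i] * 1000,
                         threats$decay[i])
    infl <- accumulate_kernel(src * 1, kern)
    # sensitivity of each cell's land-use class to this threat
    s_col <- sens[[threats$threat[i]]]
    abort_if(is.null(s_col),
             paste0("sensitivity table lacks a column for threat: ",
                    threats$threat[i]))
    s_map <- matrix(s_col[match(lulc$values, sens$lulc_code)],
                    g$n_rows, g$n_cols)
    s_map[is.na(s_map)] <- 0
    D <- D + w[i] * infl * s_map
  }
  if (!is.null(cfg$accessibility)) {
    check_same_grid(lulc, cfg$accessibility)
    D <- D * cfg$accessibility$values
  }
  D[is.na(lulc$values)] <- NA
  continuous_layer(D, g)
}

#' Habitat quality from degradation
#'
#' `Q = H_j * (1 - D^z / (D^z + k^z))`: quality equals the class suitability
#' `H_j` where degradation is zero, halves where `D = k`, and decreases
#' monotonically in `D`. Classes with `H_j = 0` (built-up classes) have zero
#' quality regardless of degradation.
#'
#' @param D `pm_continuous` degradation layer from [degradation()]
#' @param lulc `pm_categorical` land-use layer
#' @param sens a [sensitivity_table()]
#' @param cfg a [habitat_config()] supplying `z` and `k`
#' @return a `pm_continuous` quality layer, `Q` in `[0, H_j]`
#' @export
habitat_quality <- function(D, lulc, sens, cfg = habitat_config()) {
  check_same_grid(D, lulc)
  h <- sens$habitat[match(lulc$values, sens$lulc_code)]
  h <- matrix(h, lulc$grid$n_rows, lulc$grid$n_cols)
  dz <- D$values^cfg$z
  q <- h * (1 - dz / (dz + cfg$k^cfg$z))
  q[is.na(lulc$values) | is.na(D$values)] <- NA
  continuous_layer(q, lulc$grid)
}

#' Binarize a quality map into habitat hotspots
#'
#' The study never states its binarization rule; the default marks the top
#' quartile of valid cells, configurable either as another quantile or as a
#' fixed quality cut.
#'
#' @param Q `pm_continuous` quality layer
#' @param method `"quantile"` (top fraction `q`) or `"fixed"` (cells with
#'   `Q >= cut`)
#' @param q top fraction for the quantile rule (default 0.25)
#' @param cut fixed threshold for the fixed rule
#' @return binary `pm_categorical` layer (1 = hotspot)
#' @export
quality_hotspots <- function(Q, method = c("quantile", "fixed"), q = 0.25,
                             cut = NULL) {
  method <- match.arg(method)
  v <- Q$values
  valid <- !is.na(v)
  out <- matrix(NA_real_, Q$grid$n_rows, Q$grid$n_cols)
  out[valid] <- 0
  if (method == "quantile") {
    vv <- v[valid]
    if (length(unique(vv)) <= 1) {
      warning("degenerate quality map (all values equal): no hotspots marked")
      return(categorical_layer(out, Q$grid))
    }
    thr <- stats::quantile(vv, probs = 1 - q, names = FALSE)
    out[valid & v >= thr] <- 1
  } else {
    abort_if(is.null(cut), "fixed rule needs a cut value")
    out[valid & v >= cut] <- 1
  }
  categorical_layer(out, Q$grid)
}
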