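#' Define a synthetic landscape scenario
#'
#' A scenario fixes everything the generator needs: grid shape, covariate
#' autocorrelation, the land-use mosaic, the true species-environment
#' models, and the protected-area placement rule. The same seed always
#' produces the identical landscape, and the scenario round-trips through
#' JSON. The default desk-scale grid is 100 x 100 cells of 100 m (a 10 x 10
#' km landscape) so every oracle and end-to-end check runs in seconds; the
#' 30-m regional working resolution of real applications is a documented
#' rescaling of `cell_size`, not a requirement of any test.
#'
#' @param n_rows,n_cols grid dimensions
#' @param cell_size cell edge in map units (meters)
#' @param n_covariates number of environmental covariate fields
#' @param cor_range spatial autocorrelation range of the fields, in cells
#'   (Gaussian smoothing scale; 0 gives white noise)
#' @param forced_pair optional `list(from=, to=, r=)` forcing covariate `to`
#'   to correlate with covariate `from` at about `r`, to exercise variable
#'   selection
#' @param lulc_mixture named class mixture over the base land-use classes
#'   (must sum to 1); linear road/railway features and mine patches are
#'   drawn on top
#' @param n_roads,n_railways number of linear transport features
#' @param n_mines number of 2x2 mine patches
#' @param n_species number of simulated species
#' @param species_weights list (length `n_species`) of named true covariate
#'   weights; default gives each species a two-covariate signal with weights
#'   2 and 1 on a rotating covariate pair
#' @param n_presences presence records per species
#' @param pa_fraction fraction of true hotspot cells that protected areas
#'   must cover (gaps exist by construction when < 1)
#' @param pa_halfwidth half-width of placed square PAs, in cells
#' @param seed master seed; all generator stages derive child seeds from it
#' @return a `landscape_scenario` list
#' @export
landscape_scenario <- function(n_rows = 100, n_cols = 100, cell_size = 100,
                               n_covariates = 4, cor_range = 8,
                               forced_pair = NULL,
                               lulc_mixture = c(field = 0.45, grassland = 0.22,
                                                wetland = 0.15, water = 0.08,
                                                town = 0.04, village = 0.06),
                               n_roads = 1, n_railways = 1, n_mines = 3,
                               n_species = 3, species_weights = NULL,
                               n_presences = 300,
                               pa_fraction = 0.6, pa_halfwidth = 3,
                               seed = 1) {
  abort_if(abs(sum(lulc_mixture) - 1) > 1e-6, "lulc_mixture must sum to 1")
  abort_if(pa_fraction < 0 || pa_fraction > 1, "pa_fraction must lie in [0, 1]")
  if (is.null(species_weights)) {
    species_weights <- lapply(seq_len(n_species), function(s) {
      a <- ((s - 1) %% n_covariates) + 1
      b <- (s %% n_covariates) + 1
      stats::setNames(c(2, 1), paste0("cov", c(a, b)))
    })
  }
  structure(list(
    n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
    n_covariates = n_covariates, cor_range = cor_range,
    forced_pair = forced_pair, lulc_mixture = as.list(lulc_mixture),
    n_roads = n_roads, n_railways = n_railways, n_mines = n_mines,
    n_species = n_species,
    species_weights = lapply(species_weights, as.list),
    n_presences = n_presences, pa_fraction = pa_fraction,
    pa_halfwidth = pa_halfwidth, seed = seed
  ), class = "landscape_scenario")
}

#' Serialize a scenario to JSON and back
#'
#' A scenario is fully serializable: writing and re-reading it yields a
#' scenario that generates the identical landscape.
#'
#' @param scenario a [landscape_scenario()]
#' @param path JSON file path
#' @return `write_scenario()`: `path`, invisibly; `read_scenario()`: the
#'   scenario
#' @export
write_scenario <- function(scenario, path) {
  jsonlite::write_json(unclass(scenario), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  sc <- jsonlite::read_json(path, simplifyVector = FALSE)
  sc$lulc_mixture <- lapply(sc$lulc_mixture, as.numeric)
  sc$species_weights <- lapply(sc$species_weights, function(w) lapply(w, as.numeric))
  if (length(sc$forced_pair) == 0) sc$forced_pair <- NULL
  num <- c("n_rows", "n_cols", "cell_size", "n_covariates", "cor_range",
           "n_roads", "n_railways", "n_mines", "n_species", "n_presences",
           "pa_fraction", "pa_halfwidth", "seed")
  for (f in intersect(num, names(sc))) sc[[f]] <- as.numeric(sc[[f]])
  structure(sc, class = "landscape_scenario")
}

#' Land-use legend of the synthetic mosaic
#' @return named integer vector label -> code
#' @export
lulc_legend <- function() {
  c(field = 1L, grassland = 2L, wetland = 3L, water = 4L, town = 5L,
    village = 6L, road = 7L, railway = 8L, mine = 9L)
}

scenario_grid <- function(sc) {
  grid_spec(sc$n_rows, sc$n_cols, sc$cell_size)
}

# spatially autocorrelated standard-normal field: white noise convolved with
# a Gaussian kernel on the torus (FFT), then standardized. Kernel smoothing
# of white noise, not a full geostatistical simulation — sufficient for the
# autocorrelation contract of the generator.
smooth_field <- function(n_rows, n_cols, sigma) {
  w <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (sigma <= 0) return((w - mean(w)) / stats::sd(w))
  dr <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  dc <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  kern <- exp(-outer(dr^2, dc^2, "+") / (2 * sigma^2))
  f <- Re(stats::fft(stats::fft(w) * stats::fft(kern), inverse = TRUE)) /
    (n_rows * n_cols)
  (f - mean(f)) / stats::sd(f)
}

#' Generate autocorrelated covariate layers
#'
#' @param scenario a [landscape_scenario()]
#' @return named list `cov1..covK` of standardized `pm_continuous` layers;
#'   when `forced_pair` is set, the target layer is rebuilt as
#'   `r * source + sqrt(1 - r^2) * independent field`
#' @export
gen_covariates <- function(scenario) {
  g <- scenario_grid(scenario)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  fields <- lapply(seq_len(scenario$n_covariates), function(i) {
    set.seed(child_seed(scenario$seed, 100 + i))
    smooth_field(g$n_rows, g$n_cols, scenario$cor_range)
  })
  fp <- scenario$forced_pair
  if (!is.null(fp)) {
    set.seed(child_seed(scenario$seed, 199))
    eps <- smooth_field(g$n_rows, g$n_cols, scenario$cor_range)
    v <- fp$r * fields[[fp$from]] + sqrt(1 - fp$r^2) * eps
    fields[[fp$to]] <- (v - mean(v)) / stats::sd(v)
  }
  stats::setNames(lapply(fields, continuous_layer, grid = g),
                  paste0("cov", seq_len(scenario$n_covariates)))
}

# a 1-cell-wide connected line across the grid: random-walk row per column
draw_line <- function(vals, code, n_rows, n_cols) {
  r <- sample(n_rows, 1)
  for (cl in seq_len(n_cols)) {
    r <- min(max(r + sample(-1:1, 1), 1), n_rows)
    vals[r, cl] <- code
  }
  vals
}

#' Generate the land-use mosaic
#'
#' Base classes are assigned by quantile-thresholding a latent
#' autocorrelated field so observed class frequencies match the requested
#' mixture (to within the footprint of the overlaid features); linear road
#' and railway features and small mine patches are then drawn on top.
#'
#' @param scenario a [landscape_scenario()]
#' @param covariates unused placeholder kept for pipeline symmetry
#' @return a `pm_categorical` layer with the [lulc_legend()]
#' @export
gen_lulc <- function(scenario, covariates = NULL) {
  g <- scenario_grid(scenario)
  leg <- lulc_legend()
  mix <- unlist(scenario$lulc_mixture)
  abort_if(abs(sum(mix) - 1) > 1e-6, "lulc_mixture must sum to 1")
  abort_if(!all(names(mix) %in% names(leg)),
           "lulc_mixture classes must be in the legend")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(child_seed(scenario$seed, 200))
  latent <- smooth_field(g$n_rows, g$n_cols, scenario$cor_range)
  cuts <- stats::quantile(latent, probs = cumsum(mix), names = FALSE)
  cuts[length(cuts)] <- Inf
  vals <- matrix(leg[names(mix)][1], g$n_rows, g$n_cols)
  for (k in seq_along(mix)[-1]) {
    vals[latent > cuts[k - 1]] <- leg[names(mix)[k]]
  }
  for (i in seq_len(scenario$n_roads %||% 0)) {
    vals <- draw_line(vals, leg[["road"]], g$n_rows, g$n_cols)
  }
  for (i in seq_len(scenario$n_railways %||% 0)) {
    vals <- draw_line(vals, leg[["railway"]], g$n_rows, g$n_cols)
  }
  for (i in seq_len(scenario$n_mines %||% 0)) {
    r <- sample(g$n_rows - 1, 1); cl <- sample(g$n_cols - 1, 1)
    vals[r:(r + 1), cl:(cl + 1)] <- leg[["mine"]]
  }
  categorical_layer(vals, g, legend = leg)
}

# maxent-style bounded suitability from a linear predictor over all cells
eta_to_suitability <- function(eta, grid) {
  raw <- exp(eta - log_sum_exp(eta))
  H <- -sum(raw * log(raw))
  s <- exp(H) * raw
  continuous_layer(matrix(s / (1 + s), grid$n_rows, grid$n_cols), grid)
}

#' Sample species occurrences from known suitability surfaces
#'
#' For each species, presence cells are drawn without replacement with
#' probability proportional to `exp(true weights . covariates)` (the Gibbs
#' density the maxent model assumes), and records are placed at cell
#' centers. The true suitability surfaces are attached as attribute
#' `truth` (one bounded suitability layer per species) for oracle
#' comparisons.
#'
#' @param scenario a [landscape_scenario()]
#' @param covariates output of [gen_covariates()]
#' @return occurrence tibble (`species`, `x`, `y`, `source`) with attribute
#'   `truth`
#' @export
gen_occurrences <- function(scenario, covariates) {
  g <- scenario_grid(scenario)
  cc <- cell_centers(g)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  out <- list(); truth <- list()
  for (s in seq_len(scenario$n_species)) {
    w <- unlist(scenario$species_weights[[s]])
    eta <- rep(0, nrow(cc))
    for (v in names(w)) eta <- eta + w[[v]] * as.vector(covariates[[v]]$values)
    pr <- exp(eta - log_sum_exp(eta))
    n <- min(scenario$n_presences, sum(pr > 0))
    if (n < scenario$n_presences) {
      warning(sprintf("species %d: only %d cells available (%d requested)",
                      s, n, scenario$n_presences))
    }
    set.seed(child_seed(scenario$seed, 300 + s))
    cells <- sample(nrow(cc), n, prob = pr)
    sp <- paste0("sp", s)
    out[[s]] <- tibble::tibble(species = sp, x = cc$x[cells], y = cc$y[cells],
                               source = "synthetic")
    truth[[sp]] <- eta_to_suitability(eta, g)
  }
  occ <- dplyr::bind_rows(out)
  attr(occ, "truth") <- truth
  occ
}

#' Place protected areas covering a fraction of true hotspot cells
#'
#' Square PAs (side `2 * pa_halfwidth + 1` cells) are seeded on randomly
#' ordered hotspot cells and accepted while they do not overshoot the
#' coverage target; single-cell PAs then top coverage up to exactly
#' `round(pa_fraction * n_hotspot_cells)` covered hotspot cells. The
#' uncovered hotspot cells are conservation gaps by construction.
#'
#' @param scenario a [landscape_scenario()]
#' @param hotspot_truth binary `pm_categorical` layer of true hotspot cells
#' @return a `pm_polygons` set (possibly empty when `pa_fraction = 0`);
#'   attribute `covered_cells` records the achieved coverage
#' @export
gen_pas <- function(scenario, hotspot_truth) {
  g <- hotspot_truth$grid
  hot <- !is.na(hotspot_truth$values) & hotspot_truth$values == 1
  n_hot <- sum(hot)
  target <- round(scenario$pa_fraction * n_hot)
  rects <- list()
  covered <- matrix(FALSE, g$n_rows, g$n_cols)
  if (target > 0 && n_hot > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(child_seed(scenario$seed, 500))
    h <- scenario$pa_halfwidth
    seeds <- which(hot)
    seeds <- seeds[sample(length(seeds))]
    for (cell in seeds) {
      if (sum(covered & hot) >= target) break
      r0 <- (cell - 1) %% g$n_rows + 1
      c0 <- (cell - 1) %/% g$n_rows + 1
      if (covered[r0, c0]) next
      r1 <- max(1, r0 - h); r2 <- min(g$n_rows, r0 + h)
      c1 <- max(1, c0 - h); c2 <- min(g$n_cols, c0 + h)
      block <- matrix(FALSE, g$n_rows, g$n_cols)
      block[r1:r2, c1:c2] <- TRUE
      gain <- sum(block & hot & !covered)
      if (sum(covered & hot) + gain <= target) {
        covered <- covered | block
        rects[[length(rects) + 1]] <- c(r1, r2, c1, c2)
      }
    }
    # exact top-up with single-cell reserves
    for (cell in seeds) {
      if (sum(covered & hot) >= target) break
      r0 <- (cell - 1) %% g$n_rows + 1
      c0 <- (cell - 1) %/% g$n_rows + 1
      if (covered[r0, c0]) next
      covered[r0, c0] <- TRUE
      rects[[length(rects) + 1]] <- c(r0, r0, c0, c0)
    }
  }
  achieved <- sum(covered & hot)
  if (n_hot > 0 && achieved < target) {
    warning(sprintf("requested coverage %d hotspot cells, achieved %d",
                    target, achieved))
  }
  geoms <- lapply(rects, function(rc) {
    rect_ring(g$origin_x + (rc[3] - 1) * g$cell_size,
              g$origin_y - rc[2] * g$cell_size,
              g$origin_x + rc[4] * g$cell_size,
              g$origin_y - (rc[1] - 1) * g$cell_size)
  })
  pas <- if (length(geoms)) {
    polygon_set(id = seq_along(geoms),
                name = sprintf("PA_%02d", seq_along(geoms)),
                geometry = geoms)
  } else {
    polygon_set(id = integer(), name = character(), geometry = list())
  }
  attr(pas, "covered_cells") <- achieved
  pas
}

#' Generate a complete synthetic landscape
#'
#' Runs every generator stage and derives the truth layers the end-to-end
#' checks compare against: per-species true suitability, the true richness
#' surface, its four-class map, the true species-hotspot mask, and PAs
#' placed to cover `pa_fraction` of it.
#'
#' @param scenario a [landscape_scenario()]
#' @return list with `scenario`, `grid`, `covariates`, `lulc`,
#'   `occurrences`, `truth` (list: `suitability`, `richness`, `classified`,
#'   `hotspots`), `pas`, `pa_raster`
#' @export
simulate_landscape <- function(scenario = landscape_scenario()) {
  g <- scenario_grid(scenario)
  covs <- gen_covariates(scenario)
  lulc <- gen_lulc(scenario, covs)
  occ <- gen_occurrences(scenario, covs)
  truth_maps <- attr(occ, "truth")
  richness <- aggregate_richness(truth_maps)
  classified <- classify_suitability(richness)
  # true hotspot mask mirrors the analysis rule: per-species binarization at
  # the 10% training-presence threshold, then the union across species
  sp <- split(occ, occ$species)
  hotspots <- hotspot_union(lapply(names(truth_maps), function(s) {
    binarize_suitability(truth_maps[[s]], sp[[s]])
  }))
  pas <- gen_pas(scenario, hotspots)
  pa_raster <- if (nrow(pas)) rasterize_polygons(pas, g) else
    suppressWarnings(rasterize_polygons(pas, g))
  list(scenario = scenario, grid = g, covariates = covs, lulc = lulc,
       occurrences = occ,
       truth = list(suitability = truth_maps, richness = richness,
                    classified = classified, hotspots = hotspots),
       pas = pas, pa_raster = pa_raster)
}
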