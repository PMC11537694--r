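#' Priority-map legend
#'
#' The eight mutually exclusive categories of the conservation-priority
#' overlay: outside protected areas (PAs), cells flagged by the
#' habitat-quality model only are "priority", by the species model only
#' "key priority", and by both models "priority outside core"; the same
#' three tiers repeat inside PAs, and cells inside a PA flagged by neither
#' model are "over-protected".
#'
#' @return named integer vector mapping label -> code
#' @export
priority_legend <- function() {
  c(none = 0L,
    priority_outside_pa = 1L,       # habitat-quality model only, outside PA
    key_priority_outside_pa = 2L,   # species model only, outside PA
    priority_outside_core = 3L,     # both models, outside PA
    priority_inside_pa = 4L,        # habitat-quality model only, inside PA
    key_priority_inside_pa = 5L,    # species model only, inside PA
    priority_inside_core = 6L,      # both models, inside PA (core zone)
    over_protected = 7L)            # neither model, inside PA
}

#' Exclusion mask of unsuitable land
#'
#' Cell-wise union of excluded land-use classes (city areas, capital
#' farmland, ...) and a road-corridor buffer; excluded cells are forced to
#' the unsuitable class downstream.
#'
#' @param lulc `pm_categorical` land-use layer
#' @param excluded_codes land-use codes to exclude (unknown codes warn and
#'   are ignored)
#' @param road_mask optional binary layer (e.g. [buffer_mask()] output)
#' @return binary `pm_categorical` layer (1 = excluded)
#' @export
exclusion_mask <- function(lulc, excluded_codes = integer(), road_mask = NULL) {
  present <- unique(lulc$values[!is.na(lulc$values)])
  unknown <- setdiff(excluded_codes, present)
  if (length(unknown)) {
    warning("excluded code(s) absent from land-use map, ignored: ",
            paste(unknown, collapse = ", "))
  }
  m <- matrix(0, lulc$grid$n_rows, lulc$grid$n_cols)
  m[!is.na(lulc$values) & lulc$values %in% excluded_codes] <- 1
  if (!is.null(road_mask)) {
    check_same_grid(lulc, road_mask)
    m[!is.na(road_mask$values) & road_mask$values == 1] <- 1
  }
  categorical_layer(m, lulc$grid)
}

#' Classify a richness surface into four suitability classes
#'
#' Codes 0 unsuitable (`value < t1`), 1 less suitable (`t1 <= value < t2`),
#' 2 moderately suitable (`t2 <= value <= t3`), 3 highly suitable
#' (`value > t3`), default thresholds (0.25, 0.55, 0.90). Lower boundaries
#' belong to the class above; the top class is strictly above `t3`. Masked
#' cells are forced to unsuitable.
#'
#' @param richness `pm_continuous` layer with values in [0, 1]
#' @param thresholds strictly increasing numeric triple in (0, 1)
#' @param mask optional binary exclusion layer (1 = force unsuitable)
#' @return `pm_categorical` layer with codes 0:3
#' @export
classify_suitability <- function(richness, thresholds = c(0.25, 0.55, 0.90),
                                 mask = NULL) {
  abort_if(length(thresholds) != 3 || any(diff(thresholds) <= 0) ||
             any(thresholds <= 0 | thresholds >= 1),
           "thresholds must be three strictly increasing values in (0, 1)")
  v <- richness$values
  abort_if(any(v < 0 | v > 1, na.rm = TRUE), "richness values must lie in [0, 1]")
  cls <- matrix(NA_real_, richness$grid$n_rows, richness$grid$n_cols)
  ok <- !is.na(v)
  cls[ok] <- 0
  cls[ok & v >= thresholds[1]] <- 1
  cls[ok & v >= thresholds[2]] <- 2
  cls[ok & v > thresholds[3]] <- 3
  if (!is.null(mask)) {
    check_same_grid(richness, mask)
    cls[ok & !is.na(mask$values) & mask$values == 1] <- 0
  }
  categorical_layer(cls, richness$grid,
                    legend = c(unsuitable = 0L, less_suitable = 1L,
                               moderately_suitable = 2L, highly_suitable = 3L))
}

#' Species-distribution hotspots from a classified suitability map
#'
#' By default all three suitable classes count as hotspot (matching the
#' study's accounting of suitable area); restrict to the moderate and high
#' classes with `classes = c(2, 3)`.
#'
#' @param classified output of [classify_suitability()]
#' @param classes codes counting as hotspot (default 1:3)
#' @return binary `pm_categorical` layer
#' @export
species_hotspots <- function(classified, classes = c(1L, 2L, 3L)) {
  v <- classified$values
  out <- matrix(NA_real_, classified$grid$n_rows, classified$grid$n_cols)
  ok <- !is.na(v)
  out[ok] <- as.numeric(v[ok] %in% classes)
  categorical_layer(out, classified$grid)
}

#' Overlay model hotspots and protected areas into priority tiers
#'
#' Assigns every valid cell one category of [priority_legend()] from the
#' species-model hotspot flag, the habitat-quality hotspot flag, and PA
#' membership (PA raster code != 0). The core zone is by construction the
#' intersection of the two models.
#'
#' @param maxent_hot binary species-model hotspot layer
#' @param invest_hot binary habitat-quality hotspot layer
#' @param pa `pm_categorical` rasterized protected areas (0 = outside)
#' @return a `pm_categorical` priority map with the [priority_legend()]
#' @export
overlay_priorities <- function(maxent_hot, invest_hot, pa) {
  check_same_grid(maxent_hot, invest_hot, pa)
  me <- maxent_hot$values == 1
  iv <- invest_hot$values == 1
  inside <- !is.na(pa$values) & pa$values != 0
  ok <- !is.na(maxent_hot$values) & !is.na(invest_hot$values)
  code <- matrix(NA_real_, pa$grid$n_rows, pa$grid$n_cols)
  code[ok] <- 0
  code[ok & !inside & iv & !me] <- 1
  code[ok & !inside & me & !iv] <- 2
  code[ok & !inside & me & iv] <- 3
  code[ok & inside & iv & !me] <- 4
  code[ok & inside & me & !iv] <- 5
  code[ok & inside & me & iv] <- 6
  code[ok & inside & !me & !iv] <- 7
  categorical_layer(code, pa$grid, legend = priority_legend())
}

#' Area accounting with printed-style percentages
#'
#' Computes category areas as `cell count * cell_size^2` (reported in km²)
#' and percentages of a named reference total, rounded half-up to 2
#' decimals. Also usable directly on a named vector of areas (in km²) to
#' reproduce printed worked examples without rasters.
#'
#' @param x a `pm_categorical` layer, or a named numeric vector of areas in
#'   km²
#' @param reference single named reference area in km² (> 0); for layers it
#'   defaults to the total valid area
#' @param ... unused
#' @return tibble with `category`, `area_km2`, `reference`, `reference_km2`,
#'   `pct`
#' @export
area_report <- function(x, reference = NULL, ...) UseMethod("area_report")

#' @export
area_report.pm_categorical <- function(x, reference = NULL, ...) {
  counts <- table(x$values[!is.na(x$values)])
  areas <- as.numeric(counts) * x$grid$cell_size^2 / 1e6
  labels <- names(counts)
  if (!is.null(x$legend)) {
    lab <- names(x$legend)[match(as.numeric(names(counts)), x$legend)]
    labels <- ifelse(is.na(lab), names(counts), lab)
  }
  if (is.null(reference)) {
    reference <- c(total = sum(!is.na(x$values)) * x$grid$cell_size^2 / 1e6)
  }
  area_report(stats::setNames(areas, labels), reference = reference)
}

#' @export
area_report.numeric <- function(x, reference, ...) {
  abort_if(is.null(names(x)), "areas must be named")
  abort_if(length(reference) != 1 || is.null(names(reference)),
           "reference must be a single named area")
  abort_if(reference <= 0, "reference area must be > 0")
  ref_name <- names(reference)
  ref_km2 <- unname(reference)
  tibble::tibble(
    category = names(x),
    area_km2 = unname(x),
    reference = ref_name,
    reference_km2 = ref_km2,
    pct = round_half_up(100 * unname(x) / ref_km2, 2)
  )
}

#' Agreement between two binary hotspot maps
#'
#' No single agreement definition is privileged; the report carries the
#' Jaccard index (intersection over union), the overlap coefficient
#' (intersection over the smaller map), and the intersection's share of
#' each map. All values are percentages rounded half-up to 2 decimals.
#'
#' @param a,b binary `pm_categorical` layers on one grid
#' @return tibble with `definition` and `pct`; zero rows (with a warning)
#'   when both maps are empty
#' @export
model_agreement <- function(a, b) {
  check_same_grid(a, b)
  ok <- !is.na(a$values) & !is.na(b$values)
  A <- ok & a$values == 1
  B <- ok & b$values == 1
  nA <- sum(A); nB <- sum(B); nI <- sum(A & B); nU <- sum(A | B)
  if (nU == 0) {
    warning("both hotspot maps are empty: agreement undefined")
    return(tibble::tibble(definition = character(), pct = numeric()))
  }
  tibble::tibble(
    definition = c("jaccard", "overlap_coefficient", "share_of_a", "share_of_b"),
    pct = round_half_up(100 * c(
      nI / nU,
      if (min(nA, nB) > 0) nI / min(nA, nB) else NA_real_,
      if (nA > 0) nI / nA else NA_real_,
      if (nB > 0) nI / nB else NA_real_), 2)
  )
}

#' Per-protected-area priority proportions and action bins
#'
#' For each PA, the proportion `p` of its cells carrying an inside-PA
#' priority tier (codes 4-6 of [priority_legend()]), binned at 25% and 75%
#' with boundaries assigned to the higher bin: `p >= 0.75` -> `">75%"`,
#' `0.25 <= p < 0.75` -> `"25-75%"`, else `"<25%"`. PAs covering no cell on
#' the grid are flagged and left unbinned.
#'
#' @param priority a priority map from [overlay_priorities()]
#' @param pa_raster `pm_categorical` rasterized PAs (cell value = PA id)
#' @param pa_names optional named vector mapping id -> name
#' @param all_ids optional vector of every PA id that should exist (e.g.
#'   from the polygon set), so PAs rasterizing to zero cells are flagged
#' @return tibble with `pa_id`, `n_cells`, `n_priority`, `proportion`, `bin`
#' @export
pa_actions <- function(priority, pa_raster, pa_names = NULL, all_ids = NULL) {
  check_same_grid(priority, pa_raster)
  ids <- sort(unique(c(
    pa_raster$values[!is.na(pa_raster$values) & pa_raster$values != 0],
    all_ids)))
  rows <- lapply(ids, function(id) {
    cells <- !is.na(pa_raster$values) & pa_raster$values == id
    n <- sum(cells)
    npr <- sum(cells & !is.na(priority$values) & priority$values %in% 4:6)
    p <- if (n > 0) npr / n else NA_real_
    tibble::tibble(pa_id = as.integer(id), n_cells = n, n_priority = npr,
                   proportion = p,
                   bin = if (n == 0) NA_character_
                         else if (p >= 0.75) ">75%"
                         else if (p >= 0.25) "25-75%"
                         else "<25%")
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$n_cells == 0)) {
    warning("PA(s) covering no grid cell excluded from binning: ",
            paste(out$pa_id[out$n_cells == 0], collapse = ", "))
  }
  if (!is.null(pa_names)) out$name <- unname(pa_names[as.character(out$pa_id)])
  out
}

#' Conservation-gap area of a priority map
#'
#' Model-identified hotspot cells lying outside every PA: priority codes
#' 1-3.
#'
#' @param priority a priority map from [overlay_priorities()]
#' @param unit `"km2"` or `"cells"`
#' @return scalar gap area
#' @export
gap_area <- function(priority, unit = c("km2", "cells")) {
  unit <- match.arg(unit)
  n <- sum(!is.na(priority$values) & priority$values %in% 1:3)
  if (unit == "cells") n else n * priority$grid$cell_size^2 / 1e6
}
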