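#' Read a single-band raster from an ESRI ASCII grid file
#'
#' The ASCII grid (`.asc`) format is the plain-text interchange raster format
#' understood by every desktop GIS; the six-line header carries the
#' geotransform and nodata sentinel. Nodata cells become `NA`.
#'
#' @param path path to an `.asc` file
#' @param kind `"continuous"` (default) or `"categorical"`
#' @param legend optional legend passed to [categorical_layer()]
#' @return a `pm_continuous` or `pm_categorical` layer with its grid
#'   populated from the header
#' @export
read_raster <- function(path, kind = c("continuous", "categorical"), legend = NULL) {
  kind <- match.arg(kind)
  abort_if(!file.exists(path), paste0("raster file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  abort_if(length(lines) < 6, paste0("not an ASCII grid (header too short): ", path))
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    abort_if(length(parts) != 2, paste0("malformed header line: ", lines[i]))
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing <- setdiff(need, names(hdr))
  abort_if(length(missing) > 0,
           paste0("ASCII grid header missing: ", paste(missing, collapse = ", ")))
  nodata <- hdr$nodata_value %||% -9999
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  abort_if(length(body) != hdr$nrows * hdr$ncols,
           sprintf("expected %d values, found %d (multi-band or truncated input?)",
                   hdr$nrows * hdr$ncols, length(body)))
  vals <- matrix(body, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  vals[vals == nodata] <- NA
  g <- grid_spec(hdr$nrows, hdr$ncols, hdr$cellsize,
                 origin_x = hdr$xllcorner,
                 origin_y = hdr$yllcorner + hdr$nrows * hdr$cellsize,
                 nodata = nodata)
  if (kind == "continuous") continuous_layer(vals, g)
  else categorical_layer(vals, g, legend = legend)
}

#' Write a layer to an ESRI ASCII grid file
#'
#' Round-trips exactly with [read_raster()]: values, grid, and nodata are
#' preserved.
#'
#' @param layer a `pm_layer`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_raster <- function(layer, path) {
  g <- layer$grid
  vals <- layer$values
  vals[is.na(vals)] <- g$nodata
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", g$origin_y - g$n_rows * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", g$nodata)
  )
  rows <- apply(vals, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Polygon sets
#'
#' A `pm_polygons` object is a tibble with one row per feature: integer `id`,
#' character `name`, and a `geometry` list-column of rings, each ring a
#' closed two-column (x, y) matrix whose first and last vertex coincide.
#' Extra columns are carried as attributes. Interior rings (holes) are
#' honoured through the even-odd rule in point-in-polygon tests.
#'
#' @param id integer feature ids (unique)
#' @param name character feature names
#' @param geometry list of lists of closed ring matrices
#' @param ... further attribute columns, recycled tibble-style
#' @return a `pm_polygons` tibble
#' @export
polygon_set <- function(id, name = as.character(id), geometry, ...) {
  abort_if(anyDuplicated(id) > 0, "polygon ids must be unique")
  geometry <- lapply(geometry, function(rings) {
    if (is.matrix(rings)) rings <- list(rings)
    lapply(rings, function(r) {
      r <- as.matrix(r)
      abort_if(nrow(r) < 4, "polygon ring needs at least 3 distinct vertices")
      if (!isTRUE(all.equal(r[1, ], r[nrow(r), ]))) r <- rbind(r, r[1, ])
      unname(r)
    })
  })
  out <- tibble::tibble(id = as.integer(id), name = as.character(name),
                        geometry = geometry, ...)
  class(out) <- c("pm_polygons", class(out))
  out
}

#' Make an axis-aligned rectangular polygon ring
#'
#' @param xmin,ymin,xmax,ymax rectangle bounds
#' @return a closed 5x2 ring matrix
#' @export
rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin, xmin), c(ymin, ymin, ymax, ymax, ymin))
}

#' Read / write polygons as GeoJSON
#'
#' Supports `Polygon` and `MultiPolygon` features; feature properties `id`
#' and `name` are used when present, otherwise ids follow file order.
#'
#' @param path a GeoJSON file
#' @return a `pm_polygons` tibble
#' @export
read_polygons <- function(path) {
  abort_if(!file.exists(path), paste0("GeoJSON file not found: ", path))
  gj <- jsonlite::read_json(path)
  abort_if(!identical(gj$type, "FeatureCollection"), "expected a GeoJSON FeatureCollection")
  feats <- gj$features
  ring_mat <- function(ring) do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  ids <- integer(length(feats)); names_ <- character(length(feats))
  geoms <- vector("list", length(feats))
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    ids[k] <- as.integer(f$properties$id %||% k)
    names_[k] <- as.character(f$properties$name %||% paste0("feature_", ids[k]))
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(poly) lapply(poly, ring_mat)),
                            recursive = FALSE),
      stop("unsupported GeoJSON geometry type: ", geom$type, call. = FALSE)
    )
    geoms[[k]] <- rings
  }
  polygon_set(id = ids, name = names_, geometry = geoms)
}

#' @rdname read_polygons
#' @param polys a `pm_polygons` tibble
#' @return `write_polygons()`: `path`, invisibly
#' @export
write_polygons <- function(polys, path) {
  feats <- lapply(seq_len(nrow(polys)), function(k) {
    rings <- lapply(polys$geometry[[k]], function(r) {
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature",
         properties = list(id = polys$id[k], name = polys$name[k]),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read species occurrence points
#'
#' Expects a CSV with a `species,x,y` header. Rows are kept in file order;
#' that order is the canonical scan order for [thin_occurrences()].
#'
#' @param path CSV path
#' @return tibble with `species` (character), `x`, `y` (double)
#' @export
read_occurrences <- function(path) {
  occ <- readr::read_csv(path, show_col_types = FALSE)
  abort_if(!all(c("species", "x", "y") %in% names(occ)),
           "occurrence CSV must have columns species, x, y")
  tibble::tibble(species = as.character(occ$species),
                 x = as.numeric(occ$x), y = as.numeric(occ$y))
}
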