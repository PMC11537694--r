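#' Define a raster grid
#'
#' A `pm_grid` describes the georeferencing shared by every layer in an
#' analysis: cell size (map units, assumed equal-area projected), the outer
#' corner of the top-left cell, and the nodata sentinel used on disk.
#' Internally, nodata cells are stored as `NA`; the sentinel only appears in
#' file I/O. Cell (1,1) is the top-left cell; the center of cell (row, col)
#' is at `origin + ((col - 0.5), -(row - 0.5)) * cell_size`.
#'
#' @param n_rows,n_cols grid dimensions (positive integers)
#' @param cell_size cell edge length in map units (> 0); cell area is
#'   `cell_size^2`
#' @param origin_x,origin_y coordinates of the outer corner of the top-left
#'   cell (x increases east, y increases north)
#' @param nodata sentinel value written for missing cells
#' @return an object of class `pm_grid`
#' @export
grid_spec <- function(n_rows, n_cols, cell_size, origin_x = 0, origin_y = n_rows * cell_size,
                      nodata = -9999) {
  abort_if(cell_size <= 0, "cell_size must be > 0")
  abort_if(n_rows < 1 || n_cols < 1, "grid must have at least one cell")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         nodata = nodata),
    class = "pm_grid"
  )
}

#' @export
print.pm_grid <- function(x, ...) {
  cat(sprintf("<pm_grid> %d x %d cells, cell size %g, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' @export
format.pm_grid <- function(x, ...) {
  sprintf("%dx%d @ %g", x$n_rows, x$n_cols, x$cell_size)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("n_rows", "n_cols", "cell_size", "origin_x", "origin_y")],
                   b[c("n_rows", "n_cols", "cell_size", "origin_x", "origin_y")]))
}

#' Check that layers share one grid
#'
#' Cross-layer operations require identical grids; a mismatch is a hard
#' error, never a silent resample.
#'
#' @param ... layers (`pm_layer` objects)
#' @return the shared `pm_grid`, invisibly usable
#' @export
check_same_grid <- function(...) {
  layers <- list(...)
  g <- layers[[1]]$grid
  for (l in layers[-1]) {
    abort_if(!same_grid(g, l$grid),
             "layers do not share an identical grid; resample explicitly before combining")
  }
  g
}

new_layer <- function(values, grid, kind, legend = NULL) {
  abort_if(!inherits(grid, "pm_grid"), "grid must be a pm_grid")
  values <- matrix(as.numeric(values), nrow = grid$n_rows, ncol = grid$n_cols)
  abort_if(nrow(values) != grid$n_rows || ncol(values) != grid$n_cols,
           "values shape does not match grid")
  structure(list(grid = grid, values = values, legend = legend),
            class = c(paste0("pm_", kind), "pm_layer"))
}

#' Construct a continuous raster layer
#'
#' @param values numeric matrix (`n_rows` x `n_cols`), `NA` for nodata
#' @param grid a [grid_spec()]
#' @return a `pm_continuous` layer
#' @export
continuous_layer <- function(values, grid) {
  abort_if(any(is.infinite(values)), "continuous layer must be finite where not nodata")
  new_layer(values, grid, "continuous")
}

#' Construct a categorical raster layer
#'
#' @param values integer matrix of class codes, `NA` for nodata
#' @param grid a [grid_spec()]
#' @param legend optional named integer vector declaring the legend
#'   (names are class labels, values are codes)
#' @return a `pm_categorical` layer
#' @export
categorical_layer <- function(values, grid, legend = NULL) {
  v <- values[!is.na(values)]
  abort_if(any(v != round(v)), "categorical layer codes must be integers")
  if (!is.null(legend) && length(v)) {
    extra <- setdiff(unique(v), unname(legend))
    abort_if(length(extra) > 0,
             paste0("codes not in declared legend: ", paste(extra, collapse = ", ")))
  }
  new_layer(values, grid, "categorical", legend = legend)
}

#' @export
print.pm_layer <- function(x, ...) {
  kind <- if (inherits(x, "pm_continuous")) "continuous" else "categorical"
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<pm_%s> %s | %d valid cells", kind, format(x$grid), length(v)))
  if (length(v)) {
    if (kind == "continuous") cat(sprintf(" | range [%.4g, %.4g]", min(v), max(v)))
    else cat(sprintf(" | %d classes", length(unique(v))))
  }
  cat("\n")
  invisible(x)
}

#' Cell-center coordinates of every grid cell
#'
#' @param grid a [grid_spec()]
#' @return tibble with `row`, `col`, `x`, `y` (one row per cell, column-major
#'   cell order so row index matches R matrix indexing via `cell`)
#' @export
cell_centers <- function(grid) {
  rows <- rep(seq_len(grid$n_rows), times = grid$n_cols)
  cols <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  tibble::tibble(
    cell = seq_len(grid$n_rows * grid$n_cols),
    row = rows, col = cols,
    x = grid$origin_x + (cols - 0.5) * grid$cell_size,
    y = grid$origin_y - (rows - 0.5) * grid$cell_size
  )
}

# map point coordinates to column-major cell indices (NA outside grid)
points_to_cells <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  ifelse(ok, (col - 1L) * grid$n_rows + row, NA_integer_)
}

#' @rdname cell_centers
#' @param x a `pm_layer`
#' @param ... unused
#' @return for `as_tibble()`: tibble with `x`, `y`, `row`, `col`, `value`
#'   (valid cells only)
#' @export
as_tibble.pm_layer <- function(x, ...) {
  cc <- cell_centers(x$grid)
  cc$value <- as.vector(x$values)
  cc[!is.na(cc$value), c("x", "y", "row", "col", "value")]
}

#' Total valid (non-nodata) area of a layer
#'
#' @param layer a `pm_layer`
#' @param unit `"map"` for squared map units or `"km2"`
#' @return scalar area, `cell_count * cell_size^2`
#' @export
layer_area <- function(layer, unit = c("km2", "map")) {
  unit <- match.arg(unit)
  a <- sum(!is.na(layer$values)) * layer$grid$cell_size^2
  if (unit == "km2") a / 1e6 else a
}
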