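# even-odd ray-casting point-in-polygon over one or more rings, vectorized
# over points; a point inside an odd number of rings is inside the feature
points_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (r in rings) {
    n <- nrow(r) - 1  # last vertex repeats the first
    xs <- r[, 1]; ys <- r[, 2]
    hit <- rep(FALSE, length(px))
    for (i in seq_len(n)) {
      x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[i + 1]; y2 <- ys[i + 1]
      crosses <- (y1 > py) != (y2 > py)
      if (any(crosses)) {
        xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
        hit <- xor(hit, crosses & px < xint)
      }
    }
    inside <- xor(inside, hit)
  }
  inside
}

#' Rasterize polygons onto a grid
#'
#' A cell is labelled with a polygon's id when its center falls inside the
#' polygon (even-odd rule); cells covered by no polygon get 0. Polygons are
#' burned in order, so where features overlap the later polygon wins.
#'
#' @param polys a `pm_polygons` tibble
#' @param grid the target [grid_spec()]
#' @return a `pm_categorical` layer of polygon ids (0 = background)
#' @export
rasterize_polygons <- function(polys, grid) {
  vals <- matrix(0, grid$n_rows, grid$n_cols)
  if (nrow(polys) == 0) {
    warning("empty polygon set: rasterization is all zeros")
    return(categorical_layer(vals, grid))
  }
  cc <- cell_centers(grid)
  for (k in seq_len(nrow(polys))) {
    inside <- points_in_rings(cc$x, cc$y, polys$geometry[[k]])
    vals[cbind(cc$row[inside], cc$col[inside])] <- polys$id[k]
  }
  categorical_layer(vals, grid)
}

#' Euclidean buffer mask around target cells
#'
#' Marks every cell whose center lies within `radius` (map units, Euclidean
#' distance between cell centers) of the center of any cell holding one of
#' `target_codes`. Implements e.g. a 1-km corridor around road cells.
#'
#' @param layer a `pm_categorical` layer
#' @param target_codes integer codes defining the source cells
#' @param radius buffer radius in map units (>= 0); `radius = 0` returns the
#'   target cells themselves
#' @return a binary `pm_categorical` layer (1 inside the buffer)
#' @export
buffer_mask <- function(layer, target_codes, radius) {
  abort_if(radius < 0, "radius must be >= 0")
  g <- layer$grid
  src <- !is.na(layer$values) & layer$values %in% target_codes
  out <- matrix(0, g$n_rows, g$n_cols)
  if (!any(src)) return(categorical_layer(out, g))
  # dilation by the set of integer cell offsets within the radius
  rmax <- floor(radius / g$cell_size)
  offs <- expand.grid(dr = -rmax:rmax, dc = -rmax:rmax)
  offs <- offs[(offs$dr^2 + offs$dc^2) * g$cell_size^2 <= radius^2, , drop = FALSE]
  idx <- which(src, arr.ind = TRUE)
  for (k in seq_len(nrow(offs))) {
    rr <- idx[, 1] + offs$dr[k]
    cc <- idx[, 2] + offs$dc[k]
    ok <- rr >= 1 & rr <= g$n_rows & cc >= 1 & cc <= g$n_cols
    out[cbind(rr[ok], cc[ok])] <- 1
  }
  categorical_layer(out, g)
}
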