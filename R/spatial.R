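## Half-degree gridding and loess surface interpolation of per-plot metrics.

#' Grid specification
#'
#' Regular lon/lat grid anchored at integer multiples of the cell size;
#' cells are half-open `[edge, edge + cell_size)` and indexed by
#' `floor(coordinate / cell_size)`.
#'
#' @param cell_size cell size in decimal degrees (default 0.5, about
#'   55 x 55 km at the equator).
#' @param bbox numeric vector `c(lon_min, lon_max, lat_min, lat_max)`.
#' @return object of class `"grid_spec"`.
#' @export
grid_spec <- function(cell_size = 0.5, bbox) {
  stopifnot(cell_size > 0, length(bbox) == 4,
            bbox[2] > bbox[1], bbox[4] > bbox[3])
  structure(list(cell_size = cell_size, bbox = as.numeric(bbox)),
            class = "grid_spec")
}

## Default spec: expand the plot extent outward to cell edges.
grid_spec_from_coords <- function(coords, cell_size = 0.5) {
  cs <- cell_size
  grid_spec(cs, c(floor(min(coords$lon) / cs) * cs,
                  ceiling(max(coords$lon) / cs) * cs,
                  floor(min(coords$lat) / cs) * cs,
                  ceiling(max(coords$lat) / cs) * cs))
}

#' Grid cell index of a coordinate
#'
#' @param lon,lat coordinates in decimal degrees (vectorized).
#' @param spec a [grid_spec()].
#' @return data frame with integer columns `ix`, `iy`.
#' @export
assign_grid_cell <- function(lon, lat, spec) {
  b <- spec$bbox
  if (any(lon < b[1] | lon > b[2] | lat < b[3] | lat > b[4]))
    stop("coordinate outside grid bounding box")
  data.frame(ix = as.integer(floor(lon / spec$cell_size)),
             iy = as.integer(floor(lat / spec$cell_size)))
}

#' Local polynomial (loess) prediction at arbitrary points
#'
#' Fits a loess surface `value ~ lon + lat` with tricube weights over the
#' span-defined nearest-neighbour window and evaluates it at the query
#' points.  Distances are in raw degrees.  If the local degree-2 fit fails
#' (rank-deficient neighbourhoods), the fit falls back to degree 1 and then
#' to a constant surface, recorded in the `fallback` attribute.
#'
#' @param lon,lat,value plot coordinates and metric values.
#' @param qlon,qlat query coordinates.
#' @param span loess span (fraction of points in each local window).
#' @param degree local polynomial degree (1 or 2).
#' @return numeric predictions at the query points.
#' @export
loess_predict <- function(lon, lat, value, qlon, qlat,
                          span = 0.75, degree = 2) {
  stopifnot(degree %in% 1:2, span > 0)
  df <- data.frame(lon = lon, lat = lat, value = value)
  fallback <- "none"
  fit <- NULL
  for (deg in seq(degree, 1)) {
    fit <- tryCatch(
      suppressWarnings(loess(value ~ lon + lat, data = df, span = span,
                             degree = deg, normalize = FALSE,
                             control = loess.control(surface = "direct"))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      if (deg < degree) fallback <- paste0("degree", deg)
      break
    }
  }
  if (is.null(fit)) {
    fallback <- "mean"
    out <- rep(mean(value), length(qlon))
  } else {
    out <- as.numeric(predict(fit, newdata = data.frame(lon = qlon, lat = qlat)))
  }
  attr(out, "fallback") <- fallback
  out
}

#' Interpolate a per-plot metric over the grid
#'
#' Evaluates the loess surface at the centre of every grid cell inside the
#' bounding box.  Cells outside the convex hull of the plots are still
#' predicted (the method extrapolates into unsampled areas) but flagged.
#'
#' @param values named numeric vector of per-plot metric values.
#' @param coords data frame with `lon`, `lat`, rownames = plot IDs.
#' @param spec a [grid_spec()]; derived from the plot extent when `NULL`.
#' @param span,degree loess parameters (defaults 0.75 and 2).
#' @param metric label stored with the surface.
#' @return object of class `"grid_surface"`: data frame with `cell_ix`,
#'   `cell_iy`, `lon_center`, `lat_center`, `value`, `extrapolated`;
#'   attributes `metric`, `span`, `degree`, `spec`.
#' @export
interpolate_metric_surface <- function(values, coords, spec = NULL,
                                       span = 0.75, degree = 2,
                                       metric = "metric") {
  coords <- coords[names(values), , drop = FALSE]
  if (anyNA(coords$lon)) stop("coordinates missing for some plots")
  if (length(values) < 10) stop("need at least 10 plots to fit a surface")
  if (is.null(spec)) spec <- grid_spec_from_coords(coords)
  cs <- spec$cell_size
  b <- spec$bbox
  ix <- seq(floor(b[1] / cs), ceiling(b[2] / cs) - 1L)
  iy <- seq(floor(b[3] / cs), ceiling(b[4] / cs) - 1L)
  cells <- expand.grid(cell_ix = ix, cell_iy = iy)
  cells$lon_center <- (cells$cell_ix + 0.5) * cs
  cells$lat_center <- (cells$cell_iy + 0.5) * cs
  pred <- loess_predict(coords$lon, coords$lat, values,
                        cells$lon_center, cells$lat_center,
                        span = span, degree = degree)
  hull <- chull(coords$lon, coords$lat)
  inside <- mgcv::in.out(cbind(coords$lon[c(hull, hull[1])],
                               coords$lat[c(hull, hull[1])]),
                         cbind(cells$lon_center, cells$lat_center))
  out <- data.frame(cells[, c("cell_ix", "cell_iy", "lon_center", "lat_center")],
                    value = as.numeric(pred), extrapolated = !inside)
  structure(out, metric = metric, span = span, degree = degree, spec = spec,
            fallback = attr(pred, "fallback"),
            class = c("grid_surface", "data.frame"))
}

#' Write a grid surface to long CSV
#' @param surface a `"grid_surface"`.
#' @param file output path.
#' @export
write_surface <- function(surface, file) {
  write.csv(as.data.frame(surface), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
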