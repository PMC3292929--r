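#' Accumulate least-cost travel time to the nearest facility
#'
#' Multi-source Dijkstra on the 8-connected cell graph of the friction
#' surface. The time of an edge between adjacent cells is
#' `60 * d / v` minutes with `d` the centre-to-centre distance in km
#' (cellSize, or cellSize * sqrt(2) diagonally) and `v` the harmonic
#' combination of the two cells' effective speeds: half the edge length is
#' traversed at each endpoint's speed. A cell's effective speed is its
#' friction speed times the slope multiplier of the edge
#' ([walkingSpeedMultiplier()], from the DEM) for WALKING and CYCLING
#' cells, and the unmodified friction speed for MOTORIZED cells. Barrier
#' cells are excluded from the graph; cells not connected to any facility
#' get `Inf`. Allocation ties are broken towards the lowest facility id.
#'
#' @param friction a [FrictionSurface-class]
#' @param facilities data.frame with columns `id` (positive integer), `x`,
#'   `y` (planar metres)
#' @param dem optional [GridRaster-class] of elevation in metres on the
#'   same grid; `NULL` means flat terrain (no slope correction)
#' @return list with elements `minutes` (a [TravelTimeSurface-class]) and
#'   `allocation` (an [AllocationSurface-class])
#' @examples
#' g <- GridSpec(5, 5)
#' fr <- buildFrictionSurface(GridRaster(4, g)) # uniform shrub, 5 km/h
#' fac <- data.frame(id = 1, x = 2500, y = 2500)
#' tt <- accumulateCost(fr, fac)
#' gridValues(tt$minutes)[3, 3] # 0 at the facility
#' @export
accumulateCost <- function(friction, facilities, dem = NULL) {
  if (nrow(facilities) < 1L) stop("at least one facility is required")
  if (!is.null(dem)) stop_if_grid_mismatch(friction@spec, dem@spec,
                                           what = "friction and DEM")
  spec <- friction@spec
  cells <- cellFromXY(spec, facilities$x, facilities$y)
  res <- .grid_dijkstra(friction@speed, friction@mode,
                        if (is.null(dem)) NULL else dem@values,
                        spec@cellSize, cells - 1L,
                        as.integer(facilities$id))
  list(minutes = new("TravelTimeSurface", values = res$minutes, spec = spec),
       allocation = new("AllocationSurface",
                        values = res$allocation, spec = spec))
}

#' Extract travel times at point locations
#'
#' Returns the value of the cell containing each point; points in
#' unreached cells return `Inf`, points outside the grid are an error.
#'
#' @param surface a [TravelTimeSurface-class] (or any [GridRaster-class])
#' @param points data.frame with columns `x`, `y` in planar metres
#' @return numeric vector of minutes, one per point
#' @export
sampleTravelTime <- function(surface, points) {
  cells <- cellFromXY(surface@spec, points$x, points$y)
  surface@values[cells]
}

#' Straight-line distance to the nearest facility
#'
#' Planar Euclidean distance in km, the simpler access measure the
#' travel-time surface is compared against.
#'
#' @param points data.frame with columns `x`, `y` (metres)
#' @param facilities data.frame with columns `x`, `y` (metres)
#' @return numeric vector of km, one per point
#' @export
euclideanNearest <- function(points, facilities) {
  if (nrow(facilities) < 1L) stop("at least one facility is required")
  dx <- outer(points$x, facilities$x, "-")
  dy <- outer(points$y, facilities$y, "-")
  apply(sqrt(dx^2 + dy^2), 1, min) / 1000
}

#' Pearson correlation between two access measures
#'
#' Thin wrapper over [stats::cor()] used to compare modelled travel times
#' with straight-line distances; non-finite pairs are dropped.
#'
#' @param x,y numeric vectors of equal length
#' @return correlation coefficient in `[-1, 1]`
#' @export
pearsonR <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  cor(x[ok], y[ok], method = "pearson")
}
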