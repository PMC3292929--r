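#' Cells traversed by a polyline
#'
#' Supercover grid traversal: a cell is returned whenever the segment
#' passes through it ("all touched" convention), so rasterized lines are
#' gap-free. Vertices outside the grid extent are an error.
#'
#' @param spec a [GridSpec-class]
#' @param coords two-column matrix of planar vertex coordinates (metres)
#' @return integer matrix with columns `row`, `col` (unique cells, in
#'   traversal order)
#' @export
lineCells <- function(spec, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("a polyline needs at least 2 vertices")
  out <- list()
  for (i in seq_len(nrow(coords) - 1L)) {
    out[[i]] <- segment_cells(spec, coords[i, 1], coords[i, 2],
                              coords[i + 1, 1], coords[i + 1, 2])
  }
  cells <- do.call(rbind, out)
  cells[!duplicated(cells), , drop = FALSE]
}

# Amanatides-Woo voxel traversal of one segment, in cell units
segment_cells <- function(spec, x0, y0, x1, y1) {
  cs <- spec@cellSize
  gx0 <- (x0 - spec@originX) / cs; gy0 <- (y0 - spec@originY) / cs
  gx1 <- (x1 - spec@originX) / cs; gy1 <- (y1 - spec@originY) / cs
  eps <- 1e-12
  cx <- min(max(floor(gx0), 0), spec@ncols - 1)
  cy <- min(max(floor(gy0), 0), spec@nrows - 1)
  ex <- min(max(floor(gx1), 0), spec@ncols - 1)
  ey <- min(max(floor(gy1), 0), spec@nrows - 1)
  dx <- gx1 - gx0; dy <- gy1 - gy0
  stepx <- sign(dx); stepy <- sign(dy)
  tmaxx <- if (abs(dx) < eps) Inf else
    ((cx + (stepx > 0)) - gx0) / dx
  tmaxy <- if (abs(dy) < eps) Inf else
    ((cy + (stepy > 0)) - gy0) / dy
  tdx <- if (abs(dx) < eps) Inf else abs(1 / dx)
  tdy <- if (abs(dy) < eps) Inf else abs(1 / dy)
  cells <- matrix(NA_integer_, nrow = spec@nrows + spec@ncols + 2, ncol = 2)
  k <- 1L
  cells[k, ] <- c(cy, cx)
  while (!(cx == ex && cy == ey) && k < nrow(cells)) {
    if (tmaxx < tmaxy) {
      cx <- cx + stepx; tmaxx <- tmaxx + tdx
    } else {
      cy <- cy + stepy; tmaxy <- tmaxy + tdy
    }
    k <- k + 1L
    cells[k, ] <- c(cy, cx)
  }
  cells <- cells[seq_len(k), , drop = FALSE]
  # convert grid units (origin lower-left) to matrix row/col (row 1 = north)
  out <- cbind(row = spec@nrows - cells[, 1], col = cells[, 2] + 1L)
  keep <- out[, 1] >= 1 & out[, 1] <= spec@nrows &
    out[, 2] >= 1 & out[, 2] <= spec@ncols
  out[keep, , drop = FALSE]
}

#' Build the friction ("cost") surface
#'
#' Combines a land-cover raster with road and river polylines into a
#' per-pixel grid of permissible speeds and transport modes. Each cell takes
#' its land-cover speed unless a road is rasterized through it, in which
#' case the road speed wins (precedence primary > secondary > tertiary).
#' River cells are absolute barriers unless a road crosses them (bridges
#' are assumed wherever road and river rasterize to the same cell). Slope
#' is not baked in here: it is applied per edge during cost accumulation,
#' to human-powered modes only, so the table speeds remain reproducible.
#'
#' @param landcover a [GridRaster-class] of integer legend codes (see
#'   [defaultSpeedTable()] for the legend)
#' @param roads list of road features, each `list(coords = matrix,
#'   class = "primary"|"secondary"|"tertiary")`; may be `NULL`
#' @param rivers list of river features, each `list(coords = matrix)`;
#'   may be `NULL`
#' @param speedTable a speed table data.frame; defaults to
#'   [defaultSpeedTable()]
#' @return a [FrictionSurface-class]
#' @examples
#' g <- GridSpec(10, 10)
#' lc <- GridRaster(4, g) # uniform shrub
#' fr <- buildFrictionSurface(lc)
#' unique(as.vector(frictionSpeed(fr)))
#' @export
buildFrictionSurface <- function(landcover, roads = NULL, rivers = NULL,
                                 speedTable = defaultSpeedTable()) {
  validate_speed_table(speedTable)
  spec <- landcover@spec
  lc <- landcover@values
  lcTab <- speedTable[speedTable$kind == "landcover", ]
  codes <- LANDCOVER_CLASSES[lcTab$class]
  present <- unique(as.vector(lc[!is.na(lc)]))
  unknown <- setdiff(present, codes)
  if (length(unknown))
    stop(sprintf("land-cover class(es) absent from speed table: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  speedLut <- numeric(max(codes)); modeLut <- integer(max(codes))
  speedLut[codes] <- lcTab$speed
  modeLut[codes] <- MODE_LEVELS[lcTab$mode]
  speed <- matrix(speedLut[lc], spec@nrows, spec@ncols)
  mode <- matrix(modeLut[lc], spec@nrows, spec@ncols)

  for (rv in rivers) {
    cells <- lineCells(spec, rv$coords)
    speed[cells] <- 0
    mode[cells] <- MODE_NONE
  }
  roadTab <- speedTable[speedTable$kind == "road", ]
  # rasterize lowest precedence first so primary overwrites secondary etc.
  for (cls in c("tertiary", "secondary", "primary")) {
    row <- roadTab[roadTab$class == cls, ]
    if (nrow(row) == 0) next
    for (rd in roads) {
      if (!identical(rd$class, cls)) next
      cells <- lineCells(spec, rd$coords)
      speed[cells] <- row$speed
      mode[cells] <- MODE_LEVELS[[row$mode]]
    }
  }
  new("FrictionSurface", speed = speed, mode = mode,
      barrier = mode == MODE_NONE, spec = spec)
}
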